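# model frame + registry shared by the architecture tests
cascade_fixture <- function() cached("cascade_fixture", {
  eng <- small_engineered()
  pl <- loscade::fit_pipeline(eng$features, eng$meta)
  frame <- loscade::apply_pipeline(pl, eng$features)
  bundle <- loscade::bin_target_qcut(eng$features$`LOS-DAYS`)
  imp <- loscade::impute_missing(eng$features, eng$meta)
  sc <- rbind(
    loscade::score_features(imp, eng$meta, bundle$los_log, "regression"),
    loscade::score_features(imp, eng$meta, bundle$los_category,
                            "classification"))
  selectable <- eng$meta$name[loscade:::selection_kind(eng$meta) != "skip"]
  registry <- loscade::build_subset_registry(sc, selectable)
  list(frame = frame, registry = registry, pipeline = pl, eng = eng)
})

rf_cls <- function(seed = 3, subset = "FS-1")
  learner_spec("rf_classifier", list(n_trees = 40L), seed = seed,
               feature_subset = subset)
rf_reg <- function(seed = 4, subset = "FS-1")
  learner_spec("rf_regressor", list(n_trees = 40L), seed = seed,
               feature_subset = subset)

test_that("cascade_spec enforces the architecture component counts", {
  expect_error(cascade_spec("avg_vote", regressors = list(rf_reg())),
               class = "loscade_spec_error")
  expect_error(cascade_spec("seq2", regressors = list(rf_reg())),
               class = "loscade_spec_error")
  expect_error(cascade_spec("seq3", classifier = rf_cls(),
                            regressors = list(rf_reg())),
               class = "loscade_spec_error")
  expect_silent(cascade_spec("parallel", classifier = rf_cls(),
                             regressors = list(rf_reg(), rf_reg(5))))
})

test_that("augment_features widens without touching the original block", {
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, paste0("c", 1:5)))
  expect_identical(augment_features(X, matrix(numeric(), 10, 0)), X)
  meta <- matrix(runif(40), 10, 4,
                 dimnames = list(NULL, paste0("CLS-PROB-", 0:3)))
  A <- augment_features(X, meta)
  expect_equal(ncol(A), 9L)
  expect_identical(A[, 1:5], X)
  expect_identical(A[, 6:9], meta)
  expect_error(augment_features(X, meta[1:5, ]),
               class = "loscade_shape_error")
})

test_that("avg_vote prediction is exactly the mean of its components", {
  fx <- cascade_fixture()
  specs <- list(rf_reg(1), learner_spec("xgb_regressor",
                                        list(n_trees = 40L), seed = 2),
                learner_spec("ann_regressor", list(epochs = 8L), seed = 3))
  spec <- cascade_spec("avg_vote", regressors = specs)
  fc <- fit_cascade(spec, fx$frame, fx$registry)
  pred <- predict(fc, fx$frame)
  manual <- sapply(specs, function(s) {
    idx <- subset_columns(fx$frame, fx$registry, s$feature_subset)
    f <- fit_learner(s, fx$frame$X[, idx, drop = FALSE], fx$frame$y_model)
    predict(f, fx$frame$X[, idx, drop = FALSE])
  })
  expect_identical(pred, rowMeans(manual))
  comp <- sapply(fc$components$regressors, function(f)
    predict(f, fx$frame$X[, f$feature_names, drop = FALSE]))
  expect_true(all(pred >= apply(comp, 1, min) - 1e-12))
  expect_true(all(pred <= apply(comp, 1, max) + 1e-12))
})

test_that("seq2 equals the hand-wired fit -> augment -> fit oracle", {
  fx <- cascade_fixture()
  spec <- cascade_spec("seq2", classifier = rf_cls(subset = "FS-1"),
                       regressors = list(rf_reg(subset = "FS-9")))
  fc <- fit_cascade(spec, fx$frame, fx$registry)
  pred <- predict(fc, fx$frame)

  idxc <- subset_columns(fx$frame, fx$registry, "FS-1")
  clf <- fit_learner(rf_cls(subset = "FS-1"),
                     fx$frame$X[, idxc, drop = FALSE], fx$frame$y_class)
  P <- predict(clf, fx$frame$X[, idxc, drop = FALSE], type = "prob")
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  idxr <- subset_columns(fx$frame, fx$registry, "FS-9")
  X1 <- augment_features(fx$frame$X[, idxr, drop = FALSE], P)
  reg <- fit_learner(rf_reg(subset = "FS-9"), X1, fx$frame$y_model)
  expect_identical(pred, predict(reg, X1))
  # structure: regressor consumed its subset plus the 4 probability columns
  expect_equal(length(fc$components$regressors[[1]]$feature_names),
               length(idxr) + 4L)
})

test_that("seq3 feeds Regressor-2 the scalar prediction, not probabilities", {
  fx <- cascade_fixture()
  spec <- cascade_spec("seq3", classifier = rf_cls(),
                       regressors = list(rf_reg(4), rf_reg(5)))
  fc <- fit_cascade(spec, fx$frame, fx$registry)
  pred <- predict(fc, fx$frame)

  idx <- subset_columns(fx$frame, fx$registry, "FS-1")
  Xall <- fx$frame$X[, idx, drop = FALSE]
  clf <- fit_learner(rf_cls(), Xall, fx$frame$y_class)
  P <- predict(clf, Xall, type = "prob")
  r1 <- fit_learner(rf_reg(4), augment_features(Xall, P), fx$frame$y_model)
  p1 <- predict(r1, augment_features(Xall, P))
  X2 <- augment_features(Xall, matrix(p1, ncol = 1,
                                      dimnames = list(NULL, "REG1-PRED")))
  r2 <- fit_learner(rf_reg(5), X2, fx$frame$y_model)
  expect_identical(pred, predict(r2, X2))
  fn2 <- fc$components$regressors[[2]]$feature_names
  expect_equal(length(fn2), length(idx) + 1L)          # width d + 1
  expect_false(any(grepl("^CLS-PROB", fn2)))
})

test_that("parallel cascade equals its oracle and has width d + 5", {
  fx <- cascade_fixture()
  spec <- cascade_spec("parallel", classifier = rf_cls(),
                       regressors = list(rf_reg(4), rf_reg(5)))
  fc <- fit_cascade(spec, fx$frame, fx$registry)
  pred <- predict(fc, fx$frame)

  idx <- subset_columns(fx$frame, fx$registry, "FS-1")
  Xall <- fx$frame$X[, idx, drop = FALSE]
  clf <- fit_learner(rf_cls(), Xall, fx$frame$y_class)
  P <- predict(clf, Xall, type = "prob")
  r1 <- fit_learner(rf_reg(4), Xall, fx$frame$y_model)
  p1 <- predict(r1, Xall)
  X2 <- augment_features(Xall, cbind(P, `REG1-PRED` = p1))
  r2 <- fit_learner(rf_reg(5), X2, fx$frame$y_model)
  expect_identical(pred, predict(r2, X2))
  expect_equal(length(fc$components$regressors[[2]]$feature_names),
               length(idx) + 5L)
})

test_that("cascade predictions are deterministic and inventory-checked", {
  fx <- cascade_fixture()
  spec <- cascade_spec("seq2", classifier = rf_cls(),
                       regressors = list(rf_reg()))
  f1 <- fit_cascade(spec, fx$frame, fx$registry)
  f2 <- fit_cascade(spec, fx$frame, fx$registry)
  expect_identical(predict(f1, fx$frame), predict(f2, fx$frame))
  expect_equal(length(predict(f1, fx$frame)), nrow(fx$frame$X))

  Xbad <- fx$frame$X[, -1]
  err <- tryCatch(predict(f1, Xbad), error = function(e) e)
  expect_s3_class(err, "loscade_shape_error")
  expect_match(conditionMessage(err), colnames(fx$frame$X)[1], fixed = TRUE)

  days <- predict(f1, fx$frame, scale = "days", pipeline = fx$pipeline)
  expect_true(all(days >= 0))
  expect_error(predict(f1, fx$frame, scale = "days"),
               class = "loscade_state_error")
})

test_that("a fitted cascade round-trips through its directory bundle", {
  fx <- cascade_fixture()
  spec <- cascade_spec("seq2", classifier = rf_cls(),
                       regressors = list(rf_reg()))
  fc <- fit_cascade(spec, fx$frame, fx$registry)
  dir <- file.path(withr::local_tempdir(), "bundle")
  save_cascade(fc, dir)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$architecture, "seq2")
  expect_equal(manifest$inventory, colnames(fx$frame$X))
  expect_setequal(manifest$components$role, c("classifier", "regressor1"))
  fc2 <- load_cascade(dir)
  expect_identical(predict(fc2, fx$frame), predict(fc, fx$frame))
  expect_error(load_cascade(file.path(dir, "nope")),
               class = "loscade_state_error")
})

test_that("out-of-fold meta fitting changes the meta features, not the API", {
  fx <- cascade_fixture()
  spec_in <- cascade_spec("seq2", classifier = rf_cls(),
                          regressors = list(rf_reg()))
  spec_oof <- cascade_spec("seq2", classifier = rf_cls(),
                           regressors = list(rf_reg()), meta_fit = "oof")
  p_in <- predict(fit_cascade(spec_in, fx$frame, fx$registry), fx$frame)
  p_oof <- predict(fit_cascade(spec_oof, fx$frame, fx$registry), fx$frame)
  expect_length(p_oof, length(p_in))
  expect_false(identical(p_in, p_oof))
})
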