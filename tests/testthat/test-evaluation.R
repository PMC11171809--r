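test_that("metrics match hand-evaluated formulas", {
  m <- compute_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m$MAE, 0); expect_equal(m$MSE, 0)
  expect_equal(m$RMSE, 0); expect_equal(m$R2, 1)

  m <- compute_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$MAE, 2 / 3)
  expect_equal(m$MSE, 2 / 3)
  expect_equal(m$RMSE, sqrt(2 / 3))
  expect_equal(m$R2, 0)

  expect_equal(accuracy_from_counts(2, 3, 1, 4), 0.5)
  expect_equal(compute_metrics(c(0, 1, 2, 0), c(0, 1, 1, 0),
                               task = "classification")$Acc, 0.75)
})

test_that("metric edge cases error or warn as declared", {
  expect_error(compute_metrics(numeric(), numeric()),
               class = "loscade_domain_error")
  expect_error(compute_metrics(1:3, 1:2), class = "loscade_shape_error")
  expect_warning(m <- compute_metrics(c(2, 2, 2), c(1, 2, 3)),
                 "zero-variance")
  expect_true(is.na(m$R2))
})

test_that("metrics agree with textbook oracles on 1000 random vectors", {
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(2:40, 1)
    y <- rnorm(n); yh <- rnorm(n)
    m <- compute_metrics(y, yh)
    expect_equal(m$MAE, sum(abs(y - yh)) / n, tolerance = 1e-12)
    expect_equal(m$MSE, sum((y - yh)^2) / n, tolerance = 1e-12)
    expect_identical(m$RMSE, sqrt(m$MSE))
    expect_equal(m$R2, 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
    expect_lte(m$MAE, m$RMSE + 1e-12)
  }
})

test_that("stratified folds preserve class proportions within one member", {
  set.seed(7)
  labels <- sample(0:3, 203, TRUE)
  fold <- loscade:::with_seed(1, loscade:::make_folds(length(labels), 5,
                                                      labels))
  for (cl in 0:3) {
    per_fold <- table(factor(fold[labels == cl], levels = 1:5))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
})

test_that("randomized search returns the best of its own sampled set", {
  d <- toy_features(150, seed = 8)
  pl <- fit_pipeline(d$features, d$meta)
  fr <- apply_pipeline(pl, d$features)
  spec <- learner_spec("rf_regressor", seed = 5L)
  space <- list(n_trees = c(10L, 25L, 50L), max_depth = c(2L, 4L, 8L),
                max_features = c("auto", "sqrt"))
  rs <- randomized_search(spec, fr$X, fr$y_model, "regression",
                          n_iter = 6L, inner_folds = 3L, seed = 17L,
                          space = space)
  # brute-force oracle: re-score every sampled configuration independently
  oracle <- vapply(rs$configs, function(hp) {
    sp <- spec; sp$hyperparameters <- hp
    mean(vapply(1:3, function(f) {
      tr <- rs$fold_id != f
      fit <- fit_learner(sp, fr$X[tr, , drop = FALSE], fr$y_model[tr])
      mean((fr$y_model[!tr] - predict(fit, fr$X[!tr, , drop = FALSE]))^2)
    }, numeric(1)))
  }, numeric(1))
  expect_equal(rs$results$score, oracle, tolerance = 1e-12)
  expect_equal(rs$best_index, which.min(oracle))
  expect_identical(rs$best, rs$configs[[which.min(oracle)]])

  one <- randomized_search(spec, fr$X, fr$y_model, n_iter = 1L,
                           inner_folds = 2L, seed = 3L, space = space)
  expect_identical(one$best, one$configs[[1]])
  again <- randomized_search(spec, fr$X, fr$y_model, n_iter = 6L,
                             inner_folds = 3L, seed = 17L, space = space)
  expect_identical(again$configs, rs$configs)
  expect_error(randomized_search(spec, fr$X, fr$y_model, space = list()),
               class = "loscade_spec_error")
})

small_spaces <- list(
  rf_regressor = list(n_trees = c(20L, 40L), max_depth = c(4L, 8L),
                      max_features = c("auto", "sqrt")),
  rf_classifier = list(n_trees = c(20L, 40L), max_depth = c(4L, 8L),
                       max_features = "sqrt"))

test_that("nested CV produces five balanced stratified folds and a report", {
  d <- toy_features(100, seed = 12)
  spec <- cascade_spec("seq2", classifier = learner_spec("rf_classifier",
                                                         seed = 2),
                       regressors = list(learner_spec("rf_regressor",
                                                      seed = 3)))
  rep <- nested_cv_evaluate(d$features, d$meta, spec, outer_folds = 5L,
                            n_iter = 2L, inner_folds = 2L, seed = 42L,
                            spaces = small_spaces)
  expect_s3_class(rep, "cv_report")
  expect_length(rep$folds, 5L)
  for (fd in rep$folds) expect_equal(length(fd$test_rows), 20L)
  agg <- rep$aggregate
  for (a in agg) {
    expect_lte(a$min, a$mean + 1e-12)
    expect_lte(a$mean, a$max + 1e-12)
    expect_gte(a$sd, 0)
  }
  md <- cv_report_markdown(rep)
  expect_match(md[1], "seq2")
  expect_true(any(grepl("MSE", md)))
})

test_that("instrumented nested CV never touches outer-test rows", {
  d <- toy_features(120, seed = 14)
  rec <- access_recorder()
  spec <- cascade_spec("seq2",
                       classifier = learner_spec("rf_classifier", seed = 2),
                       regressors = list(learner_spec("rf_regressor",
                                                      seed = 3)))
  rep <- nested_cv_evaluate(d$features, d$meta, spec, outer_folds = 5L,
                            n_iter = 2L, inner_folds = 2L, seed = 1L,
                            spaces = small_spaces, recorder = rec)
  entries <- rec$get()
  expect_gt(length(entries), 0L)
  stages <- vapply(entries, `[[`, character(1), "stage")
  expect_setequal(unique(stages), c("transform_fit", "inner_search"))
  for (e in entries) {
    te <- rep$folds[[e$fold]]$test_rows
    expect_length(intersect(e$rows, te), 0L)
  }
})

test_that("error profile rounds half-to-even and conserves counts", {
  p <- error_profile(c(5, 5), c(3.6, 5.4))
  expect_equal(p$histogram$difference, c(0L, 1L))
  expect_equal(p$histogram$count, c(1L, 1L))

  perfect <- error_profile(c(3, 8, 12), c(3, 8, 12))
  expect_equal(perfect$histogram$difference, 0L)
  expect_equal(perfect$histogram$count, 3L)

  set.seed(3)
  a <- rpois(200, 6); b <- a + rnorm(200)
  pr <- error_profile(a, b, actual_class = sample(0:3, 200, TRUE),
                      predicted_class = sample(0:3, 200, TRUE))
  expect_equal(sum(pr$histogram$count), 200L)
  expect_equal(unname(rowSums(pr$confusion)),
               unname(pr$class_density$actual))
  expect_error(error_profile(1:3, 1:2), class = "loscade_shape_error")
})
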