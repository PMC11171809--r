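# Metrics, randomized hyperparameter search, five-fold nested
# cross-validation with leakage instrumentation, and the reporting artifacts
# (mean/min/STD table, confusion matrix, day-error histogram).

#' Regression / classification performance metrics
#'
#' Regression: MAE, MSE, RMSE (= sqrt(MSE) exactly) and R2
#' (1 - SSE/SST). Classification: Acc, the proportion of correctly
#' predicted examples. Metrics are computed on whatever scale `y` is given
#' in; the CV harness uses the model scale (min-max of the winsorized log
#' target).
#'
#' @param y actual values (or class labels).
#' @param y_hat predicted values (or class labels).
#' @param task `"regression"` or `"classification"`.
#' @return named list of metrics (class `metrics_report`).
#' @export
compute_metrics <- function(y, y_hat,
                            task = c("regression", "classification")) {
  task <- match.arg(task)
  n <- length(y)
  if (n == 0L) abort("cannot compute metrics on zero observations",
                     "loscade_domain_error")
  if (length(y_hat) != n)
    abort("y and y_hat differ in length", "loscade_shape_error")
  if (task == "classification") {
    return(structure(list(Acc = mean(y == y_hat)), class = "metrics_report"))
  }
  err <- y - y_hat
  mae <- sum(abs(err)) / n
  mse <- sum(err^2) / n
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    warning("zero-variance actuals; R2 undefined", call. = FALSE)
    NA_real_
  } else 1 - sum(err^2) / sst
  structure(list(MAE = mae, MSE = mse, RMSE = sqrt(mse), R2 = r2),
            class = "metrics_report")
}

#' Accuracy from binary confusion counts
#' @param tp,tn,fp,fn true/false positive/negative counts.
#' @return `(TP + TN) / (TP + TN + FP + FN)`.
#' @export
accuracy_from_counts <- function(tp, tn, fp, fn) {
  tot <- tp + tn + fp + fn
  if (tot == 0) abort("no classified examples", "loscade_domain_error")
  (tp + tn) / tot
}

#' Default randomized-search spaces per learner family
#'
#' Forests: 50-1000 trees in steps of 50, `auto`/`sqrt` feature subsetting,
#' depth up to 31. ANN: 5-150 nodes per hidden layer in steps of 5, learning
#' rate in {1e-1..1e-4}, dropout in {0.1, 0.3, 0.5}, activations in
#' {tanh, swish, linear, relu}. Boosted trees: 50-1000 trees, depth 1-31,
#' learning rate in {0.5, 0.1, 0.01}, row/column subsampling 0.05-1 in
#' steps of 0.05.
#'
#' @param family learner family.
#' @return named list of candidate vectors.
#' @export
default_search_space <- function(family) {
  switch(family,
    rf_regressor = ,
    rf_classifier = list(n_trees = seq(50L, 1000L, 50L),
                         max_features = c("auto", "sqrt"),
                         max_depth = 1:31),
    ann_regressor = list(hidden1 = seq(5L, 150L, 5L),
                         hidden2 = seq(5L, 150L, 5L),
                         learning_rate = c(0.1, 0.01, 0.001, 0.0001),
                         dropout1 = c(0.1, 0.3, 0.5),
                         dropout2 = c(0.1, 0.3, 0.5),
                         activation1 = c("tanh", "swish", "linear", "relu"),
                         activation2 = c("tanh", "swish", "linear", "relu")),
    xgb_regressor = list(n_trees = seq(50L, 1000L, 50L),
                         max_depth = 1:31,
                         learning_rate = c(0.5, 0.1, 0.01),
                         subsample = seq(0.05, 1, 0.05),
                         colsample = seq(0.05, 1, 0.05)),
    abort(sprintf("no search space for family '%s'", family),
          "loscade_spec_error"))
}

sample_hyperparameters <- function(space, n_iter) {
  if (!length(space)) abort("empty search space", "loscade_spec_error")
  lapply(seq_len(n_iter), function(i)
    lapply(space, function(v) v[[sample.int(length(v), 1L)]]))
}

# fold assignment: stratified keeps per-class proportions within one member
make_folds <- function(n, k, labels = NULL) {
  if (is.null(labels)) return(sample(rep_len(seq_len(k), n)))
  fold <- integer(n)
  for (lv in unique(labels)) {
    idx <- which(labels == lv)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Randomized hyperparameter search for one learner
#'
#' Samples `n_iter` configurations from the space and scores each by
#' `inner_folds`-fold cross-validation on the supplied data, minimizing mean
#' MSE (regression) or maximizing mean accuracy (classification).
#'
#' @param spec a [learner_spec()]; its hyperparameters are overridden by the
#'   sampled configurations.
#' @param X,y training data of the fold being tuned.
#' @param task `"regression"` or `"classification"`.
#' @param n_iter number of sampled configurations.
#' @param inner_folds inner CV folds.
#' @param seed seed for sampling and fold assignment.
#' @param space search space (default [default_search_space()]).
#' @param recorder,fold,row_ids leakage instrumentation: original row ids of
#'   the rows in `X`, logged under stage `"inner_search"`.
#' @return list with `best` (hyperparameter list), `results` (data.frame of
#'   per-configuration mean scores) and `configs`.
#' @export
randomized_search <- function(spec, X, y, task = "regression",
                              n_iter = 20L, inner_folds = 3L, seed = 1L,
                              space = default_search_space(spec$family),
                              recorder = NULL, fold = NA_integer_,
                              row_ids = NULL) {
  record_access(recorder, "inner_search", fold,
                row_ids %||% seq_len(nrow(X)))
  with_seed(seed, {
    configs <- sample_hyperparameters(space, n_iter)
    fold_id <- make_folds(nrow(X), inner_folds,
                          labels = if (task == "classification") y)
    scores <- vapply(configs, function(hp) {
      sp <- spec
      sp$hyperparameters <- utils::modifyList(spec$hyperparameters, hp)
      fs <- vapply(seq_len(inner_folds), function(f) {
        tr <- fold_id != f
        fit <- fit_learner(sp, X[tr, , drop = FALSE], y[tr])
        pred <- predict(fit, X[!tr, , drop = FALSE])
        if (task == "classification") mean(pred == y[!tr]) else
          mean((y[!tr] - pred)^2)
      }, numeric(1))
      mean(fs)
    }, numeric(1))
    best_i <- if (task == "classification") which.max(scores) else
      which.min(scores)
    list(best = configs[[best_i]],
         results = data.frame(config = seq_along(scores), score = scores),
         configs = configs, fold_id = fold_id, best_index = best_i)
  })
}

# Tune every component of a cascade in dependency order, feeding each
# downstream component the meta features produced by the already-tuned
# upstream fits. Returns the spec with hyperparameters pinned.
search_cascade <- function(spec, frame, registry, n_iter = 20L,
                           inner_folds = 3L, seed = 1L, spaces = list(),
                           recorder = NULL, fold = NA_integer_,
                           row_ids = NULL) {
  space_for <- function(ls) spaces[[ls$family]] %||%
    default_search_space(ls$family)
  tune_reg <- function(ls, X, y, sd) {
    rs <- randomized_search(ls, X, y, "regression", n_iter, inner_folds,
                            seed = sd, space = space_for(ls),
                            recorder = recorder, fold = fold,
                            row_ids = row_ids)
    ls$hyperparameters <- utils::modifyList(ls$hyperparameters, rs$best)
    ls
  }
  out <- spec
  if (spec$architecture %in% c("avg_vote", "single")) {
    out$regressors <- lapply(seq_along(spec$regressors), function(i) {
      ls <- spec$regressors[[i]]
      idx <- subset_columns(frame, registry, ls$feature_subset)
      tune_reg(ls, frame$X[, idx, drop = FALSE], frame$y_model, seed + i)
    })
    return(out)
  }
  cs <- spec$classifier
  idxc <- subset_columns(frame, registry, cs$feature_subset)
  rsc <- randomized_search(cs, frame$X[, idxc, drop = FALSE], frame$y_class,
                           "classification", n_iter, inner_folds,
                           seed = seed, space = space_for(cs),
                           recorder = recorder, fold = fold,
                           row_ids = row_ids)
  cs$hyperparameters <- utils::modifyList(cs$hyperparameters, rsc$best)
  out$classifier <- cs
  cp <- classifier_probs(cs, frame, registry, spec$meta_fit)

  r1 <- spec$regressors[[1]]
  idx1 <- subset_columns(frame, registry, r1$feature_subset)
  X1raw <- frame$X[, idx1, drop = FALSE]
  if (spec$architecture %in% c("seq2", "seq3")) {
    X1 <- augment_features(X1raw, cp$P)
  } else {
    X1 <- X1raw
  }
  r1 <- tune_reg(r1, X1, frame$y_model, seed + 101L)
  out$regressors[[1]] <- r1
  if (spec$architecture == "seq2") return(out)

  mo1 <- meta_output(r1, X1, frame$y_model, "response", spec$meta_fit)
  r2 <- spec$regressors[[2]]
  idx2 <- subset_columns(frame, registry, r2$feature_subset)
  meta <- if (spec$architecture == "seq3") {
    matrix(mo1$output, ncol = 1, dimnames = list(NULL, "REG1-PRED"))
  } else {
    cbind(cp$P, `REG1-PRED` = mo1$output)
  }
  X2 <- augment_features(frame$X[, idx2, drop = FALSE], meta)
  out$regressors[[2]] <- tune_reg(r2, X2, frame$y_model, seed + 202L)
  out
}

#' Five-fold nested cross-validation of a cascade
#'
#' Outer folds are stratified by LOS category so the cascade classifier sees
#' all classes. Inside each outer fold the preprocessing pipeline is fitted
#' on the training part only, hyperparameters are chosen by randomized
#' search with inner CV, the cascade is refitted with the chosen
#' configuration and scored on the untouched test part (model scale).
#'
#' @param features engineered feature table.
#' @param meta feature metadata.
#' @param spec a [cascade_spec()].
#' @param registry optional `subset_registry`; when NULL the registry is
#'   built once from the full training partition (the fixed-subset protocol;
#'   see the methods vignette for the per-fold alternative).
#' @param outer_folds,n_iter,inner_folds protocol sizes.
#' @param seed experiment seed; all fold assignment and search sampling
#'   derives from it.
#' @param spaces optional named list (family -> search space) overriding
#'   [default_search_space()].
#' @param recorder optional [access_recorder()] for the leakage audit.
#' @param keep_predictions keep per-fold day-scale predictions for the error
#'   profile.
#' @return object of class `cv_report`.
#' @export
nested_cv_evaluate <- function(features, meta, spec, registry = NULL,
                               outer_folds = 5L, n_iter = 20L,
                               inner_folds = 3L, seed = 42L,
                               spaces = list(), recorder = NULL,
                               keep_predictions = TRUE) {
  n <- nrow(features)
  full_bundle <- bin_target_qcut(features$`LOS-DAYS`)
  strata <- full_bundle$los_category
  if (is.null(registry)) {
    imp <- impute_missing(features, meta)
    sc <- rbind(
      score_features(imp, meta, full_bundle$los_log, "regression"),
      score_features(imp, meta, strata, "classification"))
    selectable <- meta$name[selection_kind(meta) != "skip"]
    registry <- build_subset_registry(sc, selectable)
  }
  fold_id <- with_seed(seed, make_folds(n, outer_folds, labels = strata))

  folds <- list()
  for (f in seq_len(outer_folds)) {
    tr <- which(fold_id != f)
    te <- which(fold_id == f)
    pl <- fit_pipeline(features, meta, rows = tr, recorder = recorder,
                       fold = f)
    frame_tr <- apply_pipeline(pl, features[tr, , drop = FALSE])
    frame_te <- apply_pipeline(pl, features[te, , drop = FALSE])
    tuned <- search_cascade(spec, frame_tr, registry, n_iter, inner_folds,
                            seed = seed * 1000L + f, spaces = spaces,
                            recorder = recorder, fold = f, row_ids = tr)
    fitted <- fit_cascade(tuned, frame_tr, registry)
    pred <- predict(fitted, frame_te)
    m <- compute_metrics(frame_te$y_model, pred)
    rec <- list(fold = f, metrics = unclass(m),
                hyperparameters = c(
                  if (!is.null(tuned$classifier))
                    list(classifier = tuned$classifier$hyperparameters),
                  list(regressors = lapply(tuned$regressors,
                                           function(r) r$hyperparameters))))
    if (!is.null(tuned$classifier)) {
      cls_pred <- predict_cascade_class(fitted, frame_te)
      rec$metrics$Acc <- mean(cls_pred == frame_te$y_class)
      rec$class_pred <- cls_pred
    }
    if (keep_predictions) {
      rec$test_rows <- te
      rec$pred_days <- back_transform_target(pl, pred)
      rec$actual_days <- frame_te$y_days
      rec$actual_class <- frame_te$y_class
    }
    folds[[f]] <- rec
  }

  metric_names <- names(folds[[1]]$metrics)
  agg <- lapply(metric_names, function(mn) {
    v <- vapply(folds, function(fd) fd$metrics[[mn]], numeric(1))
    list(metric = mn, mean = mean(v), min = min(v), max = max(v),
         sd = sd(v))
  })
  structure(list(name = spec$name, architecture = spec$architecture,
                 folds = folds, aggregate = agg, seed = seed,
                 outer_folds = outer_folds, n_iter = n_iter,
                 inner_folds = inner_folds, n = n,
                 registry_sizes = registry_sizes(registry)),
            class = "cv_report")
}

#' Aggregate table of one or more CV reports (Mean / Min-or-Max / STD)
#' @param reports a `cv_report` or list of them.
#' @return character vector of markdown lines.
#' @export
cv_report_markdown <- function(reports) {
  if (inherits(reports, "cv_report")) reports <- list(reports)
  names <- vapply(reports, function(r) r$name, character(1))
  metrics <- unique(unlist(lapply(reports, function(r)
    vapply(r$aggregate, function(a) a$metric, character(1)))))
  lines <- c(paste0("| Metric | Stat | ", paste(names, collapse = " | "),
                    " |"),
             paste0("|---|---|", paste(rep("---|", length(names)),
                                       collapse = "")))
  get_agg <- function(r, mn) {
    for (a in r$aggregate) if (a$metric == mn) return(a)
    NULL
  }
  for (mn in metrics) {
    best_stat <- if (mn %in% c("R2", "Acc")) "max" else "min"
    for (st in c("mean", best_stat, "sd")) {
      vals <- vapply(reports, function(r) {
        a <- get_agg(r, mn)
        if (is.null(a)) NA_real_ else a[[st]]
      }, numeric(1))
      label <- c(mean = "Mean", min = "Min", max = "Max", sd = "STD")[st]
      lines <- c(lines, paste0("| ", mn, " | ", label, " | ",
                               paste(sprintf("%.4f", vals),
                                     collapse = " | "), " |"))
    }
  }
  lines
}

#' Serialize a CV report to JSON
#' @param report a `cv_report`.
#' @param path output path.
#' @param extra named list merged into the JSON (e.g. provenance).
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(report, path, extra = list()) {
  obj <- utils::modifyList(unclass_deep(unclass(report)), extra)
  obj$folds <- lapply(obj$folds, function(fd) {
    fd$test_rows <- NULL; fd$pred_days <- NULL; fd$actual_days <- NULL
    fd$actual_class <- NULL; fd$class_pred <- NULL
    fd
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Day-scale error profile (and optional confusion matrix)
#'
#' Differences `actual - predicted` are rounded half-to-even before
#' histogramming.
#'
#' @param actual_days,predicted_days day-scale values.
#' @param actual_class,predicted_class optional class labels for the
#'   confusion matrix.
#' @param n_class number of LOS classes.
#' @return list with `histogram` (data.frame difference/count) and, when
#'   classes are given, `confusion` (actual x predicted count matrix) and
#'   `class_density` (per-class actual vs predicted totals).
#' @export
error_profile <- function(actual_days, predicted_days,
                          actual_class = NULL, predicted_class = NULL,
                          n_class = 4L) {
  if (length(actual_days) != length(predicted_days))
    abort("actual and predicted lengths differ", "loscade_shape_error")
  diffs <- round(actual_days - predicted_days)
  tab <- table(diffs)
  hist <- data.frame(difference = as.integer(names(tab)),
                     count = as.integer(tab))
  out <- list(histogram = hist, n = length(diffs))
  if (!is.null(actual_class)) {
    lv <- 0:(n_class - 1L)
    cm <- table(factor(actual_class, levels = lv),
                factor(predicted_class, levels = lv))
    out$confusion <- unclass(cm)
    out$class_density <- data.frame(
      class = lv,
      actual = as.integer(table(factor(actual_class, levels = lv))),
      predicted = as.integer(table(factor(predicted_class, levels = lv))))
  }
  out
}
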