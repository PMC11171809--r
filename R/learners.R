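# Pluggable base learners behind a single spec/fit/predict contract:
# bagged-CART random forests (regression and 4-class probability
# classification), a squared-loss gradient-boosted tree regressor with
# row/column subsampling, and a two-hidden-layer neural-network regressor
# (dropout, ADAM, MAE loss). Tree growing is compiled (see src/trees.cpp);
# every fit is reproducible under the spec's seed.

learner_families <- c("rf_classifier", "rf_regressor", "xgb_regressor",
                      "ann_regressor")

#' Declare a base learner
#'
#' @param family one of `rf_classifier`, `rf_regressor`, `xgb_regressor`,
#'   `ann_regressor`.
#' @param hyperparameters named list overriding
#'   [default_hyperparameters()].
#' @param seed integer; fixed seed implies a reproducible fit.
#' @param feature_subset subset name resolved against the registry at fit
#'   time.
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(family, hyperparameters = list(), seed = 1L,
                         feature_subset = "FS-1") {
  family <- match.arg(family, learner_families)
  structure(list(family = family, hyperparameters = hyperparameters,
                 seed = as.integer(seed), feature_subset = feature_subset),
            class = "learner_spec")
}

#' Default hyperparameters per learner family
#' @param family learner family name.
#' @return named list.
#' @export
default_hyperparameters <- function(family) {
  switch(family,
    rf_regressor  = list(n_trees = 300L, max_depth = 31L,
                         max_features = "auto", min_node = 5L),
    rf_classifier = list(n_trees = 300L, max_depth = 31L,
                         max_features = "sqrt", min_node = 5L),
    xgb_regressor = list(n_trees = 300L, max_depth = 6L,
                         learning_rate = 0.1, subsample = 1, colsample = 1,
                         min_node = 10L),
    ann_regressor = list(hidden1 = 5L, hidden2 = 70L,
                         activation1 = "swish", activation2 = "relu",
                         dropout1 = 0.1, dropout2 = 0.1,
                         learning_rate = 0.01, epochs = 40L,
                         batch_size = 32L),
    abort(sprintf("unknown learner family '%s'", family),
          "loscade_spec_error"))
}

resolve_mtry <- function(max_features, p, family) {
  m <- switch(as.character(max_features),
              auto = if (family == "rf_classifier") floor(sqrt(p)) else p,
              sqrt = floor(sqrt(p)),
              as.integer(max_features))
  max(1L, min(p, as.integer(m)))
}

#' Fit a base learner
#'
#' @param spec a [learner_spec()].
#' @param X numeric model matrix (no missing values).
#' @param y numeric target (regressors) or integer class labels
#'   (classifier).
#' @return object of class `fitted_learner` with a [predict] method.
#' @export
fit_learner <- function(spec, X, y) {
  stopifnot(inherits(spec, "learner_spec"))
  X <- as.matrix(X)
  if (nrow(X) != length(y))
    abort("X and y disagree on row count", "loscade_shape_error")
  hp <- utils::modifyList(default_hyperparameters(spec$family),
                          spec$hyperparameters)
  fit <- with_seed(spec$seed, switch(spec$family,
    rf_regressor = fit_rf_regressor(X, y, hp),
    rf_classifier = fit_rf_classifier(X, y, hp),
    xgb_regressor = fit_xgb_regressor(X, y, hp),
    ann_regressor = ann_fit(X, y, hp)))
  structure(list(family = spec$family, spec = spec, hp = hp, fit = fit,
                 feature_names = colnames(X)),
            class = "fitted_learner")
}

fit_rf_regressor <- function(X, y, hp) {
  mtry <- resolve_mtry(hp$max_features, ncol(X), "rf_regressor")
  forest <- .cpp_fit_forest(X, as.numeric(y), FALSE, 1L,
                            as.integer(hp$n_trees), as.integer(hp$max_depth),
                            as.integer(hp$min_node), mtry, TRUE)
  list(forest = forest)
}

fit_rf_classifier <- function(X, y, hp) {
  classes <- sort(unique(as.integer(y)))
  yi <- match(as.integer(y), classes) - 1L
  mtry <- resolve_mtry(hp$max_features, ncol(X), "rf_classifier")
  forest <- .cpp_fit_forest(X, as.numeric(yi), TRUE, length(classes),
                            as.integer(hp$n_trees), as.integer(hp$max_depth),
                            as.integer(hp$min_node), mtry, TRUE)
  list(forest = forest, classes = classes)
}

fit_xgb_regressor <- function(X, y, hp) {
  n <- nrow(X); p <- ncol(X)
  base <- mean(y)
  pred <- rep(base, n)
  trees <- vector("list", hp$n_trees)
  n_sub <- max(2L * hp$min_node, floor(hp$subsample * n))
  n_sub <- min(n, n_sub)
  n_col <- max(1L, round(hp$colsample * p))
  for (t in seq_len(hp$n_trees)) {
    rows <- if (n_sub < n) sample.int(n, n_sub) else seq_len(n)
    cand <- if (n_col < p) sort(sample.int(p, n_col)) else seq_len(p)
    resid <- y - pred
    tree <- .cpp_fit_tree(X, resid, FALSE, 1L, as.integer(hp$max_depth),
                          as.integer(hp$min_node), length(cand),
                          rows - 1L, cand - 1L)
    pred <- pred + hp$learning_rate * .cpp_predict_tree(tree, X)[, 1]
    trees[[t]] <- tree
  }
  list(trees = trees, base = base, eta = hp$learning_rate)
}

#' Predict from a fitted base learner
#'
#' @param object a `fitted_learner`.
#' @param newdata numeric matrix with the training columns.
#' @param type `"response"` (numeric prediction / hard class) or `"prob"`
#'   (classifier probability matrix, columns in ascending class order).
#' @param ... unused.
#' @export
predict.fitted_learner <- function(object, newdata,
                                   type = c("response", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (!is.null(object$feature_names)) {
    if (!identical(colnames(X), object$feature_names)) {
      if (is.null(colnames(X)) || !setequal(colnames(X),
                                            object$feature_names))
        abort("prediction columns do not match the training inventory",
              "loscade_shape_error")
      X <- X[, object$feature_names, drop = FALSE]
    }
  }
  switch(object$family,
    rf_regressor = .cpp_predict_forest(object$fit$forest, X, 1L)[, 1],
    xgb_regressor = {
      s <- .cpp_predict_forest(object$fit$trees, X, 1L)[, 1]
      object$fit$base + object$fit$eta * length(object$fit$trees) * s
    },
    ann_regressor = ann_predict(object$fit, X),
    rf_classifier = {
      P <- .cpp_predict_forest(object$fit$forest, X,
                               length(object$fit$classes))
      P <- pmin(pmax(P, 0), 1)  # guard against accumulation round-off
      colnames(P) <- paste0("CLS-PROB-", object$fit$classes)
      if (type == "prob") P else
        object$fit$classes[max.col(P, ties.method = "first")]
    })
}
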