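# The four ensemble architectures over pluggable base learners:
#   avg_vote  - independently trained regressors, arithmetic-mean prediction;
#   seq2      - LOS-category classifier whose 4 class probabilities augment
#               the regressor's features;
#   seq3      - classifier -> Regressor-1 (features + probabilities) ->
#               Regressor-2 (features + Regressor-1's scalar prediction, no
#               probabilities);
#   parallel  - classifier and Regressor-1 run side by side on raw features;
#               Regressor-2 sees features + 4 probabilities + Regressor-1's
#               prediction.
# Downstream levels train on in-sample upstream outputs by default; an
# out-of-fold mode ("oof") is available to quantify the leakage that choice
# introduces.

#' Declare a cascade architecture
#'
#' @param architecture one of `avg_vote`, `seq2`, `seq3`, `parallel`, or
#'   `single` (a bare regressor evaluated through the same harness).
#' @param classifier a [learner_spec()] for the LOS-category classifier
#'   (absent for `avg_vote`).
#' @param regressors ordered list of regressor [learner_spec()]s
#'   (`avg_vote`: >= 2; `seq2`: 1; `seq3`/`parallel`: 2).
#' @param meta_fit `"insample"` (default) or `"oof"`: whether downstream
#'   levels train on in-sample or out-of-fold upstream outputs.
#' @param name optional label used in reports.
#' @return object of class `cascade_spec`.
#' @export
cascade_spec <- function(architecture = c("avg_vote", "seq2", "seq3",
                                          "parallel", "single"),
                         classifier = NULL, regressors = list(),
                         meta_fit = c("insample", "oof"), name = NULL) {
  architecture <- match.arg(architecture)
  meta_fit <- match.arg(meta_fit)
  n_reg <- length(regressors)
  ok <- switch(architecture,
               single = is.null(classifier) && n_reg == 1L,
               avg_vote = is.null(classifier) && n_reg >= 2L,
               seq2 = !is.null(classifier) && n_reg == 1L,
               seq3 = !is.null(classifier) && n_reg == 2L,
               parallel = !is.null(classifier) && n_reg == 2L)
  if (!ok)
    abort(sprintf("invalid component counts for architecture '%s'",
                  architecture), "loscade_spec_error")
  if (!is.null(classifier)) stopifnot(inherits(classifier, "learner_spec"))
  for (r in regressors) stopifnot(inherits(r, "learner_spec"))
  structure(list(architecture = architecture, classifier = classifier,
                 regressors = regressors, meta_fit = meta_fit,
                 name = name %||% architecture),
            class = "cascade_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Append meta-feature columns to a feature block
#'
#' The original columns are preserved unchanged, followed by the meta columns
#' in their declared order.
#'
#' @param X numeric feature matrix.
#' @param meta numeric matrix of meta-feature columns (may have 0 columns).
#' @return widened matrix.
#' @export
augment_features <- function(X, meta) {
  X <- as.matrix(X)
  meta <- as.matrix(meta)
  if (ncol(meta) == 0L) return(X)
  if (nrow(meta) != nrow(X))
    abort("meta-feature row count does not match the feature block",
          "loscade_shape_error")
  cbind(X, meta)
}

prob_colnames <- function(k = 4L) paste0("CLS-PROB-", seq_len(k) - 1L)

# in-sample (default) or out-of-fold upstream outputs for downstream training
meta_output <- function(spec, X, y, type, meta_fit, oof_folds = 5L) {
  fitted <- fit_learner(spec, X, y)
  if (meta_fit == "insample") {
    out <- predict(fitted, X, type = type)
  } else {
    n <- nrow(X)
    fold <- with_seed(spec$seed, sample(rep_len(seq_len(oof_folds), n)))
    out <- NULL
    for (f in seq_len(oof_folds)) {
      tr <- fold != f
      fit_f <- fit_learner(spec, X[tr, , drop = FALSE], y[tr])
      pred_f <- predict(fit_f, X[!tr, , drop = FALSE], type = type)
      if (is.null(out)) {
        out <- if (is.matrix(pred_f)) {
          matrix(NA_real_, n, ncol(pred_f), dimnames = list(NULL,
                                                            colnames(pred_f)))
        } else rep(NA_real_, n)
      }
      if (is.matrix(out)) out[!tr, ] <- pred_f else out[!tr] <- pred_f
    }
  }
  list(fitted = fitted, output = out)
}

classifier_probs <- function(spec, frame, registry, meta_fit) {
  idx <- subset_columns(frame, registry, spec$feature_subset)
  Xc <- frame$X[, idx, drop = FALSE]
  mo <- meta_output(spec, Xc, frame$y_class, "prob", meta_fit)
  P <- mo$output
  if (ncol(P) != 4L)
    abort(sprintf("classifier emitted %d probability columns, expected 4",
                  ncol(P)), "loscade_architecture_error")
  list(fitted = mo$fitted, P = P)
}

#' Fit a cascade ensemble
#'
#' Dispatches on the architecture; see [cascade_spec()]. Regressors are
#' trained on the model-scale LOS target (`frame$y_model`), the classifier
#' on the 4-level LOS category (`frame$y_class`).
#'
#' @param spec a `cascade_spec`.
#' @param frame a `model_frame` from [apply_pipeline()].
#' @param registry a `subset_registry`.
#' @return object of class `fitted_cascade`.
#' @export
fit_cascade <- function(spec, frame, registry) {
  stopifnot(inherits(spec, "cascade_spec"), inherits(frame, "model_frame"))
  switch(spec$architecture,
         single = ,
         avg_vote = fit_avg_vote(frame, spec, registry),
         seq2 = ,
         seq3 = fit_sequential_cascade(frame, spec, registry),
         parallel = fit_parallel_cascade(frame, spec, registry))
}

new_fitted_cascade <- function(spec, components, frame) {
  structure(list(spec = spec, components = components,
                 inventory = colnames(frame$X)),
            class = "fitted_cascade")
}

#' @rdname fit_cascade
#' @export
fit_avg_vote <- function(frame, spec, registry) {
  if (spec$architecture == "avg_vote" && length(spec$regressors) < 2L)
    abort("avg_vote needs at least 2 regressors", "loscade_spec_error")
  regs <- lapply(spec$regressors, function(rs) {
    idx <- subset_columns(frame, registry, rs$feature_subset)
    fit_learner(rs, frame$X[, idx, drop = FALSE], frame$y_model)
  })
  new_fitted_cascade(spec, list(regressors = regs), frame)
}

#' @rdname fit_cascade
#' @export
fit_sequential_cascade <- function(frame, spec, registry) {
  cp <- classifier_probs(spec$classifier, frame, registry, spec$meta_fit)
  rs1 <- spec$regressors[[1]]
  idx1 <- subset_columns(frame, registry, rs1$feature_subset)
  X1 <- augment_features(frame$X[, idx1, drop = FALSE], cp$P)
  if (spec$architecture == "seq2") {
    reg1 <- fit_learner(rs1, X1, frame$y_model)
    return(new_fitted_cascade(spec, list(classifier = cp$fitted,
                                         regressors = list(reg1)), frame))
  }
  mo1 <- meta_output(rs1, X1, frame$y_model, "response", spec$meta_fit)
  rs2 <- spec$regressors[[2]]
  idx2 <- subset_columns(frame, registry, rs2$feature_subset)
  X2 <- augment_features(frame$X[, idx2, drop = FALSE],
                         matrix(mo1$output, ncol = 1,
                                dimnames = list(NULL, "REG1-PRED")))
  reg2 <- fit_learner(rs2, X2, frame$y_model)
  new_fitted_cascade(spec, list(classifier = cp$fitted,
                                regressors = list(mo1$fitted, reg2)), frame)
}

#' @rdname fit_cascade
#' @export
fit_parallel_cascade <- function(frame, spec, registry) {
  cp <- classifier_probs(spec$classifier, frame, registry, spec$meta_fit)
  rs1 <- spec$regressors[[1]]
  idx1 <- subset_columns(frame, registry, rs1$feature_subset)
  mo1 <- meta_output(rs1, frame$X[, idx1, drop = FALSE], frame$y_model,
                     "response", spec$meta_fit)
  rs2 <- spec$regressors[[2]]
  idx2 <- subset_columns(frame, registry, rs2$feature_subset)
  meta <- cbind(cp$P, `REG1-PRED` = mo1$output)
  X2 <- augment_features(frame$X[, idx2, drop = FALSE], meta)
  reg2 <- fit_learner(rs2, X2, frame$y_model)
  new_fitted_cascade(spec, list(classifier = cp$fitted,
                                regressors = list(mo1$fitted, reg2)), frame)
}

check_inventory <- function(object, X) {
  inv <- object$inventory
  if (identical(colnames(X), inv)) return(X)
  if (is.null(colnames(X)))
    abort("prediction input lacks column names", "loscade_shape_error")
  missing <- setdiff(inv, colnames(X))
  extra <- setdiff(colnames(X), inv)
  if (length(missing) || length(extra))
    abort(sprintf("feature inventory mismatch; missing: [%s] extra: [%s]",
                  paste(missing, collapse = ", "),
                  paste(extra, collapse = ", ")),
          "loscade_shape_error")
  X[, inv, drop = FALSE]
}

#' Predict from a fitted cascade
#'
#' Replays the training-time augmentation chain on new data. Predictions are
#' on the model scale; pass the fitting pipeline to obtain days.
#'
#' @param object a `fitted_cascade`.
#' @param frame a `model_frame` (or bare matrix with the training columns).
#' @param scale `"model"` or `"days"`.
#' @param pipeline the `los_pipeline` used at fit time (required for
#'   `scale = "days"`).
#' @param ... unused.
#' @return numeric predictions, one per row.
#' @export
predict.fitted_cascade <- function(object, frame, scale = c("model", "days"),
                                   pipeline = NULL, ...) {
  scale <- match.arg(scale)
  X <- if (inherits(frame, "model_frame")) frame$X else as.matrix(frame)
  X <- check_inventory(object, X)
  spec <- object$spec
  comp <- object$components
  pred <- switch(spec$architecture,
    single = ,
    avg_vote = {
      preds <- vapply(comp$regressors, function(f)
        predict(f, X[, f$feature_names, drop = FALSE]),
        numeric(nrow(X)))
      rowMeans(matrix(preds, nrow = nrow(X)))
    },
    {
      clf <- comp$classifier
      P <- predict(clf, X[, clf$feature_names, drop = FALSE], type = "prob")
      if (spec$architecture == "seq2") {
        r1 <- comp$regressors[[1]]
        base_cols <- setdiff(r1$feature_names, colnames(P))
        X1 <- augment_features(X[, base_cols, drop = FALSE], P)
        predict(r1, X1)
      } else if (spec$architecture == "seq3") {
        r1 <- comp$regressors[[1]]
        base1 <- setdiff(r1$feature_names, colnames(P))
        p1 <- predict(r1, augment_features(X[, base1, drop = FALSE], P))
        r2 <- comp$regressors[[2]]
        base2 <- setdiff(r2$feature_names, "REG1-PRED")
        X2 <- augment_features(X[, base2, drop = FALSE],
                               matrix(p1, ncol = 1,
                                      dimnames = list(NULL, "REG1-PRED")))
        predict(r2, X2)
      } else {  # parallel
        r1 <- comp$regressors[[1]]
        p1 <- predict(r1, X[, r1$feature_names, drop = FALSE])
        r2 <- comp$regressors[[2]]
        base2 <- setdiff(r2$feature_names, c(colnames(P), "REG1-PRED"))
        X2 <- augment_features(X[, base2, drop = FALSE],
                               cbind(P, `REG1-PRED` = p1))
        predict(r2, X2)
      }
    })
  if (scale == "days") {
    if (is.null(pipeline))
      abort("scale='days' requires the fitting pipeline", "loscade_state_error")
    pred <- back_transform_target(pipeline, pred)
  }
  pred
}

#' Serialize / restore a fitted cascade as a directory bundle
#'
#' Writes one file per fitted component plus a `manifest.json` describing
#' the architecture, per-component families, subsets, seeds and the feature
#' inventory. The manifest is plain JSON; component fits are RDS (runtime
#' artifacts, not source).
#'
#' @param fitted a `fitted_cascade`.
#' @param dir bundle directory (created if absent).
#' @return `dir` (save) or a `fitted_cascade` (load).
#' @export
save_cascade <- function(fitted, dir) {
  stopifnot(inherits(fitted, "fitted_cascade"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  comp_names <- c(if (!is.null(fitted$components$classifier)) "classifier",
                  paste0("regressor", seq_along(fitted$components$regressors)))
  manifest <- list(
    architecture = fitted$spec$architecture,
    name = fitted$spec$name,
    meta_fit = fitted$spec$meta_fit,
    inventory = fitted$inventory,
    components = lapply(comp_names, function(nm) {
      f <- if (nm == "classifier") fitted$components$classifier else
        fitted$components$regressors[[as.integer(sub("regressor", "", nm))]]
      list(role = nm, family = f$family, seed = f$spec$seed,
           feature_subset = f$spec$feature_subset,
           n_features = length(f$feature_names))
    }))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(fitted$components$classifier))
    saveRDS(fitted$components$classifier, file.path(dir, "classifier.rds"))
  for (i in seq_along(fitted$components$regressors))
    saveRDS(fitted$components$regressors[[i]],
            file.path(dir, sprintf("regressor%d.rds", i)))
  saveRDS(fitted$spec, file.path(dir, "spec.rds"))
  invisible(dir)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf))
    abort(sprintf("no cascade manifest at %s", mf), "loscade_state_error")
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  spec <- readRDS(file.path(dir, "spec.rds"))
  cls_f <- file.path(dir, "classifier.rds")
  classifier <- if (file.exists(cls_f)) readRDS(cls_f)
  regs <- list()
  i <- 1L
  repeat {
    f <- file.path(dir, sprintf("regressor%d.rds", i))
    if (!file.exists(f)) break
    regs[[i]] <- readRDS(f)
    i <- i + 1L
  }
  structure(list(spec = spec,
                 components = list(classifier = classifier,
                                   regressors = regs),
                 inventory = manifest$inventory),
            class = "fitted_cascade")
}

#' Predict LOS-category probabilities from a cascade's classifier
#' @param object a `fitted_cascade` with a classifier component.
#' @param frame a `model_frame` or matrix.
#' @param type `"prob"` or `"response"`.
#' @return probability matrix or hard class labels.
#' @export
predict_cascade_class <- function(object, frame,
                                  type = c("response", "prob")) {
  type <- match.arg(type)
  if (is.null(object$components$classifier))
    abort("cascade has no classifier component", "loscade_state_error")
  X <- if (inherits(frame, "model_frame")) frame$X else as.matrix(frame)
  X <- check_inventory(object, X)
  clf <- object$components$classifier
  predict(clf, X[, clf$feature_names, drop = FALSE], type = type)
}
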