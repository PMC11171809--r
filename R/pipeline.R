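# Fits the full preprocessing pipeline on a training partition and applies it
# to arbitrary partitions, producing the encoded model matrix the learners
# consume. Target chain: log1p -> IQR winsorize (log scale) -> min-max to
# [0, 1] ("model scale"); the quantile-cut category is fitted on the
# winsorized log target. Feature chain: rule imputation -> log1p on
# LOS-derived columns -> per-column min-max (numeric) / dummy encoding
# (categorical), all parameters fitted on the training rows only.

#' Fit the preprocessing pipeline
#'
#' @param features engineered feature table ([engineer_features()]).
#' @param meta feature metadata.
#' @param rows integer indices of the training partition (transform
#'   parameters derive only from these rows).
#' @param n_bins number of LOS category bins.
#' @param recorder optional [access_recorder()]; the rows used for fitting
#'   are logged under stage `"transform_fit"`.
#' @param fold fold label for the access log.
#' @return object of class `los_pipeline`.
#' @export
fit_pipeline <- function(features, meta, rows = seq_len(nrow(features)),
                         n_bins = 4L, recorder = NULL, fold = NA_integer_) {
  record_access(recorder, "transform_fit", fold, rows)
  tr <- features[rows, , drop = FALSE]

  los <- tr$`LOS-DAYS`
  wfit <- fit_winsorize(log_transform(los))
  los_logw <- apply_winsorize(wfit, log_transform(los))
  tmm <- fit_minmax(los_logw)
  bundle <- bin_target_qcut(inv_log_transform(los_logw), n_bins = n_bins)

  tr <- impute_missing(tr, meta)
  num_names <- meta$name[meta$kind %in%
                           c("numeric", "history_count", "lab_value",
                             "vital_flag")]
  cat_names <- meta$name[meta$kind == "categorical"]
  log_cols <- meta$name[meta$log_los]

  num_fits <- list()
  for (nm in num_names) {
    x <- tr[[nm]]
    if (nm %in% log_cols) x <- log_transform(pmax(x, 0))
    num_fits[[nm]] <- suppressWarnings(fit_minmax(x))
  }
  dfit <- fit_dummy(tr[cat_names])

  structure(list(target = list(winsorize = wfit, minmax = tmm,
                               bundle = bundle),
                 num_fits = num_fits, dummy = dfit,
                 num_names = num_names, cat_names = cat_names,
                 log_cols = log_cols, meta = meta, n_bins = n_bins,
                 fold = fold),
            class = "los_pipeline")
}

#' Apply a fitted pipeline, producing a model frame
#'
#' @param pipeline a `los_pipeline`.
#' @param features feature table rows to transform (any partition).
#' @return `model_frame`: `X` (numeric model matrix), `col_parent` (source
#'   feature of each column), `y_model` (target on the model scale),
#'   `y_log` (winsorized log target), `y_days`, `y_class`.
#' @export
apply_pipeline <- function(pipeline, features) {
  stopifnot(inherits(pipeline, "los_pipeline"))
  df <- impute_missing(features, pipeline$meta)

  cols <- list()
  parent <- character()
  for (nm in pipeline$num_names) {
    x <- df[[nm]]
    if (nm %in% pipeline$log_cols) x <- log_transform(pmax(x, 0))
    cols[[nm]] <- apply_minmax(pipeline$num_fits[[nm]], x)
    parent <- c(parent, nm)
  }
  dm <- apply_dummy(pipeline$dummy, df[pipeline$cat_names])
  Xn <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(), nrow(df), 0)
  colnames(Xn) <- names(cols)
  X <- cbind(Xn, dm$X)
  parent <- c(parent, dm$parent)

  los <- df$`LOS-DAYS`
  y_log <- apply_winsorize(pipeline$target$winsorize, log_transform(los))
  y_model <- apply_minmax(pipeline$target$minmax, y_log)
  y_class <- assign_los_category(pipeline$target$bundle,
                                 inv_log_transform(y_log))
  structure(list(X = X, col_parent = parent, y_model = y_model,
                 y_log = y_log, y_days = los, y_class = y_class),
            class = "model_frame")
}

#' Map model-scale predictions back to days
#' @param pipeline a `los_pipeline`.
#' @param y_model predictions on the model scale.
#' @return predicted LOS in (fractional) days.
#' @export
back_transform_target <- function(pipeline, y_model) {
  stopifnot(inherits(pipeline, "los_pipeline"))
  inv_log_transform(invert_minmax(pipeline$target$minmax, y_model))
}

#' Columns of a model frame belonging to a feature subset
#'
#' Dummy-encoded indicator columns inherit the selection status of their
#' parent categorical feature.
#'
#' @param frame a `model_frame`.
#' @param registry a `subset_registry`.
#' @param name subset name (`FS-1`..`FS-10`).
#' @return integer column indices into `frame$X`.
#' @export
subset_columns <- function(frame, registry, name) {
  feats <- registry_features(registry, name)
  idx <- which(frame$col_parent %in% feats)
  if (!length(idx))
    abort(sprintf("subset '%s' selects no model-matrix columns", name),
          "loscade_subset_error")
  idx
}
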