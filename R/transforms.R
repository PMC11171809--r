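# Statistical preprocessing: log transform, IQR winsorization, min-max
# scaling, dummy encoding, rule-based imputation and quantile target binning.
# Every fit/apply transform derives its parameters only from the data passed
# to fit (the leakage contract); quantiles use linear interpolation between
# order statistics (R type 7) throughout.

#' Log transform for nonnegative, right-skewed quantities
#'
#' Monotone map `x -> log(1 + x)`; the +1 offset admits zero-day stays.
#'
#' @param x nonnegative numeric vector.
#' @return transformed vector.
#' @export
log_transform <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    abort("log_transform requires nonnegative input", "loscade_domain_error")
  log1p(x)
}

#' @rdname log_transform
#' @param y values on the transformed scale.
#' @export
inv_log_transform <- function(y) expm1(y)

#' Fit an IQR winsorizer
#'
#' Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are computed on the input;
#' values below the lower fence are later replaced by the input's 10th
#' percentile and values above the upper fence by its 90th percentile.
#'
#' @param x numeric vector with at least 4 finite values.
#' @return object of class `winsorize_fit` (fences and replacement values).
#' @export
fit_winsorize <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4L)
    abort("winsorization needs at least 4 finite values",
          "loscade_domain_error")
  q <- quantile(x, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  iqr <- q[3] - q[2]
  structure(list(lower = q[2] - 1.5 * iqr, upper = q[3] + 1.5 * iqr,
                 p10 = q[1], p90 = q[4]),
            class = "winsorize_fit")
}

#' @rdname fit_winsorize
#' @param fit a `winsorize_fit`.
#' @export
apply_winsorize <- function(fit, x) {
  stopifnot(inherits(fit, "winsorize_fit"))
  out <- x
  out[!is.na(x) & x < fit$lower] <- fit$p10
  out[!is.na(x) & x > fit$upper] <- fit$p90
  out
}

#' One-shot winsorization with fence report
#' @rdname fit_winsorize
#' @return for `iqr_winsorize`: list with `values` and the `fit` report.
#' @export
iqr_winsorize <- function(x) {
  fit <- fit_winsorize(x)
  list(values = apply_winsorize(fit, x), fit = fit)
}

#' Fit / apply min-max normalization
#'
#' Fitted on the training partition only; applied values outside the training
#' range are not clipped. A constant training column maps everything to 0
#' (with a warning at fit time).
#'
#' @param x training values.
#' @return `minmax_fit` object.
#' @export
fit_minmax <- function(x) {
  rng <- range(x, na.rm = TRUE)
  if (!all(is.finite(rng)))
    abort("cannot fit min-max on all-missing column", "loscade_domain_error")
  if (rng[1] == rng[2])
    warning("constant training column; min-max maps it to 0",
            call. = FALSE)
  structure(list(min = rng[1], max = rng[2]), class = "minmax_fit")
}

#' @rdname fit_minmax
#' @param fit a `minmax_fit`.
#' @export
apply_minmax <- function(fit, x) {
  stopifnot(inherits(fit, "minmax_fit"))
  if (fit$max == fit$min) return(rep(0, length(x)))
  (x - fit$min) / (fit$max - fit$min)
}

#' @rdname fit_minmax
#' @param y scaled values to map back to the original scale.
#' @export
invert_minmax <- function(fit, y) {
  stopifnot(inherits(fit, "minmax_fit"))
  if (fit$max == fit$min) return(rep(fit$min, length(y)))
  y * (fit$max - fit$min) + fit$min
}

#' Fit / apply dummy (one-hot-minus-one) encoding
#'
#' Level lists are fitted on the training partition; a k-level feature yields
#' k-1 indicator columns (first level dropped). Levels unseen at apply time
#' produce an all-zero indicator row for that feature.
#'
#' @param df data.frame of categorical columns (character or factor).
#' @return `dummy_fit` holding per-feature level lists.
#' @export
fit_dummy <- function(df) {
  levels <- lapply(df, function(x) sort(unique(as.character(x))))
  structure(list(levels = levels), class = "dummy_fit")
}

#' @rdname fit_dummy
#' @param fit a `dummy_fit`.
#' @return for `apply_dummy`: list with `X` (numeric indicator matrix) and
#'   `parent` (the source feature of each column).
#' @export
apply_dummy <- function(fit, df) {
  stopifnot(inherits(fit, "dummy_fit"))
  cols <- list(); parents <- character()
  for (f in names(fit$levels)) {
    lv <- fit$levels[[f]]
    keep <- if (length(lv) > 1L) lv[-1L] else character()
    x <- as.character(df[[f]])
    for (l in keep) {
      cols[[paste0(f, "=", l)]] <- as.numeric(!is.na(x) & x == l)
      parents <- c(parents, f)
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else
    matrix(numeric(), nrow(df), 0)
  colnames(X) <- names(cols)
  list(X = X, parent = parents)
}

#' Impute missing values by declared feature kind
#'
#' History-count features (`history_count`) get 0; lab values and vital flags
#' (`lab_value`, `vital_flag`) get -1, a sentinel outside their natural
#' domain. A null in a feature with no declared rule is an error naming the
#' feature.
#'
#' @param features engineered feature data.frame.
#' @param meta feature metadata (`name`, `kind`).
#' @return the completed data.frame.
#' @export
impute_missing <- function(features, meta) {
  for (i in seq_len(nrow(meta))) {
    nm <- meta$name[i]
    x <- features[[nm]]
    if (!anyNA(x)) next
    fill <- switch(meta$kind[i],
                   history_count = 0,
                   lab_value = -1,
                   vital_flag = -1,
                   NULL)
    if (is.null(fill))
      abort(sprintf("missing values in feature '%s' (kind %s) with no %s",
                    nm, meta$kind[i], "imputation rule"),
            "loscade_impute_error")
    x[is.na(x)] <- fill
    features[[nm]] <- x
  }
  features
}

#' Quantile-cut binning of the LOS target
#'
#' Bins `log(1 + LOS)` into `n_bins` left-open/right-closed intervals of
#' approximately equal frequency and reports the interval table on the day
#' scale (edges back-transformed and rounded to 1 decimal). Fixed day-scale
#' edges may be supplied instead of fitting quantiles.
#'
#' @param los_days LOS values in days.
#' @param n_bins number of bins (default 4).
#' @param edges_days optional fixed day-scale interval edges
#'   (length `n_bins + 1`), e.g. `c(0, 2, 6, 11, 24)`.
#' @return `target_bundle`: `los_days`, `los_log`, `los_category`
#'   (integer labels `0..n_bins-1`), and `interval_table`
#'   (class, left, right, frequency on the day scale).
#' @export
bin_target_qcut <- function(los_days, n_bins = 4L, edges_days = NULL) {
  if (any(!is.finite(los_days)))
    abort("LOS values must be finite", "loscade_domain_error")
  los_log <- log_transform(los_days)
  if (is.null(edges_days)) {
    if (n_bins < 2L) abort("n_bins must be >= 2", "loscade_domain_error")
    edges <- quantile(los_log, probs = seq(0, 1, length.out = n_bins + 1L),
                      type = 7, names = FALSE)
    uq <- unique(edges)
    if (length(uq) < length(edges)) {
      warning(sprintf("only %d distinct quantile edges; reducing bins",
                      length(uq) - 1L), call. = FALSE)
      edges <- uq
    }
    edges_days_rep <- round(expm1(edges), 1)
  } else {
    if (is.unsorted(edges_days, strictly = TRUE))
      abort("edges_days must be strictly increasing", "loscade_domain_error")
    edges <- log_transform(edges_days)
    edges_days_rep <- edges_days
  }
  k <- length(edges) - 1L
  cat_int <- cut(los_log, breaks = edges, include.lowest = TRUE, right = TRUE,
                 labels = FALSE) - 1L
  freq <- tabulate(cat_int + 1L, nbins = k)
  interval_table <- data.frame(class = 0:(k - 1L),
                               left = edges_days_rep[-(k + 1L)],
                               right = edges_days_rep[-1L],
                               frequency = freq)
  structure(list(los_days = los_days, los_log = los_log,
                 los_category = cat_int, interval_table = interval_table,
                 edges_log = edges),
            class = "target_bundle")
}

#' Assign LOS categories using previously fitted bin edges
#' @param bundle a `target_bundle`.
#' @param los_days new LOS values in days.
#' @return integer class labels; values outside the outer edges are clamped
#'   into the first/last class.
#' @export
assign_los_category <- function(bundle, los_days) {
  stopifnot(inherits(bundle, "target_bundle"))
  edges <- bundle$edges_log
  x <- log_transform(los_days)
  k <- length(edges) - 1L
  cl <- cut(pmin(pmax(x, edges[1]), edges[k + 1L]), breaks = edges,
            include.lowest = TRUE, right = TRUE, labels = FALSE) - 1L
  as.integer(cl)
}

#' Serialize a fitted transform (or pipeline) to JSON
#' @param fit any fitted transform object in this file or a [fit_pipeline()]
#'   result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(fit, path) {
  jsonlite::write_json(unclass_deep(fit), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_deep)
    attr(x, "class") <- NULL
  }
  x
}
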