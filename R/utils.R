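#' Evaluate code with a temporary RNG seed
#'
#' Saves the caller's `.Random.seed`, seeds the generator, evaluates `code`,
#' and restores the previous state on exit, so no function in the package
#' perturbs global random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Stop with a classed condition
#' @keywords internal
#' @noRd
abort <- function(msg, class) {
  stop(structure(class = c(class, "loscade_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# floor of elapsed days between two datetimes
days_between <- function(from, to) {
  floor(as.numeric(difftime(to, from, units = "days")))
}

# 31-ary polynomial rolling hash; used only for provenance tags of configs
fnv1a <- function(x) {
  h <- 17
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# stable ISO-8601 rendering used for every datetime written to disk
iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

parse_dt <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' Row access recorder used by the leakage instrumentation
#'
#' The nested-CV harness creates one recorder per run; every stage that is
#' bound by the leakage contract (transform fitting, inner hyperparameter
#' search) reports the original row indices it touched. Tests assert that the
#' logged rows never intersect the outer test fold.
#'
#' @return an environment with `log(stage, fold, rows)` and `entries()`.
#' @export
access_recorder <- function() {
  rec <- new.env(parent = emptyenv())
  rec$entries <- list()
  rec$log <- function(stage, fold, rows) {
    rec$entries[[length(rec$entries) + 1L]] <-
      list(stage = stage, fold = fold, rows = as.integer(rows))
    invisible(NULL)
  }
  rec$get <- function() rec$entries
  class(rec) <- "access_recorder"
  rec
}

record_access <- function(recorder, stage, fold, rows) {
  if (!is.null(recorder)) recorder$log(stage, fold, rows)
  invisible(NULL)
}
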