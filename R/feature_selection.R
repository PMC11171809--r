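# Univariate feature scoring against the numeric and categorical LOS targets
# (Pearson, Kruskal-Wallis in both orientations, chi-square) and assembly of
# the named feature subsets FS-1..FS-10.

selection_kind <- function(meta) {
  ifelse(meta$kind %in% c("numeric", "history_count", "lab_value"), "numeric",
         ifelse(meta$kind %in% c("categorical", "vital_flag"), "categorical",
                "skip"))
}

#' Score features against a LOS target
#'
#' Method/kind pairing: numeric features use Pearson correlation against the
#' numeric target (`pearson`) and Kruskal-Wallis with classes as groups
#' against the categorical target (`kruskal_C`); categorical features use
#' Kruskal-Wallis with categories as groups against the numeric target
#' (`kruskal_R`) and the chi-square test of the observed contingency table
#' (no continuity correction) against the categorical target (`chi_square`).
#' Selection rules: `|r| >= 0.1` for Pearson, `p <= 0.05` for the tests.
#' Constant features are excluded with reason `"degenerate"`.
#'
#' @param features (imputed) feature table.
#' @param meta feature metadata.
#' @param target numeric LOS (regression) or integer/factor class
#'   (classification).
#' @param task `"regression"` or `"classification"`.
#' @return data.frame of `SelectionScore` rows: feature, method, statistic,
#'   p_value, selected, reason.
#' @export
score_features <- function(features, meta,
                           target, task = c("regression", "classification")) {
  task <- match.arg(task)
  skind <- selection_kind(meta)
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    if (skind[i] == "skip") next
    nm <- meta$name[i]
    x <- features[[nm]]
    degenerate <- length(unique(x[!is.na(x)])) < 2L
    if (task == "regression") {
      method <- if (skind[i] == "numeric") "pearson" else "kruskal_R"
    } else {
      method <- if (skind[i] == "numeric") "kruskal_C" else "chi_square"
    }
    stat <- NA_real_; p <- NA_real_; sel <- FALSE; reason <- ""
    if (degenerate) {
      reason <- "degenerate"
    } else if (method == "pearson") {
      stat <- suppressWarnings(cor(as.numeric(x), as.numeric(target),
                                   use = "complete.obs"))
      sel <- is.finite(stat) && abs(stat) >= 0.1
      if (!is.finite(stat)) reason <- "degenerate"
    } else if (method == "kruskal_R") {
      g <- factor(x)
      if (nlevels(g) < 2L) { reason <- "degenerate" } else {
        kt <- kruskal.test(as.numeric(target), g)
        stat <- unname(kt$statistic); p <- kt$p.value
        sel <- is.finite(p) && p <= 0.05
      }
    } else if (method == "kruskal_C") {
      g <- factor(target)
      if (nlevels(g) < 2L) { reason <- "degenerate" } else {
        kt <- kruskal.test(as.numeric(x), g)
        stat <- unname(kt$statistic); p <- kt$p.value
        sel <- is.finite(p) && p <= 0.05
      }
    } else {  # chi_square
      tab <- table(x, target)
      if (any(dim(tab) < 2L)) { reason <- "degenerate" } else {
        ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
        stat <- unname(ct$statistic); p <- ct$p.value
        sel <- is.finite(p) && p <= 0.05
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      feature = nm, method = method, statistic = stat, p_value = p,
      selected = sel, reason = reason, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

subset_method_map <- function() {
  list("FS-1" = character(),
       "FS-2" = "pearson",
       "FS-3" = "kruskal_R",
       "FS-4" = "kruskal_C",
       "FS-5" = "chi_square",
       "FS-6" = c("pearson", "kruskal_R"),
       "FS-7" = c("kruskal_C", "chi_square"),
       "FS-8" = c("kruskal_C", "kruskal_R"),
       "FS-9" = c("chi_square", "pearson"),
       "FS-10" = c("chi_square", "kruskal_R"))
}

#' Assemble the FS-1..FS-10 subset registry
#'
#' FS-1 is all features; FS-2..FS-5 are the single-method selections
#' (Pearson, Kruskal-Wallis vs numeric target, Kruskal-Wallis vs categorical
#' target, chi-square); FS-6..FS-10 are set unions of those. Feature order
#' follows `all_features`.
#'
#' @param scores row-bound [score_features()] output for both tasks.
#' @param all_features character vector of every selectable feature name.
#' @return object of class `subset_registry`.
#' @export
build_subset_registry <- function(scores, all_features) {
  methods <- subset_method_map()
  picked <- function(method)
    unique(scores$feature[scores$method == method & scores$selected])
  subsets <- list()
  for (fs in names(methods)) {
    ms <- methods[[fs]]
    feats <- if (!length(ms)) all_features else
      all_features[all_features %in% unlist(lapply(ms, picked))]
    subsets[[fs]] <- feats
  }
  structure(list(subsets = subsets, methods = methods,
                 all_features = all_features),
            class = "subset_registry")
}

#' Features of a named subset
#' @param registry a `subset_registry`.
#' @param name subset name.
#' @return ordered character vector of feature names.
#' @export
registry_features <- function(registry, name) {
  stopifnot(inherits(registry, "subset_registry"))
  if (!name %in% names(registry$subsets))
    abort(sprintf("unknown feature subset '%s'", name),
          "loscade_subset_error")
  registry$subsets[[name]]
}

#' Subset sizes of a registry
#' @param registry a `subset_registry`.
#' @return named integer vector of `|FS-k|`.
#' @export
registry_sizes <- function(registry) {
  vapply(registry$subsets, length, integer(1))
}

#' Serialize / deserialize a subset registry as JSON
#' @param registry a `subset_registry`.
#' @param path file path.
#' @return `path` (write) or a `subset_registry` (read).
#' @export
write_registry <- function(registry, path) {
  jsonlite::write_json(list(subsets = registry$subsets,
                            methods = registry$methods,
                            all_features = registry$all_features),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_registry
#' @export
read_registry <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(subsets = as.list(obj$subsets),
                 methods = as.list(obj$methods),
                 all_features = obj$all_features),
            class = "subset_registry")
}
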