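# Shared fixtures, built in code. Generated cohorts are cached per test run
# so several test files can reuse them without re-simulating.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

small_cohort <- function() cached("small_cohort", {
  loscade::generate_cohort(loscade::cohort_config(n_patients = 300, seed = 7))
})

small_engineered <- function() cached("small_engineered", {
  loscade::engineer_features(small_cohort())
})

# engineered table of ~2000 encounters used by the statistical checks
big_engineered <- function() cached("big_engineered", {
  co <- loscade::generate_cohort(loscade::cohort_config(n_patients = 3800,
                                                        seed = 2))
  loscade::engineer_features(co)
})

sample_skewness <- function(x) mean((x - mean(x))^3) / stats::sd(x)^3

dt <- function(x) as.POSIXct(x, tz = "UTC")

# hand-built raw cohort whose encounters pass every filter unless overridden
manual_cohort <- function(enc_rows, labs = NULL, surgeries = NULL,
                          prior = NULL) {
  defaults <- list(
    SEX = "M", `ADMIT-TYPE` = "Scheduled", `ADMIT-MODE` = "Walking",
    `NURSE-UNIT` = "CCU-1", `SOURCE-STRING` = "DX-0001",
    `ENCOUNTER-TYPE` = "inpatient",
    `DISCHARGE-DISPOSITION` = "Alive and discharge with approval",
    `DISCHARGE-TO-LOCATION` = "Home",
    `BIRTH-DT-TM` = dt("1980-01-01"),
    `OXYGEN-SATURATION` = 97, `RESPIRATORY-RATE` = 14, `HEART-RATE` = 72,
    `SYSTOLIC-BP` = 110, `DIASTOLIC-BP` = 70, TEMPERATURE = 36.8)
  rows <- lapply(enc_rows, function(r) {
    out <- utils::modifyList(defaults, r)
    stopifnot(!is.null(out$`ENCNTR-ID`), !is.null(out$`PATIENT-ID`),
              !is.null(out$`ADMISSION-ARRIVE-DT-TM`),
              !is.null(out$`DISCHARGE-DT-TM`))
    out
  })
  enc <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE, stringsAsFactors = FALSE)))
  empty <- loscade:::empty_cohort()
  list(encounters = enc,
       labs = labs %||% empty$labs,
       surgeries = surgeries %||% empty$surgeries,
       prior_admissions = prior %||% empty$prior_admissions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# minimal engineered-style table with a tie-free LOS target, for CV tests
toy_features <- function(n = 100, seed = 1) {
  set.seed(seed)
  sev <- runif(n)
  feats <- data.frame(
    x1 = sev + rnorm(n, 0, 0.2),
    x2 = rnorm(n),
    x3 = rnorm(n),
    grp = sample(c("a", "b", "c"), n, replace = TRUE),
    `LOS-DAYS` = exp(1.2 + 1.5 * sev + rnorm(n, 0, 0.3)),
    check.names = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(
    name = names(feats),
    kind = c("numeric", "numeric", "numeric", "categorical", "target"),
    log_los = FALSE, stringsAsFactors = FALSE)
  list(features = feats, meta = meta)
}

# Single-method selection stub with the published single-subset sizes
# (Pearson 18, Kruskal-R 37, Kruskal-C 24, chi-square 39) placed on pairwise
# disjoint domains, so every combined subset size is the sum of its parts.
# (The published combined counts are only consistent with disjoint
# constituents, which forces the chi-square and Kruskal-R selections apart
# even though both methods score categorical features.)
stub_scores_table3 <- function() {
  num <- sprintf("NUM-%02d", 1:26)
  cat <- sprintf("CAT-%02d", 1:76)
  mk <- function(features, method, selected_idx) {
    data.frame(feature = features, method = method,
               statistic = NA_real_, p_value = NA_real_,
               selected = seq_along(features) %in% selected_idx,
               reason = "", stringsAsFactors = FALSE)
  }
  list(all_features = c(num, cat),
       scores = rbind(mk(num, "pearson", 1:18),
                      mk(num, "kruskal_C", 1:24),
                      mk(cat, "kruskal_R", 40:76),
                      mk(cat, "chi_square", 1:39)))
}
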