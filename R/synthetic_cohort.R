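# Synthetic multi-table cardiac cohort generator. Emulates the schema and
# summary statistics of a tertiary-care admission extract (encounter table,
# long-format labs, surgery and prior-admission tables) with a planted
# covariate -> log-LOS link and a 4-level latent severity class, so that every
# downstream stage has known ground truth to recover.

#' Lab assay catalogue (27 assays)
#'
#' @return character vector of assay names; the first eight are the
#'   clinically retained blood tests used as per-encounter value columns.
#' @export
los_assays <- function() {
  c(los_retained_assays(),
    sprintf("ASSAY-%02d", 9:27))
}

#' Retained blood-test assays
#' @return character vector of the eight assays kept as feature columns.
#' @export
los_retained_assays <- function() {
  c("Hgb", "WBC", "Creat", "e-GFR", "Hgb A1c percent", "Na",
    "Pro-Brain Natriuretic Peptide", "Troponin-T")
}

#' Default normal ranges for vital signs
#'
#' Consumer-health reference ranges (temperature in Celsius, pressures in
#' mmHg); all overridable where consumed.
#' @return named list of `c(low, high)` pairs.
#' @export
default_vital_ranges <- function() {
  list(
    "TEMPERATURE"        = c(36.1, 37.2),
    "HEART-RATE"         = c(60, 100),
    "RESPIRATORY-RATE"   = c(12, 18),
    "OXYGEN-SATURATION"  = c(95, 100),
    "SYSTOLIC-BP"        = c(90, 120),
    "DIASTOLIC-BP"       = c(60, 80)
  )
}

#' Nurse units of the synthetic hospital
#' @return character vector of 74 unit names; `cardiac_units()` lists the
#'   subset treated as cardiac wards by the default filters.
#' @export
nurse_units <- function() c(cardiac_units(), sprintf("NU-%02d", 9:74))

#' @rdname nurse_units
#' @export
cardiac_units <- function() sprintf("CCU-%d", 1:8)

#' Map admission diagnosis strings to four source categories
#'
#' The high-cardinality admission diagnosis (`SOURCE-STRING`) is collapsed to
#' four clinical groups by a fixed deterministic lookup (a stand-in for an
#' unpublished consultant-curated grouping).
#'
#' @param x character vector of diagnosis strings of the form `DX-0123`.
#' @return factor-like character vector with levels `SC-1`..`SC-4`.
#' @export
source_category_map <- function(x) {
  idx <- suppressWarnings(as.integer(sub("^DX-", "", x)))
  idx[is.na(idx)] <- 0L
  paste0("SC-", (idx %% 4L) + 1L)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults are chosen to echo the published summary statistics of the real
#' (proprietary) cohort: right-skewed LOS with median near 7 days and
#' near-balanced quartile classes, 0.4% missing lab values, 28.5% missing
#' prior-admission dates, arrivals spanning 2018-2022 with 2018/2020 acting as
#' history-only years.
#'
#' @param n_patients number of patients (>= 0).
#' @param encounters_mean mean encounters per patient (>= 1); counts are
#'   `1 + Poisson(encounters_mean - 1)`.
#' @param seed integer seed; identical configs give byte-identical cohorts.
#' @param los_log_coefficients named numeric planted effects on log1p(LOS):
#'   `AGE_C` per year of age centred at 60, `SEX_M` male indicator,
#'   `VITALS_OUT` per out-of-range vital sign at admission.
#' @param los_log_intercept intercept of the log1p(LOS) linear predictor.
#' @param class_effect additive log1p(LOS) shift per latent severity class
#'   (classes 0..3).
#' @param noise_sd residual SD on the log scale (> 0).
#' @param missingness named fractions in `[0,1]`:
#'   `labs.RESULT-VALUE-NUMERIC`, `prior_admissions.PRIOR-ADMISSION-ARRIVE`,
#'   `prior_admissions.PRIOR-ADMISSION-DISCHARGE`.
#' @param date_range two Dates covering the generated arrivals.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 1000L,
                          encounters_mean = 1.4,
                          seed = 1L,
                          los_log_coefficients = c(AGE_C = 0.006,
                                                   SEX_M = 0.06,
                                                   VITALS_OUT = 0.06),
                          los_log_intercept = 1.3,
                          class_effect = 0.4,
                          noise_sd = 0.35,
                          missingness = c(
                            "labs.RESULT-VALUE-NUMERIC" = 0.004,
                            "prior_admissions.PRIOR-ADMISSION-ARRIVE" = 0.285,
                            "prior_admissions.PRIOR-ADMISSION-DISCHARGE" = 0.285),
                          date_range = as.Date(c("2018-01-01", "2022-12-31"))) {
  cfg <- list(n_patients = as.integer(n_patients),
              encounters_mean = encounters_mean,
              seed = as.integer(seed),
              los_log_coefficients = los_log_coefficients,
              los_log_intercept = los_log_intercept,
              class_effect = class_effect,
              noise_sd = noise_sd,
              missingness = missingness,
              date_range = as.Date(date_range))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 0L)
    abort("n_patients must be a non-negative integer", "loscade_config_error")
  if (!is.numeric(cfg$noise_sd) || cfg$noise_sd <= 0)
    abort("noise_sd must be > 0", "loscade_config_error")
  if (cfg$encounters_mean < 1)
    abort("encounters_mean must be >= 1", "loscade_config_error")
  if (any(cfg$missingness < 0 | cfg$missingness > 1))
    abort("missingness fractions must lie in [0, 1]", "loscade_config_error")
  if (length(cfg$date_range) != 2L || any(is.na(cfg$date_range)) ||
      cfg$date_range[1] >= cfg$date_range[2])
    abort("date_range must be two increasing dates", "loscade_config_error")
  invisible(cfg)
}

empty_cohort <- function() {
  enc <- data.frame(
    `ENCNTR-ID` = character(), `PATIENT-ID` = character(), SEX = character(),
    `BIRTH-DT-TM` = parse_dt(character()),
    `ADMIT-TYPE` = character(), `ADMIT-MODE` = character(),
    `NURSE-UNIT` = character(), `SOURCE-STRING` = character(),
    `ENCOUNTER-TYPE` = character(), `DISCHARGE-DISPOSITION` = character(),
    `DISCHARGE-TO-LOCATION` = character(),
    `ADMISSION-ARRIVE-DT-TM` = parse_dt(character()),
    `DISCHARGE-DT-TM` = parse_dt(character()),
    `OXYGEN-SATURATION` = numeric(), `RESPIRATORY-RATE` = numeric(),
    `HEART-RATE` = numeric(), `SYSTOLIC-BP` = numeric(),
    `DIASTOLIC-BP` = numeric(), `TEMPERATURE` = numeric(),
    check.names = FALSE, stringsAsFactors = FALSE)
  labs <- data.frame(`ENCNTR-ID` = character(), `TASK-ASSAY` = character(),
                     `RESULT-VALUE-NUMERIC` = numeric(),
                     `RESULT-DT-TM` = parse_dt(character()),
                     check.names = FALSE, stringsAsFactors = FALSE)
  surg <- data.frame(`PATIENT-ID` = character(),
                     `ARRIVE-DT-TM` = parse_dt(character()),
                     `DISCH-DT-TM` = parse_dt(character()),
                     check.names = FALSE, stringsAsFactors = FALSE)
  pri <- data.frame(`ENCNTR-ID` = character(),
                    `PRIOR-ADMISSION-ARRIVE` = parse_dt(character()),
                    `PRIOR-ADMISSION-DISCHARGE` = parse_dt(character()),
                    check.names = FALSE, stringsAsFactors = FALSE)
  list(encounters = enc, labs = labs, surgeries = surg, prior_admissions = pri)
}

#' Generate a synthetic raw cohort
#'
#' Draws patients, encounters, labs, surgeries and prior admissions with a
#' planted linear effect structure on log1p(LOS). The latent severity class
#' shifts both LOS and observable admission features (admission type, vital
#' signs, lab volume and natriuretic-peptide level), so a LOS-category
#' classifier has learnable signal. All randomness flows from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return object of class `raw_cohort`: a list of the four tables plus a
#'   hidden truth record retrievable with [planted_truth()].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  if (config$n_patients == 0L) {
    out <- empty_cohort()
    truth <- list(per_encounter = data.frame(
      `ENCNTR-ID` = character(), class = integer(), AGE_C = numeric(),
      SEX_M = numeric(), VITALS_OUT = numeric(), lp = numeric(),
      los_days = numeric(), check.names = FALSE),
      coefficients = config$los_log_coefficients,
      class_effect = config$class_effect,
      intercept = config$los_log_intercept, seed = config$seed)
    return(structure(out, truth = truth, config = config,
                     class = "raw_cohort"))
  }
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  np <- config$n_patients
  ranges <- default_vital_ranges()

  # --- patients -------------------------------------------------------------
  pid <- sprintf("P%05d", seq_len(np))
  sex <- sample(c("M", "F"), np, replace = TRUE, prob = c(0.6, 0.4))
  age_ref <- pmin(95, pmax(8, rnorm(np, 58, 15)))
  ref_date <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
  birth <- ref_date - (age_ref * 365.25 + runif(np, 0, 365)) * 86400

  # --- encounters -----------------------------------------------------------
  n_enc <- 1L + rpois(np, config$encounters_mean - 1)
  pat_of <- rep(seq_len(np), n_enc)
  ne <- length(pat_of)
  t0 <- as.POSIXct(paste(config$date_range[1], "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(config$date_range[2], "23:59:59"), tz = "UTC")
  arrive <- t0 + runif(ne, 0, as.numeric(difftime(t1, t0, units = "secs")))
  ord <- order(arrive, pat_of)
  pat_of <- pat_of[ord]; arrive <- arrive[ord]
  eid <- sprintf("E%06d", seq_len(ne))

  cls <- sample(0:3, ne, replace = TRUE)

  admit_types <- c("Scheduled", "Direct admission", "Emergency",
                   "Transfer", "Day surgery")
  type_probs <- rbind(c(.40, .20, .15, .10, .15),
                      c(.32, .20, .23, .12, .13),
                      c(.24, .18, .33, .15, .10),
                      c(.16, .15, .44, .17, .08))
  admit_type <- vapply(seq_len(ne), function(i)
    sample(admit_types, 1L, prob = type_probs[cls[i] + 1L, ]), character(1))

  admit_modes <- c("Walking", "Wheelchair", "Stretcher", "KFSH Ambulance",
                   "External Ambulance", "Helicopter", "Private Car", "Taxi",
                   "Police", "Other", "Unknown")
  admit_mode <- sample(admit_modes, ne, replace = TRUE,
                       prob = c(.25, .18, .12, .12, .08, .02, .12, .05,
                                .01, .03, .02))

  units <- nurse_units()
  cu <- cardiac_units()
  is_cardiac <- runif(ne) < 0.85
  nurse_unit <- ifelse(is_cardiac,
                       sample(cu, ne, replace = TRUE),
                       sample(setdiff(units, cu), ne, replace = TRUE))

  src_pool <- sprintf("DX-%04d", 1:400)
  source_string <- sample(src_pool, ne, replace = TRUE, prob = 1 / (1:400))

  enc_type <- sample(c("inpatient", "outpatient", "day case"), ne,
                     replace = TRUE, prob = c(.88, .08, .04))
  disposition <- sample(c("Alive and discharge with approval", "Transferred",
                          "Deceased"), ne, replace = TRUE,
                        prob = c(.92, .05, .03))
  disch_loc <- sample(c("Home", "Other facility"), ne, replace = TRUE,
                      prob = c(.93, .07))

  # --- vital signs, tied to severity class ----------------------------------
  vit <- matrix(NA_real_, ne, length(ranges),
                dimnames = list(NULL, names(ranges)))
  out_count <- integer(ne)
  p_out <- stats::plogis(-2.5 + 0.55 * cls)
  for (v in names(ranges)) {
    lo <- ranges[[v]][1]; hi <- ranges[[v]][2]; span <- hi - lo
    out <- runif(ne) < p_out
    val <- runif(ne, lo, hi)
    high_side <- runif(ne) < 0.5
    val[out & high_side] <- hi + runif(sum(out & high_side), 0.02, 0.4) * span
    val[out & !high_side] <- lo - runif(sum(out & !high_side), 0.02, 0.3) * span
    if (v == "OXYGEN-SATURATION") val <- pmin(val, 100)
    vit[, v] <- round(val, 1)
    out_count <- out_count + as.integer(out)
  }

  # --- planted LOS ----------------------------------------------------------
  age_at <- floor(as.numeric(difftime(arrive, birth[pat_of],
                                      units = "days")) / 365.25)
  co <- config$los_log_coefficients
  lp_mean <- config$los_log_intercept + config$class_effect * cls +
    co[["AGE_C"]] * (age_at - 60) + co[["SEX_M"]] * (sex[pat_of] == "M") +
    co[["VITALS_OUT"]] * out_count
  lp <- lp_mean + rnorm(ne, 0, config$noise_sd)
  los_frac <- pmax(0.02, expm1(lp))
  discharge <- arrive + los_frac * 86400

  encounters <- data.frame(
    `ENCNTR-ID` = eid, `PATIENT-ID` = pid[pat_of], SEX = sex[pat_of],
    `BIRTH-DT-TM` = birth[pat_of],
    `ADMIT-TYPE` = admit_type, `ADMIT-MODE` = admit_mode,
    `NURSE-UNIT` = nurse_unit, `SOURCE-STRING` = source_string,
    `ENCOUNTER-TYPE` = enc_type, `DISCHARGE-DISPOSITION` = disposition,
    `DISCHARGE-TO-LOCATION` = disch_loc,
    `ADMISSION-ARRIVE-DT-TM` = arrive, `DISCHARGE-DT-TM` = discharge,
    check.names = FALSE, stringsAsFactors = FALSE)
  encounters <- cbind(encounters,
                      as.data.frame(vit, check.names = FALSE))

  # --- labs -----------------------------------------------------------------
  assays <- los_assays()
  n_lab <- rpois(ne, 3 + 1.5 * cls)
  lab_enc <- rep(seq_len(ne), n_lab)
  nl <- length(lab_enc)
  w <- c(rep(2, 8), rep(1, 19))
  lab_assay <- sample(assays, nl, replace = TRUE, prob = w / sum(w))
  meanlog <- setNames(log(10) + 0.15 * seq_along(assays), assays)
  lab_val <- exp(rnorm(nl, meanlog[lab_assay], 0.5))
  bnp <- lab_assay == "Pro-Brain Natriuretic Peptide"
  lab_val[bnp] <- lab_val[bnp] * exp(0.3 * cls[lab_enc[bnp]])
  lab_dt <- arrive[lab_enc] - runif(nl, 0, 40) * 86400
  labs <- data.frame(`ENCNTR-ID` = eid[lab_enc], `TASK-ASSAY` = lab_assay,
                     `RESULT-VALUE-NUMERIC` = round(lab_val, 2),
                     `RESULT-DT-TM` = lab_dt,
                     check.names = FALSE, stringsAsFactors = FALSE)
  labs <- labs[order(labs$`ENCNTR-ID`, labs$`RESULT-DT-TM`), , drop = FALSE]
  rownames(labs) <- NULL

  # --- surgeries ------------------------------------------------------------
  has_surg <- runif(np) < 0.35
  n_surg <- ifelse(has_surg, sample(1:2, np, replace = TRUE), 0L)
  surg_pat <- rep(seq_len(np), n_surg)
  ns <- length(surg_pat)
  s_arr <- t0 + runif(ns, 0, as.numeric(difftime(t1, t0, units = "secs")))
  s_dis <- s_arr + runif(ns, 0.2, 10) * 86400
  surgeries <- data.frame(`PATIENT-ID` = pid[surg_pat],
                          `ARRIVE-DT-TM` = s_arr, `DISCH-DT-TM` = s_dis,
                          check.names = FALSE, stringsAsFactors = FALSE)
  surgeries <- surgeries[order(surgeries$`PATIENT-ID`,
                               surgeries$`ARRIVE-DT-TM`), , drop = FALSE]
  rownames(surgeries) <- NULL

  # --- prior admissions (with injected missingness) -------------------------
  o <- order(pat_of, arrive, eid)
  prev_same <- c(FALSE, pat_of[o][-1] == pat_of[o][-ne])
  cur_idx <- o[prev_same]
  prev_idx <- o[which(prev_same) - 1L]
  pri <- data.frame(`ENCNTR-ID` = eid[cur_idx],
                    `PRIOR-ADMISSION-ARRIVE` = arrive[prev_idx],
                    `PRIOR-ADMISSION-DISCHARGE` = discharge[prev_idx],
                    check.names = FALSE, stringsAsFactors = FALSE)
  miss <- config$missingness
  inject <- function(x, frac) {
    x[runif(length(x)) < frac] <- NA
    x
  }
  if (nrow(pri)) {
    pri$`PRIOR-ADMISSION-ARRIVE` <-
      inject(pri$`PRIOR-ADMISSION-ARRIVE`,
             miss[["prior_admissions.PRIOR-ADMISSION-ARRIVE"]])
    pri$`PRIOR-ADMISSION-DISCHARGE` <-
      inject(pri$`PRIOR-ADMISSION-DISCHARGE`,
             miss[["prior_admissions.PRIOR-ADMISSION-DISCHARGE"]])
  }
  pri <- pri[order(pri$`ENCNTR-ID`), , drop = FALSE]
  rownames(pri) <- NULL
  labs$`RESULT-VALUE-NUMERIC` <-
    inject(labs$`RESULT-VALUE-NUMERIC`, miss[["labs.RESULT-VALUE-NUMERIC"]])

  truth <- list(
    per_encounter = data.frame(
      `ENCNTR-ID` = eid, class = cls, AGE_C = age_at - 60,
      SEX_M = as.numeric(sex[pat_of] == "M"), VITALS_OUT = out_count,
      lp = lp, los_days = floor(los_frac), check.names = FALSE),
    coefficients = config$los_log_coefficients,
    class_effect = config$class_effect,
    intercept = config$los_log_intercept,
    noise_sd = config$noise_sd,
    seed = config$seed)

  structure(list(encounters = encounters, labs = labs, surgeries = surgeries,
                 prior_admissions = pri),
            truth = truth, config = config, class = "raw_cohort")
}

#' Retrieve the planted ground truth of a generated cohort
#'
#' @param cohort a `raw_cohort` produced by [generate_cohort()].
#' @return list with `per_encounter` (latent class, generating covariates,
#'   noiseless and realized linear predictors), the generating coefficients,
#'   class effect, intercept and seed.
#' @export
planted_truth <- function(cohort) {
  if (!inherits(cohort, "raw_cohort") || is.null(attr(cohort, "truth")))
    abort("cohort was not produced by generate_cohort()",
          "loscade_truth_error")
  attr(cohort, "truth")
}

#' Write a cohort as one CSV per table (plus a truth sidecar)
#'
#' Datetimes are serialized as ISO-8601 UTC; output is byte-identical for
#' identical configurations.
#'
#' @param cohort a `raw_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "raw_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fmt <- function(df) {
    for (cl in names(df)) if (inherits(df[[cl]], "POSIXct"))
      df[[cl]] <- iso8601(df[[cl]])
    df
  }
  for (tb in names(cohort)) {
    data.table::fwrite(fmt(cohort[[tb]]), file.path(dir, paste0(tb, ".csv")),
                       quote = TRUE, na = "")
  }
  truth <- planted_truth(cohort)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing the four CSV tables.
#' @return a `raw_cohort` (with truth reattached when `truth.json` exists).
#' @export
read_cohort <- function(dir) {
  rd <- function(name, dt_cols) {
    f <- file.path(dir, paste0(name, ".csv"))
    if (!file.exists(f)) abort(paste0("missing table file: ", f),
                               "loscade_schema_error")
    df <- as.data.frame(data.table::fread(f, na.strings = ""),
                        check.names = FALSE)
    for (cl in intersect(dt_cols, names(df))) df[[cl]] <- parse_dt(df[[cl]])
    df
  }
  out <- list(
    encounters = rd("encounters", c("BIRTH-DT-TM", "ADMISSION-ARRIVE-DT-TM",
                                    "DISCHARGE-DT-TM")),
    labs = rd("labs", "RESULT-DT-TM"),
    surgeries = rd("surgeries", c("ARRIVE-DT-TM", "DISCH-DT-TM")),
    prior_admissions = rd("prior_admissions",
                          c("PRIOR-ADMISSION-ARRIVE",
                            "PRIOR-ADMISSION-DISCHARGE")))
  truth <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(out, truth = truth, class = "raw_cohort")
}
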