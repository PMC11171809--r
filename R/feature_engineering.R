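# Turns a raw multi-table cohort into one engineered row per training
# encounter: cohort filters, admission/surgery history features, vital-sign
# range flags, lab aggregates and age.

required_encounter_cols <- c(
  "ENCNTR-ID", "PATIENT-ID", "SEX", "BIRTH-DT-TM", "ADMIT-TYPE", "ADMIT-MODE",
  "NURSE-UNIT", "SOURCE-STRING", "ENCOUNTER-TYPE", "DISCHARGE-DISPOSITION",
  "DISCHARGE-TO-LOCATION", "ADMISSION-ARRIVE-DT-TM", "DISCHARGE-DT-TM")

check_schema <- function(df, cols, table) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    abort(sprintf("table '%s' is missing required column(s): %s",
                  table, paste(missing, collapse = ", ")),
          "loscade_schema_error")
  invisible(df)
}

#' Completed age in years at arrival
#'
#' Calendar arithmetic (not day counting): the age increments on the
#' anniversary of the birth date.
#'
#' @param birth,arrive POSIXct vectors, `arrive >= birth`.
#' @return integer vector of completed years.
#' @export
compute_age <- function(birth, arrive) {
  if (any(arrive < birth, na.rm = TRUE))
    abort("arrival datetime precedes birth datetime", "loscade_data_error")
  b <- as.POSIXlt(birth, tz = "UTC")
  a <- as.POSIXlt(arrive, tz = "UTC")
  age <- a$year - b$year
  not_yet <- (a$mon < b$mon) | (a$mon == b$mon & a$mday < b$mday)
  as.integer(age - not_yet)
}

#' Apply the cohort inclusion filters
#'
#' The training set keeps cardiac nurse units, inpatient encounters discharged
#' alive with approval to home, patients aged 14+ and arrivals in the training
#' years; every encounter (including excluded-year ones) is retained in a
#' history index so prior-admission features can still see it.
#'
#' @param cohort a `raw_cohort` (or list with the same tables).
#' @param units character vector of nurse units treated as cardiac wards.
#' @param training_years integer arrival years kept for training.
#' @param min_age minimum age in completed years.
#' @return list with `training` and `history` encounter tables.
#' @export
filter_encounters <- function(cohort, units = cardiac_units(),
                              training_years = c(2019L, 2021L, 2022L),
                              min_age = 14L) {
  enc <- check_schema(cohort$encounters, required_encounter_cols, "encounters")
  if (nrow(enc) == 0L) return(list(training = enc, history = enc))
  age <- compute_age(enc$`BIRTH-DT-TM`, enc$`ADMISSION-ARRIVE-DT-TM`)
  year <- as.POSIXlt(enc$`ADMISSION-ARRIVE-DT-TM`, tz = "UTC")$year + 1900L
  keep <- enc$`NURSE-UNIT` %in% units &
    enc$`ENCOUNTER-TYPE` == "inpatient" &
    enc$`DISCHARGE-DISPOSITION` == "Alive and discharge with approval" &
    enc$`DISCHARGE-TO-LOCATION` == "Home" &
    age >= min_age &
    year %in% training_years
  training <- enc[keep, , drop = FALSE]
  rownames(training) <- NULL
  list(training = training, history = enc)
}

# last-observation-carried-forward that preserves POSIXct class
locf <- function(x) {
  idx <- cummax(ifelse(is.na(x), 0L, seq_along(x)))
  out <- x[pmax(idx, 1L)]
  out[idx == 0L] <- x[NA_integer_]
  out
}

#' Derive admission- and surgery-history features
#'
#' Prior-admission dates come from the chronologically previous admission of
#' the same patient (shift-by-one within patient, forward-filled); residual
#' nulls are repaired from the prior-admission lookup table when it carries a
#' value. Surgery features use the latest surgery discharged at or before the
#' current arrival. Ties on arrival timestamp are broken by encounter id.
#'
#' @param training filtered encounter table.
#' @param history full encounter table (all years).
#' @param surgeries surgery table (`PATIENT-ID`, `ARRIVE-DT-TM`,
#'   `DISCH-DT-TM`).
#' @param prior_admissions lookup table (`ENCNTR-ID`,
#'   `PRIOR-ADMISSION-ARRIVE`, `PRIOR-ADMISSION-DISCHARGE`).
#' @return data.frame keyed by `ENCNTR-ID` with the history feature columns.
#' @export
derive_history_features <- function(training, history, surgeries,
                                    prior_admissions) {
  check_schema(history, c("ENCNTR-ID", "PATIENT-ID", "ADMISSION-ARRIVE-DT-TM",
                          "DISCHARGE-DT-TM"), "history")
  check_schema(surgeries, c("PATIENT-ID", "ARRIVE-DT-TM", "DISCH-DT-TM"),
               "surgeries")
  check_schema(prior_admissions,
               c("ENCNTR-ID", "PRIOR-ADMISSION-ARRIVE",
                 "PRIOR-ADMISSION-DISCHARGE"), "prior_admissions")
  out <- data.frame(`ENCNTR-ID` = training$`ENCNTR-ID`, check.names = FALSE,
                    stringsAsFactors = FALSE)
  n <- nrow(training)
  cols <- c("HAS-PRIOR-ADMISSION", "PRIOR-LOS-DAYS", "LAST-ADMISSION-DAYS",
            "LAST-YEAR-ADMISSION-COUNT", "LAST-YEAR-LOS-MAX",
            "HAS-PRIOR-SURGERY", "HAS-PRIOR-SURGERY-60-DAYS",
            "LAST-SURGERY-DAYS")
  for (cl in cols) out[[cl]] <- rep(NA_real_, n)
  if (n == 0L) return(out)

  h <- history[order(history$`PATIENT-ID`, history$`ADMISSION-ARRIVE-DT-TM`,
                     history$`ENCNTR-ID`), , drop = FALSE]
  first_of_patient <- !duplicated(h$`PATIENT-ID`)
  pa <- h$`ADMISSION-ARRIVE-DT-TM`
  pd <- h$`DISCHARGE-DT-TM`
  # shift by one within patient
  pa <- c(pa[NA_integer_], pa[-nrow(h)]); pa[first_of_patient] <- NA
  pd <- c(pd[NA_integer_], pd[-nrow(h)]); pd[first_of_patient] <- NA
  # forward fill within patient
  for (grp in split(seq_len(nrow(h)), h$`PATIENT-ID`)) {
    pa[grp] <- locf(pa[grp])
    pd[grp] <- locf(pd[grp])
  }
  # residual nulls: fall back on the prior-admission lookup table
  m <- match(h$`ENCNTR-ID`, prior_admissions$`ENCNTR-ID`)
  fill_a <- is.na(pa) & !is.na(m)
  fill_d <- is.na(pd) & !is.na(m)
  pa[fill_a] <- prior_admissions$`PRIOR-ADMISSION-ARRIVE`[m[fill_a]]
  pd[fill_d] <- prior_admissions$`PRIOR-ADMISSION-DISCHARGE`[m[fill_d]]

  idx <- match(training$`ENCNTR-ID`, h$`ENCNTR-ID`)
  arr <- training$`ADMISSION-ARRIVE-DT-TM`
  prior_arr <- pa[idx]
  prior_dis <- pd[idx]
  out$`HAS-PRIOR-ADMISSION` <- as.numeric(!is.na(prior_arr))
  out$`PRIOR-LOS-DAYS` <- ifelse(is.na(prior_arr) | is.na(prior_dis), NA,
                                 days_between(prior_arr, prior_dis))
  out$`LAST-ADMISSION-DAYS` <- ifelse(is.na(prior_dis), NA,
                                      days_between(prior_dis, arr))

  # encounters of the same patient arriving in the 365 days before arrival
  # (half-open window, excludes the current arrival instant)
  arr_by_pat <- split(as.numeric(h$`ADMISSION-ARRIVE-DT-TM`), h$`PATIENT-ID`)
  los_by_pat <- split(pmax(0, days_between(h$`ADMISSION-ARRIVE-DT-TM`,
                                           h$`DISCHARGE-DT-TM`)),
                      h$`PATIENT-ID`)
  for (i in seq_len(n)) {
    p <- training$`PATIENT-ID`[i]
    a_num <- as.numeric(arr[i])
    past <- arr_by_pat[[p]]
    in_win <- past >= a_num - 365 * 86400 & past < a_num
    out$`LAST-YEAR-ADMISSION-COUNT`[i] <- sum(in_win)
    out$`LAST-YEAR-LOS-MAX`[i] <-
      if (any(in_win)) max(los_by_pat[[p]][in_win]) else NA_real_
  }

  # surgery recency: latest surgery discharged at/before arrival
  s <- surgeries[order(surgeries$`PATIENT-ID`, surgeries$`DISCH-DT-TM`), ,
                 drop = FALSE]
  s_by_pat <- split(as.numeric(s$`DISCH-DT-TM`), s$`PATIENT-ID`)
  for (i in seq_len(n)) {
    dis <- s_by_pat[[training$`PATIENT-ID`[i]]]
    a_num <- as.numeric(arr[i])
    before <- dis[dis <= a_num]
    if (length(before)) {
      lsd <- floor((a_num - max(before)) / 86400)
      out$`HAS-PRIOR-SURGERY`[i] <- 1
      out$`LAST-SURGERY-DAYS`[i] <- lsd
      out$`HAS-PRIOR-SURGERY-60-DAYS`[i] <- as.numeric(lsd <= 60)
    } else {
      out$`HAS-PRIOR-SURGERY`[i] <- 0
      out$`HAS-PRIOR-SURGERY-60-DAYS`[i] <- 0
    }
  }
  out
}

#' Flag vital-sign readings as inside/outside their normal range
#'
#' @param encounters encounter table carrying the vital columns.
#' @param ranges named list of `c(low, high)` per vital
#'   (default [default_vital_ranges()]).
#' @return data.frame of `<VITAL>-IN-RANGE` columns: 1 if
#'   `low <= reading <= high`, 0 otherwise, NA propagated.
#' @export
derive_vital_flags <- function(encounters, ranges = default_vital_ranges()) {
  out <- data.frame(row.names = seq_len(nrow(encounters)))
  for (v in names(ranges)) {
    r <- ranges[[v]]
    if (r[1] > r[2])
      abort(sprintf("vital range for %s has low > high", v),
            "loscade_config_error")
    x <- encounters[[v]]
    if (is.null(x)) abort(sprintf("encounters lacks vital column %s", v),
                          "loscade_schema_error")
    out[[paste0(v, "-IN-RANGE")]] <- as.numeric(x >= r[1] & x <= r[2])
  }
  out
}

#' Aggregate long-format lab results per encounter
#'
#' @param labs long lab table (`ENCNTR-ID`, `TASK-ASSAY`,
#'   `RESULT-VALUE-NUMERIC`, `RESULT-DT-TM`).
#' @param encounters table with `ENCNTR-ID` and `ADMISSION-ARRIVE-DT-TM`.
#' @param retained assays kept as per-encounter value columns.
#' @return data.frame with one `LAB-<assay>` column per retained assay
#'   (latest non-missing result at/before arrival), `TASK-ASSAY-COUNT`
#'   (all lab rows of the encounter, retained or not) and
#'   `LAST-MONTH-TASK-ASSAY-COUNT` (rows within 30 days before arrival).
#' @export
derive_lab_features <- function(labs, encounters,
                                retained = los_retained_assays()) {
  check_schema(labs, c("ENCNTR-ID", "TASK-ASSAY", "RESULT-VALUE-NUMERIC",
                       "RESULT-DT-TM"), "labs")
  eid <- encounters$`ENCNTR-ID`
  arr <- as.numeric(encounters$`ADMISSION-ARRIVE-DT-TM`)
  n <- length(eid)
  out <- data.frame(`ENCNTR-ID` = eid, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (a in retained) out[[paste0("LAB-", a)]] <- rep(NA_real_, n)
  out$`TASK-ASSAY-COUNT` <- rep(0, n)
  out$`LAST-MONTH-TASK-ASSAY-COUNT` <- rep(0, n)
  if (nrow(labs) == 0L || n == 0L) return(out)

  cnt <- table(labs$`ENCNTR-ID`)
  got <- match(eid, names(cnt))
  out$`TASK-ASSAY-COUNT` <- ifelse(is.na(got), 0, as.numeric(cnt)[got])

  lab_enc <- match(labs$`ENCNTR-ID`, eid)
  keep <- !is.na(lab_enc)
  l_enc <- lab_enc[keep]
  l_dt <- as.numeric(labs$`RESULT-DT-TM`)[keep]
  l_assay <- labs$`TASK-ASSAY`[keep]
  l_val <- labs$`RESULT-VALUE-NUMERIC`[keep]
  a_of <- arr[l_enc]

  in_month <- l_dt >= a_of - 30 * 86400 & l_dt <= a_of
  mc <- tapply(in_month, l_enc, sum)
  out$`LAST-MONTH-TASK-ASSAY-COUNT`[as.integer(names(mc))] <- as.numeric(mc)

  for (a in retained) {
    sel <- l_assay == a & !is.na(l_val) & l_dt <= a_of
    if (!any(sel)) next
    o <- order(l_enc[sel], l_dt[sel])
    enc_o <- l_enc[sel][o]
    val_o <- l_val[sel][o]
    last <- !duplicated(enc_o, fromLast = TRUE)  # latest row per encounter
    out[[paste0("LAB-", a)]][enc_o[last]] <- val_o[last]
  }
  out
}

#' Engineer the per-encounter feature table from a raw cohort
#'
#' Runs the inclusion filters and the history / vital / lab derivations, maps
#' admission diagnoses to the four source categories and computes the LOS
#' target in whole days.
#'
#' @param cohort a `raw_cohort`.
#' @param units,training_years,min_age passed to [filter_encounters()].
#' @param ranges vital range configuration.
#' @param retained retained assay list.
#' @return list with `features` (data.frame, one row per training encounter)
#'   and `meta` (data.frame of `name`, `kind`, `log_los`): kinds are `id`,
#'   `categorical`, `numeric`, `history_count`, `lab_value`, `vital_flag`,
#'   `target`; `log_los` marks LOS-derived columns that get the log
#'   transform.
#' @export
engineer_features <- function(cohort, units = cardiac_units(),
                              training_years = c(2019L, 2021L, 2022L),
                              min_age = 14L,
                              ranges = default_vital_ranges(),
                              retained = los_retained_assays()) {
  fl <- filter_encounters(cohort, units, training_years, min_age)
  tr <- fl$training
  hist_feats <- derive_history_features(tr, fl$history, cohort$surgeries,
                                        cohort$prior_admissions)
  vit_flags <- derive_vital_flags(tr)
  lab_feats <- derive_lab_features(cohort$labs, tr, retained)

  feats <- data.frame(
    `ENCNTR-ID` = tr$`ENCNTR-ID`, `PATIENT-ID` = tr$`PATIENT-ID`,
    SEX = tr$SEX, `ADMIT-TYPE` = tr$`ADMIT-TYPE`,
    `ADMIT-MODE` = tr$`ADMIT-MODE`, `NURSE-UNIT` = tr$`NURSE-UNIT`,
    `SOURCE-CATEGORY` = source_category_map(tr$`SOURCE-STRING`),
    AGE = if (nrow(tr)) compute_age(tr$`BIRTH-DT-TM`,
                                    tr$`ADMISSION-ARRIVE-DT-TM`) else integer(),
    check.names = FALSE, stringsAsFactors = FALSE)
  for (v in names(ranges)) feats[[v]] <- tr[[v]]
  feats <- cbind(feats, vit_flags,
                 hist_feats[setdiff(names(hist_feats), "ENCNTR-ID")],
                 lab_feats[setdiff(names(lab_feats), "ENCNTR-ID")])
  feats$`LOS-DAYS` <- if (nrow(tr)) {
    pmax(0, days_between(tr$`ADMISSION-ARRIVE-DT-TM`, tr$`DISCHARGE-DT-TM`))
  } else numeric()
  rownames(feats) <- NULL

  kind <- c(
    setNames(rep("id", 2), c("ENCNTR-ID", "PATIENT-ID")),
    setNames(rep("categorical", 5),
             c("SEX", "ADMIT-TYPE", "ADMIT-MODE", "NURSE-UNIT",
               "SOURCE-CATEGORY")),
    AGE = "numeric",
    setNames(rep("numeric", length(ranges)), names(ranges)),
    setNames(rep("vital_flag", length(ranges)),
             paste0(names(ranges), "-IN-RANGE")),
    `HAS-PRIOR-ADMISSION` = "categorical",
    `PRIOR-LOS-DAYS` = "history_count",
    `LAST-ADMISSION-DAYS` = "history_count",
    `LAST-YEAR-ADMISSION-COUNT` = "history_count",
    `LAST-YEAR-LOS-MAX` = "history_count",
    `HAS-PRIOR-SURGERY` = "categorical",
    `HAS-PRIOR-SURGERY-60-DAYS` = "categorical",
    `LAST-SURGERY-DAYS` = "history_count",
    setNames(rep("lab_value", length(retained)), paste0("LAB-", retained)),
    `TASK-ASSAY-COUNT` = "numeric",
    `LAST-MONTH-TASK-ASSAY-COUNT` = "numeric",
    `LOS-DAYS` = "target")
  stopifnot(setequal(names(kind), names(feats)))
  meta <- data.frame(name = names(feats), kind = kind[names(feats)],
                     row.names = NULL, stringsAsFactors = FALSE)
  meta$log_los <- meta$name %in% c("PRIOR-LOS-DAYS", "LAST-YEAR-LOS-MAX")
  list(features = feats, meta = meta)
}

#' Write engineered features and their metadata
#' @param engineered result of [engineer_features()].
#' @param path CSV path for the feature table; metadata JSON is written next
#'   to it with extension `.meta.json`.
#' @return `path`, invisibly.
#' @export
write_features <- function(engineered, path) {
  data.table::fwrite(engineered$features, path, quote = TRUE, na = "")
  jsonlite::write_json(engineered$meta,
                       sub("\\.csv$", ".meta.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
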