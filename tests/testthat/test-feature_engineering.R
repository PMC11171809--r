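test_that("compute_age does calendar arithmetic on completed years", {
  expect_equal(compute_age(dt("2000-01-01"), dt("2020-01-01")), 20L)
  expect_equal(compute_age(dt("2000-06-01"), dt("2020-05-31")), 19L)
  expect_equal(compute_age(dt("2000-06-01"), dt("2020-06-01")), 20L)
  expect_equal(compute_age(dt("2000-01-01"), dt("2000-01-01")), 0L)
  expect_error(compute_age(dt("2000-01-02"), dt("2000-01-01")),
               class = "loscade_data_error")
})

test_that("filters keep only the cardiac inpatient training population", {
  base <- list(`ADMISSION-ARRIVE-DT-TM` = dt("2019-06-01"),
               `DISCHARGE-DT-TM` = dt("2019-06-05"))
  rows <- list(
    c(base, list(`ENCNTR-ID` = "E1", `PATIENT-ID` = "P1")),
    c(base, list(`ENCNTR-ID` = "E2", `PATIENT-ID` = "P2",
                 `BIRTH-DT-TM` = dt("2006-01-01"))),          # age 13
    c(base, list(`ENCNTR-ID` = "E3", `PATIENT-ID` = "P3",
                 `NURSE-UNIT` = "NU-20")),                     # not cardiac
    c(base, list(`ENCNTR-ID` = "E4", `PATIENT-ID` = "P4",
                 `ENCOUNTER-TYPE` = "outpatient")),
    list(`ENCNTR-ID` = "E5", `PATIENT-ID` = "P5",              # 2020 arrival
         `ADMISSION-ARRIVE-DT-TM` = dt("2020-03-01"),
         `DISCHARGE-DT-TM` = dt("2020-03-04")))
  co <- manual_cohort(rows)
  fl <- filter_encounters(co)
  expect_equal(fl$training$`ENCNTR-ID`, "E1")
  expect_true("E5" %in% fl$history$`ENCNTR-ID`)
  expect_equal(nrow(fl$history), 5L)
})

test_that("empty cohorts filter to empty training and history", {
  fl <- filter_encounters(generate_cohort(cohort_config(n_patients = 0)))
  expect_equal(nrow(fl$training), 0L)
  expect_equal(nrow(fl$history), 0L)
})

test_that("schema errors name the missing column", {
  co <- manual_cohort(list(list(`ENCNTR-ID` = "E1", `PATIENT-ID` = "P1",
                                `ADMISSION-ARRIVE-DT-TM` = dt("2019-01-01"),
                                `DISCHARGE-DT-TM` = dt("2019-01-02"))))
  co$encounters$`NURSE-UNIT` <- NULL
  expect_error(filter_encounters(co), "NURSE-UNIT",
               class = "loscade_schema_error")
})

test_that("history features match the date-arithmetic oracle", {
  rows <- list(
    list(`ENCNTR-ID` = "E1", `PATIENT-ID` = "P1",
         `ADMISSION-ARRIVE-DT-TM` = dt("2019-01-01"),
         `DISCHARGE-DT-TM` = dt("2019-01-05")),
    list(`ENCNTR-ID` = "E2", `PATIENT-ID` = "P1",
         `ADMISSION-ARRIVE-DT-TM` = dt("2019-02-04"),
         `DISCHARGE-DT-TM` = dt("2019-02-08")))
  co <- manual_cohort(rows)
  fl <- filter_encounters(co)
  hf <- derive_history_features(fl$training, fl$history, co$surgeries,
                                co$prior_admissions)
  first <- hf[hf$`ENCNTR-ID` == "E1", ]
  expect_equal(first$`HAS-PRIOR-ADMISSION`, 0)
  expect_equal(first$`LAST-YEAR-ADMISSION-COUNT`, 0)
  second <- hf[hf$`ENCNTR-ID` == "E2", ]
  expect_equal(second$`HAS-PRIOR-ADMISSION`, 1)
  expect_equal(second$`PRIOR-LOS-DAYS`, 4)
  expect_equal(second$`LAST-ADMISSION-DAYS`, 30)
  expect_equal(second$`LAST-YEAR-ADMISSION-COUNT`, 1)
  expect_equal(second$`LAST-YEAR-LOS-MAX`, 4)
})

test_that("excluded-year encounters still feed prior-admission features", {
  rows <- list(
    list(`ENCNTR-ID` = "E1", `PATIENT-ID` = "P1",
         `ADMISSION-ARRIVE-DT-TM` = dt("2020-05-01"),
         `DISCHARGE-DT-TM` = dt("2020-05-03")),
    list(`ENCNTR-ID` = "E2", `PATIENT-ID` = "P1",
         `ADMISSION-ARRIVE-DT-TM` = dt("2021-02-01"),
         `DISCHARGE-DT-TM` = dt("2021-02-06")))
  co <- manual_cohort(rows)
  fl <- filter_encounters(co)
  expect_equal(fl$training$`ENCNTR-ID`, "E2")
  hf <- derive_history_features(fl$training, fl$history, co$surgeries,
                                co$prior_admissions)
  expect_equal(hf$`HAS-PRIOR-ADMISSION`, 1)
  expect_equal(hf$`PRIOR-LOS-DAYS`, 2)
})

test_that("surgery recency flags follow the 60-day rule", {
  mk <- function(days_before) {
    arr <- dt("2021-06-01")
    co <- manual_cohort(
      list(list(`ENCNTR-ID` = "E1", `PATIENT-ID` = "P1",
                `ADMISSION-ARRIVE-DT-TM` = arr,
                `DISCHARGE-DT-TM` = arr + 3 * 86400)),
      surgeries = data.frame(
        `PATIENT-ID` = "P1",
        `ARRIVE-DT-TM` = arr - (days_before + 2) * 86400,
        `DISCH-DT-TM` = arr - days_before * 86400,
        check.names = FALSE))
    fl <- filter_encounters(co)
    derive_history_features(fl$training, fl$history, co$surgeries,
                            co$prior_admissions)
  }
  h59 <- mk(59)
  expect_equal(h59$`HAS-PRIOR-SURGERY`, 1)
  expect_equal(h59$`HAS-PRIOR-SURGERY-60-DAYS`, 1)
  expect_equal(h59$`LAST-SURGERY-DAYS`, 59)
  h61 <- mk(61)
  expect_equal(h61$`HAS-PRIOR-SURGERY`, 1)
  expect_equal(h61$`HAS-PRIOR-SURGERY-60-DAYS`, 0)
})

test_that("vital flags classify against the configured ranges", {
  enc <- data.frame(`HEART-RATE` = c(72, 130, NA), check.names = FALSE)
  fl <- derive_vital_flags(enc, ranges = list("HEART-RATE" = c(60, 100)))
  expect_equal(fl$`HEART-RATE-IN-RANGE`, c(1, 0, NA))
  expect_error(derive_vital_flags(enc, list("HEART-RATE" = c(100, 60))),
               class = "loscade_config_error")
})

test_that("lab aggregation keeps the latest pre-arrival value and counts all rows", {
  arr <- dt("2021-06-01")
  enc <- data.frame(`ENCNTR-ID` = "E1", `ADMISSION-ARRIVE-DT-TM` = arr,
                    check.names = FALSE)
  labs <- data.frame(
    `ENCNTR-ID` = "E1",
    `TASK-ASSAY` = c("Hgb", "Hgb", "Hgb", "ASSAY-09"),
    `RESULT-VALUE-NUMERIC` = c(10, 12, 11, 5),
    `RESULT-DT-TM` = arr - c(10, 2, 5, 1) * 86400,
    check.names = FALSE)
  lf <- derive_lab_features(labs, enc)
  expect_equal(lf$`LAB-Hgb`, 12)             # latest of the three
  expect_equal(lf$`TASK-ASSAY-COUNT`, 4)     # non-retained assay counts too
  expect_true(is.na(lf$`LAB-WBC`))
  expect_equal(lf$`LAST-MONTH-TASK-ASSAY-COUNT`, 4)

  none <- derive_lab_features(labs[0, ], enc)
  expect_equal(none$`TASK-ASSAY-COUNT`, 0)
  expect_true(is.na(none$`LAB-Hgb`))
})

test_that("lab aggregation agrees with a brute-force oracle on random data", {
  set.seed(42)
  arr0 <- dt("2021-06-01")
  enc <- data.frame(`ENCNTR-ID` = sprintf("E%02d", 1:12),
                    `ADMISSION-ARRIVE-DT-TM` = arr0 + (1:12) * 86400,
                    check.names = FALSE)
  labs <- data.frame(
    `ENCNTR-ID` = sample(enc$`ENCNTR-ID`, 200, replace = TRUE),
    `TASK-ASSAY` = sample(los_assays(), 200, replace = TRUE),
    `RESULT-VALUE-NUMERIC` = round(runif(200, 1, 100), 2),
    `RESULT-DT-TM` = arr0 + runif(200, -50, 20) * 86400,
    check.names = FALSE)
  lf <- derive_lab_features(labs, enc)
  for (i in seq_len(nrow(enc))) {
    sub <- labs[labs$`ENCNTR-ID` == enc$`ENCNTR-ID`[i], ]
    expect_equal(lf$`TASK-ASSAY-COUNT`[i], nrow(sub))
    arr <- enc$`ADMISSION-ARRIVE-DT-TM`[i]
    expect_equal(lf$`LAST-MONTH-TASK-ASSAY-COUNT`[i],
                 sum(sub$`RESULT-DT-TM` >= arr - 30 * 86400 &
                       sub$`RESULT-DT-TM` <= arr))
    for (a in c("Hgb", "Troponin-T")) {
      sa <- sub[sub$`TASK-ASSAY` == a & sub$`RESULT-DT-TM` <= arr, ]
      want <- if (nrow(sa)) sa$`RESULT-VALUE-NUMERIC`[which.max(
        as.numeric(sa$`RESULT-DT-TM`))] else NA_real_
      expect_equal(lf[[paste0("LAB-", a)]][i], want)
    }
  }
})

test_that("engineering is row-order independent and lossless", {
  co <- small_cohort()
  eng1 <- engineer_features(co)
  co2 <- co
  set.seed(1)
  for (tb in names(co2)) {
    co2[[tb]] <- co2[[tb]][sample(nrow(co2[[tb]])), , drop = FALSE]
    rownames(co2[[tb]]) <- NULL
  }
  attr(co2, "truth") <- attr(co, "truth")
  class(co2) <- "raw_cohort"
  eng2 <- engineer_features(co2)
  o1 <- eng1$features[order(eng1$features$`ENCNTR-ID`), ]
  o2 <- eng2$features[order(eng2$features$`ENCNTR-ID`), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  # no row loss or duplication relative to the filter
  fl <- filter_encounters(co)
  expect_equal(nrow(eng1$features), nrow(fl$training))
  expect_equal(anyDuplicated(eng1$features$`ENCNTR-ID`), 0L)
})

test_that("engineered invariants hold on a generated cohort", {
  eng <- small_engineered()
  f <- eng$features
  expect_true(all(f$AGE >= 14))
  expect_true(all(f$`LAST-MONTH-TASK-ASSAY-COUNT` <= f$`TASK-ASSAY-COUNT`))
  expect_true(all(f$`HAS-PRIOR-SURGERY`[f$`HAS-PRIOR-SURGERY-60-DAYS` == 1]
                  == 1))
  has_prior <- f$`HAS-PRIOR-ADMISSION` == 1
  expect_false(anyNA(f$`PRIOR-LOS-DAYS`[has_prior]))
  expect_true(all(is.na(f$`PRIOR-LOS-DAYS`[!has_prior])))
  expect_true(all(f$`SOURCE-CATEGORY` %in% paste0("SC-", 1:4)))
})
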