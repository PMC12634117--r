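# Grade recalibration, ECG-echo pairing, discrete-time survival labels,
# exclusions, patient-level splitting, and evaluation-set selection.

test_that("grade recalibration records the least severe assessment", {
  expect_equal(as.character(recalibrate_grade("moderate-severe MR")), "moderate")
  expect_equal(as.character(recalibrate_grade("mild")), "mild")
  expect_equal(as.character(recalibrate_grade("mild to moderate")), "mild")
  expect_equal(as.character(recalibrate_grade(
    c("Severe TR", "none", "MODERATE to severe"))),
    c("severe", "none", "moderate"))
  expect_error(recalibrate_grade("normal valve function"), "unparseable")
})

test_that("pairing keeps the nearest echo within 60 days, one per ECG", {
  ecgs <- data.frame(patient_id = "A", ecg_id = c("e0", "e61"),
                     date = as.Date(c("2020-01-01", "2021-01-01")))
  echos <- data.frame(patient_id = "A",
                      date = as.Date(c("2020-01-04", "2020-01-11", "2021-03-03")),
                      mr_grade = "mild", ar_grade = "none", tr_grade = "none")
  p <- pair_ecg_echo(ecgs, echos)
  expect_equal(nrow(p), 1)             # day-61 echo is out of window
  expect_equal(p$ecg_id, "e0")
  expect_equal(p$interval_days, 3)     # day-3 echo beats day-10
  # same-day echo pairs at interval 0
  p0 <- pair_ecg_echo(data.frame(patient_id = "A", ecg_id = "e", date = echos$date[1]),
                      echos)
  expect_equal(p0$interval_days, 0)
  # equidistant tie goes to the earlier echo
  tie <- data.frame(patient_id = "A",
                    date = as.Date(c("2019-12-29", "2020-01-04")),
                    mr_grade = c("mild", "moderate"), ar_grade = "none",
                    tr_grade = "none")
  pt <- pair_ecg_echo(ecgs[1, ], tie)
  expect_equal(pt$interval_days, -3)
  expect_equal(pt$mr_grade, "mild")
})

test_that("pairing is stable under row permutation", {
  co <- mid_cohort()
  et <- ecg_table(co)
  p1 <- pair_ecg_echo(et, co$echos)
  perm_e <- withr::with_seed(5, sample(nrow(et)))
  perm_x <- withr::with_seed(6, sample(nrow(co$echos)))
  p2 <- pair_ecg_echo(et[perm_e, ], co$echos[perm_x, ])
  rownames(p1) <- rownames(p2) <- NULL
  expect_identical(p1[order(p1$ecg_id), c("ecg_id", "echo_date", "interval_days")],
                   p2[order(p2$ecg_id), c("ecg_id", "echo_date", "interval_days")])
})

make_labels <- function(ecg_date, echo_dates, grades, interval = 0) {
  ecgs <- data.frame(patient_id = "A", ecg_id = "e1", date = as.Date(ecg_date))
  echos <- data.frame(patient_id = "A", date = as.Date(echo_dates),
                      mr_grade = grades, ar_grade = "none", tr_grade = "none")
  build_survival_labels(pair_ecg_echo(ecgs, echos, keep_unpaired = TRUE),
                        echos, "mr")
}

test_that("prevalent disease is encoded at the first timepoint only", {
  lab <- make_labels("2020-01-01", "2020-01-05", "moderate")
  expect_equal(lab$y[1, ], c(1, rep(0, 6)))
  expect_equal(lab$mask[1, ], c(1, rep(0, 6)))
  expect_true(lab$prevalent[1])
})

test_that("an incident event lands in the interval containing it", {
  # yearly grid: event at ~2.5 y -> y = [0,0,0,1, masked...]
  lab <- make_labels("2020-01-01",
                     c("2020-01-05", "2021-01-05", "2022-07-01"),
                     c("mild", "mild", "moderate"))
  expect_equal(lab$y[1, ], c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(lab$mask[1, ], c(1, 1, 1, 1, 0, 0, 0))
  expect_true(lab$event[1] && !lab$prevalent[1])
  expect_equal(lab$event_time[1], as.numeric(as.Date("2022-07-01") - as.Date("2020-01-01")) / 365.25)
})

test_that("censoring observes only fully covered intervals", {
  # censored at ~1.5 y: baseline and (60 d, 1 y] observed, (1,2] masked
  lab <- make_labels("2020-01-01", c("2020-01-05", "2021-07-01"),
                     c("mild", "none"))
  expect_equal(lab$y[1, ], rep(0, 7))
  expect_equal(lab$mask[1, ], c(1, 1, 0, 0, 0, 0, 0))
  expect_false(lab$event[1])
})

test_that("ECGs without a baseline echo get a masked first timepoint", {
  # echo series starts 6 months after the ECG: survival information only
  lab <- make_labels("2020-01-01", c("2020-07-05", "2022-07-05"),
                     c("mild", "moderate"))
  expect_equal(lab$mask[1, 1], 0)
  expect_equal(lab$y[1, ], c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(lab$mask[1, ], c(0, 1, 1, 1, 0, 0, 0))
})

test_that("significant grade before a non-prevalent baseline is flagged", {
  ecgs <- data.frame(patient_id = "A", ecg_id = "e1", date = as.Date("2020-06-01"))
  echos <- data.frame(patient_id = "A",
                      date = as.Date(c("2020-01-10", "2020-06-03")),
                      mr_grade = c("severe", "mild"), ar_grade = "none",
                      tr_grade = "none")
  expect_warning(
    lab <- build_survival_labels(pair_ecg_echo(ecgs, echos), echos, "mr"),
    "inconsisten")
  expect_true(lab$inconsistent[1])
  expect_true(all(lab$mask[1, ] == 0))
})

test_that("label construction conserves information", {
  co <- mid_cohort()
  lab <- cohort_labels(co, "mr")
  expect_true(all(rowSums(lab$y * lab$mask) %in% c(0, 1)))
  # y = 1 in the first interval iff prevalent
  expect_identical(unname(lab$y[, 1] == 1 & lab$mask[, 1] == 1), lab$prevalent)
  # nothing observed after the event interval
  for (i in which(lab$event & !lab$prevalent)) {
    k <- which(lab$y[i, ] == 1)
    if (k < ncol(lab$y)) expect_true(all(lab$mask[i, (k + 1):ncol(lab$y)] == 0))
  }
})

test_that("labels rebuilt from tables match the simulator ground truth", {
  co <- mid_cohort()
  lab <- cohort_labels(co, "tr")
  edges <- lab$edges
  p <- co$patients
  for (i in withr::with_seed(8, sample(nrow(lab$y), 80))) {
    pid <- lab$pairs$patient_id[i]
    pt <- p[p$patient_id == pid, ]
    if (lab$inconsistent[i]) next
    echo_t <- as.numeric(as.Date(co$echos$date[co$echos$patient_id == pid]) -
                           lab$pairs$ecg_date[i]) / 365.25
    # truth: disease present at echo time t iff prevalent or t (relative to
    # index date) is past the true event time
    idx_t <- as.numeric(as.Date(co$echos$date[co$echos$patient_id == pid]) -
                          pt$index_date) / 365.25
    diseased <- pt$prevalent_tr | idx_t >= pt$event_time_tr
    if (any(diseased & echo_t <= 60 / 365.25)) {
      expect_true(lab$prevalent[i])
    } else if (any(diseased & echo_t > 0)) {
      t_evt <- min(echo_t[diseased & echo_t > 0])
      k <- min(findInterval(t_evt, edges, left.open = TRUE), ncol(lab$y))
      expect_equal(unname(which(lab$y[i, ] == 1)), k)
    } else {
      expect_false(lab$event[i])
    }
  }
})

test_that("exclusions apply to evaluation but not training", {
  pts <- data.frame(patient_id = c("a", "b", "c"), age = c(50, 60, 12),
                    exclusion_flag = c(TRUE, FALSE, FALSE))
  expect_equal(apply_exclusions(pts, "evaluation")$patient_id, "b")
  expect_equal(apply_exclusions(pts, "training")$patient_id, c("a", "b"))
  noflag <- data.frame(patient_id = "a", age = 50, exclusion_flag = FALSE)
  expect_equal(nrow(apply_exclusions(noflag, "evaluation")), 1)
})

test_that("the cohort split is a deterministic patient-level partition", {
  ids <- sprintf("P%02d", 1:10)
  s <- split_cohort(ids, seed = 42)
  expect_equal(as.vector(table(s$split)[c("train", "tune", "test")]), c(5, 1, 4))
  expect_identical(s, split_cohort(ids, seed = 42))
  expect_false(identical(s$split, split_cohort(ids, seed = 43)$split))
  expect_setequal(s$patient_id, ids)
  expect_equal(anyDuplicated(s$patient_id), 0)
  s1 <- split_cohort("solo", seed = 1)
  expect_equal(nrow(s1), 1)
  expect_error(split_cohort(ids, ratios = c(0.5, 0.2, 0.4)), "sum to 1")
})

test_that("evaluation selection takes the first ECG and applies blanking", {
  co <- mid_cohort()
  lab <- cohort_labels(co, "mr")
  pred <- select_evaluation_ecgs(lab, "prediction")
  # one row per patient, the earliest paired ECG
  expect_equal(anyDuplicated(pred$pairs$patient_id), 0)
  for (pid in head(unique(pred$pairs$patient_id), 20)) {
    cand <- lab$pairs$ecg_date[lab$pairs$patient_id == pid &
                                 lab$mask[, 1] == 1]
    expect_equal(pred$pairs$ecg_date[pred$pairs$patient_id == pid], min(cand))
  }
  # no prevalent subjects, no events inside the blanking window
  expect_false(any(pred$prevalent))
  expect_true(all(pred$event_time[pred$event] > 60 / 365.25))
  dg <- select_evaluation_ecgs(lab, "diagnosis")
  expect_true(any(dg$prevalent))
  expect_equal(anyDuplicated(dg$pairs$patient_id), 0)
})
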