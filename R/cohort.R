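# Cohort construction: grade recalibration, ECG-echo pairing, discrete-time
# survival label construction with prevalent disease at the first timepoint,
# exclusions, and the patient-level 50/10/40 split.

#' Recalibrate a diagnostic grade statement to the 4-level scale
#'
#' Echo reports often state a range ("moderate-severe MR", "mild to
#' moderate"); the recalibration records the least severe grade mentioned,
#' on the ordered scale none < mild < moderate < severe.
#'
#' @param statement character vector of diagnostic statements or grades.
#' @return factor with levels `none, mild, moderate, severe`.
#' @export
recalibrate_grade <- function(statement) {
  out <- vapply(statement, function(s) {
    toks <- GRADE_LEVELS[vapply(GRADE_LEVELS, function(g)
      grepl(paste0("\\b", g, "\\b"), tolower(s)), logical(1))]
    if (!length(toks)) stopf("unparseable grade: '%s'", s)
    toks[1]  # GRADE_LEVELS is ordered least to most severe
  }, "", USE.NAMES = FALSE)
  factor(out, levels = GRADE_LEVELS, ordered = TRUE)
}

.grade_num <- function(g) {
  if (is.character(g)) g <- factor(g, levels = GRADE_LEVELS, ordered = TRUE)
  as.integer(g)
}

.is_significant <- function(g) .grade_num(g) >= 3  # moderate or severe

#' Pair each ECG with its nearest echo within a window
#'
#' Each ECG is paired to at most one echo: only echos within
#' `window_days` of the ECG qualify, and the one with the shortest absolute
#' interval wins; equidistant ties go to the earlier echo. The result is
#' independent of the input row order.
#'
#' @param ecgs data frame with `patient_id`, `ecg_id`, `date`.
#' @param echos data frame with `patient_id`, `date`, and grade/measurement
#'   columns.
#' @param window_days pairing window (default 60).
#' @param keep_unpaired also return ECGs without an in-window echo, with
#'   `NA` echo columns. The discrete-time survival model can still learn
#'   from these (their first timepoint is masked), which is how it uses
#'   more ECG-echo pairs than the baseline-window classification model.
#' @return data frame of pairs: ECG columns, echo columns, and
#'   `interval_days` (echo date minus ECG date, signed).
#' @export
pair_ecg_echo <- function(ecgs, echos, window_days = 60,
                          keep_unpaired = FALSE) {
  stopifnot(all(c("patient_id", "ecg_id", "date") %in% names(ecgs)))
  stopifnot(all(c("patient_id", "date") %in% names(echos)))
  ecgs$date <- as.Date(ecgs$date)
  echos$date <- as.Date(echos$date)
  echos <- echos[order(echos$patient_id, echos$date), , drop = FALSE]
  echos$.echo_row <- seq_len(nrow(echos))
  out <- vector("list", nrow(ecgs))
  echo_by_pt <- split(seq_len(nrow(echos)), echos$patient_id)
  unpaired_row <- function(i) {
    blank <- echos[1, setdiff(names(echos), c("patient_id", "date")),
                   drop = FALSE]
    blank[1, ] <- NA
    cbind(data.frame(ecg_id = ecgs$ecg_id[i], patient_id = ecgs$patient_id[i],
                     ecg_date = ecgs$date[i], echo_date = as.Date(NA),
                     interval_days = NA_real_, stringsAsFactors = FALSE),
          blank)
  }
  for (i in seq_len(nrow(ecgs))) {
    rows <- echo_by_pt[[as.character(ecgs$patient_id[i])]]
    iv <- if (is.null(rows)) numeric(0)
          else as.numeric(echos$date[rows] - ecgs$date[i])
    ok <- abs(iv) <= window_days
    if (is.null(rows) || !any(ok)) {
      if (keep_unpaired && nrow(echos)) out[[i]] <- unpaired_row(i)
      next
    }
    rows <- rows[ok]; iv <- iv[ok]
    pick <- order(abs(iv), echos$date[rows])[1]  # nearest; earlier on ties
    row <- echos[rows[pick], setdiff(names(echos), c("patient_id", "date")),
                 drop = FALSE]
    names(row)[names(row) == "date"] <- "echo_date"
    out[[i]] <- cbind(
      data.frame(ecg_id = ecgs$ecg_id[i], patient_id = ecgs$patient_id[i],
                 ecg_date = ecgs$date[i], echo_date = echos$date[rows[pick]],
                 interval_days = iv[pick], stringsAsFactors = FALSE),
      row)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) {
    return(data.frame(ecg_id = character(), patient_id = character(),
                      ecg_date = as.Date(character()),
                      echo_date = as.Date(character()),
                      interval_days = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$ecg_id), , drop = FALSE]
}

#' Default discrete-time interval grid
#'
#' The first interval spans the 60-day diagnosis window (prevalent disease
#' is encoded there), then (60 d, 1 y] and yearly intervals to 5 years, and
#' an open final interval.
#'
#' @return numeric vector of interval edges in years.
#' @export
default_interval_edges <- function() c(0, 60 / 365.25, 1, 2, 3, 4, 5, Inf)

#' Build discrete-time survival labels from paired baseline echos and
#' follow-up echo series
#'
#' For each ECG-echo pair, the label is a per-interval event vector `y` with
#' an observation mask:
#' * prevalent moderate-or-severe disease at the paired baseline echo puts
#'   `y = 1` in the first interval and masks all later intervals;
#' * an incident event (first follow-up echo with grade >= moderate, at time
#'   `t` after the ECG) puts `y = 0` in every interval fully observed before
#'   `t`, `y = 1` in the interval containing `t`, and masks later intervals;
#' * censoring at `c` (last echo) observes `y = 0` for intervals ending at
#'   or before `c` and masks partially observed and later intervals.
#'
#' A follow-up series whose first significant echo predates the ECG while
#' the paired baseline is non-significant is flagged as a data inconsistency
#' (`inconsistent = TRUE`) and masked entirely.
#'
#' @param pairs pairs from [pair_ecg_echo()] (must carry the grade column
#'   for `valve`).
#' @param echos full echo table (used as the follow-up series).
#' @param valve one of `"mr"`, `"ar"`, `"tr"`.
#' @param interval_edges interval edges in years.
#' @return object of class `survival_labels`: matrices `y` and `mask`
#'   (pairs x intervals), vectors `prevalent`, `event`, `time` (years,
#'   event or censoring), `event_time` (years or `NA`), plus the pair
#'   metadata.
#' @export
build_survival_labels <- function(pairs, echos, valve = "mr",
                                  interval_edges = default_interval_edges()) {
  stopifnot(valve %in% VALVES)
  gcol <- paste0(valve, "_grade")
  if (!gcol %in% names(pairs)) stopf("pairs lack column %s", gcol)
  edges <- interval_edges
  K <- length(edges) - 1
  n <- nrow(pairs)
  y <- matrix(0, n, K)
  mask <- matrix(0, n, K)
  prevalent <- .is_significant(pairs[[gcol]])
  event <- logical(n)
  etime <- rep(NA_real_, n)
  otime <- rep(NA_real_, n)
  inconsistent <- logical(n)
  echos$date <- as.Date(echos$date)
  echos <- echos[order(echos$patient_id, echos$date), , drop = FALSE]
  sig <- .is_significant(echos[[gcol]])
  by_pt <- split(seq_len(nrow(echos)), echos$patient_id)
  for (i in seq_len(n)) {
    baseline_known <- !is.na(pairs$interval_days[i])
    if (isTRUE(baseline_known && prevalent[i])) {
      y[i, 1] <- 1
      mask[i, 1] <- 1
      event[i] <- TRUE
      etime[i] <- 0
      otime[i] <- 0
      next
    }
    rows <- by_pt[[as.character(pairs$patient_id[i])]]
    tdays <- as.numeric(echos$date[rows] - pairs$ecg_date[i])
    fup <- rows[tdays > 0]
    tfup <- tdays[tdays > 0] / 365.25
    sig_first <- which(sig[rows])[1]
    sig_before <- !is.na(sig_first) && tdays[sig_first] <= 0
    if (sig_before && baseline_known) {
      # significant disease recorded before a "non-prevalent" baseline pair
      inconsistent[i] <- TRUE
      next
    }
    if (sig_before) {
      # no baseline echo in window, but disease already diagnosed earlier:
      # prevalent at the first timepoint (grades are assumed not to regress)
      y[i, 1] <- 1
      mask[i, 1] <- 1
      event[i] <- TRUE
      etime[i] <- 0
      otime[i] <- 0
      next
    }
    hit <- which(sig[fup])[1]
    if (!is.na(hit)) {
      event[i] <- TRUE
      etime[i] <- tfup[hit]
      otime[i] <- tfup[hit]
      kstar <- findInterval(etime[i], edges, left.open = TRUE)
      kstar <- min(kstar, K)
      if (kstar > 1) { y[i, 1:(kstar - 1)] <- 0; mask[i, 1:(kstar - 1)] <- 1 }
      y[i, kstar] <- 1
      mask[i, kstar] <- 1
      # baseline status is observed by the paired echo only
      mask[i, 1] <- if (baseline_known) 1 else 0
    } else {
      ctime <- if (length(tfup)) max(tfup) else 0
      otime[i] <- ctime
      obs <- which(edges[-1] <= ctime)
      mask[i, obs] <- 1
      # the paired echo itself observes the first timepoint; without it the
      # baseline status stays masked
      mask[i, 1] <- if (baseline_known) 1 else 0
    }
  }
  # significant disease at the first timepoint: baseline echo significant or
  # an event inside the baseline window; y = 1 in interval 1 iff prevalent
  prevalent <- y[, 1] == 1 & mask[, 1] == 1
  if (any(inconsistent))
    warnf("%d pair(s) flagged as data inconsistencies (significant grade before a non-prevalent baseline); their labels are fully masked",
          sum(inconsistent))
  structure(list(y = y, mask = mask, edges = edges, valve = valve,
                 prevalent = prevalent, event = event, event_time = etime,
                 time = otime, inconsistent = inconsistent, pairs = pairs),
            class = "survival_labels")
}

#' @export
print.survival_labels <- function(x, ...) {
  cat(sprintf("<survival_labels %s: %d pairs, %d intervals; %d prevalent, %d incident, %d censored>\n",
              x$valve, nrow(x$y), ncol(x$y), sum(x$prevalent),
              sum(x$event & !x$prevalent), sum(!x$event & !x$inconsistent)))
  invisible(x)
}

#' Apply training/evaluation exclusions
#'
#' Patients with a history of valve surgery, a prosthetic valve, or a
#' pacemaker/defibrillator (the `exclusion_flag`) are excluded from model
#' evaluation but retained for model training. Patients younger than
#' `min_age` are always excluded.
#'
#' @param patients data frame with `patient_id`, `age`, `exclusion_flag`.
#' @param mode `"training"` or `"evaluation"`.
#' @param min_age minimal age in years (default 14).
#' @return the filtered patient data frame.
#' @export
apply_exclusions <- function(patients, mode = c("evaluation", "training"),
                             min_age = 14) {
  mode <- match.arg(mode)
  keep <- patients$age >= min_age
  if (mode == "evaluation") keep <- keep & !patients$exclusion_flag
  patients[keep, , drop = FALSE]
}

#' Split a cohort into train/tune/test at the patient level
#'
#' Assignment is by patient, never by ECG, so no patient appears in more
#' than one group; sizes follow the ratios by largest-remainder rounding
#' and the shuffle is deterministic under the seed.
#'
#' @param patient_ids character vector of unique patient ids.
#' @param ratios train/tune/test fractions summing to 1.
#' @param seed integer seed.
#' @return data frame `patient_id`, `split` (factor train/tune/test).
#' @export
split_cohort <- function(patient_ids, ratios = c(0.5, 0.1, 0.4), seed = 1) {
  if (abs(sum(ratios) - 1) > 1e-9) stopf("ratios must sum to 1")
  patient_ids <- unique(patient_ids)
  n <- length(patient_ids)
  base <- floor(n * ratios)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * ratios - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  labels <- factor(rep(c("train", "tune", "test"), times = base),
                   levels = c("train", "tune", "test"))
  perm <- with_seed(seed, sample.int(n))
  data.frame(patient_id = patient_ids[perm], split = labels,
             stringsAsFactors = FALSE)[order(perm), , drop = FALSE]
}

#' Select the evaluation set for a valve and task
#'
#' Keeps the earliest ECG per patient. For prediction tasks, patients with
#' prevalent significant disease of the tested valve are excluded, and
#' events inside the blanking window after the index ECG are removed
#' (undetected prevalent disease must not be credited as prediction).
#'
#' @param labels a `survival_labels` object.
#' @param task `"diagnosis"` or `"prediction"`.
#' @param blanking_days blanking period after the index ECG.
#' @return the `survival_labels` subset to the evaluation rows (the
#'   selection index is attached as `$index` relative to the input rows).
#' @export
select_evaluation_ecgs <- function(labels, task = c("prediction", "diagnosis"),
                                   blanking_days = 60) {
  task <- match.arg(task)
  p <- labels$pairs
  known <- labels$mask[, 1] == 1  # baseline status observed (paired ECG)
  ord <- order(p$patient_id, p$ecg_date, p$ecg_id)
  ord <- ord[known[ord]]
  first <- ord[!duplicated(p$patient_id[ord])]
  keep <- sort(first)
  if (task == "prediction") {
    keep <- keep[!labels$prevalent[keep] & !labels$inconsistent[keep]]
    blank_y <- blanking_days / 365.25
    keep <- keep[!(labels$event[keep] & labels$event_time[keep] <= blank_y)]
  }
  subset_labels(labels, keep)
}

#' Subset a `survival_labels` object by row index
#' @param labels a `survival_labels` object.
#' @param idx integer row indices.
#' @return the subset `survival_labels`; `$index` records `idx`.
#' @export
subset_labels <- function(labels, idx) {
  structure(list(y = labels$y[idx, , drop = FALSE],
                 mask = labels$mask[idx, , drop = FALSE],
                 edges = labels$edges, valve = labels$valve,
                 prevalent = labels$prevalent[idx],
                 event = labels$event[idx],
                 event_time = labels$event_time[idx],
                 time = labels$time[idx],
                 inconsistent = labels$inconsistent[idx],
                 pairs = labels$pairs[idx, , drop = FALSE],
                 index = idx),
            class = "survival_labels")
}
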