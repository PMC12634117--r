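# Evaluation battery: rank metrics with DeLong machinery, Harrell's C,
# Kaplan-Meier estimation and risk-quartile stratification, Brier score at a
# horizon, continuous net reclassification, Cox model comparison with nested
# likelihood-ratio tests, serial-ECG trajectories, and adjusted imaging
# associations. Each has a brute-force oracle in the test suite.

#' Area under the ROC curve (rank-based)
#'
#' Mann-Whitney AUROC with midrank handling of score ties.
#'
#' @param scores numeric scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural components: V10 (per case) and V01 (per control).
.delong_components <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), 0)
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), 0)
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong variance of an AUROC
#' @param scores,labels as in [auroc()].
#' @return list `auc`, `var`.
#' @export
delong_variance <- function(scores, labels) {
  cp <- .delong_components(scores, labels)
  v <- var(cp$v10) / cp$m + var(cp$v01) / cp$n
  list(auc = cp$auc, var = v)
}

#' DeLong test comparing two correlated AUROCs
#'
#' Both score vectors must be computed on the same subjects.
#'
#' @param scores1,scores2 two score vectors.
#' @param labels shared binary labels.
#' @return list with both AUCs, the difference, its variance, `z`, and the
#'   two-sided `p` value. Identical scores give `z = 0`, `p = 1`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  c1 <- .delong_components(scores1, labels)
  c2 <- .delong_components(scores2, labels)
  s10 <- stats::cov(cbind(c1$v10, c2$v10))
  s01 <- stats::cov(cbind(c1$v01, c2$v01))
  S <- s10 / c1$m + s01 / c1$n
  vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- c1$auc - c2$auc
  z <- if (vd <= 0) 0 else d / sqrt(vd)
  list(auc1 = c1$auc, auc2 = c2$auc, diff = d, var = vd, z = z,
       p = 2 * pnorm(-abs(z)))
}

#' Harrell's concordance index
#'
#' Usable pairs have distinct observed times with an event at the earlier
#' time; a pair is concordant when the earlier failure carries the higher
#' risk score, and score ties count one half.
#'
#' @param time observed times.
#' @param event event indicator (1 event, 0 censored).
#' @param score risk score (higher = riskier).
#' @return C-index in `[0, 1]`.
#' @export
harrell_c <- function(time, event, score) {
  stopifnot(length(time) == length(event), length(time) == length(score))
  r <- cpp_concordance(as.numeric(time), as.numeric(event), as.numeric(score))
  if (r$usable == 0) stopf("no usable pairs: C-index undefined")
  r$concordant / r$usable
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; the cumulative event rate is `1 - S(t)`.
#'
#' @param time observed times.
#' @param event event indicator.
#' @return data frame `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   one row per distinct observed time.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) > 0)
  ut <- sort(unique(time))
  n_risk <- vapply(ut, function(t) sum(time >= t), 0)
  n_event <- vapply(ut, function(t) sum(time == t & event == 1), 0)
  n_censor <- vapply(ut, function(t) sum(time == t & event == 0), 0)
  surv <- cumprod(1 - n_event / n_risk)
  data.frame(time = ut, n_risk = n_risk, n_event = n_event,
             n_censor = n_censor, surv = surv)
}

#' Evaluate a KM curve at arbitrary times
#' @param km result of [km_curve()].
#' @param t times.
#' @return `S(t)` (right-continuous step function, `S = 1` before the first
#'   observed time).
#' @export
km_at <- function(km, t) {
  vapply(t, function(ti) {
    i <- findInterval(ti, km$time)
    if (i == 0) 1 else km$surv[i]
  }, 0)
}

#' Risk-quartile stratification with age/sex-adjusted hazard ratios
#'
#' Quartile cutpoints are computed on the tuning-set scores
#' (linear-interpolation quantiles, frozen) and applied to the test set;
#' groups are labelled low / intermediate-low / intermediate-high / high.
#' A Cox proportional-hazards model with the group indicators plus age and
#' sex yields the hazard ratio of the highest vs the lowest quartile.
#'
#' @param tune_scores scores in the tuning set (define the cutpoints).
#' @param test data frame with `score`, `time`, `event`, `age`, `sex`.
#' @return list: `cutpoints`, `group` (factor per test row), `km` (list of
#'   KM curves per group), `hr` (top-vs-bottom hazard ratio with 95 percent
#'   CI and p), and the fitted `cox` model.
#' @export
quartile_stratify <- function(tune_scores, test) {
  cut_q <- quantile(tune_scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (anyDuplicated(cut_q)) {
    warnf("degenerate quartile cutpoints; collapsing tied groups")
    cut_q <- unique(cut_q)
  }
  lv <- c("low", "intermediate-low", "intermediate-high", "high")
  lv <- lv[seq_len(length(cut_q) + 1)]
  if (length(lv) > 2) lv[length(lv)] <- "high"
  grp <- cut(test$score, c(-Inf, cut_q, Inf), labels = lv)
  km <- lapply(split(seq_len(nrow(test)), grp), function(i)
    km_curve(test$time[i], test$event[i]))
  dat <- data.frame(time = test$time, event = test$event, group = grp,
                    age = test$age, sex = factor(test$sex))
  fit <- survival::coxph(survival::Surv(time, event) ~ group + age + sex,
                         data = dat)
  cf <- paste0("group", lv[length(lv)])
  est <- coef(fit)[cf]
  se <- sqrt(diag(vcov(fit))[cf])
  hr <- c(hr = exp(est), lower = exp(est - 1.96 * se),
          upper = exp(est + 1.96 * se),
          p = 2 * pnorm(-abs(est / se)))
  names(hr) <- c("hr", "lower", "upper", "p")
  list(cutpoints = cut_q, group = grp, km = km, hr = hr, cox = fit)
}

# Determinate horizon status: 1 = event at or before the horizon, 0 =
# followed beyond the horizon without an event; NA = censored early
# (excluded by decision; inverse-probability weighting is out of scope).
.horizon_status <- function(time, event, horizon) {
  ifelse(event == 1 & time <= horizon, 1,
         ifelse(time > horizon, 0, NA))
}

#' Brier score at a fixed horizon
#'
#' Mean squared difference between the horizon-specific predicted risk and
#' the observed outcome among subjects with determinate status; subjects
#' censored before the horizon are excluded.
#'
#' @param time,event observed follow-up.
#' @param risk predicted probability of an event by `horizon`.
#' @param horizon horizon in years.
#' @return the Brier score.
#' @export
brier_at_horizon <- function(time, event, risk, horizon = 5) {
  y <- .horizon_status(time, event, horizon)
  ok <- !is.na(y)
  if (!any(ok)) stopf("no subjects with determinate status at horizon %g", horizon)
  mean((risk[ok] - y[ok])^2)
}

#' Continuous net reclassification improvement
#'
#' `NRI = [P(up | event) - P(down | event)] + [P(down | non-event) -
#' P(up | non-event)]` where up/down is any increase/decrease of the risk
#' estimate when moving from `old` to `new`. Events are defined at the
#' horizon as in [brier_at_horizon()].
#'
#' @param old,new risk vectors on the same subjects.
#' @param time,event observed follow-up.
#' @param horizon horizon in years.
#' @return the continuous NRI (range -2..2).
#' @export
continuous_nri <- function(old, new, time, event, horizon = 5) {
  y <- .horizon_status(time, event, horizon)
  ok <- !is.na(y)
  d <- (new - old)[ok]
  y <- y[ok]
  if (!any(y == 1) || !any(y == 0)) stopf("need both events and non-events")
  (mean(d[y == 1] > 0) - mean(d[y == 1] < 0)) +
    (mean(d[y == 0] < 0) - mean(d[y == 0] > 0))
}

#' Cox model comparison: baseline covariates vs AI score vs both
#'
#' Fits three proportional-hazards models on complete cases (baseline
#' variables alone, the AI-ECG score alone, and both), reports the C-index
#' of each linear predictor, and compares the nested baseline vs
#' baseline+AI models with a likelihood-ratio test.
#'
#' @param data data frame holding all columns.
#' @param baseline_covariates character vector of baseline column names.
#' @param ai_col AI score column name.
#' @param time_col,event_col follow-up column names.
#' @return list: per-model fits and C-indices, `lrt` (chi-square, df, p for
#'   baseline vs baseline+AI), and `n` (complete cases used).
#' @export
cox_model_comparison <- function(data, baseline_covariates, ai_col,
                                 time_col = "time", event_col = "event") {
  cols <- c(time_col, event_col, baseline_covariates, ai_col)
  cc <- complete.cases(data[cols])
  d <- data[cc, cols]
  names(d)[1:2] <- c(".time", ".event")
  fit_one <- function(covs) {
    f <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(sprintf("`%s`", covs), collapse = "+")))
    fit <- survival::coxph(f, data = d, ties = "efron",
                           control = survival::coxph.control(eps = 1e-9, iter.max = 50))
    if (!is.null(fit$info) || any(is.na(coef(fit))))
      warnf("Cox fit did not fully converge for: %s", paste(covs, collapse = ", "))
    lp <- predict(fit, type = "lp")
    list(fit = fit, cindex = harrell_c(d$.time, d$.event, lp))
  }
  m_base <- fit_one(baseline_covariates)
  m_ai <- fit_one(ai_col)
  m_both <- fit_one(c(baseline_covariates, ai_col))
  ll <- function(m) m$fit$loglik[2]
  chisq <- 2 * (ll(m_both) - ll(m_base))
  df <- length(coef(m_both$fit)) - length(coef(m_base$fit))
  list(baseline = m_base, ai = m_ai, both = m_both,
       cindex = c(baseline = m_base$cindex, ai = m_ai$cindex,
                  both = m_both$cindex),
       lrt = c(chisq = chisq, df = df, p = pchisq(chisq, df, lower.tail = FALSE)),
       # reserved: competing-risk and non-nested comparisons are not part of
       # this implementation; results tables should print them as-is
       fine_gray = "not computed", partial_lrt = "not computed",
       n = sum(cc))
}

#' Threshold classification metrics and AUPRC
#'
#' Confusion-matrix metrics at a fixed threshold (predicted positive when
#' `score >= threshold`) plus the area under the precision-recall curve by
#' step-wise interpolation. Metrics with an empty denominator are `NA`.
#'
#' @param scores,labels scores and binary labels.
#' @param threshold decision threshold.
#' @return named vector: sensitivity, specificity, ppv, npv, auprc.
#' @export
classification_threshold_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2) stopf("both classes must be present")
  pos <- scores >= threshold
  tp <- sum(pos & labels == 1); fp <- sum(pos & labels == 0)
  fn <- sum(!pos & labels == 1); tn <- sum(!pos & labels == 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  # AUPRC: step-wise interpolation over unique score cutoffs
  ord <- order(scores, decreasing = TRUE)
  ys <- labels[ord]
  ss <- scores[ord]
  cum_tp <- cumsum(ys)
  cum_fp <- cumsum(1 - ys)
  last <- !duplicated(ss, fromLast = TRUE)  # last index of each tied block
  ctp <- cum_tp[last]; cfp <- cum_fp[last]
  recall <- ctp / sum(labels)
  precision <- ctp / (ctp + cfp)
  auprc <- sum(diff(c(0, recall)) * precision)
  c(sensitivity = div(tp, tp + fn), specificity = div(tn, tn + fp),
    ppv = div(tp, tp + fp), npv = div(tn, tn + fn), auprc = auprc)
}

#' Serial-ECG prediction trajectory around the diagnosis date
#'
#' Bins model scores of serial ECGs by time to the first significant-disease
#' diagnosis (90-day bins by default) and returns the per-bin mean with a
#' normal 95 percent confidence interval.
#'
#' @param scores per-ECG scores.
#' @param ecg_dates per-ECG dates.
#' @param event_dates per-ECG date of the patient's first significant
#'   diagnosis.
#' @param bin_days bin width in days.
#' @return data frame `bin` (days from diagnosis, bin lower edge), `n`,
#'   `mean`, `lower`, `upper`.
#' @export
serial_trajectory <- function(scores, ecg_dates, event_dates, bin_days = 90) {
  dt <- as.numeric(as.Date(ecg_dates) - as.Date(event_dates))
  bin <- floor(dt / bin_days) * bin_days
  agg <- lapply(split(scores, bin), function(s) {
    m <- mean(s)
    se <- if (length(s) > 1) sd(s) / sqrt(length(s)) else 0
    c(n = length(s), mean = m, lower = m - 1.96 * se, upper = m + 1.96 * se)
  })
  out <- data.frame(bin = as.numeric(names(agg)),
                    do.call(rbind, agg), row.names = NULL)
  out[order(out$bin), ]
}

#' Age/age-squared/sex-adjusted association of predictions with
#' echocardiographic measurements
#'
#' For each measurement column, fits a linear regression of the
#' standardized measurement on the standardized prediction adjusted for
#' sex, age, and age squared, and reports the prediction coefficient with
#' its 95 percent confidence interval. Constant or all-missing measurements
#' are skipped with a message.
#'
#' @param predictions numeric prediction per row.
#' @param measurements data frame of measurement columns.
#' @param age,sex covariates.
#' @return data frame: `measurement`, `n`, `beta`, `lower`, `upper`, `p`.
#' @export
imaging_association <- function(predictions, measurements, age, sex) {
  rows <- lapply(names(measurements), function(mn) {
    m <- measurements[[mn]]
    ok <- complete.cases(m, predictions, age, sex)
    if (sum(ok) < 8 || sd(m[ok]) == 0 || sd(predictions[ok]) == 0) {
      message("imaging_association: skipping '", mn, "' (constant or too few complete cases)")
      return(NULL)
    }
    d <- data.frame(m = as.numeric(scale(m[ok])),
                    p = as.numeric(scale(predictions[ok])),
                    age = age[ok], age2 = age[ok]^2, sex = factor(sex[ok]))
    fit <- lm(m ~ p + age + age2 + sex, data = d)
    est <- coef(fit)["p"]
    se <- sqrt(diag(vcov(fit))["p"])
    tval <- est / se
    data.frame(measurement = mn, n = sum(ok), beta = est,
               lower = est - 1.96 * se, upper = est + 1.96 * se,
               p = 2 * stats::pt(-abs(tval), df = fit$df.residual),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Percentile bootstrap confidence interval
#'
#' Nonparametric subject-level bootstrap of an arbitrary statistic;
#' percentile interval, deterministic under `seed`.
#'
#' @param statistic function taking an integer index vector and returning a
#'   scalar.
#' @param n number of subjects.
#' @param B bootstrap replicates (default 2000).
#' @param level confidence level.
#' @param seed integer seed.
#' @return list `estimate`, `lower`, `upper`, `replicates`.
#' @export
bootstrap_ci <- function(statistic, n, B = 2000, level = 0.95, seed = 1) {
  est <- statistic(seq_len(n))
  reps <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(statistic(idx), error = function(e) NA_real_)
    }, 0)
  })
  a <- (1 - level) / 2
  qs <- quantile(reps, c(a, 1 - a), na.rm = TRUE, names = FALSE)
  list(estimate = est, lower = qs[1], upper = qs[2], replicates = reps)
}
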