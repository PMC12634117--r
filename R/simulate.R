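#' Simulation configuration for a linked ECG-echocardiogram cohort
#'
#' Defines the generative conditions for [simulate_cohort()]: cohort size,
#' waveform geometry, per-valve baseline prevalence and hazard, and the
#' strength of the coupling between ECG morphology and progression hazard.
#'
#' The generative model is: each patient carries a latent remodelling factor
#' `z ~ N(0,1)` that shifts their resting ECG morphology (broader QRS, lower
#' P-wave amplitude, higher QRS amplitude, more likely T-wave inversion) and,
#' through the standardized morphology features, their per-valve log hazard
#' of progressing to moderate-or-severe regurgitation:
#' `log h = log(annual_hazard_base) + sum(beta_f * std(feature_f)) + frailty`.
#' Event times are exponential in this hazard; as the event approaches
#' (within `ramp_years`) the morphology degrades further, and after the event
#' (or for prevalent disease) the degraded morphology is fully expressed.
#'
#' @param n_patients number of patients.
#' @param n_leads number of ECG leads (default 12).
#' @param duration_s ECG duration in seconds (default 10).
#' @param fs sampling rate in Hz (default 500).
#' @param baseline_prevalence named fraction per valve (`mr`, `ar`, `tr`)
#'   with prevalent moderate-or-severe regurgitation at baseline.
#' @param annual_hazard_base named per-valve baseline hazard (1/year) of
#'   progression for a patient with average morphology and zero frailty.
#' @param risk_effect_sizes named log-hazard ratios per standardized
#'   morphology feature; recognised names are `qrs_width` and `p_amplitude`.
#' @param follow_up_years administrative follow-up horizon.
#' @param echo_interval_days nominal echo surveillance interval (jittered
#'   by +/-20 percent so pairing logic meets unequal gaps).
#' @param censor_rate exponential loss-to-follow-up rate (1/year).
#' @param frailty_sd standard deviation of the lognormal frailty term.
#' @param ecgs_per_patient mean number of ECGs per patient (>= 1).
#' @param prevalence_risk_slope log-odds of prevalent disease per unit of
#'   the latent remodelling factor (the intercept is calibrated so the
#'   realized prevalent fraction matches `baseline_prevalence`).
#' @param noise_sd additive white noise on the waveform, mV.
#' @param wander_amp_max maximal baseline-wander amplitude, mV (sine below
#'   0.5 Hz).
#' @param ramp_years years before the event over which morphology degrades.
#' @param seed integer seed; identical config + seed reproduces the cohort
#'   byte for byte.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients,
                       n_leads = 12,
                       duration_s = 10,
                       fs = 500,
                       baseline_prevalence = c(mr = 0.055, ar = 0.031, tr = 0.053),
                       annual_hazard_base = c(mr = 0.020, ar = 0.008, tr = 0.022),
                       risk_effect_sizes = c(qrs_width = 0.5, p_amplitude = -0.5),
                       follow_up_years = 8,
                       echo_interval_days = 180,
                       censor_rate = 0.10,
                       frailty_sd = 0.25,
                       ecgs_per_patient = 2,
                       prevalence_risk_slope = 1.5,
                       noise_sd = 0.02,
                       wander_amp_max = 0.05,
                       ramp_years = 3,
                       seed = 1) {
  expand_valve <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- setNames(rep(x, 3), VALVES)
    if (!all(VALVES %in% names(x)))
      stopf("%s must be named with %s", what, paste(VALVES, collapse = ", "))
    x[VALVES]
  }
  baseline_prevalence <- expand_valve(baseline_prevalence, "baseline_prevalence")
  annual_hazard_base <- expand_valve(annual_hazard_base, "annual_hazard_base")
  if (n_patients < 0) stopf("n_patients must be >= 0")
  if (n_leads < 1) stopf("n_leads must be >= 1")
  if (fs <= 0) stopf("fs must be > 0")
  if (duration_s <= 0) stopf("duration_s must be > 0")
  if (any(baseline_prevalence < 0 | baseline_prevalence > 1))
    stopf("baseline_prevalence must lie in [0, 1]")
  if (any(annual_hazard_base < 0) || censor_rate < 0 || frailty_sd < 0 ||
      follow_up_years < 0 || echo_interval_days <= 0)
    stopf("rates and intervals must be non-negative (echo interval positive)")
  if (ecgs_per_patient < 1) stopf("ecgs_per_patient must be >= 1")
  structure(list(
    n_patients = as.integer(n_patients), n_leads = as.integer(n_leads),
    duration_s = duration_s, fs = fs,
    baseline_prevalence = baseline_prevalence,
    annual_hazard_base = annual_hazard_base,
    risk_effect_sizes = risk_effect_sizes,
    follow_up_years = follow_up_years,
    echo_interval_days = echo_interval_days,
    censor_rate = censor_rate, frailty_sd = frailty_sd,
    ecgs_per_patient = ecgs_per_patient,
    prevalence_risk_slope = prevalence_risk_slope,
    noise_sd = noise_sd, wander_amp_max = wander_amp_max,
    ramp_years = ramp_years, seed = as.integer(seed)
  ), class = "sim_config")
}

# Population constants of the waveform/morphology model (means and the
# theoretical SDs used to standardize features in the hazard).
.GEN <- list(
  qrs_mean = 95, qrs_sd_z = 18, qrs_sd_e = 5,
  pamp_mean = 0.12, pamp_sd_z = 0.03, pamp_sd_e = 0.012,
  qamp_mean = 1.1, qamp_sd_z = 0.15, qamp_sd_e = 0.1,
  # Established (overt) disease expresses a conduction-type signature:
  # broad QRS with higher amplitude and T inversion. Subclinical risk acts
  # through the latent remodelling factor (P-wave and moderate QRS changes),
  # so the overt-disease signature is deliberately not a scaled copy of the
  # pre-disease one.
  qrs_disease_shift = 25,     # extra QRS width (ms) at full expression
  pamp_disease_shift = -0.015, # small P-amplitude change (mV)
  qamp_disease_shift = 0.30,  # QRS amplitude change (mV)
  lead_scale = c(0.5, 1, 0.5, -0.7, 0.3, 0.75, -0.6, 0.9, 1.1, 1.2, 1, 0.8)
)

.gen_sd <- function(which) {
  g <- .GEN
  switch(which,
         qrs_width = sqrt(g$qrs_sd_z^2 + g$qrs_sd_e^2),
         p_amplitude = sqrt(g$pamp_sd_z^2 + g$pamp_sd_e^2),
         stopf("unknown morphology feature '%s'", which))
}

# Fraction of the disease-state morphology shift expressed at time t (years
# since index) for a patient whose (first) event occurs at time T.
.progression <- function(t, event_time, prevalent, ramp_years) {
  if (prevalent) return(1)
  if (!is.finite(event_time)) return(0)
  if (t >= event_time) return(1)
  max(0, 1 - (event_time - t) / ramp_years)
}

#' Simulate a linked longitudinal ECG-echocardiogram cohort
#'
#' Draws latent patient states (morphology, frailty, per-valve event and
#' censoring times), realizes an echo surveillance schedule with per-valve
#' grades that progress none/mild -> moderate -> severe, and synthesizes
#' parametric 12-lead ECG waveforms (Gaussian-bump P/Q/R/S/T at a sampled
#' heart rate of 50-100 bpm) whose morphology shifts with the patient's
#' hazard and disease state.
#'
#' @param config a [sim_config()].
#' @param waveforms if `FALSE`, ECG entries carry their generative parameters
#'   but no samples; call [realize_waveform()] later (identical output).
#' @return list with elements `patients` (one row per patient, including the
#'   latent truth: `risk_z`, `frailty`, per-valve `event_time_*`,
#'   `prevalent_*`, `censor_time`), `ecgs` (list of `ecg_signal`), and
#'   `echos` (long data frame of exams with grades and chamber measures).
#' @export
simulate_cohort <- function(config, waveforms = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_patients == 0) {
    return(list(patients = data.frame(), ecgs = list(), echos = data.frame()))
  }
  with_seed(config$seed, .simulate_cohort_impl(config, waveforms))
}

.simulate_cohort_impl <- function(cfg, waveforms) {
  n <- cfg$n_patients
  g <- .GEN
  patient_id <- sprintf("P%05d", seq_len(n))
  age <- pmin(95, pmax(10, rnorm(n, 56, 15)))
  sex <- ifelse(runif(n) < 0.54, "male", "female")
  z <- rnorm(n)
  frailty <- rnorm(n, 0, cfg$frailty_sd)
  exclusion_flag <- runif(n) < 0.03

  qrs_width <- g$qrs_mean + g$qrs_sd_z * z + rnorm(n, 0, g$qrs_sd_e)
  qrs_width <- pmax(60, qrs_width)
  p_amp <- pmax(0.02, g$pamp_mean - g$pamp_sd_z * z + rnorm(n, 0, g$pamp_sd_e))
  qrs_amp <- pmax(0.4, g$qamp_mean + g$qamp_sd_z * z + rnorm(n, 0, g$qamp_sd_e))
  t_invert_prone <- runif(n) < plogis(z - 1.5)

  beta <- cfg$risk_effect_sizes
  lp <- frailty
  if (!is.null(beta["qrs_width"]) && !is.na(beta["qrs_width"]))
    lp <- lp + beta[["qrs_width"]] * (qrs_width - g$qrs_mean) / .gen_sd("qrs_width")
  if (!is.null(beta["p_amplitude"]) && !is.na(beta["p_amplitude"]))
    lp <- lp + beta[["p_amplitude"]] * (p_amp - g$pamp_mean) / .gen_sd("p_amplitude")

  # Per-valve prevalent status: logistic in z, intercept calibrated so the
  # realized mean equals the configured prevalence.
  prevalent <- sapply(VALVES, function(v) {
    p0 <- cfg$baseline_prevalence[[v]]
    if (p0 <= 0) return(rep(FALSE, n))
    if (p0 >= 1) return(rep(TRUE, n))
    s <- cfg$prevalence_risk_slope
    int <- uniroot(function(c0) mean(plogis(c0 + s * z)) - p0, c(-30, 30))$root
    runif(n) < plogis(int + s * z)
  })
  prevalent <- matrix(prevalent, nrow = n, dimnames = list(NULL, VALVES))

  event_time <- sapply(VALVES, function(v) {
    lambda <- cfg$annual_hazard_base[[v]] * exp(lp)
    ifelse(lambda > 0, rexp(n) / lambda, Inf)
  })
  event_time <- matrix(event_time, nrow = n, dimnames = list(NULL, VALVES))

  censor_draw <- if (cfg$censor_rate > 0) rexp(n) / cfg$censor_rate
                 else rep(Inf, n)
  censor_time <- pmin(censor_draw, cfg$follow_up_years)
  # earliest progression across valves drives the morphology trajectory
  first_event <- apply(event_time, 1, min)
  any_prevalent <- apply(prevalent, 1, any)
  mild_baseline <- matrix(runif(n * 3) < 0.30, n, 3, dimnames = list(NULL, VALVES))

  index_date <- .EPOCH + sample.int(365, n, replace = TRUE)

  patients <- data.frame(
    patient_id = patient_id, age = age, sex = sex,
    exclusion_flag = exclusion_flag,
    risk_z = z, frailty = frailty, log_hazard_lp = lp,
    qrs_width_ms = qrs_width, p_amplitude_mv = p_amp,
    qrs_amplitude_mv = qrs_amp,
    t_polarity = ifelse(t_invert_prone, -1, 1),
    censor_time = censor_time, index_date = index_date,
    stringsAsFactors = FALSE
  )
  for (v in VALVES) {
    patients[[paste0("event_time_", v)]] <- event_time[, v]
    patients[[paste0("prevalent_", v)]] <- prevalent[, v]
  }

  # ---- echo schedule -------------------------------------------------------
  echo_rows <- vector("list", n)
  for (i in seq_len(n)) {
    times <- 0
    t <- 0
    repeat {
      gap <- cfg$echo_interval_days * runif(1, 0.8, 1.2) / 365.25
      t <- t + gap
      if (t > censor_time[i]) break
      times <- c(times, t)
    }
    grade_at <- function(v, t) {
      if (prevalent[i, v]) {
        if (t >= 2) "severe" else "moderate"
      } else if (t < event_time[i, v]) {
        if (mild_baseline[i, v]) "mild" else "none"
      } else if (t < event_time[i, v] + 2) "moderate" else "severe"
    }
    rho <- vapply(times, .progression, numeric(1),
                  event_time = first_event[i], prevalent = any_prevalent[i],
                  ramp_years = cfg$ramp_years)
    m <- length(times)
    meas <- function(base, z_load, rho_load, noise, lo = -Inf, hi = Inf) {
      x <- pmin(hi, pmax(lo, base + z_load * z[i] + rho_load * rho +
                           rnorm(m, 0, noise)))
      x[runif(m) < 0.05] <- NA  # sporadic missingness, as in report data
      x
    }
    echo_rows[[i]] <- data.frame(
      patient_id = patient_id[i],
      date = index_date[i] + round(times * 365.25),
      mr_grade = vapply(times, function(t) grade_at("mr", t), character(1)),
      ar_grade = vapply(times, function(t) grade_at("ar", t), character(1)),
      tr_grade = vapply(times, function(t) grade_at("tr", t), character(1)),
      la_volume = meas(52, 7, 14, 8, lo = 15),
      la_dimension = meas(36, 3, 5, 3, lo = 20),
      lvedd = meas(48, 3, 5, 4, lo = 30),
      aortic_sinus_diameter = meas(33, 2, 3, 3, lo = 20),
      ascending_aorta_diameter = meas(34, 2, 3, 3, lo = 20),
      rv_diameter = meas(35, 3, 6, 4, lo = 20),
      lvef = meas(64, -3, -6, 5, lo = 15, hi = 80),
      stringsAsFactors = FALSE
    )
  }
  echos <- do.call(rbind, echo_rows)

  # ---- ECG schedule and waveforms -----------------------------------------
  ecgs <- list()
  ecg_counter <- 0
  for (i in seq_len(n)) {
    n_ecg <- max(1, stats::rpois(1, cfg$ecgs_per_patient - 1) + 1)
    pt_echo_dates <- echo_rows[[i]]$date
    ecg_days <- numeric(n_ecg)
    ecg_days[1] <- round(runif(1, -20, 20))  # near the baseline echo
    if (n_ecg > 1) {
      # later ECGs: mostly around surveillance echos, but a fraction fall
      # between exams (no echo within the pairing window), which only the
      # survival labels can use
      anchors <- sample(seq_along(pt_echo_dates), n_ecg - 1, replace = TRUE)
      near <- as.numeric(pt_echo_dates[anchors] - index_date[i]) +
        round(runif(n_ecg - 1, -30, 30))
      far <- round(runif(n_ecg - 1, 0, max(1, censor_time[i] * 365.25)))
      use_far <- runif(n_ecg - 1) < 0.4
      ecg_days[-1] <- ifelse(use_far, far, near)
    }
    for (k in seq_len(n_ecg)) {
      ecg_counter <- ecg_counter + 1
      t_years <- ecg_days[k] / 365.25
      rho <- .progression(t_years, first_event[i], any_prevalent[i],
                          cfg$ramp_years)
      morph <- list(
        qrs_width_ms = qrs_width[i] + g$qrs_disease_shift * rho,
        p_amplitude_mv = max(0.01, p_amp[i] + g$pamp_disease_shift * rho),
        qrs_amplitude_mv = qrs_amp[i] + g$qamp_disease_shift * rho,
        t_amp_mv = 0.25 * (1 - (if (t_invert_prone[i]) 1.8 else 0.3) * rho)
      )
      hr <- runif(1, 50, 100)
      wave_seed <- sample.int(2147483646, 1)
      ecg <- ecg_signal(
        patient_id = patient_id[i],
        ecg_id = sprintf("E%06d", ecg_counter),
        acquisition_date = index_date[i] + ecg_days[k],
        fs = cfg$fs,
        samples = NULL,
        leads = LEAD_NAMES[((seq_len(cfg$n_leads) - 1) %% 12) + 1],
        morph = morph, hr = hr, wave_seed = wave_seed,
        duration_s = cfg$duration_s,
        noise_sd = cfg$noise_sd, wander_amp_max = cfg$wander_amp_max
      )
      if (waveforms) ecg <- realize_waveform(ecg)
      ecgs[[ecg_counter]] <- ecg
    }
  }
  list(patients = patients, ecgs = ecgs, echos = echos)
}

#' Construct an ECG signal object
#'
#' @param patient_id,ecg_id identifiers.
#' @param acquisition_date a `Date`.
#' @param fs sampling rate (Hz).
#' @param samples lead x time matrix in mV, or `NULL` if not yet realized.
#' @param leads lead names.
#' @param ... generative metadata kept for lazy waveform realization.
#' @return an object of class `ecg_signal`.
#' @export
ecg_signal <- function(patient_id, ecg_id, acquisition_date, fs, samples,
                       leads = LEAD_NAMES, ...) {
  if (fs <= 0) stopf("fs must be > 0")
  if (!is.null(samples)) {
    samples <- as.matrix(samples)
    rownames(samples) <- leads
  }
  structure(c(list(patient_id = patient_id, ecg_id = ecg_id,
                   acquisition_date = as.Date(acquisition_date), fs = fs,
                   leads = leads, samples = samples),
              list(...)),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal %s patient %s %s fs=%g Hz %s>\n",
              x$ecg_id, x$patient_id, format(x$acquisition_date), x$fs,
              if (is.null(x$samples)) "(unrealized)"
              else paste(dim(x$samples), collapse = "x")))
  invisible(x)
}

#' Realize the waveform of a lazily simulated ECG
#'
#' Deterministic given the per-ECG `wave_seed` drawn at simulation time, so
#' eager and lazy simulation produce identical samples.
#'
#' @param ecg an `ecg_signal` carrying generative metadata.
#' @return the `ecg_signal` with `samples` filled in; ground-truth R-peak
#'   sample indices are attached as `attr(samples, "r_peaks")`.
#' @export
realize_waveform <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_signal"))
  if (!is.null(ecg$samples)) return(ecg)
  if (is.null(ecg$morph)) stopf("ECG %s has no generative parameters", ecg$ecg_id)
  with_seed(ecg$wave_seed, {
    sm <- .gen_wave(ecg$morph, ecg$hr, ecg$fs, ecg$duration_s,
                    length(ecg$leads), ecg$noise_sd, ecg$wander_amp_max)
    rownames(sm) <- ecg$leads
    ecg$samples <- sm
    ecg
  })
}

# Gaussian-bump beat model: P, Q, R, S, T bumps per beat on a per-lead
# amplitude scale, plus white noise and sub-0.5 Hz baseline wander.
.gen_wave <- function(morph, hr, fs, duration_s, n_leads, noise_sd,
                      wander_amp_max) {
  g <- .GEN
  tt <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  rr <- 60 / hr
  r_times <- seq(0.4, duration_s - 0.35, by = rr)
  r_times <- r_times + rnorm(length(r_times), 0, 0.01)
  w <- morph$qrs_width_ms / 1000
  bump <- function(center, sdv, amp) {
    out <- numeric(length(tt))
    for (rt in r_times) out <- out + amp * exp(-0.5 * ((tt - rt - center) / sdv)^2)
    out
  }
  base <- bump(-0.17, 0.025, morph$p_amplitude_mv) +
    bump(-w / 2.2, w / 8, -0.20 * morph$qrs_amplitude_mv) +
    bump(0, w / 5.5, morph$qrs_amplitude_mv) +
    bump(w / 2.2, w / 8, -0.25 * morph$qrs_amplitude_mv) +
    bump(0.30, 0.06, morph$t_amp_mv)
  ls <- rep_len(g$lead_scale, n_leads)
  sm <- matrix(0, n_leads, length(tt))
  for (l in seq_len(n_leads)) {
    wf <- runif(1, 0.1, 0.45)
    wa <- runif(1, 0, wander_amp_max)
    ph <- runif(1, 0, 2 * pi)
    sm[l, ] <- ls[l] * base + wa * sin(2 * pi * wf * tt + ph) +
      rnorm(length(tt), 0, noise_sd)
  }
  attr(sm, "r_peaks") <- round(r_times * fs) + 1
  sm
}
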