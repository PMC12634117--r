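# Shared fixtures, built in code. Heavier objects are memoized so multiple
# test files can reuse them within one run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, maker) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- maker()
  .fixtures[[key]]
}

ecg_table <- function(cohort) {
  data.frame(
    patient_id = vapply(cohort$ecgs, function(e) e$patient_id, ""),
    ecg_id = vapply(cohort$ecgs, function(e) e$ecg_id, ""),
    date = as.Date(vapply(cohort$ecgs, function(e)
      as.character(e$acquisition_date), "")),
    stringsAsFactors = FALSE)
}

cohort_labels <- function(cohort, valve = "mr", keep_unpaired = TRUE) {
  pairs <- pair_ecg_echo(ecg_table(cohort), cohort$echos,
                         keep_unpaired = keep_unpaired)
  build_survival_labels(pairs, cohort$echos, valve)
}

# A small cohort with waveforms, reused by signal/explainability tests.
small_cohort <- function() {
  memo("small_cohort", function()
    simulate_cohort(sim_config(n_patients = 12, seed = 401)))
}

# A mid-sized cohort without waveforms for label/metric tests.
mid_cohort <- function() {
  memo("mid_cohort", function()
    simulate_cohort(sim_config(n_patients = 300, seed = 402),
                    waveforms = FALSE))
}

# Independent O(n^2) concordance oracle (plain R double loop).
cindex_oracle <- function(time, event, score) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) next
    a <- if (time[i] < time[j]) i else j
    b <- if (time[i] < time[j]) j else i
    if (event[a] != 1) next
    den <- den + 1
    num <- num + if (score[a] > score[b]) 1 else if (score[a] == score[b]) 0.5 else 0
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Pairwise-enumeration AUROC oracle.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Brute-force product-limit oracle.
km_oracle <- function(time, event, at) {
  s <- 1
  for (u in sort(unique(time[event == 1]))) {
    if (u > at) break
    s <- s * (1 - sum(time == u & event == 1) / sum(time >= u))
  }
  s
}

# A deterministic synthetic 12-lead ECG with identical beats for
# median-beat tests; returns the ecg_signal and the true R-peak indices.
regular_beat_ecg <- function(fs = 400, duration = 10, rr = 0.8,
                             noise_sd = 0, qrs_amp = 1, seed = 7) {
  tt <- seq(0, duration - 1 / fs, by = 1 / fs)
  r_times <- seq(0.5, duration - 0.4, by = rr)
  base <- numeric(length(tt))
  for (rt in r_times) {
    base <- base + 0.12 * exp(-0.5 * ((tt - rt + 0.17) / 0.025)^2) +
      qrs_amp * exp(-0.5 * ((tt - rt) / 0.018)^2) -
      0.25 * qrs_amp * exp(-0.5 * ((tt - rt - 0.045) / 0.012)^2) +
      0.3 * exp(-0.5 * ((tt - rt - 0.3) / 0.06)^2)
  }
  sm <- matrix(rep(base, 12), nrow = 12, byrow = TRUE)
  if (noise_sd > 0) {
    sm <- sm + withr::with_seed(seed,
      matrix(rnorm(length(sm), 0, noise_sd), nrow = 12))
  }
  e <- ecg_signal("pt", "ecg-reg", as.Date("2020-06-01"), fs, sm)
  list(ecg = e, r_peaks = round(r_times * fs) + 1)
}
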