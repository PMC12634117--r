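# ECG pre-processing chain: zero-phase 4th-order Butterworth bandpass,
# zero-phase IIR mains notch (biquad, Q = 30), polyphase rational resampling,
# and tail zero-padding / centre-cropping to a fixed input length.

# Design caches: filter design happens once per (rate, band) combination;
# the heavy per-lead work runs in compiled code.
.dsp_cache <- new.env(parent = emptyenv())
.cached <- function(key, maker) {
  if (is.null(.dsp_cache[[key]])) .dsp_cache[[key]] <- maker()
  .dsp_cache[[key]]
}

# Zero-phase filtering and polyphase rational resampling (Kaiser-windowed
# sinc anti-alias FIR, symmetric, so the resampler is delay-free).
zp_filter <- function(flt, x) as.numeric(cpp_filtfilt(flt$b, flt$a, x))
zp_resample <- function(x, p, q) {
  h <- .cached(sprintf("fir_%d_%d", p, q), function() cpp_resample_fir(p, q))
  as.numeric(cpp_resample(x, p, q, h))
}

# RBJ biquad notch at f0 Hz with quality factor Q, for sampling rate fs.
.design_notch <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Pre-process an ECG for model input
#'
#' Applies, in order: NaN replacement (with a warning), a 4th-order
#' Butterworth bandpass, a mains notch filter (quality factor `notch_q`),
#' polyphase rational resampling to `target_fs`, and length adjustment to
#' exactly `target_len` samples per lead (zeros appended at the tail when
#' short, centre crop when long). Both filters run forward-backward
#' (zero phase). A 10-s recording at any input rate therefore becomes a
#' 12 x 4096 matrix at 400 Hz.
#'
#' Poor-quality ECGs are not rejected: the chain is linear and runs on
#' whatever it is given.
#'
#' @param ecg an `ecg_signal`.
#' @param target_fs output sampling rate, Hz.
#' @param target_len output samples per lead.
#' @param band bandpass corner frequencies, Hz.
#' @param notch mains frequency to suppress, Hz (60 default; set 50 for
#'   non-US mains, or `NULL` to skip).
#' @param notch_q notch quality factor.
#' @return the `ecg_signal` with filtered, resampled, fixed-length samples.
#' @export
preprocess_ecg <- function(ecg, target_fs = 400, target_len = 4096,
                           band = c(0.5, 100), notch = 60, notch_q = 30) {
  stopifnot(inherits(ecg, "ecg_signal"))
  ecg <- realize_waveform(ecg)
  sm <- ecg$samples
  if (is.null(sm) || ncol(sm) == 0) stopf("empty ECG signal")
  if (ncol(sm) < ecg$fs) stopf("ECG shorter than 1 s cannot be pre-processed")
  if (anyNA(sm) || any(!is.finite(sm))) {
    warnf("ECG %s: non-finite samples set to 0", ecg$ecg_id)
    sm[!is.finite(sm)] <- 0
  }
  fs <- ecg$fs
  hi <- min(band[2], 0.45 * fs)
  bp <- .cached(sprintf("bp_%g_%g_%g", fs, band[1], hi), function() {
    f <- signal::butter(4, c(band[1], hi) / (fs / 2), type = "pass")
    list(b = f$b, a = f$a)
  })
  nf <- if (!is.null(notch) && notch < fs / 2)
    .cached(sprintf("notch_%g_%g_%g", fs, notch, notch_q),
            function() .design_notch(notch, fs, notch_q))
  out <- matrix(0, nrow(sm), target_len)
  for (l in seq_len(nrow(sm))) {
    x <- zp_filter(bp, sm[l, ])
    if (!is.null(nf)) x <- zp_filter(nf, x)
    if (fs != target_fs) {
      g <- gcd2(round(fs * 1000), round(target_fs * 1000))
      x <- zp_resample(x, round(target_fs * 1000) / g, round(fs * 1000) / g)
    }
    if (length(x) >= target_len) {
      start <- floor((length(x) - target_len) / 2) + 1
      out[l, ] <- x[start:(start + target_len - 1)]
    } else {
      out[l, seq_along(x)] <- x  # zero padding appended at the tail
    }
  }
  rownames(out) <- ecg$leads
  ecg$samples <- out
  ecg$fs <- target_fs
  ecg
}

#' Detect R peaks
#'
#' Pan-Tompkins-style detector: bandpass the QRS band (5-25 Hz),
#' differentiate, square, integrate over a 150-ms moving window, threshold
#' adaptively, then refine each detection to the largest absolute deflection
#' of the signal within +/-60 ms. Runs on lead II when present, otherwise on
#' the lead with maximal energy; falls back to the maximal-energy lead when
#' lead II yields fewer than 3 beats.
#'
#' @param ecg an `ecg_signal`.
#' @param lead preferred lead name.
#' @return integer vector of R-peak sample indices.
#' @export
detect_r_peaks <- function(ecg, lead = "II") {
  stopifnot(inherits(ecg, "ecg_signal"))
  ecg <- realize_waveform(ecg)
  best_lead <- which.max(apply(ecg$samples, 1, var))
  li <- match(lead, ecg$leads)
  if (is.na(li)) li <- best_lead
  pk <- .pan_tompkins(ecg$samples[li, ], ecg$fs)
  if (length(pk) < 3 && li != best_lead)
    pk <- .pan_tompkins(ecg$samples[best_lead, ], ecg$fs)
  pk
}

.pan_tompkins <- function(x, fs) {
  bp <- .cached(sprintf("pt_%g", fs), function() {
    f <- signal::butter(3, c(5, min(25, 0.45 * fs)) / (fs / 2), type = "pass")
    list(b = f$b, a = f$a)
  })
  xf <- zp_filter(bp, x)
  d <- c(0, diff(xf))
  sq <- d^2
  w <- max(1, round(0.150 * fs))
  integ <- as.numeric(stats::filter(sq, rep(1 / w, w), sides = 2))
  integ[is.na(integ)] <- 0
  thr <- 0.35 * quantile(integ, 0.98)
  refractory <- round(0.25 * fs)
  above <- integ > thr
  peaks <- integer()
  i <- 1
  n <- length(x)
  while (i <= n) {
    if (above[i]) {
      j <- i
      while (j < n && above[j + 1]) j <- j + 1
      seg <- i:j
      peaks <- c(peaks, seg[which.max(integ[seg])])
      i <- j + refractory
    }
    i <- i + 1
  }
  # refine on the raw signal: largest |x| within +/-60 ms
  half <- round(0.06 * fs)
  as.integer(vapply(peaks, function(p) {
    lo <- max(1, p - half)
    hi <- min(n, p + half)
    lo + which.max(abs(x[lo:hi])) - 1
  }, numeric(1)))
}

#' Extract the median beat of an ECG
#'
#' Detects R peaks, cuts one window per beat (`pre_ms` before to
#' `window_ms - pre_ms` after the R peak), aligns beats to the first beat by
#' cross-correlation within +/-50 ms, and takes the per-sample median across
#' beats for every lead.
#'
#' @param ecg a pre-processed `ecg_signal`.
#' @param window_ms beat window length, ms.
#' @param pre_ms portion of the window before the R peak, ms.
#' @return an object of class `median_beat`: `samples` is a lead x window
#'   matrix, `r_index` the in-window R sample, `beats_used` the number of
#'   beats that entered the median.
#' @export
extract_median_beat <- function(ecg, window_ms = 600, pre_ms = 200) {
  stopifnot(inherits(ecg, "ecg_signal"))
  ecg <- realize_waveform(ecg)
  fs <- ecg$fs
  r <- detect_r_peaks(ecg)
  pre <- round(pre_ms / 1000 * fs)
  post <- round((window_ms - pre_ms) / 1000 * fs)
  n <- ncol(ecg$samples)
  r <- r[r - pre >= 1 & r + post - 1 <= n]
  if (length(r) < 3) stopf("insufficient beats: %d detected", length(r))
  max_shift <- round(0.05 * fs)
  ref_lead <- if ("II" %in% ecg$leads) match("II", ecg$leads)
              else which.max(apply(ecg$samples, 1, var))
  ref <- ecg$samples[ref_lead, (r[1] - pre):(r[1] + post - 1)]
  shifts <- vapply(r, function(ri) {
    cand <- (-max_shift):max_shift
    cand <- cand[ri + cand - pre >= 1 & ri + cand + post - 1 <= n]
    if (!length(cand)) return(0)
    cc <- vapply(cand, function(s) {
      seg <- ecg$samples[ref_lead, (ri + s - pre):(ri + s + post - 1)]
      sum(seg * ref)
    }, 0)
    cand[which.max(cc)]
  }, 0)
  r_al <- r + shifts
  keep <- r_al - pre >= 1 & r_al + post - 1 <= n
  r_al <- r_al[keep]
  beats <- array(NA_real_, c(nrow(ecg$samples), pre + post, length(r_al)))
  for (b in seq_along(r_al))
    beats[, , b] <- ecg$samples[, (r_al[b] - pre):(r_al[b] + post - 1)]
  med <- apply(beats, c(1, 2), median)
  rownames(med) <- ecg$leads
  structure(list(ecg_id = ecg$ecg_id, patient_id = ecg$patient_id, fs = fs,
                 window_ms = window_ms, r_index = pre + 1,
                 beats_used = length(r_al), samples = med),
            class = "median_beat")
}

#' @export
print.median_beat <- function(x, ...) {
  cat(sprintf("<median_beat %s: %d beats, %d leads x %d samples @ %g Hz>\n",
              x$ecg_id, x$beats_used, nrow(x$samples), ncol(x$samples), x$fs))
  invisible(x)
}
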