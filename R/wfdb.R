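# Minimal WFDB (PhysioNet) record I/O: format 16 (little-endian int16),
# one .hea header + one .dat signal file per record. Covers the subset of
# the header grammar this package emits; adu gain fixed per record.

#' Write an ECG as a WFDB record
#'
#' @param ecg an `ecg_signal` with realized samples (mV).
#' @param dir output directory (created if needed).
#' @param record record name; defaults to the `ecg_id`.
#' @param gain analogue-to-digital units per mV (default 200).
#' @return the record name, invisibly.
#' @export
write_wfdb <- function(ecg, dir, record = ecg$ecg_id, gain = 200) {
  stopifnot(inherits(ecg, "ecg_signal"), !is.null(ecg$samples))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sm <- ecg$samples
  n_sig <- nrow(sm)
  n_samp <- ncol(sm)
  adc <- round(sm * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  dat <- paste0(record, ".dat")
  # samples interleaved by time: s1(t1) s2(t1) ... s_n(t1) s1(t2) ...
  con <- file(file.path(dir, dat), "wb")
  writeBin(as.integer(adc[seq_along(adc)]), con, size = 2, endian = "little")
  close(con)
  hea <- c(
    sprintf("%s %d %g %d", record, n_sig, ecg$fs, n_samp),
    sprintf("%s 16 %g/mV 16 0 0 0 0 %s", dat, gain, ecg$leads),
    sprintf("# patient_id %s", ecg$patient_id),
    sprintf("# acquisition_date %s", format(ecg$acquisition_date))
  )
  writeLines(hea, file.path(dir, paste0(record, ".hea")))
  invisible(record)
}

#' Read a WFDB record written by [write_wfdb()]
#'
#' @param dir directory holding the record.
#' @param record record name (no extension).
#' @return an `ecg_signal` with samples in mV. NaN samples are replaced by 0
#'   with a warning.
#' @export
read_wfdb <- function(dir, record) {
  hea_path <- file.path(dir, paste0(record, ".hea"))
  if (!file.exists(hea_path)) stopf("no WFDB header: %s", hea_path)
  hea <- readLines(hea_path)
  top <- strsplit(trimws(hea[1]), "\\s+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- as.numeric(top[3])
  n_samp <- as.integer(top[4])
  sig_lines <- hea[2:(1 + n_sig)]
  fields <- strsplit(trimws(sig_lines), "\\s+")
  gains <- vapply(fields, function(f) as.numeric(sub("/mV$", "", f[3])), 0)
  leads <- vapply(fields, function(f) f[length(f)], "")
  dat <- fields[[1]][1]
  meta <- hea[grepl("^# ", hea)]
  get_meta <- function(key) {
    ln <- meta[grepl(paste0("^# ", key, " "), meta)]
    if (length(ln)) sub(paste0("^# ", key, " "), "", ln[1]) else NA
  }
  con <- file(file.path(dir, dat), "rb")
  raw <- readBin(con, integer(), n = n_sig * n_samp, size = 2,
                 endian = "little", signed = TRUE)
  close(con)
  sm <- matrix(raw, nrow = n_sig) / gains
  if (anyNA(sm) || any(!is.finite(sm))) {
    warnf("record %s: non-finite samples set to 0", record)
    sm[!is.finite(sm)] <- 0
  }
  ecg_signal(patient_id = get_meta("patient_id"), ecg_id = record,
             acquisition_date = as.Date(get_meta("acquisition_date")),
             fs = fs, samples = sm, leads = leads)
}

#' Write a simulated cohort to disk
#'
#' ECGs become one WFDB record each plus a CSV manifest (`ecgs.csv`); echo
#' exams and demographics are written as CSVs with ISO-8601 dates. The file
#' set round-trips losslessly (to ADC quantization of 1/200 mV on waveforms)
#' through [read_cohort()].
#'
#' @param cohort result of [simulate_cohort()].
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create directory '%s'", out_dir)
  }
  wfdb_dir <- file.path(out_dir, "wfdb")
  manifest <- data.frame(patient_id = character(), ecg_id = character(),
                         date = character(), path = character(),
                         stringsAsFactors = FALSE)
  if (length(cohort$ecgs)) {
    rows <- lapply(cohort$ecgs, function(e) {
      e <- realize_waveform(e)
      write_wfdb(e, wfdb_dir)
      data.frame(patient_id = e$patient_id, ecg_id = e$ecg_id,
                 date = format(e$acquisition_date),
                 path = file.path("wfdb", e$ecg_id),
                 stringsAsFactors = FALSE)
    })
    manifest <- do.call(rbind, rows)
  }
  write.csv(manifest, file.path(out_dir, "ecgs.csv"), row.names = FALSE)
  echos <- cohort$echos
  if (nrow(echos)) echos$date <- format(as.Date(echos$date))
  write.csv(echos, file.path(out_dir, "echos.csv"), row.names = FALSE)
  pts <- cohort$patients
  keep <- intersect(c("patient_id", "age", "sex", "exclusion_flag"),
                    names(pts))
  write.csv(pts[keep], file.path(out_dir, "patients.csv"), row.names = FALSE)
  invisible(out_dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @param waveforms read the WFDB signal files (`TRUE`) or just the manifest.
#' @return list with `patients`, `ecgs` (list of `ecg_signal` or the
#'   manifest when `waveforms = FALSE`), `echos`.
#' @export
read_cohort <- function(dir, waveforms = TRUE) {
  manifest <- read.csv(file.path(dir, "ecgs.csv"), stringsAsFactors = FALSE)
  echos <- read.csv(file.path(dir, "echos.csv"), stringsAsFactors = FALSE)
  if (nrow(echos)) echos$date <- as.Date(echos$date)
  patients <- read.csv(file.path(dir, "patients.csv"), stringsAsFactors = FALSE)
  ecgs <- if (waveforms && nrow(manifest)) {
    lapply(seq_len(nrow(manifest)), function(i)
      read_wfdb(file.path(dir, "wfdb"), manifest$ecg_id[i]))
  } else {
    manifest
  }
  list(patients = patients, ecgs = ecgs, echos = echos, manifest = manifest)
}
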