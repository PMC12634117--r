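# End-to-end pipeline: simulate -> preprocess -> build cohort -> train ->
# evaluate -> explain, with a manifest so every run is reproducible from its
# config and seed.

#' Pipeline configuration
#'
#' @param profile `"tiny"` (CPU-sized) or `"default"`.
#' @param n_patients cohort size.
#' @param valves valves to model (subset of `mr`, `ar`, `tr`).
#' @param epochs,batch_size,lr training settings.
#' @param explain run the explainability stage.
#' @param n_explain_beats median beats used in the explainability stage.
#' @param seed global seed; every stage derives its stream from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("tiny", "default"), n_patients = 500,
                            valves = VALVES, epochs = 12, batch_size = 64,
                            lr = 1e-3, explain = FALSE, n_explain_beats = 150,
                            seed = 1) {
  profile <- match.arg(profile)
  stopifnot(all(valves %in% VALVES))
  structure(list(profile = profile, n_patients = n_patients, valves = valves,
                 epochs = epochs, batch_size = batch_size, lr = lr,
                 explain = explain, n_explain_beats = n_explain_beats,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates a cohort, writes it to disk (WFDB + CSV manifests), builds
#' model inputs and discrete-time survival labels, splits by patient
#' (50/10/40), trains one survival model per requested valve, evaluates
#' diagnosis (first-timepoint AUROC) and prediction (5-year C-index, Brier,
#' risk-quartile hazard ratio) on the held-out test patients with the
#' evaluation exclusions and 60-day blanking applied, optionally runs the
#' explainability stage, and writes `metrics_<valve>.json` plus a run
#' manifest.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created).
#' @return list of per-valve metric lists, invisibly; artifacts under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  scfg <- sim_config(n_patients = config$n_patients, seed = config$seed)
  cohort <- simulate_cohort(scfg, waveforms = FALSE)
  write_cohort(cohort, file.path(out_dir, "cohort"))
  bcfg <- backbone_config(config$profile)
  X <- prepare_model_input(cohort$ecgs, bcfg)
  ecg_tab <- data.frame(
    patient_id = vapply(cohort$ecgs, function(e) e$patient_id, ""),
    ecg_id = vapply(cohort$ecgs, function(e) e$ecg_id, ""),
    date = as.Date(vapply(cohort$ecgs, function(e) as.character(e$acquisition_date), "")))
  split <- split_cohort(unique(cohort$patients$patient_id), seed = config$seed + 1)
  write.csv(split, file.path(out_dir, "split.csv"), row.names = FALSE)
  pairs <- pair_ecg_echo(ecg_tab, cohort$echos, keep_unpaired = TRUE)
  results <- list()
  for (valve in config$valves) {
    labels <- build_survival_labels(pairs, cohort$echos, valve)
    keep <- match(labels$pairs$ecg_id, dimnames(X)[[3]])
    Xp <- X[, , keep, drop = FALSE]
    model <- train_risk_model(Xp, labels, split, head = "survival",
                              config = bcfg, epochs = config$epochs,
                              batch_size = config$batch_size, lr = config$lr,
                              seed = config$seed + 2)
    metrics <- evaluate_model(model, Xp, labels, split, cohort$patients)
    results[[valve]] <- metrics
    jsonlite::write_json(metrics, file.path(out_dir, paste0("metrics_", valve, ".json")),
                         auto_unbox = TRUE, digits = NA)
    write.csv(model$log, file.path(out_dir, paste0("training_log_", valve, ".csv")),
              row.names = FALSE)
  }
  if (config$explain) {
    idx <- seq_len(min(config$n_explain_beats, length(cohort$ecgs)))
    beats <- lapply(cohort$ecgs[idx], function(e)
      extract_median_beat(preprocess_ecg(realize_waveform(e))))
    B <- beats_matrix(beats, leads = "II")
    risk <- cohort$patients$log_hazard_lp[
      match(vapply(beats, function(b) b$patient_id, ""), cohort$patients$patient_id)]
    ext <- extreme_group_waveforms(B, risk, n_extreme = max(5, floor(length(idx) / 4)))
    utils::write.csv(data.frame(sample = seq_along(ext$high$mean),
                                high_mean = ext$high$mean, high_sd = ext$high$sd,
                                low_mean = ext$low$mean, low_sd = ext$low$sd),
                     file.path(out_dir, "extreme_waveforms.csv"), row.names = FALSE)
  }
  manifest <- list(config = unclass(config),
                   n_ecgs = length(cohort$ecgs),
                   n_pairs = nrow(pairs),
                   started = format(t0), finished = format(Sys.time()),
                   package_version = as.character(utils::packageVersion("valvecg")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Evaluate a trained model on the held-out test patients
#'
#' Applies the evaluation protocol: evaluation exclusions (valve surgery /
#' prosthesis / device, age under 14), first ECG per patient, prevalent
#' cases excluded and 60-day blanking for the prediction task.
#'
#' @param model a `valvecg_model` (survival head).
#' @param X input array aligned with `labels`.
#' @param labels `survival_labels` aligned with `X`.
#' @param split cohort split from [split_cohort()].
#' @param patients patient table (for exclusions, age, sex).
#' @param split_group which split to evaluate (default `"test"`).
#' @return list of metrics: `n_diagnosis`, `auroc_diagnosis`,
#'   `n_prediction`, `n_events`, `cindex_prediction`, `brier_5y`, and the
#'   top-vs-bottom risk-quartile hazard ratio (when estimable).
#' @export
evaluate_model <- function(model, X, labels, split, patients,
                           split_group = "test") {
  ok_pat <- apply_exclusions(patients, "evaluation")
  sp <- setNames(as.character(split$split), split$patient_id)
  in_group <- sp[labels$pairs$patient_id] == split_group &
    labels$pairs$patient_id %in% ok_pat$patient_id
  base <- subset_labels(labels, which(in_group & !labels$inconsistent))
  Xg <- X[, , base$index, drop = FALSE]
  pred <- predict(model, Xg)
  # diagnosis: first ECG per patient, prevalent vs not, first-timepoint score
  diag_set <- select_evaluation_ecgs(base, task = "diagnosis")
  sc_d <- pred$diagnosis_score[diag_set$index]
  out <- list(n_diagnosis = length(sc_d))
  out$auroc_diagnosis <- tryCatch(auroc(sc_d, diag_set$prevalent),
                                  error = function(e) NA_real_)
  # prediction: prevalent excluded, 60-day blanking, 5-year risk
  pr_set <- select_evaluation_ecgs(base, task = "prediction")
  risk <- pred$risk[pr_set$index]
  tt <- pr_set$time
  ev <- as.numeric(pr_set$event)
  out$n_prediction <- length(risk)
  out$n_events <- sum(ev)
  out$cindex_prediction <- tryCatch(harrell_c(tt, ev, risk),
                                    error = function(e) NA_real_)
  out$brier_5y <- tryCatch(brier_at_horizon(tt, ev, risk, 5),
                           error = function(e) NA_real_)
  # risk quartiles frozen on the tuning set
  tune_rows <- which(sp[labels$pairs$patient_id] == "tune" & !labels$prevalent)
  if (length(tune_rows) >= 8 && sum(ev) >= 3) {
    tune_pred <- predict(model, X[, , tune_rows, drop = FALSE])
    pinfo <- patients[match(pr_set$pairs$patient_id, patients$patient_id), ]
    qs <- tryCatch(
      quartile_stratify(tune_pred$risk,
                        data.frame(score = risk, time = pmax(tt, 1e-6),
                                   event = ev, age = pinfo$age, sex = pinfo$sex)),
      error = function(e) NULL)
    if (!is.null(qs)) {
      out$hr_top_vs_bottom <- unname(qs$hr["hr"])
      out$hr_lower <- unname(qs$hr["lower"])
      out$hr_upper <- unname(qs$hr["upper"])
    }
  }
  out
}
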