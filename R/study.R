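# End-to-end orchestration: configuration object, in-memory study runner
# (simulate -> both pipelines -> peak extraction -> validity table), and
# config serialization so a run is reproducible from config + seed alone.

#' Study run configuration
#'
#' Bundles every tunable of the pipeline into one serializable object:
#' cohort shape and noise profile, filter settings, calibration window,
#' peak-extraction mode and the seed.
#'
#' @param n_subjects,n_trials Cohort shape (default 44 x 3).
#' @param noise `"default"` (study noise levels) or `"none"`.
#' @param seed Base seed for all randomness.
#' @param side Stance side.
#' @param filter_order,filter_cutoff Butterworth settings (see
#'   [butterworth_zero_phase()]).
#' @param cal_duration Static calibration window, seconds.
#' @param peak_mode `"per_modality"` (each system read at its own peak-knee-
#'   flexion instant, default) or `"shared"` (both systems read at the
#'   reference system's instant).
#' @param max_gap See [fill_gaps()].
#' @param ... Overrides passed to [population_spec()] (e.g. `sta_amplitude`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_subjects = 44, n_trials = 3,
                       noise = c("default", "none"), seed = 1L,
                       side = "right", filter_order = 4, filter_cutoff = 3,
                       cal_duration = 1, peak_mode = c("per_modality", "shared"),
                       max_gap = 0.1, ...) {
  noise <- match.arg(noise)
  peak_mode <- match.arg(peak_mode)
  spec <- population_spec(n_subjects = n_subjects, n_trials = n_trials,
                          seed = seed, ...)
  if (noise == "none") spec <- noise_free(spec)
  structure(list(spec = spec, noise = noise, seed = as.integer(seed), side = side,
                 filter_order = filter_order, filter_cutoff = filter_cutoff,
                 cal_duration = cal_duration, peak_mode = peak_mode,
                 max_gap = max_gap),
            class = "run_config")
}

#' Serialize a run configuration to JSON
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  raw <- unclass(config)
  raw$spec <- unclass(raw$spec)
  # named atomic vectors must become lists to survive as JSON objects
  for (f in c("means", "sds", "sta_amplitude")) raw$spec[[f]] <- as.list(raw$spec[[f]])
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from JSON
#' @param path JSON path written by [write_run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- raw$spec
  run_config(n_subjects = sp$n_subjects, n_trials = sp$n_trials,
             noise = raw$noise, seed = raw$seed, side = raw$side,
             filter_order = raw$filter_order, filter_cutoff = raw$filter_cutoff,
             cal_duration = raw$cal_duration, peak_mode = raw$peak_mode,
             max_gap = raw$max_gap,
             means = unlist(sp$means), sds = unlist(sp$sds),
             between_trial_sd = sp$between_trial_sd,
             sta_amplitude = unlist(sp$sta_amplitude), sta_tau = sp$sta_tau,
             sta_marker_frac = sp$sta_marker_frac,
             marker_white_sd = sp$marker_white_sd,
             imu_noise_sd = sp$imu_noise_sd, imu_noise_tau = sp$imu_noise_tau,
             mounting_sd = sp$mounting_sd)
}

# process one simulated trial through both pipelines and extract peaks
.process_trial <- function(trial, config) {
  opt <- optical_joint_angles(trial$markers, trial$cal_markers,
                              side = trial$side,
                              order = config$filter_order,
                              cutoff = config$filter_cutoff,
                              max_gap = config$max_gap)
  sen <- sensor_joint_angles(trial$imu, trial$cal_imu, side = trial$side,
                             ref_time = opt$time_s)
  pk_opt <- extract_at_peak(opt)
  pk_sen <- if (config$peak_mode == "shared")
    extract_at_peak(sen, peak_time = pk_opt$peak_time_s)
  else extract_at_peak(sen)
  rbind(cbind(data.frame(subject = trial$subject, trial = trial$trial,
                         modality = "optical"), pk_opt),
        cbind(data.frame(subject = trial$subject, trial = trial$trial,
                         modality = "sensor"), pk_sen))
}

#' Run a complete simulated validity study
#'
#' Simulates the cohort, runs both measurement pipelines on every trial,
#' extracts all variables at peak knee flexion and assembles the
#' concurrent-validity table. Deterministic for a fixed config.
#'
#' @param config A [run_config()].
#' @param progress Print a progress line per subject.
#' @return An object of class `squat_study`: list with `config`, `peaks`
#'   (long data frame, one row per trial x modality), `validity`
#'   (a [build_validity_table()] result) and `truth_peaks`.
#' @export
run_study <- function(config = run_config(), progress = FALSE) {
  spec <- config$spec
  pop <- sample_population(spec)
  peak_rows <- vector("list", 2L * nrow(pop))
  truth_rows <- vector("list", nrow(pop))
  for (i in seq_len(nrow(pop))) {
    su <- pop$subject[i]; tr <- pop$trial[i]
    if (progress && tr == 1L) message("subject ", su)
    model <- body_model(mounting = draw_mounting(spec, subject_seed(spec$seed, su)))
    peaks <- unlist(pop[i, names(.peak_vars)])
    trial <- simulate_trial(peaks, model, spec,
                            seed = trial_seed(spec$seed, su, tr),
                            side = config$side,
                            cal_duration = config$cal_duration)
    trial$subject <- su; trial$trial <- tr
    peak_rows[[i]] <- .process_trial(trial, config)
    truth_rows[[i]] <- data.frame(subject = su, trial = tr, t(peaks))
  }
  peaks_df <- do.call(rbind, peak_rows)
  rownames(peaks_df) <- NULL
  structure(list(config = config,
                 peaks = peaks_df,
                 truth_peaks = do.call(rbind, truth_rows),
                 validity = build_validity_table(peaks_df)),
            class = "squat_study")
}

#' @export
print.squat_study <- function(x, ...) {
  cat(sprintf("Simulated single-leg-squat validity study: %d subjects x %d trials (noise: %s, seed %d)\n\n",
              x$config$spec$n_subjects, x$config$spec$n_trials,
              x$config$noise, x$config$seed))
  print(summary(x$validity))
  invisible(x)
}
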