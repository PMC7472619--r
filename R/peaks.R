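# Peak extraction: all five kinematic variables are read at the instant of
# peak knee flexion, each modality on its own knee curve (the two systems were
# analysed as paired per-trial summary values, not on a shared clock).

#' Locate peak knee flexion
#'
#' Global maximum of the knee sagittal curve; ties are broken by the earliest
#' time. A maximum on the first or last sample (no interior maximum, e.g. a
#' monotone ramp) is returned with a warning; an all-missing or flat-at-zero
#' series is an error (no squat detected).
#'
#' @param angles Joint-angle data frame (from [optical_joint_angles()] or
#'   [sensor_joint_angles()]), or any data frame with `time_s` and
#'   `knee_sagittal_deg`.
#' @return List with `time` (s), `value` (degrees) and `index`.
#' @export
detect_peak_knee_flexion <- function(angles) {
  x <- angles$knee_sagittal_deg
  if (is.null(x)) stop("no knee_sagittal_deg column in the series")
  if (all(is.na(x))) stop("no squat detected: knee series all missing")
  if (max(x, na.rm = TRUE) - min(x, na.rm = TRUE) < 1e-9 &&
      abs(max(x, na.rm = TRUE)) < 1e-9)
    stop("no squat detected: knee series flat at zero")
  i <- which.max(x)                      # first index at the maximum
  if (i == 1L || i == length(x))
    warning("peak knee flexion on a series endpoint (no interior maximum)")
  list(time = angles$time_s[i], value = x[i], index = i)
}

.extract_vars <- c(knee_flexion = "knee_sagittal_deg",
                   hip_flexion = "hip_sagittal_deg",
                   hip_sway = "hip_frontal_deg",
                   spine_flexion = "spine_sagittal_deg",
                   spine_sway = "spine_frontal_deg")

#' Read all variables at the peak-knee-flexion instant
#'
#' @param angles Joint-angle data frame for one trial.
#' @param peak_time Peak instant, seconds; defaults to this series' own peak
#'   from [detect_peak_knee_flexion()].
#' @return One-row data frame: `peak_time_s` and the five variables (degrees).
#'   A missing variable at the peak frame is an error.
#' @export
extract_at_peak <- function(angles, peak_time = NULL) {
  if (is.null(peak_time)) peak_time <- detect_peak_knee_flexion(angles)$time
  i <- which.min(abs(angles$time_s - peak_time))
  vals <- lapply(.extract_vars, function(cl) {
    if (is.null(angles[[cl]])) stop("variable column missing: ", cl)
    v <- angles[[cl]][i]
    if (is.na(v)) stop("variable ", cl, " missing at the peak frame")
    v
  })
  cbind(data.frame(peak_time_s = angles$time_s[i]), as.data.frame(vals))
}

#' Write a peaks table to CSV
#'
#' `subject`, `trial`, `modality`, `peak_time_s` and the five variables,
#' angles rounded to one decimal.
#'
#' @param peaks Peaks data frame (see [run_study()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  num <- names(.extract_vars)
  peaks[num] <- lapply(peaks[num], round, digits = 1L)
  utils::write.csv(peaks, path, row.names = FALSE)
  invisible(path)
}

#' Read a peaks table written by [write_peaks_csv()]
#' @param path CSV path.
#' @return Peaks data frame.
#' @export
read_peaks_csv <- function(path) utils::read.csv(path)
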