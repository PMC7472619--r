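# Sensor path: 50 Hz orientation quaternions -> segment-level calibration ->
# relative orientations -> tilt/sway/twist -> optional SLERP resampling onto
# the 120 Hz optical reference timeline (orientations are resampled, never
# finished angle curves).

#' Read a sensor quaternion CSV
#'
#' Expects the dialect written by [render_imu()]: a `time_s` column then
#' `<segment>_<w|x|y|z>` columns, scalar first. Rows are validated
#' (unit norm within 1e-2, else a hard error naming the line), renormalized
#' when the deviation exceeds 1e-6 (logged in the `warnings` attribute), and
#' made sign-continuous along time.
#'
#' @param path CSV file path.
#' @return Data frame of quaternion streams with attribute `warnings`.
#' @export
read_quaternion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("quaternion CSV must have a time_s column: ", path)
  if (any(diff(df$time_s) <= 0)) stop("non-monotone timestamps in ", path)
  segs <- .quat_segments_names(df)
  renorm <- integer(0)
  for (s in segs) {
    q <- as.matrix(df[paste0(s, "_", c("w", "x", "y", "z"))])
    nrm <- sqrt(rowSums(q^2))
    bad <- which(abs(nrm - 1) > 1e-2)
    if (length(bad))
      stop(sprintf("corrupt quaternion stream for %s: norm %.4f at line %d of %s",
                   s, nrm[bad[1L]], bad[1L] + 1L, path))
    renorm[s] <- sum(abs(nrm - 1) > 1e-6)
    q <- quat_continuity(q / nrm)
    df[paste0(s, "_", c("w", "x", "y", "z"))] <- q
  }
  attr(df, "warnings") <- c(renormalized = sum(renorm))
  df
}

.quat_segments_names <- function(df) {
  nm <- setdiff(names(df), "time_s")
  segs <- unique(sub("_[wxyz]$", "", nm))
  ok <- vapply(segs, function(s) all(paste0(s, "_", c("w", "x", "y", "z")) %in% nm),
               logical(1L))
  if (!any(ok)) stop("no complete <segment>_{w,x,y,z} column sets found")
  segs[ok]
}

# per-segment n x 4 matrices from the wide table
.quat_segments <- function(df) {
  segs <- .quat_segments_names(df)
  stats::setNames(lapply(segs, function(s)
    quat_continuity(quat_normalize(
      as.matrix(df[paste0(s, "_", c("w", "x", "y", "z"))])))), segs)
}

# vectorized row-wise slerp between paired quaternions (shorter arc)
.slerp_rows <- function(q0, q1, frac) {
  d <- rowSums(q0 * q1)
  q1[d < 0, ] <- -q1[d < 0, , drop = FALSE]
  d <- pmin(1, abs(d))
  theta <- acos(d)
  small <- theta < 1e-8
  w0 <- ifelse(small, 1 - frac, sin((1 - frac) * theta) / sin(pmax(theta, 1e-12)))
  w1 <- ifelse(small, frac, sin(frac * theta) / sin(pmax(theta, 1e-12)))
  quat_normalize(w0 * q0 + w1 * q1)
}

#' Resample an orientation series onto a reference timeline
#'
#' Spherical linear interpolation between the bracketing samples for every
#' reference timestamp. Reference times outside the sensor window are
#' truncated with a warning; an empty overlap is an error. A reference time
#' equal to a sample time returns that sample exactly.
#'
#' @param time Sensor timestamps, seconds (strictly increasing).
#' @param quat n x 4 quaternion matrix.
#' @param ref_time Reference timestamps, seconds.
#' @return List `time` (the retained reference times) and `quat`.
#' @export
resample_orientations <- function(time, quat, ref_time) {
  quat <- as_quat(quat)
  eps <- 1e-9
  keep <- ref_time >= time[1L] - eps & ref_time <= time[length(time)] + eps
  if (!any(keep)) stop("reference timeline does not overlap the sensor window")
  if (!all(keep))
    warning(sprintf("reference timeline truncated to sensor window (%d of %d samples kept)",
                    sum(keep), length(ref_time)))
  tt <- pmin(pmax(ref_time[keep], time[1L]), time[length(time)])
  idx <- findInterval(tt, time, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(time) - 1L)
  frac <- (tt - time[idx]) / (time[idx + 1L] - time[idx])
  list(time = ref_time[keep],
       quat = .slerp_rows(quat[idx, , drop = FALSE],
                          quat[idx + 1L, , drop = FALSE], frac))
}

#' Sensor joint angles from quaternion streams
#'
#' Each segment's orientation stream is calibrated against its averaged
#' upright orientation (chordal mean over the static calibration capture);
#' this zeroes all joint angles in the upright pose and exactly cancels any
#' constant sensor mounting rotation. Joint-wise relative orientations
#' (spine: trunk vs sacrum sensor; hip: thigh vs sacrum; knee: shank vs thigh)
#' are then zeroed against the averaged calibration relative orientation and
#' decomposed into tilt (sagittal), sway (frontal) and twist (transverse) with
#' anatomical signs. When `ref_time` is supplied the segment orientations are
#' SLERP-resampled onto it first, so angles are recomputed after resampling.
#'
#' @param imu Movement quaternion table (50 Hz dialect of [render_imu()]).
#' @param calibration Upright calibration capture, same dialect.
#' @param side Stance side.
#' @param ref_time Optional reference timestamps (e.g. the 120 Hz optical
#'   timeline) to resample onto.
#' @return Data frame `time_s` plus `<joint>_<sagittal|frontal|transverse>_deg`
#'   columns; attributes `provenance` ("sensor") and `warnings` (singular
#'   frame counts per joint).
#' @export
sensor_joint_angles <- function(imu, calibration, side = "right", ref_time = NULL) {
  mov <- .quat_segments(imu)
  cal <- .quat_segments(calibration)
  if (!setequal(names(mov), names(cal)))
    stop("movement and calibration captures carry different sensor sets")
  t_out <- imu$time_s
  for (s in names(mov)) {
    q0inv <- quat_conjugate(quat_mean(cal[[s]]))
    mov[[s]] <- quat_multiply(mov[[s]], q0inv)   # segment-level calibration
    cal[[s]] <- quat_multiply(cal[[s]], q0inv)
    if (!is.null(ref_time)) {
      rs <- resample_orientations(imu$time_s, mov[[s]], ref_time)
      mov[[s]] <- rs$quat
      t_out <- rs$time
    }
  }
  out <- data.frame(time_s = t_out)
  warn <- integer(0)
  for (j in names(.joints)) {
    p <- .joints[[j]][["primary"]]; s <- .joints[[j]][["secondary"]]
    rel <- relative_orientation(mov[[p]], mov[[s]])
    rel_cal <- relative_orientation(cal[[p]], cal[[s]])
    qc <- calibrate(rel, quat_mean(rel_cal))
    ang <- tilt_sway_twist(qc, sign_convention(j, side))
    out[[paste0(j, "_sagittal_deg")]] <- ang$tilt
    out[[paste0(j, "_frontal_deg")]] <- ang$sway
    out[[paste0(j, "_transverse_deg")]] <- ang$twist
    warn[paste0(j, "_singular")] <- sum(ang$singular)
  }
  attr(out, "provenance") <- "sensor"
  attr(out, "warnings") <- warn
  out
}
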