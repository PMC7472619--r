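# Gold-standard optical path: marker CSV -> gap fill -> zero-phase Butterworth
# filtering of the trajectories -> SVD Procrustes cluster pose -> calibrated
# Euler joint angles on the 120 Hz timeline.

#' Read a marker-trajectory CSV
#'
#' Expects the dialect written by [render_markers()]: a `time_s` column then
#' `<segment>_m<k>_<x|y|z>` columns in mm. Timestamps must be strictly
#' increasing.
#'
#' @param path CSV file path.
#' @return Data frame of marker trajectories.
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df)) stop("marker CSV must have a time_s column: ", path)
  if (any(diff(df$time_s) <= 0)) stop("non-monotone timestamps in ", path)
  df
}

#' Fill short marker-trajectory gaps by linear interpolation
#'
#' Gaps no longer than `max_gap` seconds are interpolated per coordinate.
#' Longer gaps (and gaps touching the series ends, which cannot be
#' interpolated) are a hard error naming the column and interval by default;
#' with `on_long = "keep"` they are left missing and reported in the
#' `gap_report` attribute instead.
#'
#' @param series Marker data frame (a `time_s` column plus coordinates).
#' @param max_gap Longest fillable gap, seconds (default 0.1).
#' @param on_long `"error"` (default) or `"keep"`.
#' @return The series with short gaps filled.
#' @export
fill_gaps <- function(series, max_gap = 0.1, on_long = c("error", "keep")) {
  on_long <- match.arg(on_long)
  t <- series$time_s
  dt <- stats::median(diff(t))
  report <- list()
  for (nm in setdiff(names(series), "time_s")) {
    x <- series[[nm]]
    if (!anyNA(x)) next
    r <- rle(is.na(x))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts[j]; i1 <- ends[j]
      gap_s <- (i1 - i0 + 1L) * dt     # duration of the missing stretch
      long <- i0 == 1L || i1 == length(x) || gap_s > max_gap + 1e-12
      if (long) {
        msg <- sprintf("%s unusable for %.3f s (%.3f-%.3f s) exceeds max_gap %.3f s",
                       nm, t[i1] - t[i0], t[i0], t[i1], max_gap)
        if (on_long == "error") stop(msg)
        report[[length(report) + 1L]] <- msg
      } else {
        x[i0:i1] <- stats::approx(t[c(i0 - 1L, i1 + 1L)], x[c(i0 - 1L, i1 + 1L)],
                                  xout = t[i0:i1])$y
      }
    }
    series[[nm]] <- x
  }
  attr(series, "gap_report") <- unlist(report)
  series
}

#' Zero-phase low-pass Butterworth filter
#'
#' Designs a low-pass Butterworth filter of the given order and applies it
#' forward and backward (zero phase lag, effective magnitude response
#' squared), after odd-reflective padding of `pad` seconds at each end which
#' is trimmed afterwards. Used on marker coordinates, never on angles.
#'
#' @param x Numeric vector, matrix or data frame (a `time_s` column, if
#'   present, passes through unfiltered).
#' @param order Filter order per pass (default 4).
#' @param cutoff Cutoff frequency, Hz (default 3).
#' @param fs Sampling rate, Hz (default 120).
#' @param pad Reflective padding, seconds (default 1).
#' @return Filtered object of the same shape.
#' @export
butterworth_zero_phase <- function(x, order = 4, cutoff = 3, fs = 120, pad = 1) {
  if (is.data.frame(x)) {
    keep <- names(x) == "time_s"
    x[!keep] <- lapply(x[!keep], butterworth_zero_phase,
                       order = order, cutoff = cutoff, fs = fs, pad = pad)
    return(x)
  }
  if (is.matrix(x))
    return(apply(x, 2L, butterworth_zero_phase,
                 order = order, cutoff = cutoff, fs = fs, pad = pad))
  n <- length(x)
  if (anyNA(x)) stop("fill gaps before filtering")
  np <- max(round(pad * fs), 3L * order)
  if (n < max(20L, np %/% 4L))
    stop("series too short to filter (", n, " samples)")
  np <- min(np, n - 1L)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # odd reflection preserves level and slope at the boundaries
  padded <- c(2 * x[1L] - x[(np + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - np)])
  # filter the deviation from the boundary value so a constant passes exactly
  # (zero-state startup transient then decays inside the padding)
  y <- as.numeric(signal::filter(bf, padded - padded[1L])) + padded[1L]
  y <- rev(y)
  y <- rev(as.numeric(signal::filter(bf, y - y[1L])) + y[1L])
  y[(np + 1L):(np + n)]
}

#' Least-squares rigid rotation of a marker cluster
#'
#' Orthogonal Procrustes fit (Kabsch SVD with reflection guard) of each frame
#' of a cluster against its calibration template, centroid-aligned. The
#' rotation maps the template onto the frame; the per-frame RMS residual is
#' attached.
#'
#' @param frames n x (3m) matrix or data frame, columns ordered
#'   `m1_x, m1_y, m1_z, m2_x, ...`.
#' @param template m x 3 template marker positions (same units as `frames`).
#' @param residual_warn Residual RMS (same units) above which frames are
#'   counted as suspect in a warning.
#' @return List: `quat` (n x 4, sign-continuous), `residual` (n).
#' @export
cluster_pose <- function(frames, template, residual_warn = 10) {
  template <- as.matrix(template)
  m <- nrow(template)
  ctr <- scale(template, scale = FALSE)
  if (m < 3L || qr(ctr, tol = 1e-10)$rank < 2L)
    stop("degenerate cluster: need >= 3 non-collinear markers")
  W <- as.matrix(frames)
  if (ncol(W) != 3L * m) stop("frames must have 3 columns per template marker")
  if (anyNA(W)) stop("missing marker samples; run fill_gaps first")
  n <- nrow(W)
  stacked <- matrix(NA_real_, n * m, 3L)
  for (k in seq_len(m))
    stacked[(seq_len(n) - 1L) * m + k, ] <- W[, (3L * k - 2L):(3L * k), drop = FALSE]
  fit <- procrustes_frames(template, stacked)
  bad <- sum(fit$residual > residual_warn)
  if (bad > 0L)
    warning(sprintf("%d frame(s) with Procrustes residual above %g", bad, residual_warn))
  list(quat = quat_continuity(fit$quat), residual = as.numeric(fit$residual))
}

# split wide marker table into per-segment coordinate matrices
.marker_segments <- function(df) {
  nm <- setdiff(names(df), "time_s")
  segs <- unique(sub("_m[0-9]+_[xyz]$", "", nm))
  stats::setNames(lapply(segs, function(s) {
    cols <- grep(paste0("^", s, "_m[0-9]+_[xyz]$"), names(df), value = TRUE)
    as.matrix(df[cols])
  }), segs)
}

# mean marker positions over a (filtered) calibration capture -> m x 3 template
.cluster_template <- function(seg_matrix) {
  mu <- colMeans(seg_matrix)
  matrix(mu, ncol = 3L, byrow = TRUE)
}

#' Optical joint angles from marker trajectories
#'
#' The full gold-standard path: gap filling and zero-phase Butterworth
#' filtering of movement and calibration captures alike, cluster templates
#' taken from the calibration capture, per-frame Procrustes segment poses,
#' relative orientations per joint (spine: trunk vs sacrum cluster; hip: thigh
#' vs sacrum; knee: shank vs thigh), zeroing against the averaged upright
#' relative orientation, and the intrinsic sagittal-frontal-transverse Euler
#' decomposition with anatomical signs.
#'
#' @param markers Movement marker table (120 Hz dialect of [render_markers()]).
#' @param calibration Upright calibration capture, same dialect.
#' @param side Stance side.
#' @param order,cutoff,fs Filter settings, see [butterworth_zero_phase()].
#' @param max_gap See [fill_gaps()].
#' @return Data frame `time_s` plus `<joint>_<sagittal|frontal|transverse>_deg`
#'   columns; attributes `provenance` ("optical") and `warnings` (named counts
#'   of gimbal-flagged frames per joint).
#' @export
optical_joint_angles <- function(markers, calibration, side = "right",
                                 order = 4, cutoff = 3, fs = 120, max_gap = 0.1) {
  markers <- butterworth_zero_phase(fill_gaps(markers, max_gap),
                                    order = order, cutoff = cutoff, fs = fs)
  calibration <- butterworth_zero_phase(fill_gaps(calibration, max_gap),
                                        order = order, cutoff = cutoff, fs = fs)
  mov <- .marker_segments(markers)
  cal <- .marker_segments(calibration)
  if (!setequal(names(mov), names(cal)))
    stop("movement and calibration captures carry different marker sets")
  poses <- lapply(names(mov), function(s) {
    tmpl <- .cluster_template(cal[[s]])
    list(mov = cluster_pose(mov[[s]], tmpl), cal = cluster_pose(cal[[s]], tmpl))
  })
  names(poses) <- names(mov)
  out <- data.frame(time_s = markers$time_s)
  warn <- integer(0)
  for (j in names(.joints)) {
    p <- .joints[[j]][["primary"]]; s <- .joints[[j]][["secondary"]]
    rel <- relative_orientation(poses[[p]]$mov$quat, poses[[s]]$mov$quat)
    rel_cal <- relative_orientation(poses[[p]]$cal$quat, poses[[s]]$cal$quat)
    qc <- calibrate(rel, quat_mean(rel_cal))
    ang <- euler_sagittal_frontal_transverse(qc, sign_convention(j, side))
    out[[paste0(j, "_sagittal_deg")]] <- ang$sagittal
    out[[paste0(j, "_frontal_deg")]] <- ang$frontal
    out[[paste0(j, "_transverse_deg")]] <- ang$transverse
    warn[paste0(j, "_gimbal")] <- sum(ang$gimbal)
  }
  attr(out, "provenance") <- "optical"
  attr(out, "warnings") <- warn
  out
}
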