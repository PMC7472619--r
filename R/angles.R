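# Local segment frames: every segment carries the same right-handed axis set,
#   x = anterior, y = superior (longitudinal), z = subject's right.
# A joint angle is computed from the calibrated orientation of the distal
# (secondary) segment in the proximal (primary) segment's frame.
#
# With v the rotated longitudinal axis (the second column of the rotation
# matrix), the sensor-side units are
#   tilt  = atan2(v.anterior, v.longitudinal)   sagittal-plane deviation
#   sway  = asin(v.lateral)                     frontal-plane deviation
#   swing = angle(u, v) >= 0                    total longitudinal deviation
#   twist = signed twist about the longitudinal axis (swing-twist factor).
# tilt and sway are algebraically identical to the first two angles of the
# intrinsic sagittal -> frontal -> transverse Euler sequence used on the
# optical side, so the two measurement paths differ only through noise and
# filtering, never by definition. (An atan2 ratio for sway would diverge from
# the Euler frontal angle by several degrees at deep flexion; see the methods
# vignette.)

#' Segment axis convention
#'
#' @return Named list of the three unit axes of every local segment frame.
#' @export
segment_axes <- function() {
  list(anterior = c(1, 0, 0), longitudinal = c(0, 1, 0), lateral = c(0, 0, 1))
}

#' Sign convention mapping raw angles to anatomically positive directions
#'
#' Flexion, adduction, internal rotation and homolateral spine lateral flexion
#' are reported positive. In the package's frames this requires a sagittal flip
#' for the knee (the distal shank rotates opposite to the flexion direction of
#' the proximal joints) and frontal/transverse flips for left-leg stance, so
#' the anatomical directions stay positive regardless of side.
#'
#' @param joint One of `"spine"`, `"hip"`, `"knee"`.
#' @param side Stance side, `"right"` (default) or `"left"`.
#' @return Named numeric vector of multipliers in \{-1, +1\} for
#'   (sagittal, frontal, transverse).
#' @export
sign_convention <- function(joint = c("spine", "hip", "knee"),
                            side = c("right", "left")) {
  joint <- match.arg(joint)
  side <- match.arg(side)
  sag <- if (joint == "knee") -1 else 1
  fro <- if (side == "right") 1 else -1
  tra <- if (side == "right") -1 else 1
  c(sagittal = sag, frontal = fro, transverse = tra)
}

# internal: the three rotation-matrix entries needed for angles, vectorized
.angle_elems <- function(q) {
  q <- quat_normalize(q)
  w <- q[, 1L]; x <- q[, 2L]; y <- q[, 3L]; z <- q[, 4L]
  list(R12 = 2 * (x * y - w * z), R22 = 1 - 2 * (x^2 + z^2),
       R32 = 2 * (y * z + w * x), R31 = 2 * (x * z - w * y),
       R33 = 1 - 2 * (x^2 + y^2))
}

#' Tilt / sway / swing / twist of a calibrated relative orientation
#'
#' @param q_cal Calibrated relative orientation(s), n x 4.
#' @param signs Multipliers from [sign_convention()]; the default applies none.
#' @return Data frame with columns `tilt`, `sway`, `twist`, `swing` (degrees)
#'   and logical `singular` (longitudinal axis antiparallel, or the swing-twist
#'   factorisation degenerate: tilt/sway/twist unreliable there). `swing` is
#'   always non-negative.
#' @export
tilt_sway_twist <- function(q_cal, signs = c(sagittal = 1, frontal = 1, transverse = 1)) {
  q_cal <- quat_normalize(q_cal)
  e <- .angle_elems(q_cal)
  rad <- 180 / pi
  tilt <- atan2(e$R12, e$R22) * rad
  sway <- asin(pmin(1, pmax(-1, e$R32))) * rad
  swing <- acos(pmin(1, pmax(-1, e$R22))) * rad
  st <- swing_twist_decompose(q_cal, segment_axes()$longitudinal)
  antiparallel <- e$R22 < -1 + 1e-12
  data.frame(tilt = unname(signs[["sagittal"]] * tilt),
             sway = unname(signs[["frontal"]] * sway),
             twist = unname(signs[["transverse"]] * st$twist_deg),
             swing = swing,
             singular = st$singular | antiparallel)
}

#' Intrinsic sagittal-frontal-transverse Euler angles
#'
#' Decomposes a calibrated relative orientation as an intrinsic sequence: first
#' a rotation about the mediolateral axis (sagittal), then about the anterior
#' axis (frontal), then about the longitudinal axis (transverse). Valid for
#' frontal angles strictly inside (-90, 90) degrees; within 1 degree of the
#' gimbal-lock singularity at +/-90 the rows are flagged.
#'
#' @inheritParams tilt_sway_twist
#' @return Data frame with `sagittal`, `frontal`, `transverse` (degrees) and
#'   logical `gimbal` flag.
#' @export
euler_sagittal_frontal_transverse <- function(q_cal,
                                              signs = c(sagittal = 1, frontal = 1, transverse = 1)) {
  e <- .angle_elems(q_cal)
  rad <- 180 / pi
  sagittal <- atan2(e$R12, e$R22) * rad
  frontal <- asin(pmin(1, pmax(-1, e$R32))) * rad
  transverse <- atan2(-e$R31, e$R33) * rad
  data.frame(sagittal = unname(signs[["sagittal"]] * sagittal),
             frontal = unname(signs[["frontal"]] * frontal),
             transverse = unname(signs[["transverse"]] * transverse),
             gimbal = abs(frontal) > 89)
}

#' Compose a rotation from sagittal-frontal-transverse angles
#'
#' Inverse of [euler_sagittal_frontal_transverse()] (raw convention, i.e. sign
#' multipliers not applied): intrinsic rotations about the mediolateral,
#' anterior and longitudinal axes in that order.
#'
#' @param sagittal,frontal,transverse Angles in degrees (vectors recycle).
#' @return n x 4 quaternion matrix.
#' @export
euler_compose <- function(sagittal, frontal = 0, transverse = 0) {
  n <- max(length(sagittal), length(frontal), length(transverse))
  sagittal <- rep_len(sagittal, n); frontal <- rep_len(frontal, n)
  transverse <- rep_len(transverse, n)
  qz <- quat_from_axis_angle(matrix(c(0, 0, 1), 1L), -sagittal)
  qx <- quat_from_axis_angle(matrix(c(1, 0, 0), 1L), frontal)
  qy <- quat_from_axis_angle(matrix(c(0, 1, 0), 1L), transverse)
  quat_multiply(quat_multiply(qz, qx), qy)
}
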