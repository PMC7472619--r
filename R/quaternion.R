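#' @useDynLib squatkin, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Quaternion convention used throughout the package (documented once, enforced
# everywhere): scalar-first (w, x, y, z), Hamilton product, so that
# quat_multiply(q1, q2) means "apply q2 first, then q1" and
# quat_to_matrix(quat_multiply(q1, q2)) == quat_to_matrix(q1) %*% quat_to_matrix(q2).
# Quaternions are stored as numeric length-4 vectors or n x 4 matrices; q and -q
# encode the same rotation and all angle-producing functions treat them as equal.

#' Coerce to a quaternion matrix
#'
#' Promotes a length-4 numeric vector to a 1 x 4 matrix and validates shape and
#' finiteness. Columns are (w, x, y, z), scalar first.
#'
#' @param q Numeric length-4 vector or n x 4 matrix.
#' @return An n x 4 numeric matrix.
#' @export
as_quat <- function(q) {
  if (is.null(dim(q))) {
    if (length(q) != 4L) stop("a quaternion has exactly 4 components (w, x, y, z)")
    q <- matrix(q, nrow = 1L)
  }
  q <- as.matrix(q)
  if (ncol(q) != 4L) stop("quaternion matrices must have 4 columns (w, x, y, z)")
  if (!all(is.finite(q))) stop("quaternion components must be finite")
  storage.mode(q) <- "double"
  dimnames(q) <- NULL
  q
}

#' The identity quaternion
#' @param n Number of copies (rows).
#' @return n x 4 matrix of identity quaternions.
#' @export
quat_identity <- function(n = 1L) {
  matrix(c(rep(1, n), rep(0, 3L * n)), n, 4L)
}

#' Normalize quaternions to unit norm
#'
#' @param q Quaternion(s), see [as_quat()].
#' @return Unit quaternion(s). The zero quaternion is rejected with an error.
#' @export
quat_normalize <- function(q) {
  q <- as_quat(q)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) stop("cannot normalize a zero-norm quaternion")
  q / nrm
}

#' Hamilton product of quaternions
#'
#' `quat_multiply(q1, q2)` composes rotations: the result applies `q2` first and
#' `q1` second. Rows recycle when one argument has a single row.
#'
#' @param q1,q2 Quaternion(s).
#' @return Quaternion product, n x 4.
#' @export
quat_multiply <- function(q1, q2) {
  q1 <- as_quat(q1); q2 <- as_quat(q2)
  n <- max(nrow(q1), nrow(q2))
  if (nrow(q1) == 1L && n > 1L) q1 <- q1[rep(1L, n), , drop = FALSE]
  if (nrow(q2) == 1L && n > 1L) q2 <- q2[rep(1L, n), , drop = FALSE]
  if (nrow(q1) != nrow(q2)) stop("row counts must match (or be 1)")
  w1 <- q1[, 1L]; x1 <- q1[, 2L]; y1 <- q1[, 3L]; z1 <- q1[, 4L]
  w2 <- q2[, 1L]; x2 <- q2[, 2L]; y2 <- q2[, 3L]; z2 <- q2[, 4L]
  cbind(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
        w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
        w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
        w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2,
        deparse.level = 0L)
}

#' Quaternion conjugate
#'
#' For unit quaternions the conjugate is the inverse rotation.
#' @param q Quaternion(s).
#' @return Conjugate quaternion(s).
#' @export
quat_conjugate <- function(q) {
  q <- as_quat(q)
  q[, 2:4] <- -q[, 2:4]
  q
}

#' Quaternion from axis and angle
#'
#' @param axis Length-3 rotation axis (normalized internally) or n x 3 matrix.
#' @param angle_deg Rotation angle(s) in degrees, right-handed about `axis`.
#' @return Unit quaternion(s).
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  if (is.null(dim(axis))) axis <- matrix(axis, nrow = 1L)
  nrm <- sqrt(rowSums(axis^2))
  if (any(nrm < 1e-12)) stop("rotation axis must be non-zero")
  axis <- axis / nrm
  half <- angle_deg * (pi / 180) / 2
  cbind(cos(half), sin(half) * axis[, 1L], sin(half) * axis[, 2L],
        sin(half) * axis[, 3L], deparse.level = 0L)
}

#' Rotation angle of a quaternion
#'
#' @param q Quaternion(s).
#' @return Angle(s) in degrees in \[0, 180\]; insensitive to the sign of `q`.
#' @export
quat_angle <- function(q) {
  q <- quat_normalize(q)
  2 * atan2(sqrt(rowSums(q[, 2:4, drop = FALSE]^2)), abs(q[, 1L])) * 180 / pi
}

#' Rotation axis of a quaternion
#'
#' @param q A single quaternion.
#' @return Unit length-3 axis; arbitrary (z) for the identity rotation.
#' @export
quat_axis <- function(q) {
  q <- quat_normalize(q)[1L, ]
  if (q[1L] < 0) q <- -q          # canonical hemisphere so axis pairs with angle in [0,180]
  v <- q[2:4]
  s <- sqrt(sum(v^2))
  if (s < 1e-12) return(c(0, 0, 1))
  v / s
}

#' Quaternion to rotation matrix
#'
#' @param q A single unit quaternion.
#' @return 3 x 3 rotation matrix (determinant +1).
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(q)[1L, ]
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3L)
}

#' Rotation matrix to quaternion
#'
#' Shepperd's method: picks the numerically largest of the four candidate
#' pivots, stable for all rotations.
#'
#' @param R 3 x 3 rotation matrix.
#' @return Unit quaternion (1 x 4), w >= 0.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  if (q[1L] < 0) q <- -q
  quat_normalize(q)
}

#' Rotate vectors by quaternions
#'
#' @param q Quaternion(s), n x 4 (or 1 x 4, recycled).
#' @param v Vector(s), length 3 or n x 3.
#' @return Rotated vector(s), n x 3.
#' @export
quat_rotate <- function(q, v) {
  q <- as_quat(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) == 1L && n > 1L) q <- q[rep(1L, n), , drop = FALSE]
  if (nrow(v) == 1L && n > 1L) v <- v[rep(1L, n), , drop = FALSE]
  w <- q[, 1L]; u <- q[, 2:4, drop = FALSE]
  # v' = v + 2 u x (u x v + w v)
  t1 <- cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
              u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
              u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]) + w * v
  v + 2 * cbind(u[, 2L] * t1[, 3L] - u[, 3L] * t1[, 2L],
                u[, 3L] * t1[, 1L] - u[, 1L] * t1[, 3L],
                u[, 1L] * t1[, 2L] - u[, 2L] * t1[, 1L])
}

#' Relative orientation of a secondary segment in a primary segment's frame
#'
#' Both inputs must be expressed in a common world frame. The result is
#' `conjugate(q_primary) * q_secondary`, i.e. the secondary segment's
#' orientation seen from the primary segment, and is unchanged when both
#' segments are pre-rotated by any shared world rotation.
#'
#' @param q_primary,q_secondary Unit quaternion(s) in the world frame.
#' @return Relative orientation quaternion(s).
#' @export
relative_orientation <- function(q_primary, q_secondary) {
  quat_multiply(quat_conjugate(q_primary), q_secondary)
}

#' Zero a relative orientation against its upright-calibration value
#'
#' Returns `conjugate(q_rel_upright) * q_rel`, the identity whenever the
#' current relative orientation equals the upright capture, so that all joint
#' angles are zero in the calibration pose.
#'
#' @param q_rel Relative orientation(s) during movement.
#' @param q_rel_upright Relative orientation captured in the upright pose.
#' @return Calibrated relative orientation(s).
#' @export
calibrate <- function(q_rel, q_rel_upright) {
  quat_multiply(quat_conjugate(q_rel_upright), q_rel)
}

#' Swing-twist decomposition
#'
#' Factors each rotation into a twist about `twist_axis` and a swing about an
#' axis perpendicular to it, with `swing * twist = q` (up to quaternion sign).
#' The decomposition projects the vector part of `q` onto the twist axis; it is
#' singular for a 180 degree rotation exactly perpendicular to the axis, in
#' which case the twist is set to identity and flagged.
#'
#' @param q Unit quaternion(s).
#' @param twist_axis Unit length-3 axis.
#' @return List with `swing` (n x 4), `twist` (n x 4), `twist_deg` (signed
#'   twist angle about `twist_axis`, degrees, in (-180, 180\]) and `singular`
#'   (logical vector).
#' @export
swing_twist_decompose <- function(q, twist_axis) {
  q <- quat_normalize(q)
  a <- twist_axis / sqrt(sum(twist_axis^2))
  proj <- q[, 2:4, drop = FALSE] %*% a      # component of the vector part along the axis
  tw <- cbind(q[, 1L], proj %*% t(a), deparse.level = 0L)
  nrm <- sqrt(rowSums(tw^2))
  singular <- nrm < 1e-9
  tw[singular, ] <- quat_identity(sum(singular))
  tw[!singular, ] <- tw[!singular, , drop = FALSE] / nrm[!singular]
  sw <- quat_multiply(q, quat_conjugate(tw))
  # signed twist angle, sign fixed to the +axis direction
  neg <- tw[, 1L] < 0
  tw[neg, ] <- -tw[neg, , drop = FALSE]
  twist_deg <- 2 * atan2(tw[, 2:4, drop = FALSE] %*% a, tw[, 1L]) * 180 / pi
  list(swing = sw, twist = tw, twist_deg = as.numeric(twist_deg),
       singular = singular)
}

#' Spherical linear interpolation between two orientations
#'
#' Constant-angular-speed interpolation along the shorter great-circle arc
#' (`q1` is negated when the 4-vector dot product is negative). When the two
#' quaternions are nearly antipodal as 4-vectors (|dot| < 1e-6, a rotation gap
#' of essentially 180 degrees with no unique shortest arc) the function falls
#' back to normalized linear interpolation and flags the result.
#'
#' @param q0,q1 Single unit quaternions.
#' @param t Interpolation fraction(s) in \[0, 1\].
#' @return n x 4 quaternion matrix with attribute `nlerp_fallback` (logical).
#' @export
slerp <- function(q0, q1, t) {
  if (any(t < 0 | t > 1)) stop("interpolation fraction t must lie in [0, 1]")
  q0 <- quat_normalize(q0)[1L, ]
  q1 <- quat_normalize(q1)[1L, ]
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  fallback <- FALSE
  if (abs(d) < 1e-6 || d > 1 - 1e-12) {
    # antipodal (ambiguous arc) or coincident: linear interpolation, renormalized
    fallback <- abs(d) < 1e-6
    out <- quat_normalize(outer(1 - t, q0) + outer(t, q1))
  } else {
    theta <- acos(min(1, d))
    out <- (outer(sin((1 - t) * theta), q0) + outer(sin(t * theta), q1)) / sin(theta)
  }
  attr(out, "nlerp_fallback") <- fallback
  out
}

#' Chordal mean of a quaternion series
#'
#' Hemisphere-aligns all samples to the first, averages component-wise and
#' renormalizes. Intended for tight clusters such as a static calibration
#' window, where the chordal mean matches the geodesic mean to high accuracy.
#'
#' @param q n x 4 quaternion matrix.
#' @return A single unit quaternion (1 x 4).
#' @export
quat_mean <- function(q) {
  q <- quat_normalize(q)
  flip <- as.numeric(q %*% q[1L, ]) < 0
  q[flip, ] <- -q[flip, , drop = FALSE]
  quat_normalize(colMeans(q))
}

#' Enforce sign continuity along a quaternion series
#'
#' Negates samples as needed so consecutive rows have a non-negative 4-vector
#' dot product; the encoded rotations are unchanged.
#'
#' @param q n x 4 quaternion matrix.
#' @return n x 4 matrix, sign-continuous.
#' @export
quat_continuity <- function(q) {
  q <- as_quat(q)
  if (nrow(q) < 2L) return(q)
  d <- rowSums(q[-1L, , drop = FALSE] * q[-nrow(q), , drop = FALSE])
  flip <- cumsum(c(FALSE, d < 0)) %% 2 == 1
  q[flip, ] <- -q[flip, , drop = FALSE]
  q
}

# internal: quaternion from a rotation vector (radians, axis * angle), n x 3
quat_from_rotvec <- function(rv) {
  if (is.null(dim(rv))) rv <- matrix(rv, nrow = 1L)
  ang <- sqrt(rowSums(rv^2))
  k <- ifelse(ang < 1e-12, 0.5, sin(ang / 2) / ang)  # small-angle limit
  cbind(cos(ang / 2), k * rv, deparse.level = 0L)
}
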