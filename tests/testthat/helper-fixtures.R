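# Shared fixtures and small oracles, all generated in code.

# uniform random unit quaternions
rand_quat <- function(n) quat_normalize(matrix(rnorm(4L * n), n, 4L))

# rotation angle (degrees) between two orientations, sign-insensitive
rot_gap_deg <- function(q1, q2) quat_angle(quat_multiply(quat_conjugate(q1), q2))

# base-R rotation matrices (independent of the quaternion path)
Rz <- function(deg) { a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3L) }
Rx <- function(deg) { a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3L) }
Ry <- function(deg) { a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3L) }

# quaternion from rotation-vector rows (radians), via the exported axis-angle API
quat_from_rotvec_test <- function(rv) {
  ang <- sqrt(rowSums(rv^2))
  axis <- rv
  tiny <- ang < 1e-12
  if (any(tiny)) axis[tiny, ] <- matrix(c(0, 0, 1), sum(tiny), 3L, byrow = TRUE)
  quat_from_axis_angle(axis, ang * 180 / pi)
}

# standard multi-plane peak set used by recovery tests (degrees)
default_peaks <- c(knee_flexion = 75, hip_flexion = 60, hip_sway = -8,
                   spine_flexion = 14, spine_sway = 4)

# memoized noise-free trial + pipeline outputs (several files reuse these)
.fix <- new.env()
nf_trial <- function() {
  if (is.null(.fix$trial))
    .fix$trial <- simulate_trial(default_peaks, body_model(),
                                 noise_free(population_spec()), seed = 42L)
  .fix$trial
}
nf_optical <- function() {
  if (is.null(.fix$opt)) {
    tr <- nf_trial()
    .fix$opt <- optical_joint_angles(tr$markers, tr$cal_markers)
  }
  .fix$opt
}
nf_sensor <- function() {
  if (is.null(.fix$sen)) {
    tr <- nf_trial()
    .fix$sen <- sensor_joint_angles(tr$imu, tr$cal_imu, ref_time = nf_optical()$time_s)
  }
  .fix$sen
}
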