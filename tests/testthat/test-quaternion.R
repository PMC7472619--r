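test_that("quaternion algebra composes, inverts and round-trips", {
  q <- quat_from_axis_angle(c(0, 0, 1), 90)
  expect_equal(quat_multiply(q, quat_identity()), q)
  expect_equal(quat_multiply(quat_identity(), q), q)

  # composing two quarter turns about one axis gives a half turn
  half <- quat_multiply(q, q)
  expect_equal(quat_angle(half), 180, tolerance = 1e-12)
  expect_equal(quat_axis(half), c(0, 0, 1), tolerance = 1e-12)

  set.seed(11)
  qs <- rand_quat(50L)
  # conjugate inverts: q * conj(q) is the identity rotation
  prod <- quat_multiply(qs, quat_conjugate(qs))
  expect_lt(max(abs(prod[, 1L] - 1)), 1e-12)
  expect_lt(max(abs(prod[, 2:4])), 1e-12)

  # rotation-matrix oracle: M(q1 q2) = M(q1) M(q2), and matrix round trip
  for (i in 1:10) {
    q1 <- qs[2 * i - 1, ]; q2 <- qs[2 * i, ]
    expect_equal(quat_to_matrix(quat_multiply(q1, q2)),
                 quat_to_matrix(q1) %*% quat_to_matrix(q2), tolerance = 1e-12)
    expect_lt(rot_gap_deg(quat_from_matrix(quat_to_matrix(q1)), q1), 1e-9)
  }

  # axis-angle round trip
  ax <- c(1, 2, -1) / sqrt(6)
  qa <- quat_from_axis_angle(ax, 37)
  expect_equal(quat_angle(qa), 37, tolerance = 1e-12)
  expect_equal(quat_axis(qa), ax, tolerance = 1e-12)

  expect_error(quat_normalize(c(0, 0, 0, 0)), "zero-norm")
  expect_error(quat_from_axis_angle(c(0, 0, 0), 10), "non-zero")
})

test_that("unit norm is preserved by algebra within 1e-9", {
  set.seed(3)
  q <- rand_quat(200L)
  for (out in list(quat_multiply(q, q[1L, ]), quat_conjugate(q),
                   quat_multiply(quat_conjugate(q), q[200:1, ])))
    expect_lt(max(abs(rowSums(out^2) - 1)), 1e-9)
})

test_that("relative orientation expresses the secondary segment in the primary frame", {
  q <- quat_from_axis_angle(c(0, 0, 1), 30)
  expect_equal(relative_orientation(q, q), quat_identity(), tolerance = 1e-12)
  expect_equal(relative_orientation(quat_identity(), q), q)

  # left-invariance: a shared world rotation of both segments changes nothing
  set.seed(21)
  for (i in 1:25) {
    qp <- rand_quat(1L); qs <- rand_quat(1L); w <- rand_quat(1L)
    expect_lt(rot_gap_deg(relative_orientation(qp, qs),
                          relative_orientation(quat_multiply(w, qp),
                                               quat_multiply(w, qs))), 1e-9)
  }
})

test_that("joint-level calibration zeroes the upright pose", {
  set.seed(5)
  q <- rand_quat(1L)
  expect_equal(calibrate(q, q), quat_identity(), tolerance = 1e-12)
  expect_equal(calibrate(q, quat_identity()), q)
})

test_that("swing-twist factorisation recombines and splits about the chosen axis", {
  st <- swing_twist_decompose(quat_identity(), c(0, 0, 1))
  expect_equal(st$swing, quat_identity())
  expect_equal(st$twist, quat_identity())

  q90z <- quat_from_axis_angle(c(0, 0, 1), 90)
  st <- swing_twist_decompose(q90z, c(0, 0, 1))
  expect_lt(rot_gap_deg(st$twist, q90z), 1e-12)
  expect_equal(quat_angle(st$swing), 0, tolerance = 1e-9)
  expect_equal(st$twist_deg, 90, tolerance = 1e-9)

  # worked half-unit example: twist 90 about z, swing 90 about y
  q <- c(0.5, 0.5, 0.5, 0.5)
  st <- swing_twist_decompose(q, c(0, 0, 1))
  expect_lt(rot_gap_deg(st$twist, quat_from_axis_angle(c(0, 0, 1), 90)), 1e-9)
  expect_lt(rot_gap_deg(st$swing, quat_from_axis_angle(c(0, 1, 0), 90)), 1e-9)
  recomposed <- quat_multiply(st$swing, st$twist)
  expect_equal(abs(sum(recomposed * q)), 1, tolerance = 1e-12)

  # property: swing * twist = +/-q; twist axis parallel, swing axis orthogonal
  set.seed(8)
  qs <- rand_quat(500L)
  axes <- matrix(rnorm(1500L), ncol = 3L)
  axes <- axes / sqrt(rowSums(axes^2))
  for (i in seq_len(nrow(qs))) {
    a <- axes[i, ]
    st <- swing_twist_decompose(qs[i, ], a)
    rec <- quat_multiply(st$swing, st$twist)
    expect_lt(min(max(abs(rec - qs[i, , drop = FALSE])),
                  max(abs(rec + qs[i, , drop = FALSE]))), 1e-9)
    tv <- st$twist[1L, 2:4]
    if (sqrt(sum(tv^2)) > 1e-9)                      # parallel to the axis
      expect_lt(abs(abs(sum(tv * a)) - sqrt(sum(tv^2))), 1e-9)
    expect_lt(abs(sum(st$swing[1L, 2:4] * a)), 1e-9) # orthogonal swing
  }

  # singular case: 180 degrees perpendicular to the twist axis
  st <- swing_twist_decompose(quat_from_axis_angle(c(1, 0, 0), 180), c(0, 0, 1))
  expect_true(st$singular)
  expect_equal(st$twist, quat_identity())
})

test_that("slerp interpolates at constant angular speed along the shorter arc", {
  q0 <- quat_identity()
  q1 <- quat_from_axis_angle(c(0, 0, 1), 90)
  expect_equal(slerp(q0, q1, 0), q0, ignore_attr = TRUE, tolerance = 1e-12)
  expect_lt(rot_gap_deg(slerp(q0, q1, 1), q1), 1e-9)
  expect_lt(rot_gap_deg(slerp(q0, q1, 0.5),
                        quat_from_axis_angle(c(0, 0, 1), 45)), 1e-9)

  # angle from q0 grows linearly in t (numeric angle extraction on a grid)
  set.seed(13)
  qa <- rand_quat(1L); qb <- rand_quat(1L)
  gap <- rot_gap_deg(qa, qb)
  if (gap > 179) qb <- quat_multiply(qb, quat_from_axis_angle(c(1, 0, 0), 20))
  gap <- rot_gap_deg(qa, qb)
  ts <- seq(0, 1, by = 0.1)
  angles <- vapply(ts, function(t) rot_gap_deg(qa, slerp(qa, qb, t)), numeric(1L))
  expect_equal(angles, ts * gap, tolerance = 1e-8)

  # shorter arc: interpolating towards -q1 must behave as towards q1
  expect_lt(rot_gap_deg(slerp(q0, -q1, 0.5),
                        quat_from_axis_angle(c(0, 0, 1), 45)), 1e-9)

  # antipodal 4-vectors (a 180 degree rotation gap): flagged nlerp fallback
  out <- slerp(c(1, 0, 0, 0), c(0, 0, 0, 1), 0.25)
  expect_true(attr(out, "nlerp_fallback"))
  expect_lt(abs(sum(out^2) - 1), 1e-12)

  expect_error(slerp(q0, q1, 1.5), "\\[0, 1\\]")
})

test_that("chordal mean and sign continuity handle hemisphere flips", {
  base <- quat_from_axis_angle(c(0, 1, 0), 40)
  set.seed(2)
  cluster <- quat_multiply(base, quat_from_rotvec_test(matrix(rnorm(60L, 0, 0.005), ncol = 3L)))
  # flip half the samples: the mean must not care about quaternion sign
  flipped <- cluster
  flipped[seq(1L, 20L, by = 2L), ] <- -flipped[seq(1L, 20L, by = 2L), ]
  expect_lt(rot_gap_deg(quat_mean(cluster), quat_mean(flipped)), 1e-9)
  expect_lt(rot_gap_deg(quat_mean(cluster), base), 0.5)

  # alternating-sign stream encoding one smooth rotation
  smooth <- quat_from_axis_angle(matrix(c(0, 0, 1), 1L), seq(0, 30, length.out = 40L))
  alt <- smooth * rep_len(c(1, -1), 40L)
  fixed <- quat_continuity(alt)
  steps <- rot_gap_deg(fixed[-40L, ], fixed[-1L, ])
  expect_lt(max(steps), 5)
  expect_gt(min(rowSums(fixed[-1L, ] * fixed[-40L, ])), 0)
})
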