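# Synthetic single-leg-squat generator: a 4-segment rigid chain (trunk, pelvis,
# thigh, shank) follows a metronome-timed 2 s down / 2 s up squat and is
# rendered both as a 120 Hz optical marker-cluster capture and as a 50 Hz
# orientation-sensor stream, with the ground-truth joint curves retained.

# run code under a temporary RNG state; NULL seed means "use the current stream"
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Squat movement shape
#'
#' Smooth descent-ascent profile `sin^2(pi * t / duration)`: zero at the start
#' and end, unity at mid-movement (2 s into the default 4 s trial). Every joint
#' angle follows its peak value times this shape.
#'
#' @param t Time(s) in seconds.
#' @param duration Trial duration in seconds (default 4: 2 s down, 2 s up).
#' @return Dimensionless shape value(s) in \[0, 1\].
#' @export
squat_shape <- function(t, duration = 4) sin(pi * t / duration)^2

#' Population specification for the synthetic cohort
#'
#' Defaults reproduce the descriptive scale of the study population this
#' simulator emulates: 44 subjects, 3 trials each, subject-level peak angles
#' drawn from Normal(mean, SD^2) per variable with first-trial reference means
#' knee 73.8 (9.1), hip 60.8 (14.7), hip sway -8.1 (17.1), spine 13.8 (10.9)
#' and spine sway 3.8 (5.7) degrees, plus within-subject between-trial jitter.
#'
#' Noise magnitudes: soft-tissue artefact (STA) is a correlated Gaussian
#' process (correlation time `sta_tau`) with 3-D RMS displacement
#' `sta_amplitude` per segment, split into a cluster-common rigid displacement
#' and a per-marker independent residual (`sta_marker_frac` of the amplitude);
#' additive white marker noise `marker_white_sd` (mm, per axis); sensor
#' orientation noise as a correlated rotation-vector process with stationary
#' SD `imu_noise_sd` (degrees); constant per-subject sensor mounting
#' misalignment with SD `mounting_sd` (degrees).
#'
#' @param means,sds Named numeric vectors (degrees) of subject-level peak-angle
#'   means and SDs for `knee_flexion`, `hip_flexion`, `hip_sway`,
#'   `spine_flexion`, `spine_sway`.
#' @param between_trial_sd Within-subject between-trial SD, degrees.
#' @param n_subjects,n_trials Cohort shape (default 44 x 3 = 132 trials).
#' @param sta_amplitude Named 3-D RMS STA amplitude per segment, mm.
#' @param sta_tau,imu_noise_tau Correlation times, seconds.
#' @param sta_marker_frac Fraction of STA amplitude that is per-marker
#'   independent rather than cluster-common.
#' @param marker_white_sd Per-axis white marker noise SD, mm.
#' @param imu_noise_sd Stationary sensor orientation noise SD, degrees.
#' @param mounting_sd Sensor mounting misalignment SD, degrees.
#' @param seed Base seed; all randomness in dataset generation derives from it.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(means = c(knee_flexion = 73.8, hip_flexion = 60.8,
                                      hip_sway = -8.1, spine_flexion = 13.8,
                                      spine_sway = 3.8),
                            sds = c(knee_flexion = 9.1, hip_flexion = 14.7,
                                    hip_sway = 17.1, spine_flexion = 10.9,
                                    spine_sway = 5.7),
                            between_trial_sd = 3,
                            n_subjects = 44, n_trials = 3,
                            sta_amplitude = c(trunk = 5, pelvis = 5, thigh = 10, shank = 5),
                            sta_tau = 0.5, sta_marker_frac = 0.3,
                            marker_white_sd = 0.5,
                            imu_noise_sd = 1, imu_noise_tau = 0.5,
                            mounting_sd = 5,
                            seed = 1L) {
  vars <- c("knee_flexion", "hip_flexion", "hip_sway", "spine_flexion", "spine_sway")
  if (!all(vars %in% names(means)) || !all(vars %in% names(sds)))
    stop("means and sds must name all five variables: ", paste(vars, collapse = ", "))
  if (any(sds < 0) || between_trial_sd < 0 || any(sta_amplitude < 0) ||
      marker_white_sd < 0 || imu_noise_sd < 0 || mounting_sd < 0)
    stop("standard deviations and noise amplitudes must be non-negative")
  if (n_subjects < 1 || n_trials < 1) stop("n_subjects and n_trials must be positive")
  structure(list(means = means[vars], sds = sds[vars],
                 between_trial_sd = between_trial_sd,
                 n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
                 sta_amplitude = sta_amplitude, sta_tau = sta_tau,
                 sta_marker_frac = sta_marker_frac,
                 marker_white_sd = marker_white_sd,
                 imu_noise_sd = imu_noise_sd, imu_noise_tau = imu_noise_tau,
                 mounting_sd = mounting_sd, seed = as.integer(seed)),
            class = "population_spec")
}

#' Remove all noise sources from a population specification
#'
#' @param spec A [population_spec()].
#' @return The spec with every noise amplitude (STA, white marker noise,
#'   sensor orientation noise, mounting misalignment) set to zero; the
#'   peak-angle distributions are untouched.
#' @export
noise_free <- function(spec) {
  spec$sta_amplitude[] <- 0
  spec$marker_white_sd <- 0
  spec$imu_noise_sd <- 0
  spec$mounting_sd <- 0
  spec
}

#' Draw per-subject, per-trial peak angles
#'
#' Subject-level peaks are drawn from Normal(mean, SD^2) per variable, then
#' trial-level jitter with SD `between_trial_sd` is added. Deterministic for a
#' fixed seed.
#'
#' @param spec A [population_spec()].
#' @param seed Seed; defaults to the spec's own.
#' @return Data frame with `subject`, `trial` and the five peak-angle columns
#'   (degrees).
#' @export
sample_population <- function(spec, seed = spec$seed) {
  vars <- names(spec$means)
  with_seed(seed, {
    subj <- matrix(stats::rnorm(spec$n_subjects * 5L,
                                mean = rep(spec$means, each = spec$n_subjects),
                                sd = rep(spec$sds, each = spec$n_subjects)),
                   ncol = 5L, dimnames = list(NULL, vars))
    out <- do.call(rbind, lapply(seq_len(spec$n_trials), function(tr) {
      jit <- matrix(stats::rnorm(spec$n_subjects * 5L, 0, spec$between_trial_sd),
                    ncol = 5L)
      data.frame(subject = seq_len(spec$n_subjects), trial = tr, subj + jit)
    }))
  })
  out <- out[order(out$subject, out$trial), ]
  rownames(out) <- NULL
  out
}

#' Rigid-body model of the instrumented segments
#'
#' Segment lengths of a ~1.75 m adult, a 4-marker rigid cluster plate template
#' (80 x 120 mm, non-collinear) shared by all segments, the cluster mounting
#' sites (sternal manubrium for the trunk, sacrum for the pelvis, lateral
#' mid-thigh, anteromedial mid-shank) and per-segment sensor mounting
#' rotations (identity unless perturbed).
#'
#' @param lengths Named segment lengths in metres.
#' @param mounting Optional named list of unit quaternions, one per segment.
#' @return An object of class `body_model`.
#' @export
body_model <- function(lengths = c(shank = 0.43, thigh = 0.45, pelvis = 0.10, trunk = 0.50),
                       mounting = NULL) {
  template <- rbind(c(0.04, 0.06, 0), c(0.04, -0.06, 0),
                    c(-0.04, 0.06, 0), c(-0.04, -0.06, 0))
  segs <- c("trunk", "pelvis", "thigh", "shank")
  if (is.null(mounting)) mounting <- stats::setNames(rep(list(quat_identity()), 4L), segs)
  for (s in segs) {
    if (abs(sum(as_quat(mounting[[s]])^2) - 1) > 1e-9)
      stop("mounting rotations must be unit quaternions")
  }
  # centred template must span a plane (markers not collinear)
  ctr <- scale(template, scale = FALSE)
  if (qr(ctr)$rank < 2L) stop("cluster template markers are collinear")
  structure(list(
    lengths = lengths,
    ankle = c(0, 0.09, 0),
    cluster_offset = list(trunk = c(0.06, 0.45, 0), pelvis = c(-0.10, 0.10, 0),
                          thigh = c(0, 0.225, 0.08), shank = c(0.03, 0.215, -0.02)),
    template = template,
    mounting = mounting,
    segments = segs
  ), class = "body_model")
}

# joint -> (sagittal variable, frontal variable) in the reported convention
.joint_vars <- list(spine = c("spine_flexion", "spine_sway"),
                    hip = c("hip_flexion", "hip_sway"),
                    knee = c("knee_flexion", NA))

.joints <- list(spine = c(primary = "pelvis", secondary = "trunk"),
                hip = c(primary = "pelvis", secondary = "thigh"),
                knee = c(primary = "thigh", secondary = "shank"))

#' Forward kinematics of the squat chain
#'
#' Builds world position and orientation of each segment at the requested
#' times. Joint rotations are composed from the peak angles (reported
#' anatomical convention; converted internally to the raw frame convention via
#' [sign_convention()]) scaled by [squat_shape()]. The ankle stays fixed, so
#' pelvis vertical drop follows geometrically from knee and hip flexion. At
#' `t = 0` (all shapes zero) the chain is exactly in the upright reference
#' pose.
#'
#' @param model A [body_model()].
#' @param peaks Named numeric vector of the five peak angles, degrees.
#' @param times Sample times, seconds.
#' @param side Stance side for the sign convention.
#' @return List with `time`, and per segment a list of `origin` (n x 3 metres)
#'   and `quat` (n x 4).
#' @export
forward_kinematics <- function(model, peaks, times, side = "right") {
  shape <- squat_shape(times)
  jq <- lapply(names(.joints), function(j) {
    sc <- sign_convention(j, side)
    v <- .joint_vars[[j]]
    sag <- sc[["sagittal"]] * (if (is.na(v[1])) 0 else peaks[[v[1]]]) * shape
    fro <- sc[["frontal"]] * (if (is.na(v[2])) 0 else peaks[[v[2]]]) * shape
    euler_compose(sag, fro)
  })
  names(jq) <- names(.joints)
  n <- length(times)
  q_pelvis <- quat_identity(n)
  q_trunk <- jq$spine
  q_thigh <- jq$hip
  q_shank <- quat_multiply(q_thigh, jq$knee)
  L <- model$lengths
  ankle <- matrix(model$ankle, n, 3L, byrow = TRUE)
  knee <- ankle + quat_rotate(q_shank, c(0, L[["shank"]], 0))
  hip <- knee + quat_rotate(q_thigh, c(0, L[["thigh"]], 0))
  list(time = times,
       trunk = list(origin = hip, quat = q_trunk),
       pelvis = list(origin = hip, quat = q_pelvis),
       thigh = list(origin = knee, quat = q_thigh),
       shank = list(origin = ankle, quat = q_shank))
}

# stationary AR(1) (Ornstein-Uhlenbeck) sample paths, n x ncols
ar1_noise <- function(n, ncols, dt, tau, sd) {
  if (sd <= 0 || n == 0L) return(matrix(0, n, ncols))
  if (tau <= 0) return(matrix(stats::rnorm(n * ncols, 0, sd), n, ncols))
  phi <- exp(-dt / tau)
  innov_sd <- sd * sqrt(1 - phi^2)
  vapply(seq_len(ncols), function(k) {
    x0 <- stats::rnorm(1L, 0, sd)
    as.numeric(stats::filter(stats::rnorm(n, 0, innov_sd), phi,
                             method = "recursive", init = x0))
  }, numeric(n))
}

#' Render noisy 120 Hz marker trajectories
#'
#' World marker positions from the rigid chain, plus soft-tissue artefact
#' (cluster-common and per-marker correlated displacement processes) and white
#' measurement noise. With all amplitudes zero the output is the exact
#' rigid-body geometry.
#'
#' @param fk Output of [forward_kinematics()].
#' @param model A [body_model()].
#' @param spec A [population_spec()] supplying the noise magnitudes.
#' @param seed Optional seed for reproducible rendering.
#' @return Data frame: `time_s`, then `<segment>_m<k>_<x|y|z>` columns in mm.
#' @export
render_markers <- function(fk, model, spec, seed = NULL) {
  with_seed(seed, {
    n <- length(fk$time)
    dt <- if (n > 1L) fk$time[2L] - fk$time[1L] else 1 / 120
    cols <- list(time_s = fk$time)
    for (s in model$segments) {
      amp <- spec$sta_amplitude[[s]]
      common_sd <- amp * sqrt(1 - spec$sta_marker_frac^2) / sqrt(3)
      marker_sd <- amp * spec$sta_marker_frac / sqrt(3)
      sta_common <- ar1_noise(n, 3L, dt, spec$sta_tau, common_sd)
      off <- model$cluster_offset[[s]]
      for (k in seq_len(nrow(model$template))) {
        world_mm <- 1000 * (fk[[s]]$origin +
                              quat_rotate(fk[[s]]$quat, off + model$template[k, ]))
        noise <- sta_common + ar1_noise(n, 3L, dt, spec$sta_tau, marker_sd)
        if (spec$marker_white_sd > 0)
          noise <- noise + matrix(stats::rnorm(n * 3L, 0, spec$marker_white_sd), n, 3L)
        world_mm <- world_mm + noise
        for (a in 1:3)
          cols[[paste0(s, "_m", k, "_", c("x", "y", "z")[a])]] <- world_mm[, a]
      }
    }
    as.data.frame(cols)
  })
}

#' Render noisy 50 Hz sensor orientation quaternions
#'
#' Each sensor reports its segment's world orientation right-multiplied by its
#' constant mounting rotation, perturbed by a correlated small-angle
#' orientation noise process (stationary SD `imu_noise_sd` degrees).
#'
#' @inheritParams render_markers
#' @return Data frame: `time_s`, then `<segment>_<w|x|y|z>` columns.
#' @export
render_imu <- function(fk, model, spec, seed = NULL) {
  with_seed(seed, {
    n <- length(fk$time)
    dt <- if (n > 1L) fk$time[2L] - fk$time[1L] else 1 / 50
    cols <- list(time_s = fk$time)
    sd_rad <- spec$imu_noise_sd * pi / 180 / sqrt(3)   # per rotation-vector axis
    for (s in model$segments) {
      q <- quat_multiply(fk[[s]]$quat, model$mounting[[s]])
      if (spec$imu_noise_sd > 0) {
        rv <- ar1_noise(n, 3L, dt, spec$imu_noise_tau, sd_rad)
        q <- quat_multiply(q, quat_from_rotvec(rv))
      }
      q <- quat_continuity(quat_normalize(q))
      for (a in 1:4)
        cols[[paste0(s, "_", c("w", "x", "y", "z")[a])]] <- q[, a]
    }
    as.data.frame(cols)
  })
}

#' Simulate one complete single-leg-squat trial
#'
#' Produces the movement capture on both modalities (120 Hz markers, 50 Hz
#' sensor quaternions), a 1 s static upright calibration capture for each, and
#' the ground-truth joint-angle curves in the reported anatomical convention.
#'
#' @param peaks Named numeric vector of the five peak angles, degrees.
#' @param model A [body_model()]; supply per-subject mounting rotations here.
#' @param spec A [population_spec()] (noise magnitudes).
#' @param seed Seed for this trial's noise.
#' @param side Stance side.
#' @param duration Movement duration, seconds.
#' @param cal_duration Calibration capture duration, seconds.
#' @return An object of class `synthetic_trial`: list with `markers`, `imu`,
#'   `cal_markers`, `cal_imu`, `truth`, `peaks`, `side`, `seed`.
#' @export
simulate_trial <- function(peaks, model = body_model(), spec = population_spec(),
                           seed = NULL, side = "right", duration = 4,
                           cal_duration = 1) {
  t_m <- seq(0, duration, by = 1 / 120)
  t_i <- seq(0, duration, by = 1 / 50)
  tc_m <- seq(0, cal_duration, by = 1 / 120)
  tc_i <- seq(0, cal_duration, by = 1 / 50)
  fk_m <- forward_kinematics(model, peaks, t_m, side)
  fk_i <- forward_kinematics(model, peaks, t_i, side)
  zero <- stats::setNames(rep(0, 5L), names(.peak_vars))
  fk_cal_m <- forward_kinematics(model, zero, tc_m, side)
  fk_cal_i <- forward_kinematics(model, zero, tc_i, side)
  shape <- squat_shape(t_m, duration)
  truth <- data.frame(time_s = t_m,
                      knee_sagittal_deg = peaks[["knee_flexion"]] * shape,
                      knee_frontal_deg = 0,
                      hip_sagittal_deg = peaks[["hip_flexion"]] * shape,
                      hip_frontal_deg = peaks[["hip_sway"]] * shape,
                      spine_sagittal_deg = peaks[["spine_flexion"]] * shape,
                      spine_frontal_deg = peaks[["spine_sway"]] * shape)
  out <- with_seed(seed, list(
    markers = render_markers(fk_m, model, spec),
    imu = render_imu(fk_i, model, spec),
    cal_markers = render_markers(fk_cal_m, model, spec),
    cal_imu = render_imu(fk_cal_i, model, spec)
  ))
  out$truth <- truth
  out$peaks <- peaks
  out$side <- side
  out$seed <- seed
  class(out) <- "synthetic_trial"
  out
}

.peak_vars <- c(knee_flexion = "knee_sagittal_deg", hip_flexion = "hip_sagittal_deg",
                hip_sway = "hip_frontal_deg", spine_flexion = "spine_sagittal_deg",
                spine_sway = "spine_frontal_deg")

# deterministic per-subject / per-trial seed derivation, kept under 2^31
# (numeric arithmetic: exact in doubles, no 32-bit integer overflow)
subject_seed <- function(base, subject)
  as.integer((as.numeric(base) * 1009 + subject * 7) %% 2147483647)
trial_seed <- function(base, subject, trial)
  as.integer((as.numeric(base) * 1013 + subject * 101 + trial) %% 2147483647)

# draw a per-subject set of constant sensor mounting rotations
draw_mounting <- function(spec, seed) {
  with_seed(seed, {
    segs <- c("trunk", "pelvis", "thigh", "shank")
    stats::setNames(lapply(segs, function(s) {
      rv <- stats::rnorm(3L, 0, spec$mounting_sd * pi / 180 / sqrt(3))
      quat_from_rotvec(rv)
    }), segs)
  })
}

#' Simulate a full study cohort in memory
#'
#' @param spec A [population_spec()].
#' @return List of trials; each element carries the [simulate_trial()] output
#'   plus `subject` and `trial` ids.
#' @export
simulate_study <- function(spec = population_spec()) {
  pop <- sample_population(spec)
  trials <- vector("list", nrow(pop))
  for (i in seq_len(nrow(pop))) {
    su <- pop$subject[i]; tr <- pop$trial[i]
    model <- body_model(mounting = draw_mounting(spec, subject_seed(spec$seed, su)))
    peaks <- unlist(pop[i, names(.peak_vars)])
    trial <- simulate_trial(peaks, model, spec,
                            seed = trial_seed(spec$seed, su, tr))
    trial$subject <- su
    trial$trial <- tr
    trials[[i]] <- trial
  }
  trials
}

#' Write a synthetic dataset to disk
#'
#' One directory per subject/trial containing `markers.csv`, `imu.csv`,
#' `cal_markers.csv`, `cal_imu.csv` and `truth.csv` (dialects documented in
#' the rendering functions), plus a JSON manifest at the root recording the
#' spec and every derived seed, sufficient to regenerate the dataset
#' byte-identically.
#'
#' @param spec A [population_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(spec = population_spec(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  pop <- sample_population(spec)
  entries <- vector("list", nrow(pop))
  for (i in seq_len(nrow(pop))) {
    su <- pop$subject[i]; tr <- pop$trial[i]
    model <- body_model(mounting = draw_mounting(spec, subject_seed(spec$seed, su)))
    peaks <- unlist(pop[i, names(.peak_vars)])
    trial <- simulate_trial(peaks, model, spec,
                            seed = trial_seed(spec$seed, su, tr))
    tdir <- file.path(out_dir, sprintf("subject%02d", su), sprintf("trial%d", tr))
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    for (f in c("markers", "imu", "cal_markers", "cal_imu", "truth")) {
      path <- file.path(tdir, paste0(f, ".csv"))
      tryCatch(utils::write.csv(trial[[f]], path, row.names = FALSE),
               error = function(e) stop("failed writing ", path, ": ",
                                        conditionMessage(e)))
    }
    entries[[i]] <- list(subject = su, trial = tr,
                         dir = file.path(sprintf("subject%02d", su),
                                         sprintf("trial%d", tr)),
                         seed = trial_seed(spec$seed, su, tr),
                         peaks = as.list(peaks))
  }
  manifest <- list(format_version = "1.0",
                   spec = unclass(spec), trials = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
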