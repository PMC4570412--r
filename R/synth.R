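# Seeded multi-sensor movement simulator. Forward kinematics of a two-
# segment arm drives the skeleton stream; IMU accelerometer channels are the
# projection of gravity onto the rotating sensor axes (so a 180-degree
# supination sweeps the Z channel from +1 g to -1 g), gyroscope channels are
# the angular-velocity profiles; glove and pressure channels follow the
# finger-flexion and grip profiles. Score 2 executes the template fully,
# score 1 scales the movement amplitude by a partial factor, score 0 leaves
# only residual motion. Everything is deterministic given the seed.

#' Subject parameters for the simulator
#'
#' @param upper_arm_length,forearm_length segment lengths in meters.
#' @param movement_speed_factor multiplicative speed factor (> 0); 1 is the
#'   template's nominal pace.
#' @param tremor_amplitude tremor acceleration amplitude in g.
#' @param position_noise_sd Gaussian skeleton position noise (meters).
#' @param occlusion_rate expected fraction of skeleton frames lost to
#'   occlusion, in `[0, 1)`.
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(upper_arm_length = 0.30, forearm_length = 0.26,
                           movement_speed_factor = 1,
                           tremor_amplitude = 0.005,
                           position_noise_sd = 0.002,
                           occlusion_rate = 0) {
  if (upper_arm_length <= 0 || forearm_length <= 0)
    stop("subject_params: segment lengths must be > 0")
  if (movement_speed_factor <= 0)
    stop("subject_params: movement_speed_factor must be > 0")
  if (occlusion_rate < 0 || occlusion_rate >= 1)
    stop("subject_params: occlusion_rate must be in [0, 1)")
  structure(list(upper_arm_length = upper_arm_length,
                 forearm_length = forearm_length,
                 movement_speed_factor = movement_speed_factor,
                 tremor_amplitude = tremor_amplitude,
                 position_noise_sd = position_noise_sd,
                 occlusion_rate = occlusion_rate),
            class = "subject_params")
}

# Noise presets: "low_noise" emulates cooperative healthy subjects in a
# controlled lab; "clinical_noise" emulates the noisier stroke-patient
# setting (more tremor, more occlusion, sloppier tracking).
SYNTH_PRESETS <- list(
  low_noise = list(tremor_amplitude = 0.005, position_noise_sd = 0.002,
                   occlusion_rate = 0.01),
  clinical_noise = list(tremor_amplitude = 0.04, position_noise_sd = 0.010,
                        occlusion_rate = 0.06))

SKELETON_RATE <- 30    # Hz
IMU_RATE <- 100        # Hz
GLOVE_RATE <- 100      # Hz
PRESSURE_RATE <- 30    # Hz

# Movement templates: joint-angle / rotation / finger / grip profiles of the
# full (score-2) execution. Angles in degrees; plane "frontal" moves the arm
# in the camera X-Y plane (abduction), "sagittal" in Y-Z (flexion, toward
# the camera). rotation is the forearm pronation/supination angle driving
# the IMU gravity projection. lead_in/tail are rest paddings (seconds).
movement_template <- function(test_id) {
  base <- list(plane = "sagittal", shoulder_start = 0, shoulder_range = 0,
               elbow_start = 5, elbow_range = 0, rotation_start = 0,
               rotation_range = 0, finger_start = 0, finger_range = 0,
               grip_range = 0, duration = 2.5, lead_in = 0.8, tail = 1.6,
               oscillations = 0, tremor_scored = FALSE)
  tweak <- switch(test_id,
    shoulder_abduction = list(plane = "frontal", shoulder_range = 120),
    shoulder_external_rotation = list(plane = "frontal", shoulder_start = 15,
                                      elbow_range = 90),
    shoulder_abduction_0_90 = list(plane = "frontal", shoulder_range = 90),
    shoulder_flexion_0_90 = list(shoulder_range = 90),
    shoulder_flexion_90_180 = list(shoulder_start = 90, shoulder_range = 85),
    elbow_flexion = list(shoulder_start = 10, elbow_range = 115),
    elbow_extension = list(shoulder_start = 10, elbow_start = 125,
                           elbow_range = -110),
    prosupination_elbow_90 = list(rotation_range = 180),
    prosupination_elbow_0 = list(rotation_range = 180),
    forearm_supination = list(rotation_range = 180),
    forearm_pronation = list(rotation_start = 180, rotation_range = -180),
    finger_mass_flexion = list(finger_range = 1),
    finger_mass_extension = list(finger_start = 1, finger_range = -1),
    grasp_a = list(finger_range = 0.8, grip_range = 1),
    grasp_b = list(finger_range = 0.7, grip_range = 0.9),
    grasp_c = list(finger_range = 0.6, grip_range = 0.8),
    grasp_d = list(finger_range = 0.9, grip_range = 1),
    grasp_e = list(finger_range = 0.85, grip_range = 0.95),
    wrist_flexext_elbow_90 = list(rotation_range = 70),
    wrist_flexext_elbow_0 = list(rotation_range = 70),
    wrist_circumduction = list(rotation_range = 60, oscillations = 2),
    coordination_tremor = list(shoulder_range = 40, elbow_range = 30,
                               tremor_scored = TRUE),
    coordination_speed = list(shoulder_range = 60, elbow_range = 60,
                              duration = 1.5),
    stop("simulate_movement: unknown test id: ", test_id))
  base[names(tweak)] <- tweak
  base
}

# smoothstep ramp 0..1
smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  u * u * (3 - 2 * u)
}

# Movement phase profile over absolute time: 0 during lead-in, smoothstep
# ramp during the movement, then held (or oscillating for circumduction).
template_phase <- function(t, tpl, move_dur) {
  u <- (t - tpl$lead_in) / move_dur
  if (tpl$oscillations > 0) {
    p <- smoothstep(u) * sin(2 * pi * tpl$oscillations * pmin(1, pmax(0, u)))
    p
  } else {
    smoothstep(u)
  }
}

deg2rad <- function(d) d * pi / 180

#' Simulate one test-movement recording
#'
#' Generates the streams the test requires (skeleton at 30 Hz via forward
#' kinematics, IMU at 100 Hz via gravity projection and angular-velocity
#' profiles, glove at 100 Hz, pressure at 30 Hz), injects Gaussian position
#' noise, tremor and occlusion dropouts, and records the generating score.
#'
#' @param test_id registry test id.
#' @param score generating impairment level 0, 1 or 2.
#' @param subject a [subject_params()].
#' @param seed integer seed; identical seeds give identical bundles.
#' @param subject_id,side metadata for the bundle.
#' @param registry the test registry.
#' @return a [recording_bundle()] with `true_score` set.
#' @export
simulate_movement <- function(test_id, score, subject = subject_params(),
                              seed = 1, subject_id = "sim", side = "right",
                              registry = fma_registry()) {
  def <- registry_lookup(registry, test_id)
  if (!(score %in% 0:2)) stop("simulate_movement: score must be 0, 1 or 2")
  tpl <- movement_template(test_id)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))

  # score 2: full amplitude; score 1: partial; score 0: residual motion only
  amp <- switch(as.character(score),
                "2" = 1,
                "1" = runif(1, 0.3, 0.7),
                "0" = runif(1, 0, 0.05))
  if (tpl$tremor_scored) amp <- 1
  tremor <- subject$tremor_amplitude +
    if (tpl$tremor_scored) (2 - score) * 0.12 else 0

  move_dur <- tpl$duration / subject$movement_speed_factor
  total <- tpl$lead_in + move_dur + tpl$tail

  profiles <- function(t) {
    p <- template_phase(t, tpl, move_dur)
    list(shoulder = tpl$shoulder_start + amp * tpl$shoulder_range * p,
         elbow = tpl$elbow_start + amp * tpl$elbow_range * p,
         rotation = tpl$rotation_start + amp * tpl$rotation_range * p,
         finger = pmin(1, pmax(0, tpl$finger_start +
                                    amp * tpl$finger_range * p)),
         grip = pmin(1, pmax(0, amp * tpl$grip_range * p)))
  }

  streams <- list()
  if ("skeleton" %in% def$required_sensors)
    streams$skeleton <- synth_skeleton(profiles, total, tpl, subject, side)
  if ("imu" %in% def$required_sensors)
    streams$imu <- synth_imu(profiles, total, tremor)
  if ("glove" %in% def$required_sensors)
    streams$glove <- synth_glove(profiles, total)
  if ("pressure" %in% def$required_sensors)
    streams$pressure <- synth_pressure(profiles, total)

  recording_bundle(test_id, subject_id, side,
                   skeleton = streams$skeleton, imu = streams$imu,
                   glove = streams$glove, pressure = streams$pressure,
                   true_score = score, registry = registry)
}

# Forward kinematics: neck anchored in front of the camera, arm moving in
# the template plane; the off side rests. Joint positions get Gaussian
# noise; occlusion marks runs of side joints "missing".
synth_skeleton <- function(profiles, total, tpl, subject, side) {
  tt <- seq(0, total, by = 1 / SKELETON_RATE)
  n <- length(tt)
  p <- profiles(tt)
  th <- deg2rad(p$shoulder)   # shoulder elevation from hanging
  ph <- deg2rad(p$elbow)      # elbow flexion relative to upper arm

  neck <- c(0, 0.55, 2.0)
  sx <- if (side == "left") 0.18 else -0.18
  lat <- sign(sx)
  # unit direction of a segment elevated by angle a in the movement plane
  seg_dir <- function(a) {
    if (tpl$plane == "frontal")
      cbind(lat * sin(a), -cos(a), rep(0, length(a)))
    else
      cbind(rep(0, length(a)), -cos(a), -sin(a))
  }
  du <- seg_dir(th)
  df_ <- seg_dir(th + ph)
  shoulder <- matrix(rep(neck + c(sx, -0.03, 0), each = n), n)
  elbow <- shoulder + subject$upper_arm_length * du
  wrist <- elbow + subject$forearm_length * df_
  hand <- wrist + 0.08 * df_

  off <- if (side == "left") "r" else "l"
  on_ <- if (side == "left") "l" else "r"
  rest_sh <- matrix(rep(neck + c(-sx, -0.03, 0), each = n), n)
  rest_el <- rest_sh + subject$upper_arm_length *
    matrix(rep(c(0, -1, 0), each = n), n)
  rest_wr <- rest_el + subject$forearm_length *
    matrix(rep(c(0, -1, 0), each = n), n)

  jn <- c("neck", paste0("shoulder_", c("l", "r")),
          paste0("elbow_", c("l", "r")), paste0("wrist_", c("l", "r")),
          paste0("hand_", on_))
  joints <- array(0, c(n, length(jn), 3), dimnames = list(NULL, jn, NULL))
  joints[, "neck", ] <- matrix(rep(neck, each = n), n)
  joints[, paste0("shoulder_", on_), ] <- shoulder
  joints[, paste0("elbow_", on_), ] <- elbow
  joints[, paste0("wrist_", on_), ] <- wrist
  joints[, paste0("hand_", on_), ] <- hand
  joints[, paste0("shoulder_", off), ] <- rest_sh
  joints[, paste0("elbow_", off), ] <- rest_el
  joints[, paste0("wrist_", off), ] <- rest_wr
  joints <- joints + array(rnorm(length(joints), 0,
                                 subject$position_noise_sd), dim(joints))

  conf <- matrix("tracked", n, length(jn), dimnames = list(NULL, jn))
  if (subject$occlusion_rate > 0) {
    # occlusion dropouts: runs with geometrically distributed lengths on the
    # moving side's distal joints
    mean_run <- 3
    p_start <- subject$occlusion_rate / mean_run
    i <- 1L
    occ_joints <- paste0(c("elbow_", "wrist_", "hand_"), on_)
    occ_joints <- intersect(occ_joints, jn)
    while (i <= n) {
      if (runif(1) < p_start) {
        len <- stats::rgeom(1, 1 / mean_run) + 1L
        conf[i:min(n, i + len - 1L), occ_joints] <- "missing"
        i <- i + len
      } else i <- i + 1L
    }
  }
  skeleton_sequence(tt, joints, conf, SKELETON_RATE)
}

# IMU worn like a wristwatch: gravity projects onto the sensor Y/Z axes as
# the forearm rotates; gyro X carries the rotation rate, gyro Y the elbow/
# shoulder angular rate. Tremor is a 8 Hz oscillation on the accelerometer
# with a matched angular-rate ripple on the gyro.
synth_imu <- function(profiles, total, tremor) {
  tt <- seq(0, total, by = 1 / IMU_RATE)
  n <- length(tt)
  p <- profiles(tt)
  rho <- deg2rad(p$rotation)
  dt <- 1 / IMU_RATE
  drot <- c(0, diff(p$rotation)) / dt            # deg/s
  darm <- c(0, diff(p$shoulder + p$elbow)) / dt  # deg/s
  accel_noise <- 0.01
  gyro_noise <- 1.0
  phase <- runif(3, 0, 2 * pi)
  trem <- function(k) tremor * sin(2 * pi * 8 * tt + phase[k])
  accel <- cbind(trem(1) + rnorm(n, 0, accel_noise),
                 sin(rho) + trem(2) + rnorm(n, 0, accel_noise),
                 cos(rho) + trem(3) + rnorm(n, 0, accel_noise))
  gyro <- cbind(drot + tremor * 150 * sin(2 * pi * 8 * tt + phase[1]) +
                  rnorm(n, 0, gyro_noise),
                darm + tremor * 150 * sin(2 * pi * 8 * tt + phase[2]) +
                  rnorm(n, 0, gyro_noise),
                rnorm(n, 0, gyro_noise))
  imu_trace(tt, accel, gyro, "wrist")
}

synth_glove <- function(profiles, total) {
  tt <- seq(0, total, by = 1 / GLOVE_RATE)
  p <- profiles(tt)
  offs <- c(0, 20, 40, 25, 10)      # per-finger resting offsets (counts)
  gain <- c(700, 720, 710, 690, 680)
  flex <- sapply(1:5, function(k)
    150 + offs[k] + gain[k] * p$finger + rnorm(length(tt), 0, 3))
  flex[] <- pmin(1023, pmax(0, flex))
  glove_trace(tt, flex, raw_max = 1023)
}

synth_pressure <- function(profiles, total) {
  tt <- seq(0, total, by = 1 / PRESSURE_RATE)
  p <- profiles(tt)
  val <- pmax(0, 40 + 700 * p$grip + rnorm(length(tt), 0, 5))
  pressure_trace(tt, val)
}

# Deterministic per-recording seed derived from the root seed and a running
# index (documented splitting scheme; stays below 2^31).
derive_seed <- function(root, index) {
  as.integer((as.double(root) %% 100000) * 20000 + index) %% 2147483647L
}

#' Simulate a cohort of subjects performing the registry tests
#'
#' Draws per-subject parameters from seeded distributions (segment lengths
#' Normal around 0.30/0.26 m, speed factor Uniform 0.8--1.25, noise per the
#' preset), generates `reps_per_score` recordings per (subject, test, score),
#' and assembles per-test labeled feature datasets.
#'
#' @param n_subjects number of simulated subjects (`>= 1`).
#' @param reps_per_score recordings per (subject, test, score).
#' @param preset `"low_noise"` or `"clinical_noise"`.
#' @param seed root seed; all randomness derives from it.
#' @param tests test ids to simulate (default: the full registry).
#' @param registry the test registry.
#' @return list with `bundles` (flat list of [recording_bundle()]s),
#'   `datasets` (named list of [labeled_dataset()]s per test) and
#'   `subjects` (list of drawn [subject_params()]).
#' @export
simulate_cohort <- function(n_subjects, reps_per_score = 1,
                            preset = c("low_noise", "clinical_noise"),
                            seed = 1, tests = NULL,
                            registry = fma_registry()) {
  preset <- match.arg(preset)
  if (n_subjects < 1) stop("simulate_cohort: n_subjects must be >= 1")
  if (is.null(tests)) tests <- names(registry)
  pz <- SYNTH_PRESETS[[preset]]

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  set.seed(derive_seed(seed, 0L))
  subjects <- lapply(seq_len(n_subjects), function(i)
    subject_params(upper_arm_length = max(0.2, rnorm(1, 0.30, 0.02)),
                   forearm_length = max(0.18, rnorm(1, 0.26, 0.02)),
                   movement_speed_factor = runif(1, 0.8, 1.25),
                   tremor_amplitude = pz$tremor_amplitude,
                   position_noise_sd = pz$position_noise_sd,
                   occlusion_rate = pz$occlusion_rate))
  names(subjects) <- sprintf("S%02d", seq_len(n_subjects))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())

  bundles <- vector("list", n_subjects * length(tests) * 3 * reps_per_score)
  idx <- 0L
  for (si in seq_len(n_subjects)) {
    for (ti in seq_along(tests)) {
      for (score in 0:2) {
        for (rep_ in seq_len(reps_per_score)) {
          idx <- idx + 1L
          bundles[[idx]] <- simulate_movement(
            tests[ti], score, subjects[[si]],
            seed = derive_seed(seed, idx),
            subject_id = names(subjects)[si],
            registry = registry)
        }
      }
    }
  }

  datasets <- lapply(tests, function(id) {
    sel <- Filter(function(b) b$test_id == id, bundles)
    fvs <- lapply(sel, extract_features, registry = registry)
    labeled_dataset(fvs,
                    vapply(sel, `[[`, integer(1), "true_score"),
                    vapply(sel, `[[`, character(1), "subject_id"),
                    id)
  })
  names(datasets) <- tests
  list(bundles = bundles, datasets = datasets, subjects = subjects)
}
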