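G_MS2 <- 9.80665

#' Movement profile for the synthetic generator
#'
#' Describes one task regime: cycle rate and amplitudes of the dominant-axis
#' angular velocity, their trial-internal variability, pauses, optional
#' tremor and sensor noise. The generator builds half-sine velocity lobes
#' (closed-form integrals make the analytic feature oracles exact) and
#' synthesises acceleration as gravity rotated by the integrated angle plus
#' noise.
#'
#' @param cycle_rate Movement rate, Hz.
#' @param open_amp,close_amp Lobe peak angular velocities, deg/s (> 0).
#' @param rate_jitter,amp_jitter Fractional SD of per-cycle rate/amplitude.
#' @param pause_fraction Fraction of each cycle spent at rest, in `[0, 1)`.
#' @param tremor_freq,tremor_amp Optional additive tremor sinusoid (Hz,
#'   deg/s).
#' @param noise_gyro,noise_accel White-noise SD, deg/s and m/s^2.
#' @param duration Active task duration, s (10 in the protocol).
#' @param lead_in,lead_out Static baseline before/after the task, s.
#' @param ... Task-specific extras: `lobe_shape` (`"half_sine"` default, or
#'   `"raised_cosine"` for C1-smooth lobes that survive the task filters
#'   with negligible ringing), `lever_arm` (m; tangential linear
#'   acceleration coupled into the gravity axis), `final_dur_factor` /
#'   `final_amp_factor` (the last movement of a trial is often slower and
#'   reduced when the stop cue arrives; default 1 = unmodified),
#'   gait: `stride_time`,
#'   `swing_time`, `heeloff_time`, `heelstrike_time`, `ang_range`,
#'   `n_strides`; rotation: `n_steps`, `move_time`, `pause_time`,
#'   `step_angle`; tremor tasks: `accel_tremor_amp`, `tremor2_freq`,
#'   `tremor2_amp`, `accel_tremor2_amp`.
#' @return An object of class `movement_profile`.
#' @export
movement_profile <- function(cycle_rate = 3, open_amp = 200,
                             close_amp = open_amp, rate_jitter = 0.05,
                             amp_jitter = 0.1, pause_fraction = 0.2,
                             tremor_freq = NULL, tremor_amp = 0,
                             noise_gyro = 0, noise_accel = 0,
                             duration = 10, lead_in = 3, lead_out = 3, ...) {
  p <- c(list(cycle_rate = cycle_rate, open_amp = open_amp,
              close_amp = close_amp, rate_jitter = rate_jitter,
              amp_jitter = amp_jitter, pause_fraction = pause_fraction,
              tremor_freq = tremor_freq, tremor_amp = tremor_amp,
              noise_gyro = noise_gyro, noise_accel = noise_accel,
              duration = duration, lead_in = lead_in, lead_out = lead_out),
         list(...))
  if (p$cycle_rate <= 0 || p$open_amp <= 0 || p$close_amp <= 0)
    stopf("rates and amplitudes must be positive")
  if (p$rate_jitter < 0 || p$amp_jitter < 0) stopf("jitters must be >= 0")
  if (p$pause_fraction < 0 || p$pause_fraction >= 1)
    stopf("pause_fraction must be in [0, 1)")
  structure(p, class = "movement_profile")
}

half_sine <- function(amp, dur, sample_rate) {
  n <- max(2L, round(dur * sample_rate))
  amp * sin(pi * seq_len(n) / (n + 1))
}

# raised-cosine lobe: C1-continuous at the rest junctions, so the task
# filters ring far less than with half-sine lobes; integral = amp * dur / 2
raised_cosine <- function(amp, dur, sample_rate) {
  n <- max(2L, round(dur * sample_rate))
  amp * sin(pi * seq_len(n) / (n + 1))^2
}

lobe_fun <- function(profile) {
  if (identical(profile$lobe_shape %||% "half_sine", "raised_cosine"))
    raised_cosine else half_sine
}

# rescale a unit lobe so its time integral equals `area` degrees
scale_to_area <- function(lobe, area, sample_rate) {
  lobe * area / (pracma::trapz(lobe) / sample_rate)
}

# assemble a full recording from the dominant-axis task signal
assemble_recording <- function(omega_task, profile, exercise, side, trial,
                               subject_id, group, sample_rate, seed,
                               truth = list(), raw_sign = 1) {
  p <- profile
  n_lead <- round(p$lead_in * sample_rate)
  n_tail <- round(p$lead_out * sample_rate)
  omega <- c(numeric(n_lead), omega_task, numeric(n_tail))
  n <- length(omega)
  t <- (seq_len(n) - 1) / sample_rate
  if (!is.null(p$tremor_freq) && p$tremor_amp > 0)
    omega <- omega + p$tremor_amp * sin(2 * pi * p$tremor_freq * t)
  gyro <- matrix(rnorm(3 * n, sd = p$noise_gyro), n, 3)
  cfg <- exercise_registry()[[exercise]]
  ax_i <- match(cfg$axis, c("x", "y", "z"))
  gyro[, ax_i] <- gyro[, ax_i] + raw_sign * omega
  theta <- cum_angle(raw_sign * omega, sample_rate) * pi / 180
  accel <- matrix(rnorm(3 * n, sd = p$noise_accel), n, 3)
  at <- p$accel_tremor_amp %||% 0
  if (!is.null(p$tremor_freq) && at > 0)
    accel[, 3] <- accel[, 3] + at * sin(2 * pi * p$tremor_freq * t)
  # tangential linear acceleration of the moving segment (lever arm in m),
  # aligned with gravity so the acceleration magnitude carries the movement
  lever <- p$lever_arm %||% 0
  if (lever > 0) {
    alpha <- c(0, diff(omega)) * sample_rate * pi / 180   # rad/s^2
    accel[, 3] <- accel[, 3] + lever * alpha
  }
  accel[, 1] <- accel[, 1] + G_MS2 * sin(theta)
  accel[, 3] <- accel[, 3] + G_MS2 * cos(theta)
  rec <- imu_recording(subject_id, exercise, side, trial, accel = accel,
                       gyro = gyro, sample_rate = sample_rate,
                       sensor_unit = cfg$sensor_unit, group = group)
  attr(rec, "truth") <- truth
  rec
}

# sign the raw dominant axis must carry so that the pipeline's canonical
# view (task sign + left mirroring) sees a positive-leading signal
raw_sign_for <- function(exercise, side) {
  cfg <- exercise_registry()[[exercise]]
  s <- cfg$sign
  if (isTRUE(cfg$mirror_left) && side == "left") s <- -s
  s
}

#' Generate a biphasic tapping-type recording
#'
#' Builds repetitive open/close cycles of half-sine angular-velocity lobes
#' separated by pauses, with per-cycle rate and amplitude jitter, optional
#' tremor and white noise, a 3 s static lead-in and lead-out, and
#' acceleration consistent with gravity rotated by the integrated angle.
#' Serves THFF, OPCL, PSUP, TTHP, HTTP, HEHE and (with `close_amp` equal
#' to `open_amp` and no pause) the alternating heel-toe task.
#'
#' @param profile A [movement_profile()].
#' @param exercise Task code.
#' @param side `"left"` or `"right"`.
#' @param trial Trial number.
#' @param subject_id Subject identifier.
#' @param group Optional cohort label.
#' @param sample_rate Hz (default 100).
#' @param seed Integer seed; fixed seed gives an identical recording.
#' @return An [imu_recording()] with a `truth` attribute: `n_cycles` and
#'   the per-cycle open-lobe excursions (degrees).
#' @export
gen_tapping <- function(profile, exercise = "THFF", side = "right",
                        trial = 1, subject_id = "sim", group = NULL,
                        sample_rate = 100, seed = 1) {
  p <- profile
  cfg <- exercise_registry()[[exercise]]
  if (length(cfg$thresholds) && p$open_amp < 2 * abs(cfg$thresholds[[1]]))
    warning("open_amp below twice the start threshold; cycles may be missed",
            call. = FALSE)
  with_seed(seed, {
    # draw per-cycle periods and amplitudes until the task time is filled
    Tc <- numeric(0); a_o <- numeric(0); a_c <- numeric(0)
    t_used <- 0
    repeat {
      Ti <- (1 / p$cycle_rate) * exp(rnorm(1, 0, p$rate_jitter))
      if (t_used + Ti > p$duration) break
      Tc <- c(Tc, Ti)
      a_o <- c(a_o, p$open_amp * exp(rnorm(1, 0, p$amp_jitter)))
      a_c <- c(a_c, p$close_amp * exp(rnorm(1, 0, p$amp_jitter)))
      t_used <- t_used + Ti
    }
    n_cycles <- length(Tc)
    if (n_cycles >= 2) {
      # movement termination: the last cycle is optionally slower and
      # reduced in amplitude (profile fields final_dur_factor /
      # final_amp_factor, default 1 = unmodified)
      Tc[n_cycles] <- (p$final_dur_factor %||% 1) * Tc[n_cycles]
      a_o[n_cycles] <- (p$final_amp_factor %||% 1) * a_o[n_cycles]
      a_c[n_cycles] <- (p$final_amp_factor %||% 1) * a_c[n_cycles]
    }
    omega <- numeric(0)
    exc <- numeric(0)
    for (i in seq_len(n_cycles)) {
      d <- (1 - p$pause_fraction) * Tc[i] / 2
      lobe_o <- lobe_fun(p)(a_o[i], d, sample_rate)
      lobe_c <- -lobe_fun(p)(a_c[i], d, sample_rate)
      pause <- numeric(round(p$pause_fraction * Tc[i] * sample_rate))
      omega <- c(omega, lobe_o, lobe_c, pause)
      exc <- c(exc, pracma::trapz(lobe_o) / sample_rate)
    }
    assemble_recording(omega, p, exercise, side, trial, subject_id, group,
                       sample_rate, seed,
                       truth = list(n_cycles = n_cycles, excursions = exc,
                                    rate = p$cycle_rate),
                       raw_sign = raw_sign_for(exercise, side))
  })
}

#' Generate a gait recording (foot module)
#'
#' Per stride the sagittal foot angular velocity follows the gait grammar:
#' a heel-off negative lobe, a positive swing lobe, a heel-strike negative
#' lobe and a foot-flat rest. Lobe areas are set so the dorsiflexion angle
#' range equals `ang_range` and the foot returns flat each stride. The
#' x/z acceleration encodes the corresponding pitch trace.
#'
#' @inheritParams gen_tapping
#' @return An [imu_recording()]; `truth` holds stride count, swing/stance
#'   times and the relative stance.
#' @export
gen_gait <- function(profile, side = "right", trial = 1, subject_id = "sim",
                     group = NULL, sample_rate = 100, seed = 1) {
  p <- profile
  strd_t <- p$stride_time %||% 1.05
  swing <- p$swing_time %||% 0.32
  d1 <- p$heeloff_time %||% 0.16
  d2 <- p$heelstrike_time %||% 0.20
  rng <- p$ang_range %||% 90
  n_str <- p$n_strides %||% 11
  stopifnot(swing + d1 + d2 < strd_t)
  with_seed(seed, {
    omega <- numeric(0)
    strd_times <- numeric(0)
    for (i in seq_len(n_str)) {
      st <- strd_t * exp(rnorm(1, 0, p$rate_jitter))
      r <- rng * exp(rnorm(1, 0, p$amp_jitter))
      a1 <- 0.38 * r; a2 <- 0.62 * r      # heel-off vs swing-return split
      lobe1 <- -scale_to_area(lobe_fun(p)(1, d1, sample_rate), a1, sample_rate)
      lobe2 <- scale_to_area(lobe_fun(p)(1, swing, sample_rate), a1 + a2,
                             sample_rate)
      lobe3 <- -scale_to_area(lobe_fun(p)(1, d2, sample_rate), a2,
                              sample_rate)
      flat <- numeric(round((st - swing - d1 - d2) * sample_rate))
      omega <- c(omega, lobe1, lobe2, lobe3, flat)
      strd_times <- c(strd_times, st)
    }
    p2 <- p; p2$duration <- length(omega) / sample_rate
    assemble_recording(omega, p2, "GTAF", side, trial, subject_id, group,
                       sample_rate, seed,
                       truth = list(n_strides = n_str, swing_time = swing,
                                    stride_times = strd_times,
                                    relative_stance =
                                      100 * (1 - swing / mean(strd_times)),
                                    ang_range = rng))
  })
}

#' Generate a 360-degree rotation recording
#'
#' Turning steps as angular-velocity bursts on the vertical axis (negative
#' for the clockwise right-foot pivot, positive anticlockwise) separated by
#' stance pauses.
#'
#' @inheritParams gen_tapping
#' @return An [imu_recording()]; `truth` holds step count, per-step move
#'   and pause times.
#' @export
gen_rotation <- function(profile, side = "right", trial = 1,
                         subject_id = "sim", group = NULL,
                         sample_rate = 100, seed = 1) {
  p <- profile
  n_steps <- p$n_steps %||% 4
  move <- p$move_time %||% 0.45
  pause <- p$pause_time %||% 0.25
  ang <- p$step_angle %||% (360 / n_steps)
  dir_sign <- if (side == "right") -1 else 1   # clockwise on the right foot
  with_seed(seed, {
    omega <- numeric(0)
    for (i in seq_len(n_steps)) {
      mv <- move * exp(rnorm(1, 0, p$rate_jitter))
      a <- ang * exp(rnorm(1, 0, p$amp_jitter))
      lobe <- scale_to_area(lobe_fun(p)(1, mv, sample_rate), a, sample_rate)
      omega <- c(omega, lobe,
                 if (i < n_steps) numeric(round(pause * sample_rate)))
    }
    p2 <- p; p2$duration <- length(omega) / sample_rate
    assemble_recording(dir_sign * omega, p2, "ROTA", side, trial,
                       subject_id, group, sample_rate, seed,
                       truth = list(n_steps = n_steps, move_time = move,
                                    pause_time = pause),
                       raw_sign = 1)
  })
}

#' Generate an arm-swing recording (wrist module during gait)
#'
#' Continuous sinusoidal swing at the gait cadence with amplitude and rate
#' jitter; serves GTAH.
#'
#' @inheritParams gen_tapping
#' @return An [imu_recording()]; `truth` holds the swing rate and count.
#' @export
gen_arm_swing <- function(profile, side = "right", trial = 1,
                          subject_id = "sim", group = NULL,
                          sample_rate = 100, seed = 1) {
  p <- profile
  with_seed(seed, {
    n <- round(p$duration * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    # slowly wandering amplitude models stride-to-stride variability
    k <- pmax(1L, ceiling(p$cycle_rate * t))
    amps <- p$open_amp * exp(rnorm(ceiling(p$cycle_rate * p$duration) + 1,
                                   0, p$amp_jitter))
    omega <- amps[k] * sin(2 * pi * p$cycle_rate * t)
    assemble_recording(omega, p, "GTAH", side, trial, subject_id, group,
                       sample_rate, seed,
                       truth = list(rate = p$cycle_rate,
                                    n_swings = floor(p$duration * p$cycle_rate)),
                       raw_sign = raw_sign_for("GTAH", side))
  })
}

#' Generate a tremor-task recording (HRST or POST)
#'
#' A static posture: the dominant gyro axis carries an optional tremor
#' sinusoid (plus a second component, e.g. a physiological 8–12 Hz peak)
#' and white noise; acceleration is gravity plus a small tremor-coupled
#' oscillation and noise.
#'
#' @inheritParams gen_tapping
#' @return An [imu_recording()]; `truth` holds the tremor parameters.
#' @export
gen_tremor <- function(profile, exercise = "HRST", side = "right",
                       trial = 1, subject_id = "sim", group = NULL,
                       sample_rate = 100, seed = 1) {
  p <- profile
  with_seed(seed, {
    n <- round((p$lead_in + p$duration + p$lead_out) * sample_rate)
    t <- (seq_len(n) - 1) / sample_rate
    cfg <- exercise_registry()[[exercise]]
    gyro <- matrix(rnorm(3 * n, sd = p$noise_gyro), n, 3)
    ax_i <- match(cfg$axis, c("x", "y", "z"))
    sig <- numeric(n)
    if (!is.null(p$tremor_freq) && p$tremor_amp > 0)
      sig <- sig + p$tremor_amp * sin(2 * pi * p$tremor_freq * t)
    if (!is.null(p$tremor2_freq) && (p$tremor2_amp %||% 0) > 0)
      sig <- sig + p$tremor2_amp * sin(2 * pi * p$tremor2_freq * t + 1)
    gyro[, ax_i] <- gyro[, ax_i] + sig
    accel <- matrix(rnorm(3 * n, sd = p$noise_accel), n, 3)
    at <- p$accel_tremor_amp %||% 0
    if (!is.null(p$tremor_freq) && at > 0)
      accel[, 3] <- accel[, 3] + at * sin(2 * pi * p$tremor_freq * t)
    if (!is.null(p$tremor2_freq) && (p$accel_tremor2_amp %||% 0) > 0)
      accel[, 3] <- accel[, 3] +
        p$accel_tremor2_amp * sin(2 * pi * p$tremor2_freq * t + 1)
    accel[, 3] <- accel[, 3] + G_MS2
    rec <- imu_recording(subject_id, exercise, side, trial, accel = accel,
                         gyro = gyro, sample_rate = sample_rate,
                         sensor_unit = cfg$sensor_unit, group = group)
    attr(rec, "truth") <- list(tremor_freq = p$tremor_freq,
                               tremor_amp = p$tremor_amp)
    rec
  })
}

#' Generate any task's recording
#'
#' Dispatches to the task-appropriate generator.
#'
#' @inheritParams gen_tapping
#' @export
gen_recording <- function(profile, exercise, side = "right", trial = 1,
                          subject_id = "sim", group = NULL,
                          sample_rate = 100, seed = 1) {
  kind <- exercise_registry()[[exercise]]$segmentation_kind
  switch(kind,
    tapping_biphasic = ,
    heel_toe = gen_tapping(profile, exercise, side, trial, subject_id,
                           group, sample_rate, seed),
    gait = gen_gait(profile, side, trial, subject_id, group, sample_rate,
                    seed),
    rotation = gen_rotation(profile, side, trial, subject_id, group,
                            sample_rate, seed),
    arm_swing = gen_arm_swing(profile, side, trial, subject_id, group,
                              sample_rate, seed),
    static = gen_tremor(profile, exercise, side, trial, subject_id, group,
                        sample_rate, seed))
}

#' Default task profiles for the two cohorts
#'
#' The generator's study conditions: per-task movement profiles for an
#' HC-like regime (faster, wider, steadier movements; negligible tremor)
#' and a PD-like regime (bradykinetic rates and amplitudes, raised
#' cycle-to-cycle variability, a 5 Hz-band rest tremor and reduced arm
#' swing). The numbers are chosen to reproduce the typical feature scales
#' of mild-to-moderate cohorts (e.g. pronation-supination excursions near
#' 150 deg HC vs 110 deg PD, gait cadence near 1 Hz, dorsiflexion range
#' near 90 deg HC vs 75 deg PD); they are illustrative regimes, not fits
#' to any clinical dataset.
#'
#' @param group `"HC"` or `"PD"`.
#' @return Named list of [movement_profile()]s, one per task code.
#' @export
default_profiles <- function(group = c("HC", "PD")) {
  group <- match.arg(group)
  rc <- list(lobe_shape = "raised_cosine", lever_arm = 0.02,
             final_dur_factor = 2.2, final_amp_factor = 0.35)
  hc <- list(
    THFF = movement_profile(4.5, 550, rate_jitter = 0.06, amp_jitter = 0.12,
                            noise_gyro = 2, noise_accel = 0.05),
    OPCL = movement_profile(3.5, 1100, rate_jitter = 0.05, amp_jitter = 0.10,
                            noise_gyro = 2, noise_accel = 0.05),
    PSUP = movement_profile(2.3, 1150, rate_jitter = 0.05, amp_jitter = 0.08,
                            noise_gyro = 2, noise_accel = 0.05),
    TTHP = movement_profile(3.7, 160, rate_jitter = 0.08, amp_jitter = 0.15,
                            noise_gyro = 1.5, noise_accel = 0.05),
    HTTP = movement_profile(3.9, 170, rate_jitter = 0.08, amp_jitter = 0.15,
                            noise_gyro = 1.5, noise_accel = 0.05),
    HETO = movement_profile(1.6, 185, rate_jitter = 0.07, amp_jitter = 0.12,
                            pause_fraction = 0, noise_gyro = 1.5,
                            noise_accel = 0.05),
    HEHE = movement_profile(3.9, 320, rate_jitter = 0.06, amp_jitter = 0.10,
                            noise_gyro = 1.5, noise_accel = 0.08,
                            lever_arm = 0.04),
    GTAF = movement_profile(1, 200, rate_jitter = 0.03, amp_jitter = 0.05,
                            noise_gyro = 1.5, noise_accel = 0.05,
                            stride_time = 1.06, swing_time = 0.32,
                            ang_range = 92, n_strides = 11),
    ROTA = movement_profile(1, 200, rate_jitter = 0.08, amp_jitter = 0.10,
                            noise_gyro = 1.5, noise_accel = 0.05,
                            n_steps = 4, move_time = 0.42, pause_time = 0.22),
    GTAH = movement_profile(0.95, 220, rate_jitter = 0.04, amp_jitter = 0.10,
                            duration = 12, noise_gyro = 1.5,
                            noise_accel = 0.05),
    HRST = movement_profile(1, 1, tremor_freq = 8.5, tremor_amp = 0.8,
                            accel_tremor_amp = 0.04, noise_gyro = 1.0,
                            noise_accel = 0.03),
    POST = movement_profile(1, 1, tremor_freq = 9.5, tremor_amp = 2.5,
                            accel_tremor_amp = 0.25, noise_gyro = 1.2,
                            noise_accel = 0.05)
  )
  hc <- lapply(hc, function(p) {
    for (nm in names(rc)) if (is.null(p[[nm]])) p[[nm]] <- rc[[nm]]
    p
  })
  if (group == "HC") return(hc)
  pd <- hc
  slow <- function(p, rate_f, amp_f, jit_f = 2) {
    p$cycle_rate <- p$cycle_rate * rate_f
    p$open_amp <- p$open_amp * amp_f
    p$close_amp <- p$close_amp * amp_f
    p$rate_jitter <- p$rate_jitter * jit_f
    p$amp_jitter <- p$amp_jitter * jit_f
    p
  }
  pd$THFF <- slow(pd$THFF, 0.68, 0.9)
  pd$OPCL <- slow(pd$OPCL, 0.62, 0.7)
  pd$PSUP <- slow(pd$PSUP, 0.66, 0.5)
  pd$TTHP <- slow(pd$TTHP, 0.82, 0.8)
  pd$HTTP <- slow(pd$HTTP, 0.81, 0.6)
  pd$HETO <- slow(pd$HETO, 0.92, 0.58)
  pd$HEHE <- slow(pd$HEHE, 0.92, 0.38)
  pd$GTAF$stride_time <- 1.08
  pd$GTAF$n_strides <- 13
  pd$GTAF$ang_range <- 74
  pd$GTAF$rate_jitter <- 0.05
  pd$ROTA$n_steps <- 5
  pd$ROTA$move_time <- 0.48
  pd$ROTA$pause_time <- 0.30
  pd$GTAH <- slow(pd$GTAH, 1.0, 0.55)
  pd$HRST$tremor_freq <- 5.2
  pd$HRST$tremor_amp <- 4.5
  pd$HRST$accel_tremor_amp <- 0.08
  pd$POST$tremor_freq <- 6
  pd$POST$tremor_amp <- 2.5
  pd$POST$tremor2_freq <- 9.5
  pd$POST$tremor2_amp <- 1.0
  pd$POST$accel_tremor_amp <- 0.3
  pd
}

#' Cohort specification for the synthetic generator
#'
#' @param n_hc,n_pd Subjects per group.
#' @param seed Integer master seed; the whole cohort is reproducible from it.
#' @param between_subject_sd Fractional SD of per-subject rate/amplitude
#'   multipliers (`c(HC =, PD =)`).
#' @param asymmetry Amplitude/rate multiplier applied to each PD subject's
#'   more affected side (unilateral onset; default 0.85).
#' @param exercises Task codes to generate (default all).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_hc = 40, n_pd = 40, seed = 1,
                        between_subject_sd = c(HC = 0.08, PD = 0.12),
                        asymmetry = 0.85,
                        exercises = setdiff(EXERCISES, character(0))) {
  structure(list(n_hc = n_hc, n_pd = n_pd, seed = seed,
                 between_subject_sd = between_subject_sd,
                 asymmetry = asymmetry, exercises = exercises,
                 profiles = list(HC = default_profiles("HC"),
                                 PD = default_profiles("PD"))),
            class = "cohort_spec")
}

#' Generate a full synthetic cohort
#'
#' For every subject, task, side and trial (2 trials each) a recording is
#' generated from the group's profile, modulated by a per-subject severity
#' multiplier and, for PD subjects, a lateral asymmetry factor on a
#' randomly chosen side. Deterministic given the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (list of [imu_recording()]),
#'   `meta` (subject_id/group data.frame) and `truth` (per-subject
#'   generating multipliers).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  subjects <- data.frame(
    subject_id = c(sprintf("HC%03d", seq_len(spec$n_hc)),
                   sprintf("PD%03d", seq_len(spec$n_pd))),
    group = rep(c("HC", "PD"), c(spec$n_hc, spec$n_pd)))
  truth <- list()
  recordings <- vector("list", nrow(subjects) * length(spec$exercises) * 4L)
  ri <- 0L
  for (si in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[si]; grp <- subjects$group[si]
    sseed <- child_seed(spec$seed, sid)
    subj <- with_seed(sseed, {
      list(sev = exp(rnorm(1, 0, spec$between_subject_sd[[grp]])),
           bad_side = sample(SIDES, 1))
    })
    truth[[sid]] <- subj
    for (ex in spec$exercises) {
      prof0 <- spec$profiles[[grp]][[ex]]
      for (side in SIDES) {
        f <- subj$sev
        if (grp == "PD" && side == subj$bad_side) f <- f * spec$asymmetry
        p <- prof0
        p$cycle_rate <- p$cycle_rate * f
        p$open_amp <- p$open_amp * f
        p$close_amp <- p$close_amp * f
        if (!is.null(p$ang_range)) p$ang_range <- p$ang_range * f
        p$tremor_amp <- p$tremor_amp / f          # tremor worsens with severity
        for (tr in 1:2) {
          ri <- ri + 1L
          recordings[[ri]] <- gen_recording(
            p, ex, side, tr, sid, grp,
            seed = child_seed(spec$seed, sid, ex, side, tr))
        }
      }
    }
  }
  list(recordings = recordings[seq_len(ri)], meta = subjects, truth = truth)
}
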