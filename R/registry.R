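#' Per-exercise analysis configuration
#'
#' Returns the registry of the twelve analysis tasks: the dominant signal
#' (sensor unit, gyro/accel, axis), filter cutoffs, segmentation grammar and
#' the detection thresholds, all in deg/s. Threshold values:
#'
#' * `THFF`: movement start `TH_TF` = 15, end `TH_TFv` = -3
#' * `OPCL`: `TH_OC` = 30, `TH_OCv` = -3
#' * `PSUP`: `TH_PS` = 50, `TH_PSv` = -5
#' * `GTAH`: swing start `TH_GT` = 10, turn bound 2
#' * `GTAF`: heel-off `TH_HO` = 50, foot-flat `TH_FF` = 3
#' * `ROTA`: `TH_RO` = 50, `TH_ROv` = 5
#' * `TTHP`/`HEHE`: toe-off `TH_TO` = 10, `TH_FF` = 3
#' * `HTTP`: heel-off `TH_HO` = 10 (negative lobe leads), `TH_FF` = 3
#' * `HETO`: `TH_TO` = `TH_HO` = 20
#'
#' Movement tasks are low-passed at 5 Hz (gait tasks at 3 Hz); the tremor
#' tasks HRST/POST are low-passed at 15/20 Hz with an additional 0.5 Hz
#' high-pass.
#'
#' `sign` is -1 for tasks whose leading lobe is negative on the dominant axis
#' (HTTP, GTAF heel-off, clockwise ROTA) so one segmentation state machine
#' serves all tapping-type grammars. `mirror_left` marks the tasks whose sign
#' convention flips with body side (PSUP, GTAH, ROTA).
#'
#' @return Named list of `exercise_config` objects, one per task code.
#' @examples
#' exercise_registry()$THFF$thresholds[["TH_TF"]]  # 15 deg/s
#' @export
exercise_registry <- function() {
  cfg <- function(exercise, unit, signal, axis, lowpass, highpass = NA_real_,
                  kind, thresholds, sign = 1, mirror_left = FALSE,
                  static_window = NULL, prefix, condition) {
    structure(list(exercise = exercise, sensor_unit = unit, signal = signal,
                   axis = axis, lowpass_cutoff = lowpass,
                   highpass_cutoff = highpass, segmentation_kind = kind,
                   thresholds = thresholds, sign = sign,
                   mirror_left = mirror_left, static_window = static_window,
                   prefix = prefix, condition = condition),
              class = "exercise_config")
  }
  list(
    THFF = cfg("THFF", "index", "gyro", "y", 5, kind = "tapping_biphasic",
               thresholds = c(TH_TF = 15, TH_TFv = -3),
               prefix = "TF", condition = "HANDS"),
    OPCL = cfg("OPCL", "index", "gyro", "y", 5, kind = "tapping_biphasic",
               thresholds = c(TH_OC = 30, TH_OCv = -3),
               prefix = "OC", condition = "HANDS"),
    PSUP = cfg("PSUP", "wrist", "gyro", "x", 5, kind = "tapping_biphasic",
               thresholds = c(TH_PS = 50, TH_PSv = -5), mirror_left = TRUE,
               prefix = "PS", condition = "HANDS"),
    HRST = cfg("HRST", "wrist", "gyro", "y", 15, highpass = 0.5, kind = "static",
               thresholds = c(), static_window = c(3, 13),
               prefix = "RT", condition = "HANDS"),
    POST = cfg("POST", "wrist", "gyro", "y", 20, highpass = 0.5, kind = "static",
               thresholds = c(), static_window = c(3, 13),
               prefix = "PT", condition = "HANDS"),
    TTHP = cfg("TTHP", "foot", "gyro", "y", 5, kind = "tapping_biphasic",
               thresholds = c(TH_TO = 10, TH_FF = 3),
               prefix = "TT", condition = "FEET"),
    HEHE = cfg("HEHE", "foot", "gyro", "y", 5, kind = "tapping_biphasic",
               thresholds = c(TH_TO = 10, TH_FF = 3),
               static_window = c(3, 13),
               prefix = "HE", condition = "FEET"),
    HTTP = cfg("HTTP", "foot", "gyro", "y", 5, kind = "tapping_biphasic",
               thresholds = c(TH_HO = 10, TH_FF = 3), sign = -1,
               prefix = "HH", condition = "FEET"),
    HETO = cfg("HETO", "foot", "gyro", "y", 5, kind = "heel_toe",
               thresholds = c(TH_TO = 20, TH_HO = 20),
               prefix = "HT", condition = "FEET"),
    ROTA = cfg("ROTA", "foot", "gyro", "z", 5, kind = "rotation",
               thresholds = c(TH_RO = 50, TH_ROv = 5),
               prefix = "RO", condition = "FEET"),
    GTAF = cfg("GTAF", "foot", "gyro", "y", 3, kind = "gait",
               thresholds = c(TH_HO = 50, TH_FF = 3),
               prefix = "GT", condition = "FEET"),
    GTAH = cfg("GTAH", "wrist", "gyro", "z", 3, kind = "arm_swing",
               thresholds = c(TH_GT = 10, turn_bound = 2), mirror_left = TRUE,
               prefix = "GT", condition = "HANDS")
  )
}

#' @export
print.exercise_config <- function(x, ...) {
  th <- if (length(x$thresholds))
    paste(sprintf("%s=%g", names(x$thresholds), x$thresholds), collapse = ", ")
  else "none"
  cat(sprintf("<exercise_config> %s: %s %s omega_%s | LP %g Hz%s | %s | thresholds: %s\n",
              x$exercise, x$sensor_unit, x$signal, x$axis, x$lowpass_cutoff,
              if (is.na(x$highpass_cutoff)) "" else sprintf(" + HP %g Hz", x$highpass_cutoff),
              x$segmentation_kind, th))
  invisible(x)
}

# Required threshold names by segmentation grammar (used by validation tests).
required_thresholds <- function(kind) {
  switch(kind,
    tapping_biphasic = c("start", "end"),   # positional: first=start, second=end
    heel_toe = c("TH_TO", "TH_HO"),
    gait = c("TH_HO", "TH_FF"),
    rotation = c("TH_RO", "TH_ROv"),
    arm_swing = c("TH_GT", "turn_bound"),
    static = character(0))
}

# Dominant-axis angular velocity with task sign convention applied:
# the configured task sign, and left-side mirroring for the side-dependent
# tasks (PSUP, GTAH, ROTA).
dominant_signal <- function(rec, cfg) {
  m <- rec[[cfg$signal]]
  s <- m[, cfg$axis]
  sgn <- cfg$sign
  if (isTRUE(cfg$mirror_left) && rec$side == "left") sgn <- -sgn
  sgn * s
}
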