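#' Exercise codes of the motor-examination protocol
#'
#' Eleven exercises are acquired per subject and side; the gait trial is
#' analysed twice (foot module, `GTAF`, and arm-swing from the wrist module,
#' `GTAH`), giving twelve analysis tasks.
#'
#' @format Character vector of the twelve task codes.
#' @export
EXERCISES <- c("THFF", "OPCL", "PSUP", "HRST", "POST",
               "TTHP", "HEHE", "HTTP", "HETO", "ROTA", "GTAF", "GTAH")

SIDES <- c("left", "right")
SENSOR_UNITS <- c("wrist", "thumb", "index", "middle", "foot")
GROUPS <- c("HC", "PD")

#' Construct a validated inertial recording
#'
#' One trial of synchronised 6-axis inertial data for one subject, exercise
#' and body side: triaxial acceleration in m/s^2 (gravity included) and
#' triaxial angular rate in deg/s, sampled at `sample_rate` Hz (100 Hz in the
#' standard protocol).
#'
#' @param subject_id Subject identifier (character scalar).
#' @param exercise One of [EXERCISES].
#' @param side `"left"` or `"right"`.
#' @param trial Trial number, 1 or 2.
#' @param accel Numeric matrix, n x 3, acceleration in m/s^2 (columns x, y, z).
#' @param gyro Numeric matrix, n x 3, angular rate in deg/s (columns x, y, z).
#' @param sample_rate Sampling frequency in Hz (> 0).
#' @param time Optional time vector in seconds; defaults to
#'   `(0:(n-1))/sample_rate` and must be strictly increasing with spacing
#'   `1/sample_rate` (tolerance 1e-9 s).
#' @param sensor_unit Sensing module the recording comes from, one of
#'   `"wrist"`, `"thumb"`, `"index"`, `"middle"`, `"foot"`.
#' @param group Optional cohort label, `"HC"` or `"PD"`.
#'
#' @return An object of class `imu_recording`.
#' @examples
#' r <- imu_recording("s1", "THFF", "right", 1,
#'                    accel = matrix(0, 100, 3), gyro = matrix(0, 100, 3))
#' r
#' @export
imu_recording <- function(subject_id, exercise, side, trial,
                          accel, gyro, sample_rate = 100,
                          time = NULL, sensor_unit = NULL, group = NULL) {
  exercise <- match.arg(exercise, EXERCISES)
  side <- match.arg(side, SIDES)
  if (!is_scalar_number(sample_rate) || sample_rate <= 0)
    stopf("sample_rate must be a positive number")
  trial <- as.integer(trial)
  if (!trial %in% c(1L, 2L)) stopf("trial must be 1 or 2")
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (ncol(accel) != 3L || ncol(gyro) != 3L)
    stopf("accel and gyro must have 3 columns (x, y, z)")
  n <- nrow(accel)
  if (n < 1L || nrow(gyro) != n)
    stopf("accel and gyro must have equal length >= 1")
  if (is.null(time)) time <- (seq_len(n) - 1) / sample_rate
  if (length(time) != n)
    stopf("time must match the number of samples")
  if (n > 1L) {
    dt <- diff(time)
    if (any(dt <= 0)) stopf("time must be strictly increasing")
    if (any(abs(dt - 1 / sample_rate) > 1e-9))
      stopf("time spacing must equal 1/sample_rate within 1e-9 s")
  }
  if (is.null(sensor_unit)) sensor_unit <- default_sensor_unit(exercise)
  sensor_unit <- match.arg(sensor_unit, SENSOR_UNITS)
  if (!is.null(group)) group <- match.arg(group, GROUPS)
  colnames(accel) <- colnames(gyro) <- c("x", "y", "z")
  structure(list(
    subject_id = as.character(subject_id), exercise = exercise, side = side,
    trial = trial, sample_rate = sample_rate, time = as.numeric(time),
    accel = accel, gyro = gyro, sensor_unit = sensor_unit, group = group
  ), class = "imu_recording")
}

default_sensor_unit <- function(exercise) {
  switch(exercise,
    THFF = "index", OPCL = "index",
    PSUP = "wrist", HRST = "wrist", POST = "wrist", GTAH = "wrist",
    "foot")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s | %s %s trial %d | %d samples @ %g Hz (%.2f s)%s\n",
              x$subject_id, x$exercise, x$side, x$trial,
              length(x$time), x$sample_rate,
              length(x$time) / x$sample_rate,
              if (is.null(x$group)) "" else paste0(" | ", x$group)))
  invisible(x)
}

#' @export
plot.imu_recording <- function(x, what = c("gyro", "accel"), ...) {
  what <- match.arg(what)
  m <- x[[what]]
  ylab <- if (what == "gyro") "angular rate [deg/s]" else "acceleration [m/s²]"
  plot(x$time, m[, 1], type = "l", xlab = "time [s]", ylab = ylab,
       ylim = range(m), main = sprintf("%s %s (%s)", x$exercise, x$side, what), ...)
  lines(x$time, m[, 2], col = 2)
  lines(x$time, m[, 3], col = 4)
  legend("topright", legend = c("x", "y", "z"), col = c(1, 2, 4), lty = 1, bty = "n")
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `imu_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$time)
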