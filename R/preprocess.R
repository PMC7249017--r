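#' Apply a Butterworth filter to a signal
#'
#' Fourth-order (by default) digital Butterworth filtering, zero-phase by
#' default: the signal is padded with an odd (point-reflected) extension of
#' `3 * order` samples, filtered forward and backward with steady-state
#' initial conditions, and trimmed. Zero-phase filtering squares the
#' magnitude response and cancels group delay, so detected event times are
#' not biased by filter lag.
#'
#' @param x Numeric signal.
#' @param sample_rate Sampling frequency in Hz.
#' @param cutoff Cutoff frequency in Hz, must be below the Nyquist frequency.
#' @param kind `"low"` or `"high"`.
#' @param order Filter order (even, >= 2; default 4).
#' @param zero_phase Forward-backward filtering (default `TRUE`).
#' @return Filtered signal, same length as `x`. Low-pass DC gain is 1 to
#'   within 1e-6.
#' @export
butter_filter <- function(x, sample_rate, cutoff, kind = c("low", "high"),
                          order = 4, zero_phase = TRUE) {
  kind <- match.arg(kind)
  if (!is_scalar_number(cutoff) || cutoff <= 0 || cutoff >= sample_rate / 2)
    stopf("cutoff must lie in (0, sample_rate/2)")
  if (order < 2 || order %% 2 != 0) stopf("order must be even and >= 2")
  if (length(x) <= 3 * order)
    stopf("signal too short: need more than %d samples", 3 * order)
  co <- butter_coefs(order, cutoff / (sample_rate / 2), kind)
  pad <- 3L * order
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[length(x)] - rev(x[(length(x) - pad):(length(x) - 1)]))
  y <- lfilter_ss(co$b, co$a, xp, co$zi)
  if (zero_phase) y <- rev(lfilter_ss(co$b, co$a, rev(y), co$zi))
  y[(pad + 1):(pad + length(x))]
}

# coefficient + initial-state cache (designs are reused thousands of times)
.butter_cache <- new.env(parent = emptyenv())
butter_coefs <- function(order, W, kind) {
  key <- paste(order, format(W, digits = 12), kind)
  co <- .butter_cache[[key]]
  if (is.null(co)) {
    bf <- signal::butter(order, W, type = kind)
    co <- list(b = bf$b, a = bf$a, zi = lfilter_zi(bf$b, bf$a))
    .butter_cache[[key]] <- co
  }
  co
}

# steady-state (step-response) initial filter state, as in the standard
# lfilter_zi construction: solve (I - A^T) zi = B for the companion form
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  A <- rbind(-a[2:n], cbind(diag(n - 2), numeric(n - 2)))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# IIR filter starting from the step steady state for x[1], removing the
# start-up transient that zero-state filtering leaves on non-zero-mean input
lfilter_ss <- function(b, a, x, zi = lfilter_zi(b, a)) {
  df2t_filter(b / a[1], a / a[1], x, zi * x[1])
}

# Exact magnitude response of the digital Butterworth used above, |H(e^{-jw})|,
# evaluated from the coefficient polynomials. Squared when zero-phase.
butter_gain <- function(sample_rate, cutoff, kind = "low", order = 4,
                        freq, zero_phase = TRUE) {
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = kind)
  w <- 2 * pi * freq / sample_rate
  z <- exp(-1i * w)
  H <- sapply(seq_along(w), function(i) {
    sum(bf$b * z[i]^(seq_along(bf$b) - 1)) /
      sum(bf$a * z[i]^(seq_along(bf$a) - 1))
  })
  g <- Mod(H)
  if (zero_phase) g^2 else g
}

#' Condition a recording with its task-specific filters
#'
#' Movement tasks: all six channels low-passed at the task cutoff (5 Hz; 3 Hz
#' for the gait tasks GTAF/GTAH) to remove high-frequency noise and the
#' tremor band. Tremor tasks (HRST 15 Hz, POST 20 Hz low-pass) additionally
#' pass a 0.5 Hz fourth-order high-pass cascade that removes the continuous
#' component. The unfiltered channels are retained in `$raw` because the
#' acceleration-integral feature (IAV) and the tremor acceleration-magnitude
#' spectra are computed from gravity-inclusive signals.
#'
#' @param rec An [imu_recording()].
#' @param cfg Matching `exercise_config`; defaults to the registry entry for
#'   `rec$exercise`.
#' @param channels `"all"` (default) filters every channel; `"needed"`
#'   filters only the channels the task's features read (the three
#'   acceleration axes and the dominant gyro axis), leaving the others raw.
#' @return The recording with filtered `accel`/`gyro`, a `$raw` element
#'   (original matrices) and `$conditioned = TRUE`.
#' @export
condition_recording <- function(rec, cfg = exercise_registry()[[rec$exercise]],
                                channels = c("all", "needed")) {
  stopifnot(inherits(rec, "imu_recording"))
  channels <- match.arg(channels)
  if (cfg$exercise != rec$exercise)
    stopf("config is for %s but recording is %s", cfg$exercise, rec$exercise)
  fs <- rec$sample_rate
  filt <- function(col) {
    y <- butter_filter(col, fs, cfg$lowpass_cutoff, "low")
    if (!is.na(cfg$highpass_cutoff))
      y <- butter_filter(y, fs, cfg$highpass_cutoff, "high")
    y
  }
  out <- rec
  out$raw <- list(accel = rec$accel, gyro = rec$gyro)
  for (j in 1:3) out$accel[, j] <- filt(rec$accel[, j])
  gyro_cols <- if (channels == "all") 1:3
               else match(cfg$axis, c("x", "y", "z"))
  for (j in gyro_cols) out$gyro[, j] <- filt(rec$gyro[, j])
  out$conditioned <- TRUE
  out
}
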