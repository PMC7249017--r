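#' Welch power spectral density estimate
#'
#' One-sided PSD by Welch's method: the de-meaned signal is split into
#' `segment_length`-sample segments with `overlap` fractional overlap, each
#' segment is Hann-tapered, periodograms are scaled to density
#' (signal-units^2 per Hz) and averaged. The band integral of the estimate
#' satisfies Parseval against the signal's mean square within 2%. A plain
#' periodogram (single full-length segment) is available via
#' `method = "periodogram"`.
#'
#' @param x Numeric signal (>= 256 samples).
#' @param sample_rate Hz.
#' @param segment_length Samples per Welch segment (default 256).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param method `"welch"` or `"periodogram"`.
#' @return An object of class `psd_estimate`: `frequencies` (Hz),
#'   `psd` (units^2/Hz), `df`, `total_power` and `estimator_params`.
#' @export
estimate_psd <- function(x, sample_rate, segment_length = 256, overlap = 0.5,
                         method = c("welch", "periodogram")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 256) stopf("signal too short for PSD estimation (need >= 256 samples)")
  if (method == "periodogram") { segment_length <- n; overlap <- 0 }
  nseg <- min(segment_length, n)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hann
  U <- sum(w^2)
  x <- x - mean(x)
  nf <- nseg %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (sample_rate * U)
  }
  psd <- acc / length(starts)
  psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]   # one-sided doubling
  freqs <- (seq_len(nf) - 1) * sample_rate / nseg
  df <- sample_rate / nseg
  structure(list(frequencies = freqs, psd = psd, df = df,
                 total_power = sum(psd) * df,
                 estimator_params = list(segment_length = nseg,
                                         overlap = overlap, taper = "hann",
                                         n_segments = length(starts))),
            class = "psd_estimate")
}

#' @export
print.psd_estimate <- function(x, ...) {
  cat(sprintf("<psd_estimate> %d bins, df = %.3g Hz, total power = %.4g (%d Welch segments)\n",
              length(x$frequencies), x$df, x$total_power,
              x$estimator_params$n_segments))
  invisible(x)
}

#' @export
plot.psd_estimate <- function(x, ...) {
  plot(x$frequencies, x$psd, type = "l", xlab = "frequency [Hz]",
       ylab = "PSD [units²/Hz]", ...)
  invisible(x)
}

# band power with half-open bins [lo, hi) so that band fractions over a
# partition of the reference band sum exactly to the reference power
band_power <- function(est, band) {
  sel <- est$frequencies >= band[1] & est$frequencies < band[2]
  sum(est$psd[sel]) * est$df
}

#' Frequency of the spectral peak in a search band
#'
#' @param est A `psd_estimate`.
#' @param search_band `c(lo, hi)` Hz.
#' @return Peak frequency in Hz (ties broken to the lowest frequency).
#' @export
fundamental_frequency <- function(est, search_band) {
  sel <- which(est$frequencies >= search_band[1] &
               est$frequencies <= search_band[2])
  if (!length(sel)) return(NA_real_)
  est$frequencies[sel[which.max(est$psd[sel])]]
}

#' Percentage of spectral power in a frequency band
#'
#' `100 * P[band] / P[reference_band]` with half-open band membership, so
#' fractions over a partition of the reference band sum to 100%.
#'
#' @param est A `psd_estimate`.
#' @param band `c(lo, hi)` Hz, contained in `reference_band`.
#' @param reference_band `c(lo, hi)` Hz denominator band.
#' @return Percent, or `NA` when the reference power is zero.
#' @export
band_power_fraction <- function(est, band, reference_band) {
  pref <- band_power(est, reference_band)
  if (!is.finite(pref) || pref <= 0) return(NA_real_)
  100 * band_power(est, band) / pref
}

# average power = band power / band width (units^2); reported over the
# reference band of the task
average_power <- function(est, band) band_power(est, band) / diff(band)

#' Tremor-task spectral features (rest and postural tremor)
#'
#' Computed over the static 3–13 s window. The `A` variants come from the
#' Euclidean norm of the raw acceleration passed through the task's
#' low-pass/high-pass cascade (the norm linearises gravity away after the
#' 0.5 Hz high-pass and is orientation-invariant); the `G` variants from
#' the conditioned dominant gyro axis. Features: average PSD power over the
#' reference band `[0.5, lowpass cutoff]` Hz, fundamental (peak) frequency,
#' percentage power in the parkinsonian tremor band 3.5–7.5 Hz (`Perc1`)
#' and — for postural tremor only — in the physiological band 8–12 Hz
#' (`Perc2`), plus the IAV of the low-pass-only acceleration (gravity
#' included).
#'
#' @param rec A raw [imu_recording()] of exercise HRST or POST.
#' @param cfg Matching `exercise_config`.
#' @return Named list of 7 (HRST) or 9 (POST) parameters.
#' @export
tremor_task_features <- function(rec, cfg = exercise_registry()[[rec$exercise]]) {
  stopifnot(rec$exercise %in% c("HRST", "POST"))
  fs <- rec$sample_rate
  win <- static_window(rec)
  i1 <- floor(win[1] * fs) + 1L
  i2 <- min(n_samples(rec), floor(win[2] * fs) + 1L)
  raw <- rec$raw %||% list(accel = rec$accel, gyro = rec$gyro)
  cascade <- function(x) {
    y <- butter_filter(x, fs, cfg$lowpass_cutoff, "low")
    butter_filter(y, fs, cfg$highpass_cutoff, "high")
  }
  a_sig <- cascade(sqrt(rowSums(raw$accel^2)))[i1:i2]
  g_sig <- cascade(raw$gyro[, cfg$axis])[i1:i2]
  ref <- c(0.5, cfg$lowpass_cutoff)
  est_a <- estimate_psd(a_sig, fs)
  est_g <- estimate_psd(g_sig, fs)
  accel_lp <- apply(raw$accel, 2, butter_filter, sample_rate = fs,
                    cutoff = cfg$lowpass_cutoff, kind = "low")
  out <- list(
    PwrA = average_power(est_a, ref),
    PwrG = average_power(est_g, ref),
    FreqA = fundamental_frequency(est_a, ref),
    FreqG = fundamental_frequency(est_g, ref),
    Perc1A = band_power_fraction(est_a, c(3.5, 7.5), ref),
    Perc1G = band_power_fraction(est_g, c(3.5, 7.5), ref)
  )
  if (rec$exercise == "POST") {
    out$Perc2A <- band_power_fraction(est_a, c(8, 12), ref)
    out$Perc2G <- band_power_fraction(est_g, c(8, 12), ref)
  }
  out$IAV <- iav(accel_lp, fs, win)
  out[c(names(out)[names(out) != "IAV"], "IAV")]
}

#' Leg-agility (heel tapping) spectral features
#'
#' The leg-agility task is analysed in the frequency domain only, over the
#' 3–13 s window: average power and fundamental frequency of the
#' acceleration-magnitude signal (movement-conditioned, 5 Hz low-pass,
#' de-meaned by the estimator), the maximum PSD value (`Peak`), and IAV.
#' The fundamental is searched in `[0.5, lowpass cutoff]` Hz.
#'
#' @param rec A raw [imu_recording()] of exercise HEHE.
#' @param cfg Matching `exercise_config`.
#' @return Named list (`Power`, `Peak`, `Freq`, `IAV`).
#' @export
hehe_features <- function(rec, cfg = exercise_registry()[["HEHE"]]) {
  stopifnot(rec$exercise == "HEHE")
  fs <- rec$sample_rate
  win <- static_window(rec)
  i1 <- floor(win[1] * fs) + 1L
  i2 <- min(n_samples(rec), floor(win[2] * fs) + 1L)
  raw <- rec$raw %||% list(accel = rec$accel, gyro = rec$gyro)
  a_mag <- butter_filter(sqrt(rowSums(raw$accel^2)), fs,
                         cfg$lowpass_cutoff, "low")[i1:i2]
  est <- estimate_psd(a_mag, fs)
  ref <- c(0.5, cfg$lowpass_cutoff)
  sel <- est$frequencies >= ref[1] & est$frequencies <= ref[2]
  accel_lp <- apply(raw$accel, 2, butter_filter, sample_rate = fs,
                    cutoff = cfg$lowpass_cutoff, kind = "low")
  list(Power = average_power(est, ref),
       Peak = if (any(sel)) max(est$psd[sel]) else NA_real_,
       Freq = fundamental_frequency(est, ref),
       IAV = iav(accel_lp, fs, win))
}
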