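# Independent oracles used across tests. These deliberately avoid the
# package's segmentation/feature code paths.

# Count complete biphasic cycles by an exhaustive forward scan over the
# threshold/zero-crossing grammar (positive lobe >= start_th, downward zero
# crossing, dip below end_th, recovery to end_th).
oracle_count_tapping <- function(omega, start_th, end_th) {
  state <- "idle"; count <- 0L
  for (v in omega) {
    if (state == "idle" && v >= start_th) state <- "open"
    else if (state == "open" && v < 0) state <- "closing"
    else if (state == "closing" && v < end_th) state <- "deep"
    else if (state == "deep" && v >= end_th) { count <- count + 1L; state <- "idle" }
  }
  count
}

# exact two-sided rank-sum p-value by enumeration of all group assignments
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled); nx <- length(x)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  combos <- utils::combn(n, nx)
  ws <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- nx * (n + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-12)
}

# exact magnitude of the implemented zero-phase digital Butterworth at
# frequency f, from the coefficient polynomials (not the filtering path)
oracle_butter_mag <- function(fs, cutoff, kind, f, order = 4) {
  bf <- signal::butter(order, cutoff / (fs / 2), type = kind)
  z <- exp(-1i * 2 * pi * f / fs)
  Mod(sum(bf$b * z^(seq_along(bf$b) - 1)) /
        sum(bf$a * z^(seq_along(bf$a) - 1)))^2
}

# amplitude of a (quasi-)sinusoid from its RMS over an interior window,
# avoiding sample-phase artefacts of max()
sine_amplitude <- function(x) stats::sd(x) * sqrt(2)

make_events <- function(kinds, times, fs = 100) {
  event_sequence(data.frame(kind = kinds, index = round(times * fs) + 1L,
                            time = times),
                 NULL, "test", fs)
}

# plain noise-free test profile for ground-truth recovery checks
clean_profile <- function(rate = 2, amp = 100, ...) {
  movement_profile(cycle_rate = rate, open_amp = amp, rate_jitter = 0,
                   amp_jitter = 0, noise_gyro = 0, noise_accel = 0, ...)
}
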