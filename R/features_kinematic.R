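#' Trapezoidal angle integration with per-cycle linear drift correction
#'
#' Integrates the dominant-axis angular velocity over one movement cycle
#' (trapezoidal rule at the sampling step, 10 ms at 100 Hz) and removes
#' integration drift by the zero-velocity-update principle: the start and
#' end of a cycle are motionless, so the accumulated end angle is drift and
#' a linear ramp towards it is subtracted,
#' `theta_corr(j) = theta(j) - (j - j0)/(jN - j0) * theta(jN)`.
#' A constant gyro bias contributes exactly such a ramp and is cancelled to
#' machine precision.
#'
#' @param omega In-cycle angular velocity, deg/s (from `T_start` to `T_end`).
#' @param sample_rate Hz.
#' @return List with `angle` (drift-corrected angle series, degrees) and
#'   `peak` (its maximum); cycles shorter than 3 samples are degenerate and
#'   return `NA` peak.
#' @export
drift_corrected_excursion <- function(omega, sample_rate) {
  n <- length(omega)
  if (n < 3) return(list(angle = rep(NA_real_, n), peak = NA_real_))
  theta <- cum_angle(omega, sample_rate)
  corr <- theta - seq(0, 1, length.out = n) * theta[n]
  list(angle = corr, peak = max(corr))
}

# cumulative trapezoidal integral at the sampling step (deg/s -> deg)
cum_angle <- function(omega, sample_rate) {
  n <- length(omega)
  c(0, cumsum((omega[-1] + omega[-n]) / 2)) / sample_rate
}

#' Movement count and mean frequency
#'
#' `Taps` is the number of completed movements (count of `T_end` events);
#' the mean frequency is the inverse of the mean interval between
#' consecutive `T_end` times (`Taps - 1` intervals).
#'
#' @param ev An [event_sequence()] from a tapping-type grammar.
#' @return `c(Taps =, Freq =)`; `Freq` is `NA` when fewer than 2 movements.
#' @export
count_and_frequency <- function(ev) {
  tend <- event_times(ev, "T_end")
  taps <- length(tend)
  freq <- if (taps >= 2) 1 / mean(diff(tend)) else NA_real_
  c(Taps = taps, Freq = freq)
}

#' Mean of per-cycle peaks, first and last movements excluded
#'
#' The first movement is often larger (anticipation) and the last often
#' truncated by the stop cue, so per-cycle averages run over cycles
#' `2..N-1` and need at least 3 cycles.
#'
#' @param peaks Per-cycle values.
#' @return Mean over the interior cycles, or `NA` if fewer than 3.
#' @export
mean_excursion <- function(peaks) {
  n <- length(peaks)
  if (n < 3) return(NA_real_)
  mean(peaks[2:(n - 1)])
}

#' Range-based variability in percent
#'
#' `100 * (max - min) / max`, applied to per-cycle instantaneous frequencies
#' and per-cycle excursions.
#'
#' @param values Per-cycle series (>= 2 values, positive maximum).
#' @return Percent, or `NA` when degenerate.
#' @export
variability <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) return(NA_real_)
  mx <- max(values)
  if (mx <= 0) return(NA_real_)
  100 * (mx - min(values)) / mx
}

#' Integral of the acceleration magnitude (IAV)
#'
#' Trapezoidal integral of `sqrt(ax^2 + ay^2 + az^2)` (gravity included)
#' over a time window; a proxy for energy expenditure, m/s.
#'
#' @param accel n x 3 acceleration matrix, m/s^2.
#' @param sample_rate Hz.
#' @param window `c(start, end)` seconds relative to the first sample.
#' @return IAV in m/s.
#' @export
iav <- function(accel, sample_rate, window) {
  n <- nrow(accel)
  i1 <- max(1L, floor(window[1] * sample_rate) + 1L)
  i2 <- min(n, floor(window[2] * sample_rate) + 1L)
  if (i2 <= i1) stopf("empty IAV window")
  mag <- sqrt(rowSums(accel[i1:i2, , drop = FALSE]^2))
  pracma::trapz(mag) / sample_rate
}

#' Per-cycle mean opening and closing velocities
#'
#' Mean angular velocity over the opening phase (`T_start..T_mid`) and the
#' closing phase (`T_mid+1..T_end`) of each cycle, averaged over interior
#' cycles `2..N-1`. Signed: for the canonical sign convention the opening
#' mean is positive and the closing mean negative.
#'
#' @param cycles Cycle index triples (`start`, `mid`, `end`).
#' @param omega Dominant-axis angular velocity, deg/s.
#' @return `c(open =, close =)`, `NA` when fewer than 3 cycles.
#' @export
phase_velocities <- function(cycles, omega) {
  n <- nrow(cycles)
  if (n < 3) return(c(open = NA_real_, close = NA_real_))
  per <- vapply(seq_len(n), function(i) {
    c(mean(omega[cycles$start[i]:cycles$mid[i]]),
      mean(omega[(cycles$mid[i] + 1):cycles$end[i]]))
  }, numeric(2))
  c(open = mean(per[1, 2:(n - 1)]), close = mean(per[2, 2:(n - 1)]))
}

# Features for the five biphasic tapping tasks (TTHP, HTTP, THFF, OPCL,
# PSUP). `omega` must already carry the canonical sign (leading lobe
# positive). Velocities are reported only for the hand tasks.
tapping_features <- function(ev, omega, accel, sample_rate,
                             velocities = FALSE) {
  cf <- count_and_frequency(ev)
  taps <- cf[["Taps"]]
  cyc <- ev$cycles
  out <- list(Taps = taps, Freq = cf[["Freq"]], Exc = NA_real_,
              CVfreq = NA_real_, CVexc = NA_real_, IAV = NA_real_)
  if (taps >= 1) {
    peaks <- vapply(seq_len(nrow(cyc)), function(i) {
      drift_corrected_excursion(omega[cyc$start[i]:cyc$end[i]],
                                sample_rate)$peak
    }, numeric(1))
    out$Exc <- mean_excursion(peaks)
    out$CVexc <- variability(peaks)
    tend <- event_times(ev, "T_end")
    if (taps >= 2) out$CVfreq <- variability(1 / diff(tend))
    out$IAV <- iav(accel, sample_rate,
                   c(ev$events$time[1], tend[length(tend)]))
    if (velocities) {
      v <- phase_velocities(cyc, omega)
      out$wo <- abs(v[["open"]]); out$wc <- abs(v[["close"]])
    }
  } else if (velocities) {
    out$wo <- NA_real_; out$wc <- NA_real_
  }
  order_names <- if (velocities)
    c("Taps", "Freq", "Exc", "wo", "wc", "CVfreq", "CVexc", "IAV")
  else c("Taps", "Freq", "Exc", "CVfreq", "CVexc", "IAV")
  out[order_names]
}

#' Features of the alternating heel-toe tapping task
#'
#' `Taps = min(#T_HS, #T_TO)`; three frequencies (toe, heel and combined
#' heel-toe) from interior event intervals; toe and heel excursions as the
#' extremum of the angle integral over each toe-up / heel-up interval,
#' averaged over interior cycles; range variabilities; IAV.
#'
#' @param ev [event_sequence()] from [segment_heel_toe()].
#' @param omega Dominant-axis angular velocity, deg/s.
#' @param accel n x 3 conditioned acceleration, m/s^2.
#' @param sample_rate Hz.
#' @param drift_correct Apply the per-interval linear drift correction to
#'   the excursion integrals (default `FALSE`: the interval integrals are
#'   used as defined).
#' @return Named list of the 10 heel-toe parameters.
#' @export
heto_features <- function(ev, omega, accel, sample_rate,
                          drift_correct = FALSE) {
  hs_t <- event_times(ev, "T_HS"); to_t <- event_times(ev, "T_TO")
  hs_i <- ev$events$index[ev$events$kind == "T_HS"]
  to_i <- ev$events$index[ev$events$kind == "T_TO"]
  taps <- min(length(hs_t), length(to_t))
  out <- list(Taps = taps, FreqT = NA_real_, FreqH = NA_real_,
              FreqHT = NA_real_, ExcT = NA_real_, ExcH = NA_real_,
              CVfreq = NA_real_, CVexcT = NA_real_, CVexcH = NA_real_,
              IAV = NA_real_)
  if (taps == 0) return(out)
  interior <- function(x) if (length(x) >= 1) x else numeric(0)
  inv_mean <- function(intervals, idx) {
    idx <- idx[idx >= 2 & idx <= taps - 1]
    if (!length(idx)) return(NA_real_)
    1 / mean(intervals[idx])
  }
  if (taps >= 3) {
    if (length(to_t) >= taps)
      out$FreqT <- inv_mean(diff(to_t), seq_len(length(to_t) - 1))
    if (length(hs_t) >= taps)
      out$FreqH <- inv_mean(diff(hs_t), seq_len(length(hs_t) - 1))
  }
  toe_first <- to_t[1] < hs_t[1]
  # combined heel-toe interval: the half-tap between a toe-off and the
  # heel-strike of the same pair (or vice versa)
  ht_int <- if (toe_first) hs_t[seq_len(taps)] - to_t[seq_len(taps)]
            else to_t[seq_len(taps)] - hs_t[seq_len(taps)]
  if (taps >= 3) out$FreqHT <- inv_mean(ht_int, seq_len(taps))
  out$CVfreq <- variability(1 / ht_int)

  exc_of <- function(i1, i2, flip) {
    if (is.na(i1) || is.na(i2) || i2 - i1 < 2) return(NA_real_)
    seg <- omega[i1:i2]
    theta <- cum_angle(seg, sample_rate)
    if (drift_correct)
      theta <- theta - seq(0, 1, length.out = length(theta)) * theta[length(theta)]
    if (flip) max(-theta) else max(theta)
  }
  # toe interval: toe rises (positive lobe) between T_TO and next T_HS;
  # heel interval: negative lobe between T_HS and next T_TO
  if (toe_first) {
    exc_t <- vapply(seq_len(taps), function(i)
      exc_of(to_i[i], hs_i[i], FALSE), numeric(1))
    exc_h <- vapply(seq_len(taps), function(i)
      exc_of(hs_i[i], if (i + 1 <= length(to_i)) to_i[i + 1] else NA, TRUE),
      numeric(1))
  } else {
    exc_h <- vapply(seq_len(taps), function(i)
      exc_of(hs_i[i], to_i[i], TRUE), numeric(1))
    exc_t <- vapply(seq_len(taps), function(i)
      exc_of(to_i[i], if (i + 1 <= length(hs_i)) hs_i[i + 1] else NA, FALSE),
      numeric(1))
  }
  mean_int <- function(x) {
    x <- x[2:(taps - 1)]; x <- x[is.finite(x)]
    if (!length(x)) NA_real_ else mean(x)
  }
  if (taps >= 3) {
    out$ExcT <- mean_int(exc_t)
    out$ExcH <- mean_int(exc_h)
  }
  out$CVexcT <- variability(exc_t)
  out$CVexcH <- variability(exc_h)
  tt <- ev$events$time
  out$IAV <- iav(accel, sample_rate, c(tt[1], tt[length(tt)]))
  out
}

#' Gait features from one foot's stride sequence
#'
#' Total walking time, stride count and cadence; mean stride, swing and
#' stance times and relative stance from the heel-strike / toe-off events;
#' and the mean dorsiflexion angular range per stride, with the initial
#' foot pitch estimated from the two-argument arctangent of `(a_x, a_z)`
#' averaged over the foot-flat interval preceding each stride (10 samples
#' before the first stride).
#'
#' @param ev [event_sequence()] from [segment_gait()] .
#' @param omega Sagittal foot angular velocity, deg/s.
#' @param accel n x 3 conditioned acceleration (columns x, y, z), m/s^2.
#' @param sample_rate Hz.
#' @return Named list of the 8 gait parameters (`Time`, `Strd`, `Freq`,
#'   `StrdT`, `SWT`, `STT`, `RS`, `Ang`).
#' @export
gait_features <- function(ev, omega, accel, sample_rate) {
  cyc <- ev$cycles
  strd <- nrow(cyc)
  out <- list(Time = NA_real_, Strd = strd, Freq = NA_real_,
              StrdT = NA_real_, SWT = NA_real_, STT = NA_real_,
              RS = NA_real_, Ang = NA_real_)
  if (strd == 0) return(out)
  t_of <- function(i) (i - 1) / sample_rate
  t_start <- t_of(cyc$start); t_to <- t_of(cyc$to)
  t_hs <- t_of(cyc$hs); t_end <- t_of(cyc$end)
  out$Time <- t_end[strd] - t_start[1]
  out$Freq <- strd / out$Time
  out$SWT <- mean(t_hs - t_to)
  if (strd >= 2) {
    strd_t <- diff(t_hs)                      # stride i -> i+1
    swt <- (t_hs - t_to)[seq_len(strd - 1)]
    stt <- strd_t - swt
    out$StrdT <- mean(strd_t)
    out$STT <- mean(stt)
    out$RS <- mean(100 * stt / strd_t)
  }
  if (strd >= 3) {
    theta_init <- function(i1, i2) {
      i1 <- max(1L, i1); i2 <- max(i1, i2)
      mean(atan2(accel[i1:i2, 1], accel[i1:i2, 3])) * 180 / pi
    }
    rng <- vapply(2:(strd - 1), function(i) {
      th0 <- theta_init(cyc$end[i - 1], cyc$start[i])
      theta <- cum_angle(omega[cyc$start[i]:cyc$end[i]], sample_rate) + th0
      max(theta) - min(theta)
    }, numeric(1))
    out$Ang <- mean(rng)
  }
  out
}

#' Rotation features
#'
#' Total turning time, step count, step frequency, summed between-step
#' stance time and relative stance.
#'
#' @param ev [event_sequence()] from [segment_rotation()].
#' @return Named list (`Time`, `Strd`, `Freq`, `STT`, `RS`); stance features
#'   are `NA` with fewer than 2 steps.
#' @export
rotation_features <- function(ev) {
  t_start <- event_times(ev, "T_start"); t_end <- event_times(ev, "T_end")
  strd <- length(t_end)
  out <- list(Time = NA_real_, Strd = strd, Freq = NA_real_,
              STT = NA_real_, RS = NA_real_)
  if (strd == 0) return(out)
  out$Time <- t_end[strd] - t_start[1]
  out$Freq <- strd / out$Time
  if (strd >= 2) {
    out$STT <- sum(t_start[2:strd] - t_end[seq_len(strd - 1)])
    out$RS <- 100 * out$STT / out$Time
  }
  out
}

#' Arm-swing features during gait
#'
#' Swing cycles are delimited by consecutive direction reversals
#' (`T_front`/`T_back`); a full cycle spans two reversals. Count, cycle
#' frequency, drift-corrected maximum swing excursion, mean forward and
#' backward phase velocities (magnitudes averaged over interior cycles),
#' range variabilities and IAV.
#'
#' @param ev [event_sequence()] from [segment_arm_swing()].
#' @param omega Arm angular velocity (canonical sign), deg/s.
#' @param accel n x 3 conditioned acceleration, m/s^2.
#' @param sample_rate Hz.
#' @return Named list (`Taps`, `HFreq`, `Exc`, `wf`, `wb`, `CVfreq`,
#'   `CVexc`, `IAV`).
#' @export
arm_swing_features <- function(ev, omega, accel, sample_rate) {
  out <- list(Taps = 0, HFreq = NA_real_, Exc = NA_real_, wf = NA_real_,
              wb = NA_real_, CVfreq = NA_real_, CVexc = NA_real_,
              IAV = NA_real_)
  evd <- ev$events
  if (nrow(evd) < 3) return(out)
  rev_i <- evd$index[-1]; rev_k <- evd$kind[-1]   # reversals after T_start
  n_cyc <- length(rev_i) %/% 2
  out$Taps <- n_cyc
  if (n_cyc == 0) return(out)
  b0 <- c(evd$index[1], rev_i[seq_len(max(0, n_cyc - 1)) * 2])  # cycle starts
  mid <- rev_i[seq_len(n_cyc) * 2 - 1]
  end <- rev_i[seq_len(n_cyc) * 2]
  mid_kind <- rev_k[seq_len(n_cyc) * 2 - 1]
  t_end <- (end - 1) / sample_rate
  if (n_cyc >= 2) {
    ints <- diff(t_end)
    out$HFreq <- 1 / mean(ints)
    out$CVfreq <- variability(1 / ints)
  }
  peaks <- vapply(seq_len(n_cyc), function(i) {
    seg <- omega[b0[i]:end[i]]
    if (mid_kind[i] == "T_back") seg <- -seg   # backward-first swing
    drift_corrected_excursion(seg, sample_rate)$peak
  }, numeric(1))
  out$Exc <- mean_excursion(peaks)
  out$CVexc <- variability(peaks)
  if (n_cyc >= 3) {
    ph <- vapply(seq_len(n_cyc), function(i) {
      m1 <- mean(omega[b0[i]:mid[i]])
      m2 <- mean(omega[(mid[i] + 1):end[i]])
      if (mid_kind[i] == "T_front") c(m1, m2) else c(m2, m1)
    }, numeric(2))
    out$wf <- abs(mean(ph[1, 2:(n_cyc - 1)]))
    out$wb <- abs(mean(ph[2, 2:(n_cyc - 1)]))
  }
  out$IAV <- iav(accel, sample_rate,
                 c(evd$time[1], evd$time[nrow(evd)]))
  out
}
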