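fs <- 100

test_that("counts and mean frequency follow the end-event intervals", {
  ev <- make_events(rep("T_end", 10), seq(0.5, 5, by = 0.5))
  cf <- count_and_frequency(ev)
  expect_equal(cf[["Taps"]], 10)
  expect_equal(cf[["Freq"]], 2)

  ev2 <- make_events(rep("T_end", 3), c(1, 2, 4))
  expect_equal(count_and_frequency(ev2)[["Freq"]], 1 / 1.5)

  ev3 <- make_events("T_end", 1)
  cf3 <- count_and_frequency(ev3)
  expect_equal(cf3[["Taps"]], 1)
  expect_true(is.na(cf3[["Freq"]]))
})

test_that("drift-corrected excursion matches closed forms and cancels bias", {
  om <- 100 * sin(2 * pi * seq(0, 0.5, by = 1 / fs) / 0.5)
  e <- drift_corrected_excursion(om, fs)
  expect_equal(e$peak, 100 * 0.5 / pi, tolerance = 0.005)
  # a constant rate bias integrates to exactly the removed linear ramp
  eb <- drift_corrected_excursion(om + 5, fs)
  expect_lt(abs(eb$peak - e$peak), 1e-6)
  expect_equal(drift_corrected_excursion(numeric(60), fs)$peak, 0)
  expect_true(is.na(drift_corrected_excursion(c(1, 2), fs)$peak))
})

test_that("interior-cycle averaging excludes the first and last movements", {
  expect_equal(mean_excursion(c(99, 10, 12, 14, 1)), 12)
  expect_true(is.na(mean_excursion(c(5, 7))))
  expect_equal(mean_excursion(c(3, 8, 4)), 8)
})

test_that("range variability is 100*(max-min)/max", {
  expect_equal(variability(rep(4.2, 6)), 0)
  expect_equal(variability(c(2, 1)), 50)
  expect_equal(variability(c(10, 5, 8)), 50)
  expect_true(is.na(variability(3)))
  expect_true(is.na(variability(c(-2, -1))))
})

test_that("IAV integrates the acceleration magnitude", {
  n <- 1001
  expect_equal(iav(matrix(0, n, 3), fs, c(0, 10)), 0)
  a <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  expect_equal(iav(a, fs, c(0, 10)), 98.1, tolerance = 1e-3)
  b <- matrix(rep(c(3, 4, 0), each = 201), 201, 3)
  expect_equal(iav(b, fs, c(0, 2)), 10, tolerance = 1e-3)
  expect_error(iav(a, fs, c(5, 5)), "empty")
})

test_that("phase velocities are half-sine means over the two phases", {
  A <- 90; d <- 25  # quarter-second lobes
  lobe <- A * sin(pi * (1:d) / d)
  om <- rep(c(lobe, -lobe), 5)
  cycles <- data.frame(start = (0:4) * 2 * d + 1,
                       mid = (0:4) * 2 * d + d,
                       end = (1:5) * 2 * d)
  v <- phase_velocities(cycles, om)
  expect_equal(v[["open"]], 2 * A / pi, tolerance = 0.05)
  expect_equal(v[["open"]], -v[["close"]], tolerance = 1e-6)
  flat <- phase_velocities(cycles, numeric(length(om)))
  expect_equal(unname(flat), c(0, 0))
  expect_true(all(is.na(phase_velocities(cycles[1:2, ], om))))
})

test_that("heel-toe features follow the event grammar", {
  times <- seq(0.25, 4, by = 0.25)
  kinds <- rep(c("T_HS", "T_TO"), 8)
  ev <- make_events(kinds, times)
  f <- heto_features(ev, numeric(420), matrix(0, 420, 3), fs)
  expect_equal(f$Taps, 8)
  expect_equal(f$FreqT, 2, tolerance = 1e-9)
  expect_equal(f$FreqH, 2, tolerance = 1e-9)
  expect_equal(f$FreqHT, 4, tolerance = 1e-9)

  # min rule: 5 heel strikes, 4 toe-offs -> 4 taps
  ev2 <- make_events(c(rep(c("T_HS", "T_TO"), 4), "T_HS"),
                     seq(0.25, 2.25, by = 0.25))
  expect_equal(heto_features(ev2, numeric(240), matrix(0, 240, 3),
                             fs)$Taps, 4)

  # full-sine lobes amplitude A, half-period 0.25 s -> ExcT = ExcH = 2A*0.25/pi
  A <- 120
  t <- seq(0, 6, by = 1 / fs)
  om <- A * sin(2 * pi * 2 * t)
  seg <- segment_heel_toe(om, 20, fs)
  f3 <- heto_features(seg, om, matrix(0, length(om), 3), fs)
  expect_equal(f3$ExcT, 2 * A * 0.25 / pi, tolerance = 0.01)
  expect_equal(f3$ExcH, 2 * A * 0.25 / pi, tolerance = 0.01)
})

test_that("gait features reproduce constructed stance and swing times", {
  # strides: heel-off 0.15, swing 0.30, heel-strike 0.15, flat 0.40 -> 1.0 s
  stride <- c(-300 * sin(pi * (1:15) / 15), 400 * sin(pi * (1:30) / 30),
              -250 * sin(pi * (1:15) / 15), numeric(40))
  om <- c(numeric(100), rep(stride, 12), numeric(100))
  ev <- segment_gait(om, 50, 3, fs)
  a <- matrix(rep(c(0, 0, 9.81), each = length(om)), length(om), 3)
  f <- gait_features(ev, om, a, fs)
  expect_equal(f$Strd, 12)
  expect_equal(f$StrdT, 1.0, tolerance = 0.01)
  expect_equal(f$SWT, 0.30, tolerance = 0.02)
  expect_equal(f$RS, 70, tolerance = 2)
  expect_equal(f$Freq, f$Strd / f$Time, tolerance = 1e-9)
  # dorsiflexion range: lobe areas are 28.65 + 47.75 (deg) on the 0.3 s swing
  expect_gt(f$Ang, 0)
})

test_that("the foot-pitch convention reads atan2(ax, az) in degrees", {
  n <- 400
  level <- matrix(rep(c(0, 0, 9.81), each = n), n, 3)
  tilted <- matrix(rep(c(9.81 * sin(pi / 9), 0, 9.81 * cos(pi / 9)),
                       each = n), n, 3)
  th0 <- mean(atan2(level[, 1], level[, 3])) * 180 / pi
  th20 <- mean(atan2(tilted[, 1], tilted[, 3])) * 180 / pi
  expect_equal(th0, 0)
  expect_equal(th20, 20, tolerance = 1e-9)
  # generator encodes the same convention: integrated angle reappears in accel
  prof <- clean_profile(rate = 1, amp = 60, duration = 4)
  rec <- gen_tapping(prof, "TTHP", "right", seed = 1)
  theta_g <- atan2(rec$accel[, 1], rec$accel[, 3]) * 180 / pi
  theta_i <- cumsum(rec$gyro[, 2]) / fs
  expect_lt(max(abs(theta_g - theta_i)), 0.5)
})

test_that("rotation features are direct event arithmetic", {
  ev <- make_events(rep(c("T_start", "T_end"), 3),
                    c(0, 0.4, 0.6, 1.0, 1.2, 1.6))
  f <- rotation_features(ev)
  expect_equal(f$Time, 1.6)
  expect_equal(f$Strd, 3)
  expect_equal(f$STT, 0.4, tolerance = 1e-9)
  expect_equal(f$RS, 25, tolerance = 1e-9)

  ev4 <- make_events(rep(c("T_start", "T_end"), 4),
                     seq(0, 2, length.out = 8))
  expect_equal(rotation_features(ev4)$Freq, 2, tolerance = 1e-9)

  single <- make_events(c("T_start", "T_end"), c(0, 1.3))
  fs1 <- rotation_features(single)
  expect_equal(fs1$Strd, 1)
  expect_true(is.na(fs1$STT))
})

test_that("arm-swing features are symmetric for a pure sinusoidal swing", {
  t <- seq(0, 12, by = 1 / fs)
  om <- 60 * sin(2 * pi * 1 * t)
  ev <- segment_arm_swing(om, 10, 2, fs)
  a <- matrix(rep(c(0, 0, 9.81), each = length(om)), length(om), 3)
  f <- arm_swing_features(ev, om, a, fs)
  expect_equal(f$HFreq, 1, tolerance = 0.02)
  expect_equal(f$wf, f$wb, tolerance = 0.02 * f$wf)
  expect_equal(f$Exc, 60 / pi, tolerance = 0.05 * 60 / pi)
  zero <- arm_swing_features(segment_arm_swing(numeric(1000), 10, 2, fs),
                             numeric(1000), a[1:1000, ], fs)
  expect_true(is.na(zero$Exc) && is.na(zero$HFreq))
})

test_that("features are invariant to first/last cycle amplitude and stable
           under refinement", {
  build <- function(rate, amps, f) {
    d <- round(f / (2 * rate))
    om <- numeric(0)
    for (a in amps) om <- c(om, a * sin(pi * (1:d) / d),
                            -a * sin(pi * (1:d) / d))
    om
  }
  amps <- c(80, 120, 110, 130, 90)
  om1 <- build(2, amps, fs)
  ev1 <- segment_tapping(om1, 15, -3, fs)
  f1 <- tapping_features(ev1, om1, matrix(0, length(om1), 3), fs)
  # scaling the first and last cycles leaves the interior mean unchanged
  om2 <- build(2, c(300, amps[2:4], 40), fs)
  ev2 <- segment_tapping(om2, 15, -3, fs)
  f2 <- tapping_features(ev2, om2, matrix(0, length(om2), 3), fs)
  expect_equal(f1$Exc, f2$Exc, tolerance = 1e-9)

  # doubling the sample rate moves Exc and Freq by < 0.5%
  om_h <- build(2, amps, 200)
  ev_h <- segment_tapping(om_h, 15, -3, 200)
  f_h <- tapping_features(ev_h, om_h, matrix(0, length(om_h), 3), 200)
  expect_equal(f_h$Exc, f1$Exc, tolerance = 0.005)
  expect_equal(f_h$Freq, f1$Freq, tolerance = 0.005)
  a_mag <- function(n, sr) matrix(rep(c(1, 2, 2), each = n), n, 3)
  expect_equal(iav(a_mag(1001, 100), 100, c(0, 10)),
               iav(a_mag(2001, 200), 200, c(0, 10)), tolerance = 0.005)
})

test_that("every task emits exactly its schema parameters", {
  reg <- exercise_registry()
  params <- pdmotor:::exercise_parameters()
  profs <- default_profiles("HC")
  for (ex in EXERCISES) {
    rec <- gen_recording(profs[[ex]], ex, "right", seed = 3)
    f <- extract_features(rec, reg[[ex]])
    expect_identical(names(f), paste(reg[[ex]]$prefix, params[[ex]],
                                     sep = "_"), info = ex)
  }
})
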