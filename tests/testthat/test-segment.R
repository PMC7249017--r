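fs <- 100

test_that("tapping segmentation matches the exhaustive crossing-scan oracle", {
  t <- seq(0, 10, by = 1 / fs)
  om <- 120 * sin(2 * pi * 2 * t)
  ev <- segment_tapping(om, 15, -3, fs)
  expect_equal(nrow(ev$cycles), 20)
  expect_equal(nrow(ev$cycles), oracle_count_tapping(om, 15, -3))

  # irregular multi-rate signal: oracle agreement is the ground truth
  set.seed(7)
  om2 <- numeric(0)
  for (k in 1:15) {
    d <- sample(8:30, 1)
    a <- runif(1, 40, 300)
    om2 <- c(om2, a * sin(pi * (1:d) / d), -a * sin(pi * (1:d) / d),
             numeric(sample(3:20, 1)))
  }
  ev2 <- segment_tapping(om2, 15, -3, fs)
  expect_equal(nrow(ev2$cycles), oracle_count_tapping(om2, 15, -3))

  expect_equal(nrow(segment_tapping(numeric(500), 15, -3, fs)$cycles), 0)
  expect_equal(nrow(segment_tapping(10 * sin(2 * pi * 2 * t), 15, -3,
                                    fs)$cycles), 0)
})

test_that("event sequences are deterministic, ordered and shift-equivariant", {
  t <- seq(0, 10, by = 1 / fs)
  om <- 80 * sin(2 * pi * 1.5 * t)
  ev1 <- segment_tapping(om, 15, -3, fs)
  ev2 <- segment_tapping(om, 15, -3, fs)
  expect_identical(ev1$events, ev2$events)
  expect_true(all(diff(ev1$events$time) > 0))
  # cycles do not overlap
  expect_true(all(ev1$cycles$start[-1] > head(ev1$cycles$end, -1)))
  # prepending 1 s of zeros shifts every event by exactly 1 s
  ev3 <- segment_tapping(c(numeric(fs), om), 15, -3, fs)
  expect_equal(ev3$events$time, ev1$events$time + 1)
})

test_that("heel-toe segmentation alternates events and is antisymmetric", {
  t <- seq(0, 10, by = 1 / fs)
  om <- 60 * sin(2 * pi * 2 * t)    # positive lobe first
  ev <- segment_heel_toe(om, 20, fs)
  k <- ev$events$kind
  expect_equal(k[1], "T_HS")
  expect_true(all(k[seq(1, length(k), 2)] == "T_HS"))
  expect_true(all(k[seq(2, length(k), 2)] == "T_TO"))
  expect_lte(abs(sum(k == "T_HS") - sum(k == "T_TO")), 1)

  flip <- segment_heel_toe(-om, 20, fs)
  expect_equal(flip$events$index, ev$events$index)
  expect_equal(flip$events$kind,
               ifelse(ev$events$kind == "T_HS", "T_TO", "T_HS"))

  expect_equal(nrow(segment_heel_toe(10 * sin(2 * pi * 2 * t), 20,
                                     fs)$events), 0)
})

test_that("gait segmentation recovers constructed strides", {
  # build 12 strides straight from the grammar's lobe structure
  stride <- c(-300 * sin(pi * (1:15) / 15),      # heel-off
              400 * sin(pi * (1:30) / 30),       # swing
              -250 * sin(pi * (1:15) / 15),      # heel-strike
              numeric(40))                       # foot flat
  om <- c(numeric(50), rep(stride, 12), numeric(50))
  ev <- segment_gait(om, 50, 3, fs)
  expect_equal(nrow(ev$cycles), 12)
  expect_true(all(ev$cycles$start < ev$cycles$to &
                  ev$cycles$to < ev$cycles$hs &
                  ev$cycles$hs < ev$cycles$end))
  expect_equal(nrow(segment_gait(numeric(1000), 50, 3, fs)$cycles), 0)
  # a swing-only lobe reaching -40 never crosses the heel-off threshold
  weak <- c(numeric(50), -40 * sin(pi * (1:30) / 30),
            200 * sin(pi * (1:30) / 30), numeric(100))
  expect_equal(nrow(segment_gait(weak, 50, 3, fs)$cycles), 0)
})

test_that("rotation segmentation counts bursts and mirrors direction", {
  om <- numeric(400)
  for (s in c(20, 150, 280)) om[s:(s + 45)] <- -200 * sin(pi * (0:45) / 45)
  ev <- segment_rotation(om, "clockwise", 50, 5, fs)
  expect_equal(nrow(ev$cycles), 3)
  ev2 <- segment_rotation(-om, "anticlockwise", 50, 5, fs)
  expect_equal(ev2$events, ev$events)
  expect_equal(nrow(segment_rotation(0.2 * om, "clockwise", 50, 5,
                                     fs)$cycles), 0)  # sub-threshold sway
  expect_error(segment_rotation(om, "sideways"), "arg")
})

test_that("arm-swing segmentation detects reversals inside the turn bound", {
  t <- seq(0, 10, by = 1 / fs)
  om <- 60 * sin(2 * pi * 1 * t)
  ev <- segment_arm_swing(om, 10, 2, fs)
  k <- ev$events$kind
  expect_equal(k[1], "T_start")
  expect_equal(sum(k == "T_front"), 10, tolerance = 1)
  expect_equal(sum(k == "T_back"), 10, tolerance = 1)
  # reversals alternate
  rev_k <- k[-1]
  expect_true(all(rev_k[seq(1, length(rev_k), 2)] == "T_front"))
  expect_equal(nrow(segment_arm_swing(5 * sin(2 * pi * t), 10, 2,
                                      fs)$events), 0)
  expect_equal(nrow(segment_arm_swing(numeric(500), 10, 2, fs)$events), 0)
})

test_that("the static window is 3-13 s, clipped to the recording", {
  mk <- function(dur) imu_recording("w", "HRST", "left", 1,
                                    accel = matrix(0, dur * fs + 1, 3),
                                    gyro = matrix(0, dur * fs + 1, 3))
  expect_equal(static_window(mk(16)), c(3, 13))
  expect_equal(static_window(mk(10)), c(3, 10))
  expect_error(static_window(mk(2)), "3 s")
  rec <- mk(16); rec$exercise <- "THFF"
  expect_error(static_window(rec), "applies to")
})

test_that("generated cycles are recovered exactly across grammars and sides", {
  reg <- exercise_registry()
  for (ex in c("THFF", "OPCL", "PSUP", "TTHP", "HTTP")) {
    cfg <- reg[[ex]]
    amp <- 2 * abs(cfg$thresholds[[1]])
    for (side in c("left", "right")) {
      for (K in c(4, 17)) {
        prof <- clean_profile(rate = 2, amp = max(amp, 60),
                              duration = K / 2 + 0.4)
        rec <- gen_tapping(prof, ex, side, seed = K)
        expect_equal(attr(rec, "truth")$n_cycles, K)
        ev <- segment_recording(condition_recording(rec, cfg), cfg)
        expect_equal(nrow(ev$cycles), K,
                     info = sprintf("%s %s K=%d", ex, side, K))
      }
    }
  }
})
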