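test_that("recordings validate their invariants", {
  ok <- imu_recording("s1", "THFF", "right", 1,
                      accel = matrix(0, 1000, 3), gyro = matrix(0, 1000, 3))
  expect_s3_class(ok, "imu_recording")
  expect_equal(n_samples(ok), 1000)
  expect_equal(ok$sample_rate, 100)
  expect_equal(ok$sensor_unit, "index")

  bad_t <- c(0, 0.01, 0.01, 0.03)  # duplicated timestamp
  expect_error(imu_recording("s1", "THFF", "right", 1,
                             accel = matrix(0, 4, 3), gyro = matrix(0, 4, 3),
                             time = bad_t),
               "strictly increasing")
  expect_error(imu_recording("s1", "XXXX", "right", 1,
                             accel = matrix(0, 4, 3), gyro = matrix(0, 4, 3)))
  expect_error(imu_recording("s1", "THFF", "right", 1,
                             accel = matrix(0, 4, 3), gyro = matrix(0, 5, 3)),
               "equal length")
  expect_error(imu_recording("s1", "THFF", "right", 1,
                             accel = matrix(0, 4, 3), gyro = matrix(0, 4, 3),
                             time = c(0, 0.011, 0.02, 0.03)),
               "1/sample_rate")
})

test_that("recording serialisation round-trips", {
  set.seed(42)
  for (i in 1:3) {
    n <- sample(200:600, 1)
    rec <- imu_recording(sprintf("s%d", i), sample(EXERCISES, 1),
                         sample(c("left", "right"), 1), sample(1:2, 1),
                         accel = matrix(rnorm(3 * n, sd = 5), n, 3),
                         gyro = matrix(rnorm(3 * n, sd = 300), n, 3),
                         group = sample(c("HC", "PD"), 1))
    stem <- file.path(tempdir(), sprintf("roundtrip%d", i))
    write_recording(rec, stem)
    back <- read_recording(stem)
    expect_identical(back$subject_id, rec$subject_id)
    expect_identical(back$exercise, rec$exercise)
    expect_identical(back$side, rec$side)
    expect_identical(back$trial, rec$trial)
    expect_identical(back$group, rec$group)
    expect_lt(max(abs(back$accel - rec$accel)), 1e-9)
    expect_lt(max(abs(back$gyro - rec$gyro)), 1e-9)
    expect_lt(max(abs(back$time - rec$time)), 1e-9)
  }
})

test_that("declared input units are converted on read", {
  n <- 300
  rec <- imu_recording("u1", "PSUP", "left", 1,
                       accel = matrix(9.80665, n, 3),
                       gyro = matrix(180, n, 3))
  stem <- file.path(tempdir(), "units")
  write_recording(rec, stem)
  # rewrite sidecar declaring g and rad/s
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  meta$units <- list(accel = "g", gyro = "rad/s")
  jsonlite::write_json(meta, paste0(stem, ".json"), auto_unbox = TRUE)
  body <- read.csv(paste0(stem, ".csv"))
  body[, c("ax", "ay", "az")] <- 1      # 1 g
  body[, c("gx", "gy", "gz")] <- pi     # pi rad/s
  write.csv(body, paste0(stem, ".csv"), row.names = FALSE)
  back <- read_recording(stem)
  expect_equal(unname(back$accel[1, 1]), 9.80665, tolerance = 1e-12)
  expect_equal(unname(back$gyro[1, 1]), 180, tolerance = 1e-12)
})

test_that("read errors are informative", {
  stem <- file.path(tempdir(), "badrec")
  writeLines("t,ax,ay\n0,0,0", paste0(stem, ".csv"))
  jsonlite::write_json(list(subject_id = "x", exercise = "THFF",
                            side = "left", trial = 1, sample_rate = 100),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(stem), "missing columns")
})

test_that("the registry covers the twelve tasks with the printed thresholds", {
  reg <- exercise_registry()
  expect_setequal(names(reg), EXERCISES)

  expect_equal(reg$THFF$thresholds[["TH_TF"]], 15)
  expect_equal(reg$THFF$thresholds[["TH_TFv"]], -3)
  expect_equal(reg$OPCL$thresholds[["TH_OC"]], 30)
  expect_equal(reg$OPCL$thresholds[["TH_OCv"]], -3)
  expect_equal(reg$PSUP$thresholds[["TH_PS"]], 50)
  expect_equal(reg$PSUP$thresholds[["TH_PSv"]], -5)
  expect_equal(reg$GTAH$thresholds[["TH_GT"]], 10)
  expect_equal(reg$GTAH$thresholds[["turn_bound"]], 2)
  expect_equal(reg$GTAF$thresholds[["TH_HO"]], 50)
  expect_equal(reg$GTAF$thresholds[["TH_FF"]], 3)
  expect_equal(reg$ROTA$thresholds[["TH_RO"]], 50)
  expect_equal(reg$ROTA$thresholds[["TH_ROv"]], 5)
  expect_equal(reg$TTHP$thresholds[["TH_TO"]], 10)
  expect_equal(reg$HTTP$thresholds[["TH_HO"]], 10)
  expect_equal(reg$HETO$thresholds[["TH_TO"]], 20)
  expect_equal(reg$HETO$thresholds[["TH_HO"]], 20)
  expect_equal(reg$HEHE$thresholds[["TH_TO"]], 10)

  # task-dependent cutoffs: 5 Hz movement, 3 Hz gait, tremor 15/20 + 0.5 Hz
  expect_equal(reg$THFF$lowpass_cutoff, 5)
  expect_equal(reg$GTAF$lowpass_cutoff, 3)
  expect_equal(reg$GTAH$lowpass_cutoff, 3)
  expect_equal(reg$HRST$lowpass_cutoff, 15)
  expect_equal(reg$POST$lowpass_cutoff, 20)
  expect_equal(reg$HRST$highpass_cutoff, 0.5)
  expect_equal(reg$POST$highpass_cutoff, 0.5)

  # GTAF and GTAH are distinct configurations of the same walk
  expect_false(identical(reg$GTAF$sensor_unit, reg$GTAH$sensor_unit))
  for (cfg in reg) {
    expect_true(cfg$segmentation_kind %in%
                  c("tapping_biphasic", "heel_toe", "gait", "rotation",
                    "arm_swing", "static"))
    if (cfg$segmentation_kind != "tapping_biphasic")
      expect_true(all(required_thresholds(cfg$segmentation_kind) %in%
                        names(cfg$thresholds)))
    else expect_length(cfg$thresholds, 2)
  }
})

test_that("the feature schema enumerates 39 + 48 parameters per side", {
  sch <- feature_schema()
  expect_equal(nrow(sch), 174)
  expect_false(anyDuplicated(sch$name) > 0)
  counts <- table(sch$condition, sch$side)
  expect_true(all(counts["FEET", ] == 39))
  expect_true(all(counts["HANDS", ] == 48))
  expect_equal(sum(sch$side == "left"), 87)
  # every column maps to exactly one task and parameter
  expect_true(all(sch$exercise %in% EXERCISES))
  expect_true("TT_Taps_right" %in% sch$name)
  expect_true("PT_Perc2G_left" %in% sch$name)
})
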