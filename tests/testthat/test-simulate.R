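test_that("step bookkeeping and determinism hold", {
  spec <- synthetic_spec("natural_walk", "ankle", duration_s = 60,
                         cadence_hz = 1.5, seed = 7)
  sim <- simulate_recording(spec)
  expect_length(sim$truth$step_times, 90)
  expect_length(sim$recording$timestamps, round(60 * 100))
  expect_equal(sim$truth$source, "simulated")

  sim2 <- simulate_recording(spec)
  expect_identical(sim$recording, sim2$recording)
  expect_identical(sim$truth, sim2$truth)

  # the simulator restores the caller's RNG stream
  set.seed(99)
  before <- rnorm(1)
  set.seed(99)
  invisible(simulate_recording(spec))
  expect_identical(rnorm(1), before)
})

test_that("ground-truth spacing stays above 0.8 periods", {
  for (seed in 1:5) {
    for (sc in c("natural_walk", "jog", "stairs_combined")) {
      spec <- synthetic_spec(sc, "ankle", duration_s = 30, seed = seed)
      sim <- simulate_recording(spec)
      expect_gte(min(diff(sim$truth$step_times)),
                 0.8 / spec$cadence_hz)
    }
  }
})

test_that("the arm signal's spectral peak sits at the cadence", {
  spec <- synthetic_spec("natural_walk", "upper_arm", duration_s = 30,
                         cadence_hz = 1.6, noise_sd = 0, seed = 5)
  sim <- simulate_recording(spec)
  mag <- accel_magnitude(sim$recording$accel)
  sig <- mag - median(mag)
  pw <- Mod(fft(sig))[1:(length(sig) / 2)]^2
  freqs <- (0:(length(sig) / 2 - 1)) / (length(sig) / 100)
  inband <- freqs >= 0.8 & freqs <= 2.0
  fpeak <- freqs[inband][which.max(pw[inband])]
  expect_lt(abs(fpeak - 1.6), 1 / 30 + 1e-9)  # within one frequency bin
})

test_that("stair descent carries larger per-step impacts than ascent", {
  peak_amp <- function(sim) {
    mag <- accel_magnitude(sim$recording$accel)
    sig <- mag - median(mag)
    mean(vapply(sim$truth$step_times, function(s) {
      max(sig[abs(sim$recording$timestamps - s) < 0.15])
    }, numeric(1)))
  }
  for (seed in c(2, 13)) {
    up <- simulate_recording(synthetic_spec("stairs_up", "ankle",
                                            duration_s = 30, noise_sd = 0,
                                            seed = seed))
    dn <- simulate_recording(synthetic_spec("stairs_down", "ankle",
                                            duration_s = 30, noise_sd = 0,
                                            seed = seed))
    expect_gt(peak_amp(dn), peak_amp(up))
  }
})

test_that("TUG trials confine steps to the walking bouts", {
  spec <- synthetic_spec("tug", "ankle", seed = 4)
  sim <- simulate_recording(spec)
  dur <- tail(sim$recording$timestamps, 1)
  expect_gte(dur, 10 - 0.1)
  expect_lte(dur, 15)
  n_bout <- spec$tug$steps_per_bout
  expect_length(sim$truth$step_times, 2 * n_bout)
  # walking bouts sit strictly between the stand-up and turn segments
  bout_len <- 0.3 + n_bout / spec$cadence_hz + 0.2
  w1 <- spec$tug$sit_s + spec$tug$stand_s
  t0 <- spec$tug$sit_s + spec$tug$stand_s
  turn0 <- t0 + bout_len
  w2 <- turn0 + spec$tug$turn_s
  in_bout <- (sim$truth$step_times > w1 & sim$truth$step_times < turn0) |
    (sim$truth$step_times > w2 & sim$truth$step_times < w2 + bout_len)
  expect_true(all(in_bout))

  # sit-stand-sit only: no steps at all, nothing for any detector to match
  empty <- simulate_recording(synthetic_spec("tug", "ankle", seed = 4,
                                             tug = list(steps_per_bout = 0L)))
  expect_length(empty$truth$step_times, 0)
  r <- detect_peaks(empty$recording)
  expect_equal(match_steps(r$step_times, empty$truth$step_times)$TP, 0)
})

test_that("stationary recordings are quiet negative controls", {
  sim <- simulate_recording(synthetic_spec("stationary", "ankle",
                                           duration_s = 20, noise_sd = 0,
                                           seed = 1))
  expect_length(sim$truth$step_times, 0)
  expect_equal(max(abs(sim$recording$gyro)), 0)
  expect_equal(unname(sim$recording$accel[1, ]), c(0, 0, 9.80665))

  # small sensor noise still drives no peak detections: the rolling-SD
  # threshold scales with the noise floor and prominence filters the rest
  noisy <- simulate_recording(synthetic_spec("stationary", "ankle",
                                             duration_s = 20,
                                             noise_sd = 0.05, seed = 1))
  expect_equal(detect_peaks(noisy$recording)$count, 0)
})

test_that("morphology overrides are applied and typos rejected", {
  expect_error(morphology_defaults(nope = 1), "unknown morphology")
  mo <- morphology_defaults(arm_sin_amp = 3.5)
  expect_equal(mo$arm_sin_amp, 3.5)
  spec <- synthetic_spec("natural_walk", "upper_arm", duration_s = 10,
                         noise_sd = 0, seed = 1, morphology = mo)
  sim <- simulate_recording(spec)
  sig <- accel_magnitude(sim$recording$accel)
  expect_gt(max(sig) - median(sig), 3)  # amplitude override visible
})
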