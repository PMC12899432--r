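test_that("peak detection finds steps and respects its constraints", {
  # pure gravity: no maxima above threshold
  rec <- make_rec(rep(0, 1000))
  expect_equal(detect_peaks(rec)$count, 0)

  # noiseless ankle walk at 1.5 Hz for 60 s: one peak per generated
  # heel strike (oracle = the simulator's ground truth)
  sim <- simulate_recording(synthetic_spec("natural_walk", "ankle",
                                           duration_s = 60, cadence_hz = 1.5,
                                           noise_sd = 0, seed = 4))
  expect_length(sim$truth$step_times, 90)
  r <- detect_peaks(sim$recording)
  expect_equal(r$count, 90)
  expect_equal(recovery_f1(r, sim$truth), 1.0)

  # two identical sharp peaks 0.2 s apart collapse under the 0.35 s
  # refractory constraint
  t <- (0:999) / 100
  z <- 3 * exp(-(t - 5.0)^2 / (2 * 0.04^2)) +
    3 * exp(-(t - 5.2)^2 / (2 * 0.04^2))
  rec2 <- make_rec(z)
  r2 <- detect_peaks(rec2, peak_params(smooth_window_s = 0.1))
  expect_equal(r2$count, 1)

  rec_nog <- rec
  rec_nog$accel <- NULL
  expect_error(detect_peaks(rec_nog), "accelerometer")
})

test_that("zero-crossing counts one step per completed hysteresis cycle", {
  expect_equal(detect_zero_crossing(make_rec(rep(0, 1000)))$count, 0)

  t <- (0:999) / 100
  r <- detect_zero_crossing(make_rec(1.0 * sin(2 * pi * 1 * t)))
  expect_equal(r$count, 10)
  # step timestamps sit at the downward zero crossings (t = 0.5, 1.5, ...)
  expect_lt(max(abs(r$step_times - (0:9 + 0.5))), 0.05)

  # amplitude below the band: the signal never exits it
  expect_equal(detect_zero_crossing(make_rec(0.2 * sin(2 * pi * t)))$count, 0)
})

test_that("spectral detector estimates cadence and places uniform steps", {
  # 20 s at a 1.1 Hz dominant gait frequency: round(1.1 * 20) = 22 steps
  t <- (0:1999) / 100
  r <- detect_spectral(make_rec(sin(2 * pi * 1.1 * t)))
  expect_equal(r$count, 22)
  # uniform placement at bin midpoints
  expect_equal(r$step_times, (0:21 + 0.5) * 20 / 22)

  # constant signal: no in-band power, count 0 with a warning
  r0 <- detect_spectral(make_rec(rep(0, 2000)))
  expect_equal(r0$count, 0)
  expect_match(r0$warnings, "no in-band", all = FALSE)

  # closed form count = round(f * T) for a 60 s pure sinusoid
  t60 <- (0:5999) / 100
  expect_equal(detect_spectral(make_rec(sin(2 * pi * 1.5 * t60)))$count, 90)

  # a recording shorter than the window is analysed whole, flagged
  t5 <- (0:499) / 100
  r5 <- detect_spectral(make_rec(sin(2 * pi * 1.5 * t5)))
  expect_match(r5$warnings, "single full-length window", all = FALSE)
  expect_equal(r5$count, round(1.5 * 5))
})

test_that("adaptive threshold retains peaks by relative amplitude", {
  expect_equal(detect_adaptive(make_rec(rep(0, 1000)))$count, 0)

  # alternating 1.0 / 0.2 amplitude pulse train: mean amplitude 0.6, so
  # the 0.5-sensitivity threshold (0.3) keeps only the large pulses
  t <- (0:1999) / 100
  amps <- rep(c(1.0, 0.2), 10)
  centers <- 0.5 + 0:19
  pulse_train <- function(a) {
    z <- numeric(2000)
    for (k in 1:20) z <- z + a[k] * exp(-(t - centers[k])^2 / (2 * 0.15^2))
    z
  }
  r <- detect_adaptive(make_rec(pulse_train(amps)))
  expect_equal(r$count, 10)
  expect_lt(max(abs(r$step_times - centers[amps == 1.0])), 0.1)

  # homogeneous amplitudes: every pulse is at least mean * 0.5
  expect_equal(detect_adaptive(make_rec(pulse_train(rep(1, 20))))$count, 20)
})

test_that("SHOE registers stance-entry transitions and falls back cleanly", {
  # fully stationary: stance throughout, no swing-to-stance transition
  rec0 <- make_rec(rep(0, 1000), gyro = matrix(0, 1000, 3))
  expect_equal(detect_shoe(rec0)$count, 0)

  # simulated ankle gait, quiet stance / gyro-burst swing at 1 Hz, 30 s:
  # one stance entry per stride
  sim <- simulate_recording(synthetic_spec("natural_walk", "ankle",
                                           duration_s = 30, cadence_hz = 1.0,
                                           noise_sd = 0, seed = 3))
  expect_equal(detect_shoe(sim$recording)$count,
               length(sim$truth$step_times))

  # continuous high-variance oscillation leaves no stance window: the
  # fallback peak-detection path is taken and flagged
  t <- (0:1999) / 100
  recf <- make_rec(3 * sin(2 * pi * 5 * t),
                   gyro = cbind(0, 150 + 80 * sin(2 * pi * 5 * t), 0))
  rf <- detect_shoe(recf)
  expect_match(rf$warnings, "fallback", all = FALSE)

  # absent gyroscope: combined signal is the normalized acceleration
  rn <- detect_shoe(make_rec(rep(0, 500)))
  expect_match(rn$warnings, "no gyroscope", all = FALSE)
})

test_that("all detectors emit sorted, in-span, properly spaced step times", {
  sims <- list(
    simulate_recording(synthetic_spec("natural_walk", "ankle",
                                      duration_s = 25, seed = 8)),
    simulate_recording(synthetic_spec("fast_walk", "wrist",
                                      duration_s = 25, seed = 9)),
    simulate_recording(synthetic_spec("tug", "thigh", seed = 10))
  )
  for (sim in sims) {
    rec <- sim$recording
    span <- range(rec$timestamps)
    for (alg in algorithm_names()) {
      r <- detect_steps(rec, alg)
      if (r$count < 2) next
      expect_true(all(diff(r$step_times) > 0))
      expect_gte(min(r$step_times), span[1])
      expect_lte(max(r$step_times), span[2])
      if (alg != "spectral") {
        expect_gte(min(diff(r$step_times)),
                   r$params_used$min_step_interval_s - 1e-9)
      }
    }
  }
})

test_that("detections are equivariant under a time shift", {
  sim <- simulate_recording(synthetic_spec("natural_walk", "upper_arm",
                                           duration_s = 20, seed = 12))
  rec <- sim$recording
  delta <- 3.7
  rec2 <- imu_recording(rec$timestamps + delta, rec$accel, rec$gyro,
                        rec$mag, rec$sampling_rate, rec$meta)
  for (alg in algorithm_names()) {
    t1 <- detect_steps(rec, alg)$step_times
    t2 <- detect_steps(rec2, alg)$step_times
    expect_equal(t2, t1 + delta, tolerance = 1e-9)
  }
})

test_that("SHOE is invariant to positive rescaling of its channels", {
  sim <- simulate_recording(synthetic_spec("natural_walk", "ankle",
                                           duration_s = 20, cadence_hz = 1.0,
                                           noise_sd = 0, seed = 6))
  rec <- sim$recording
  r1 <- detect_shoe(rec)
  rec2 <- imu_recording(rec$timestamps, rec$accel * 1.8, rec$gyro * 0.4,
                        rec$mag, rec$sampling_rate, rec$meta)
  r2 <- detect_shoe(rec2)
  expect_equal(r2$count, r1$count)
  expect_equal(r2$step_times, r1$step_times, tolerance = 0.05)
})
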