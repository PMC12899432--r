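#' Declarative specification of a simulated recording
#'
#' Describes a synthetic gait scenario: what activity is performed, where
#' the sensor is mounted, how long and how fast, how noisy, and under which
#' seed. [simulate_recording()] turns the spec into a 9-axis recording with
#' exact ground-truth step times.
#'
#' Scenario defaults when `cadence_hz`/`duration_s` are omitted: natural
#' walking 1.6 Hz (the dominant gait frequency of typical self-paced level
#' walking) for 60 s, fast walking 2.0 Hz, jogging 2.5 Hz, stairs 1.4 Hz
#' for 30 s, and a Timed Up and Go trial sized so the walking bouts hold
#' 2 x 5 steps in a 10-15 s trial.
#'
#' @param scenario one of `"natural_walk"`, `"fast_walk"`, `"jog"`,
#'   `"stairs_up"`, `"stairs_down"`, `"stairs_combined"`, `"tug"`,
#'   `"stationary"`.
#' @param mounting sensor site: `"ankle"`, `"wrist"`, `"upper_arm"` or
#'   `"thigh"`.
#' @param duration_s recording length in seconds (`NULL` = scenario
#'   default; for TUG the natural segment total).
#' @param cadence_hz step rate in steps per second (`NULL` = scenario
#'   default).
#' @param noise_sd additive Gaussian accelerometer noise, m/s^2 per axis
#'   (gyroscope noise scales as `5 * noise_sd` deg/s).
#' @param seed integer RNG seed; identical specs give bit-identical output.
#' @param sampling_rate sampling rate in Hz (100 by default).
#' @param tug named list of TUG segment overrides: `sit_s`, `stand_s`,
#'   `turn_s`, `steps_per_bout`.
#' @param morphology waveform-shape configuration, see
#'   [morphology_defaults()].
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(scenario = c("natural_walk", "fast_walk", "jog",
                                        "stairs_up", "stairs_down",
                                        "stairs_combined", "tug", "stationary"),
                           mounting = c("ankle", "wrist", "upper_arm", "thigh"),
                           duration_s = NULL, cadence_hz = NULL,
                           noise_sd = 0.15, seed = 1L, sampling_rate = 100,
                           tug = list(), morphology = morphology_defaults()) {
  scenario <- match.arg(scenario)
  mounting <- match.arg(mounting)
  if (is.null(cadence_hz)) {
    cadence_hz <- switch(scenario, fast_walk = 2.0, jog = 2.5,
                         stairs_up = 1.4, stairs_down = 1.4,
                         stairs_combined = 1.4, 1.6)
  }
  tug_def <- list(sit_s = 1.5, stand_s = 0.7, turn_s = 1.5,
                  steps_per_bout = 5L)
  tug_def[names(tug)] <- tug
  if (is.null(duration_s)) {
    duration_s <- switch(scenario,
                         tug = tug_total_duration(tug_def, cadence_hz),
                         stairs_up = 30, stairs_down = 30,
                         stairs_combined = 30, stationary = 30, 60)
  }
  stopifnot(duration_s > 0, cadence_hz > 0, noise_sd >= 0, sampling_rate > 0)
  structure(
    list(scenario = scenario, mounting = mounting, duration_s = duration_s,
         cadence_hz = cadence_hz, noise_sd = noise_sd,
         seed = as.integer(seed), sampling_rate = sampling_rate,
         tug = tug_def, morphology = morphology),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %s @ %s, %.3g s, cadence %.3g Hz, noise %.3g m/s^2, seed %d\n",
              x$scenario, x$mounting, x$duration_s, x$cadence_hz,
              x$noise_sd, x$seed))
  invisible(x)
}

#' Waveform-shape configuration of the simulator
#'
#' One config block holding every invented waveform parameter, so fixtures
#' remain tunable. Lengths tagged `_frac` are fractions of the step period;
#' amplitudes are m/s^2 (accelerometer) or deg/s (gyroscope).
#'
#' The site-specific morphologies emulate the signal families seen in real
#' walking data: the ankle produces a sharp biexponential heel-strike
#' transient preceded by a biphasic swing oscillation and followed by a
#' quiet stance, with a gyroscope burst spanning the swing; the upper arm
#' swings like a pendulum, a near-sinusoid at the step cadence; the wrist
#' adds sporadic low-amplitude gesture artifacts to the arm sinusoid; the
#' thigh (trouser pocket) sees an attenuated impact plus a sinusoid. The
#' oscillatory waveform peaks one eighth of a period before the annotated
#' heel strike (`phase_lead_frac`), placing both the signal maximum and the
#' following downward zero crossing symmetrically around the step time.
#'
#' @param ... overrides of individual defaults, by name.
#' @return Named list of waveform parameters.
#' @export
morphology_defaults <- function(...) {
  m <- list(
    # ankle
    impact_amp = 6.0, impact_rise_s = 0.01, impact_decay_s = 0.04,
    swing_pos_amp = 2.8, swing_neg_amp = 1.2,
    swing_neg_start_frac = -0.55, swing_neg_len_frac = 0.30,
    swing_pos_start_frac = -0.25, swing_pos_len_frac = 0.25,
    ankle_gyro_amp = 180, gyro_start_frac = -0.50, gyro_len_frac = 0.52,
    gyro_ramp_frac = 0.06,
    # sinusoidal sites
    arm_sin_amp = 2.0, wrist_sin_amp = 1.8, thigh_sin_amp = 1.2,
    thigh_impact_amp = 2.5, phase_lead_frac = 0.125,
    arm_gyro_amp = 60, wrist_gyro_amp = 80, thigh_gyro_amp = 40,
    # wrist gesture artifacts
    gesture_amp = 0.15, gesture_rate_hz = 0.05, gesture_sd_s = 0.08,
    # timing jitter around the cadence grid
    jitter_sd_frac = 0.02, jitter_clamp_frac = 0.04,
    # scenario amplitude multipliers
    fast_mult = 1.2, jog_mult = 1.8, stairs_up_mult = 0.85,
    stairs_down_mult = 1.25,
    # TUG transients / turning
    stand_amp = 4.0, turn_accel_amp = 0.5, turn_gyro_amp = 120,
    # cross-axis leakage of the vertical waveform
    cross_axis = c(0.2, 0.1)
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(m))
    if (length(bad)) stop("unknown morphology parameter(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    m[names(ov)] <- ov
  }
  m
}

# ---- kernel builders (all add in place into a preallocated vector) -------

add_half_sine <- function(w, t, t0, len, amp) {
  idx <- which(t >= t0 & t <= t0 + len)
  if (length(idx)) w[idx] <- w[idx] + amp * sin(pi * (t[idx] - t0) / len)
  w
}

# Hann-shaped lobe: like a half-sine but with zero slope at both ends, so
# smoothing filters do not ring at the lobe boundaries
add_hann_lobe <- function(w, t, t0, len, amp) {
  idx <- which(t >= t0 & t <= t0 + len)
  if (length(idx)) {
    w[idx] <- w[idx] + amp * 0.5 * (1 - cos(2 * pi * (t[idx] - t0) / len))
  }
  w
}

add_impact <- function(w, t, t0, amp, rise, decay) {
  idx <- which(t >= t0 & t <= t0 + 10 * decay)
  if (length(idx)) {
    u <- t[idx] - t0
    tm <- rise * decay / (decay - rise) * log(decay / rise)
    vmax <- exp(-tm / decay) - exp(-tm / rise)
    w[idx] <- w[idx] + (amp / vmax) * (exp(-u / decay) - exp(-u / rise))
  }
  w
}

# one full cosine period centred at `center`: abutting kernels on an exact
# grid tile into a continuous sinusoid, and gate themselves off outside the
# walking span
add_cos_period <- function(w, t, center, period, amp) {
  idx <- which(t >= center - period / 2 & t < center + period / 2)
  if (length(idx)) {
    w[idx] <- w[idx] + amp * cos(2 * pi * (t[idx] - center) / period)
  }
  w
}

add_plateau <- function(w, t, t0, len, amp, ramp) {
  idx <- which(t >= t0 & t <= t0 + len)
  if (length(idx)) {
    u <- t[idx] - t0
    env <- rep(1, length(u))
    up <- u < ramp
    dn <- u > len - ramp
    env[up] <- 0.5 * (1 - cos(pi * u[up] / ramp))
    env[dn] <- 0.5 * (1 - cos(pi * (len - u[dn]) / ramp))
    w[idx] <- w[idx] + amp * env
  }
  w
}

add_gauss <- function(w, t, t0, sd, amp) {
  idx <- which(abs(t - t0) <= 4 * sd)
  if (length(idx)) {
    w[idx] <- w[idx] + amp * exp(-(t[idx] - t0)^2 / (2 * sd^2))
  }
  w
}

# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# jittered step times around the cadence grid: Gaussian perturbation of
# each grid slot (SD = jitter_sd_frac of the period) clamped to +/- 2 SD so
# ordering and the >= 0.8 * period spacing bound are preserved by
# construction
jitter_times <- function(grid, period, morph, lo, hi) {
  if (!length(grid)) return(numeric(0))
  e <- rnorm(length(grid), 0, morph$jitter_sd_frac * period)
  cl <- morph$jitter_clamp_frac * period
  pmin(pmax(grid + pmin(pmax(e, -cl), cl), lo), hi)
}

scenario_mult <- function(scenario, morph) {
  switch(scenario,
         fast_walk = morph$fast_mult, jog = morph$jog_mult,
         stairs_up = morph$stairs_up_mult,
         stairs_down = morph$stairs_down_mult, 1)
}

# accelerometer + gyroscope waveform of a walking span: kernels are placed
# per step so bouts gate themselves; `step_times` carry the (jittered)
# ground truth, `grid` the nominal slots driving the oscillatory component
walk_waveform <- function(t, step_times, grid, period, mounting, morph,
                          mult) {
  w <- numeric(length(t))
  g <- numeric(length(t))
  if (!length(step_times)) return(list(accel = w, gyro = g))
  if (length(mult) == 1L) mult <- rep(mult, length(step_times))
  lead <- morph$phase_lead_frac * period
  for (k in seq_along(step_times)) {
    tk <- step_times[k]
    gk <- grid[k]
    m <- mult[k]
    if (mounting == "ankle") {
      w <- add_hann_lobe(w, t, tk + morph$swing_neg_start_frac * period,
                         morph$swing_neg_len_frac * period,
                         -morph$swing_neg_amp * m)
      w <- add_hann_lobe(w, t, tk + morph$swing_pos_start_frac * period,
                         morph$swing_pos_len_frac * period,
                         morph$swing_pos_amp * m)
      w <- add_impact(w, t, tk, morph$impact_amp * m,
                      morph$impact_rise_s, morph$impact_decay_s)
      g <- add_plateau(g, t, tk + morph$gyro_start_frac * period,
                       morph$gyro_len_frac * period,
                       morph$ankle_gyro_amp * m,
                       morph$gyro_ramp_frac * period)
    } else {
      sin_amp <- switch(mounting, upper_arm = morph$arm_sin_amp,
                        wrist = morph$wrist_sin_amp,
                        thigh = morph$thigh_sin_amp)
      gyro_amp <- switch(mounting, upper_arm = morph$arm_gyro_amp,
                         wrist = morph$wrist_gyro_amp,
                         thigh = morph$thigh_gyro_amp)
      w <- add_cos_period(w, t, gk - lead, period, sin_amp * m)
      g <- add_cos_period(g, t, gk - lead, period, gyro_amp * m)
      if (mounting == "thigh") {
        w <- add_impact(w, t, tk, morph$thigh_impact_amp * m,
                        morph$impact_rise_s, morph$impact_decay_s)
      }
    }
  }
  list(accel = w, gyro = g)
}

assemble_recording <- function(spec, t, accel_wave, gyro_wave, truth_times) {
  n <- length(t)
  ca <- spec$morphology$cross_axis
  noise <- function(sd) if (sd > 0) rnorm(n, 0, sd) else numeric(n)
  accel <- cbind(ca[1] * accel_wave + noise(spec$noise_sd),
                 ca[2] * accel_wave + noise(spec$noise_sd),
                 STANDARD_GRAVITY + accel_wave + noise(spec$noise_sd))
  gyro <- cbind(0.2 * gyro_wave + noise(5 * spec$noise_sd),
                gyro_wave + noise(5 * spec$noise_sd),
                0.1 * gyro_wave + noise(5 * spec$noise_sd))
  mag <- cbind(20 + noise(spec$noise_sd), 1 + noise(spec$noise_sd),
               -43 + noise(spec$noise_sd))
  rec <- imu_recording(t, accel, gyro, mag,
                       sampling_rate = spec$sampling_rate,
                       meta = list(scenario = spec$scenario,
                                   mounting = spec$mounting,
                                   cadence_hz = spec$cadence_hz,
                                   seed = spec$seed))
  list(recording = rec,
       truth = ground_truth(truth_times, source = "simulated"))
}

#' Simulate an IMU recording with ground truth
#'
#' Generates a seeded 9-axis recording for the scenario in `spec` together
#' with the exact step times used to build it. Walking-type scenarios place
#' `round(cadence * duration)` steps on a jittered cadence grid and render
#' the mounting-specific waveform around each (see
#' [morphology_defaults()]); stair scenarios scale amplitudes down for
#' ascent and up for descent (gravitational assistance raises descent
#' impacts); jogging raises amplitude and cadence; `"tug"` produces the
#' sit - stand - walk - turn - walk - sit activity sequence with steps only
#' inside the walking bouts; `"stationary"` is gravity plus noise with an
#' empty ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `recording` ([imu_recording()]) and `truth`
#'   ([ground_truth()]).
#' @examples
#' sim <- simulate_recording(synthetic_spec("natural_walk", "upper_arm",
#'                                          duration_s = 30, seed = 7))
#' length(sim$truth$step_times)
#' @export
simulate_recording <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("spec must be a synthetic_spec", call. = FALSE)
  }
  with_seed(spec$seed, {
    switch(spec$scenario,
           stationary = simulate_stationary_impl(spec),
           tug = simulate_tug_impl(spec),
           simulate_walk_impl(spec))
  })
}

simulate_walk_impl <- function(spec) {
  rate <- spec$sampling_rate
  d <- spec$duration_s
  cad <- spec$cadence_hz
  period <- 1 / cad
  morph <- spec$morphology
  n <- round(d * rate)
  t <- (0:(n - 1L)) / rate
  k <- 0:ceiling(d * cad + 1)
  grid <- (k + 0.5) / cad
  grid <- grid[grid < d]
  steps <- jitter_times(grid, period, morph, 0.02, d - 0.02)
  mult <- scenario_mult(spec$scenario, morph)
  if (spec$scenario == "stairs_combined") {
    half <- length(steps) %/% 2
    mult <- c(rep(morph$stairs_up_mult, half),
              rep(morph$stairs_down_mult, length(steps) - half))
  }
  wf <- walk_waveform(t, steps, grid, period, spec$mounting, morph, mult)
  if (spec$mounting == "wrist") {
    n_g <- rpois(1, morph$gesture_rate_hz * d)
    if (n_g > 0) {
      centers <- runif(n_g, 0, d)
      signs <- sample(c(-1, 1), n_g, replace = TRUE)
      for (i in seq_len(n_g)) {
        wf$accel <- add_gauss(wf$accel, t, centers[i], morph$gesture_sd_s,
                              signs[i] * morph$gesture_amp)
      }
    }
  }
  assemble_recording(spec, t, wf$accel, wf$gyro, steps)
}

tug_total_duration <- function(tug, cadence) {
  bout <- 0.3 + tug$steps_per_bout / cadence + 0.2
  tug$sit_s + tug$stand_s + bout + tug$turn_s + bout + tug$stand_s +
    tug$sit_s
}

simulate_tug_impl <- function(spec) {
  rate <- spec$sampling_rate
  cad <- spec$cadence_hz
  period <- 1 / cad
  morph <- spec$morphology
  tug <- spec$tug
  needed <- tug_total_duration(tug, cad)
  d <- max(spec$duration_s, needed)
  n <- round(d * rate)
  t <- (0:(n - 1L)) / rate
  bout_len <- 0.3 + tug$steps_per_bout / cad + 0.2
  stand1 <- tug$sit_s
  walk1 <- stand1 + tug$stand_s
  turn0 <- walk1 + bout_len
  walk2 <- turn0 + tug$turn_s
  sitdn <- walk2 + bout_len
  accel <- numeric(n)
  gyro <- numeric(n)
  # sit-to-stand / stand-to-sit vertical transients
  accel <- add_half_sine(accel, t, stand1, tug$stand_s, morph$stand_amp)
  accel <- add_half_sine(accel, t, sitdn, tug$stand_s, -morph$stand_amp * 0.8)
  # turning: rotational burst with low-amplitude irregular acceleration
  accel <- add_plateau(accel, t, turn0, tug$turn_s,
                       morph$turn_accel_amp, 0.3)
  gyro <- add_plateau(gyro, t, turn0, tug$turn_s, morph$turn_gyro_amp, 0.3)
  steps_all <- numeric(0)
  for (b0 in c(walk1, walk2)) {
    if (tug$steps_per_bout < 1L) next
    grid <- b0 + 0.3 + (seq_len(tug$steps_per_bout) - 0.5) / cad
    steps <- jitter_times(grid, period, morph, b0 + 0.05,
                          b0 + bout_len - 0.05)
    wf <- walk_waveform(t, steps, grid, period, spec$mounting, morph, 1)
    accel <- accel + wf$accel
    gyro <- gyro + wf$gyro
    steps_all <- c(steps_all, steps)
  }
  assemble_recording(spec, t, accel, gyro, steps_all)
}

simulate_stationary_impl <- function(spec) {
  n <- round(spec$duration_s * spec$sampling_rate)
  t <- (0:(n - 1L)) / spec$sampling_rate
  assemble_recording(spec, t, numeric(n), numeric(n), numeric(0))
}
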