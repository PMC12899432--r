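#' Detect steps with a chosen algorithm
#'
#' Dispatcher over the five detectors. All detectors are deterministic,
#' never modify the input recording, and return step times that are sorted,
#' unique and inside the recording span. Except for the spectral detector
#' (whose uniformly placed times are governed by the estimated cadence),
#' consecutive detections are at least `min_step_interval_s` apart.
#'
#' @param rec an [imu_recording()].
#' @param algorithm one of `"peak"`, `"zero_crossing"`, `"spectral"`,
#'   `"adaptive"`, `"shoe"`.
#' @param params a matching parameter set (see [peak_params()] and friends);
#'   defaults are used when `NULL`.
#' @return A `step_result` with elements `step_times`, `count`,
#'   `algorithm`, `params_used` and `warnings`.
#' @examples
#' spec <- synthetic_spec("natural_walk", "ankle", duration_s = 30,
#'                        noise_sd = 0, seed = 1)
#' sim <- simulate_recording(spec)
#' detect_steps(sim$recording, "peak")
#' @export
detect_steps <- function(rec, algorithm = algorithm_names(), params = NULL) {
  algorithm <- match.arg(algorithm)
  fn <- switch(algorithm,
               peak = detect_peaks, zero_crossing = detect_zero_crossing,
               spectral = detect_spectral, adaptive = detect_adaptive,
               shoe = detect_shoe)
  if (is.null(params)) fn(rec) else fn(rec, params)
}

check_recording <- function(rec) {
  if (!inherits(rec, "imu_recording")) {
    stop("rec must be an imu_recording", call. = FALSE)
  }
  if (is.null(rec$accel)) stop("recording has no accelerometer data", call. = FALSE)
  invisible(rec)
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Peak-detection step detector
#'
#' Identifies steps as local maxima of the preprocessed acceleration
#' magnitude. A candidate is retained when its height exceeds a point-wise
#' adaptive threshold -- the rolling standard deviation over
#' `rolling_sd_window_s` (shrunk at the signal edges) times
#' `threshold_multiplier` -- and its topographic prominence reaches
#' `prominence`. Retained candidates are thinned to the minimum inter-step
#' interval, keeping the higher peak on conflict.
#'
#' @inheritParams detect_steps
#' @param p parameters from [peak_params()].
#' @return A `step_result`.
#' @export
detect_peaks <- function(rec, p = peak_params()) {
  check_recording(rec)
  sig <- preprocess_signal(rec, p$smooth_window_s, p$sg_order)
  res <- peak_core(sig, rec$timestamps, rec$sampling_rate, p)
  new_step_result(res, "peak", p, rec)
}

# Peak-detection logic on an arbitrary preprocessed signal; reused by the
# SHOE fallback path.
peak_core <- function(sig, timestamps, rate, p) {
  thr <- rolling_sd(sig, round(p$rolling_sd_window_s * rate)) *
    p$threshold_multiplier
  cand <- local_maxima(sig)
  cand <- cand[sig[cand] > thr[cand]]
  if (length(cand)) {
    cand <- cand[peak_prominence(sig, cand) >= p$prominence]
  }
  if (!length(cand)) return(numeric(0))
  keep <- thin_by_spacing(timestamps[cand], sig[cand],
                          p$min_step_interval_s)
  timestamps[cand[keep]]
}

#' Hysteresis zero-crossing step detector
#'
#' Registers one step per completed hysteresis cycle of the centred
#' acceleration magnitude: the signal must rise above `+hysteresis_band`,
#' and subsequently fall below `-hysteresis_band`; the step timestamp is
#' the (linearly interpolated) downward crossing of zero between the two
#' excursions. An inhibition period of `min_step_interval_s` follows each
#' registered detection.
#'
#' @inheritParams detect_steps
#' @param p parameters from [zero_crossing_params()].
#' @return A `step_result`.
#' @export
detect_zero_crossing <- function(rec, p = zero_crossing_params()) {
  check_recording(rec)
  sig <- preprocess_signal(rec, p$smooth_window_s, p$sg_order)
  band <- p$hysteresis_band
  ts <- rec$timestamps
  n <- length(sig)
  state <- "idle"
  tc <- NA_real_
  last <- -Inf
  times <- numeric(0)
  for (i in seq_len(n)) {
    if (state == "idle") {
      if (sig[i] >= band) state <- "above"
    } else {
      if (i > 1L && sig[i - 1L] > 0 && sig[i] <= 0) {
        # downward zero crossing; while waiting for the -band confirmation
        # a later crossing supersedes the earlier one
        frac <- sig[i - 1L] / (sig[i - 1L] - sig[i])
        tc <- ts[i - 1L] + frac * (ts[i] - ts[i - 1L])
        state <- "crossed"
      }
      if (state == "crossed" && sig[i] >= band) {
        state <- "above"
      } else if (state == "crossed" && sig[i] <= -band) {
        if (tc - last >= p$min_step_interval_s) {
          times <- c(times, tc)
          last <- tc
        }
        state <- "idle"
      }
    }
  }
  new_step_result(times, "zero_crossing", p, rec)
}

#' Spectral (STFT) step detector
#'
#' Estimates the cadence in the frequency domain. The median-centred
#' acceleration magnitude is analysed with overlapping Hann windows of
#' `window_s` seconds (hop `window_s * (1 - overlap)`); for every window
#' the dominant frequency is the power-spectrum maximum restricted to
#' `freq_range`, located with sub-bin resolution on a zero-padded FFT.
#' The cadence is the median of the per-window dominants, the step count
#' is `round(cadence * duration)` (half away from zero), and step times are
#' placed uniformly at the midpoints of `count` equal bins. Windows without
#' in-band power contribute nothing; if no window has in-band power the
#' count is 0 and a warning is recorded. Recordings shorter than one window
#' are analysed as a single full-length window, also flagged.
#'
#' @inheritParams detect_steps
#' @param p parameters from [spectral_params()].
#' @return A `step_result`; `params_used$window_samples` reports the
#'   realized STFT window length in samples.
#' @export
detect_spectral <- function(rec, p = spectral_params()) {
  check_recording(rec)
  warnings <- character()
  rate <- rec$sampling_rate
  mag <- accel_magnitude(rec$accel)
  sig <- mag - median(mag)
  n <- length(sig)
  wlen <- round(p$window_s * rate)
  if (wlen > n) {
    wlen <- n
    warnings <- c(warnings,
                  "recording shorter than the analysis window; using a single full-length window")
  }
  hop <- max(1L, round(wlen * (1 - p$overlap)))
  starts <- seq(1L, n - wlen + 1L, by = hop)
  han <- if (wlen > 1L) {
    0.5 * (1 - cos(2 * pi * (0:(wlen - 1L)) / (wlen - 1L)))
  } else 1
  nfft <- 2^ceiling(log2(max(wlen * 64, 1024)))
  freqs <- (0:(nfft / 2)) * rate / nfft
  band <- which(freqs >= p$freq_range[1] & freqs <= p$freq_range[2])
  doms <- numeric(0)
  for (s in starts) {
    xw <- sig[s:(s + wlen - 1L)] * han
    pw <- Mod(fft(c(xw, rep(0, nfft - wlen))))[seq_len(nfft / 2 + 1)]^2
    if (max(pw[band]) <= 1e-20) next  # no in-band power (e.g. constant input)
    doms <- c(doms, freqs[band[which.max(pw[band])]])
  }
  duration <- n / rate
  p_used <- p
  p_used$window_samples <- wlen
  if (!length(doms)) {
    return(new_step_result(numeric(0), "spectral", p_used, rec,
                           c(warnings, "no in-band spectral power; step count is 0")))
  }
  cadence <- median(doms)
  count <- round_half_away(cadence * duration)
  p_used$cadence_hz <- cadence
  times <- if (count >= 1) {
    rec$timestamps[1] + (seq_len(count) - 0.5) * duration / count
  } else numeric(0)
  new_step_result(times, "spectral", p_used, rec, warnings)
}

#' Adaptive amplitude-threshold step detector
#'
#' Two-phase detection: first all local maxima of the preprocessed
#' magnitude are collected regardless of height; each candidate's amplitude
#' is the peak value minus the minimum within a centred window of
#' `amplitude_window_s`. The retention threshold adapts to the signal as
#' `mean(amplitudes) * sensitivity`; surviving candidates are thinned to
#' the minimum inter-step interval, keeping the larger amplitude on
#' conflict (ties to the earlier peak).
#'
#' @inheritParams detect_steps
#' @param p parameters from [adaptive_params()].
#' @return A `step_result`; an input with no local maxima yields an empty
#'   result, not an error.
#' @export
detect_adaptive <- function(rec, p = adaptive_params()) {
  check_recording(rec)
  sig <- preprocess_signal(rec, p$smooth_window_s, p$sg_order)
  # numerically flat input (e.g. pure gravity): no motion, no candidates
  if (max(sig) - min(sig) < 1e-9) {
    return(new_step_result(numeric(0), "adaptive", p, rec))
  }
  cand <- local_maxima(sig)
  if (!length(cand)) {
    return(new_step_result(numeric(0), "adaptive", p, rec))
  }
  h <- max(1L, round(p$amplitude_window_s * rec$sampling_rate / 2))
  amp <- vapply(cand, function(i) {
    lo <- max(1L, i - h)
    hi <- min(length(sig), i + h)
    sig[i] - min(sig[lo:hi])
  }, numeric(1))
  thr <- mean(amp) * p$sensitivity
  keep <- amp >= thr
  cand <- cand[keep]
  amp <- amp[keep]
  if (!length(cand)) {
    return(new_step_result(numeric(0), "adaptive", p, rec))
  }
  sel <- thin_by_spacing(rec$timestamps[cand], amp, p$min_step_interval_s)
  new_step_result(rec$timestamps[cand[sel]], "adaptive", p, rec)
}

#' SHOE stance-phase step detector
#'
#' Fuses accelerometer and gyroscope magnitudes to find stance phases, when
#' a foot-mounted sensor is momentarily stationary. Both magnitudes are
#' smoothed and min-max normalized to `[0, 1]`; the combined signal is
#' `accel_weight * accel_n + gyro_weight * gyro_n`. A sliding window of
#' `stance_window_s` is classified as stance when the stance statistic
#' (see [shoe_params()]) is below `threshold`; one step is registered at
#' each transition from non-stance into stance (stance at the very start of
#' the recording is not a transition), thinned to the minimum interval.
#'
#' Two degraded paths are flagged in `warnings`: without a gyroscope the
#' combined signal is the normalized acceleration alone, and when no stance
#' window exists at all the detector falls back to peak detection on the
#' combined signal.
#'
#' @inheritParams detect_steps
#' @param p parameters from [shoe_params()].
#' @return A `step_result`.
#' @export
detect_shoe <- function(rec, p = shoe_params()) {
  check_recording(rec)
  warnings <- character()
  rate <- rec$sampling_rate
  minmax <- function(x) {
    rng <- max(x) - min(x)
    # a numerically flat channel carries no motion information
    if (rng <= 1e-9 * max(abs(x), 1)) rep(0, length(x)) else
      (x - min(x)) / rng
  }
  smooth_if_possible <- function(x) {
    if (length(x) >= p$sg_order + 2) {
      sg_smooth(x, p$smooth_window_s, rate, p$sg_order)
    } else x
  }
  an <- minmax(smooth_if_possible(accel_magnitude(rec$accel)))
  if (is.null(rec$gyro)) {
    warnings <- c(warnings,
                  "no gyroscope channel; combined signal is normalized acceleration only")
    gn <- rep(0, length(an))
    comb <- an
  } else {
    gn <- minmax(smooth_if_possible(sqrt(rowSums(rec$gyro^2))))
    comb <- p$accel_weight * an + p$gyro_weight * gn
  }
  win <- max(2L, round(p$stance_window_s * rate))
  stat <- p$var_scale * rolling_var(comb, win) +
    p$gyro_scale * rolling_mean(gn, win)
  stance <- stat < p$threshold
  if (!any(stance)) {
    warnings <- c(warnings,
                  "no stance phase detected; fallback to peak detection on the combined signal")
    pk <- peak_params(smooth_window_s = p$smooth_window_s,
                      min_step_interval_s = p$min_step_interval_s,
                      sg_order = p$sg_order)
    times <- peak_core(comb - median(comb), rec$timestamps, rate, pk)
    return(new_step_result(times, "shoe", p, rec, warnings))
  }
  onset <- which(stance & !c(TRUE, stance[-length(stance)]))
  times <- rec$timestamps[onset]
  if (length(times)) {
    # sequential refractory: keep the first onset, suppress followers
    kept <- times[1]
    for (tt in times[-1]) {
      if (tt - kept[length(kept)] >= p$min_step_interval_s) kept <- c(kept, tt)
    }
    times <- kept
  }
  new_step_result(times, "shoe", p, rec, warnings)
}
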