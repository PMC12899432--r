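#' Detector parameter sets
#'
#' One constructor per algorithm, with defaults fixed to the universal
#' configuration used for validation (no scenario-specific tuning). Windows
#' and intervals are in seconds, the hysteresis band in m/s^2, thresholds
#' are dimensionless. Some descriptions in the literature quote looser
#' values (peak minimum distance 0.3 s, a 5 s/50% spectral window over
#' 1.0-2.5 Hz, adaptive sensitivity 0.6 over a ~1 s window, a ~0.2 s stance
#' window); the defaults here are the validated set and the alternatives
#' remain reachable through the arguments.
#'
#' @param smooth_window_s Savitzky-Golay smoothing window in seconds.
#' @param threshold_multiplier multiplier applied to the 2 s rolling
#'   standard deviation to form the point-wise peak height threshold.
#' @param min_step_interval_s minimum time between detected steps;
#'   caps the detectable cadence at `60/min_step_interval_s` steps/min.
#' @param rolling_sd_window_s window of the rolling standard deviation used
#'   for the adaptive peak threshold.
#' @param prominence minimum topographic prominence of a retained peak.
#' @param sg_order Savitzky-Golay polynomial order (advanced; order 3
#'   preserves peak shape).
#' @return A named list of class `detector_params`.
#' @name detector_params
NULL

new_detector_params <- function(algorithm, fields) {
  structure(c(list(algorithm = algorithm), fields),
            class = c(paste0(algorithm, "_params"), "detector_params"))
}

#' @rdname detector_params
#' @export
peak_params <- function(smooth_window_s = 0.6, threshold_multiplier = 0.5,
                        min_step_interval_s = 0.35, rolling_sd_window_s = 2.0,
                        prominence = 0.2, sg_order = 3L) {
  stopifnot(smooth_window_s > 0, threshold_multiplier > 0,
            min_step_interval_s > 0, rolling_sd_window_s > 0,
            prominence >= 0, sg_order >= 1)
  new_detector_params("peak", list(
    smooth_window_s = smooth_window_s,
    threshold_multiplier = threshold_multiplier,
    min_step_interval_s = min_step_interval_s,
    rolling_sd_window_s = rolling_sd_window_s,
    prominence = prominence, sg_order = as.integer(sg_order)))
}

#' @rdname detector_params
#' @param hysteresis_band symmetric threshold band in m/s^2 that the centred
#'   signal must fully traverse (above `+band`, then below `-band`) before a
#'   crossing is registered.
#' @export
zero_crossing_params <- function(smooth_window_s = 0.5,
                                 min_step_interval_s = 0.4,
                                 hysteresis_band = 0.3, sg_order = 3L) {
  stopifnot(smooth_window_s > 0, min_step_interval_s > 0,
            hysteresis_band > 0, sg_order >= 1)
  new_detector_params("zero_crossing", list(
    smooth_window_s = smooth_window_s,
    min_step_interval_s = min_step_interval_s,
    hysteresis_band = hysteresis_band, sg_order = as.integer(sg_order)))
}

#' @rdname detector_params
#' @param window_s STFT analysis window length in seconds.
#' @param overlap window overlap ratio in `[0, 1)`.
#' @param freq_range two-element numeric, the physiological gait band in Hz
#'   within which the dominant frequency is sought.
#' @export
spectral_params <- function(window_s = 8.0, overlap = 0.8,
                            freq_range = c(0.8, 2.0)) {
  stopifnot(window_s > 0, overlap >= 0, overlap < 1,
            length(freq_range) == 2L, freq_range[1] < freq_range[2],
            freq_range[1] > 0)
  new_detector_params("spectral", list(
    window_s = window_s, overlap = overlap, freq_range = freq_range))
}

#' @rdname detector_params
#' @param amplitude_window_s centred window within which the local minimum
#'   is taken when computing a candidate peak's amplitude.
#' @param sensitivity multiplier on the mean candidate amplitude forming the
#'   retention threshold.
#' @export
adaptive_params <- function(amplitude_window_s = 0.8, sensitivity = 0.5,
                            min_step_interval_s = 0.4, smooth_window_s = 0.5,
                            sg_order = 3L) {
  stopifnot(amplitude_window_s > 0, sensitivity > 0, min_step_interval_s > 0,
            smooth_window_s > 0, sg_order >= 1)
  new_detector_params("adaptive", list(
    amplitude_window_s = amplitude_window_s, sensitivity = sensitivity,
    min_step_interval_s = min_step_interval_s,
    smooth_window_s = smooth_window_s, sg_order = as.integer(sg_order)))
}

#' @rdname detector_params
#' @param stance_window_s sliding-window length for stance classification.
#' @param threshold stance statistic threshold: a window is stance when
#'   `var_scale * var(combined) + gyro_scale * mean(normalized gyro)` falls
#'   below it. The statistic operates on the min-max normalized signals; the
#'   two scale factors encode the "low acceleration variance AND low angular
#'   rate" condition as a single score and are exposed because the exact
#'   mapping is a convention of this implementation.
#' @param accel_weight,gyro_weight weights of the normalized accelerometer
#'   and gyroscope magnitudes in the combined signal; must sum to 1.
#' @param var_scale,gyro_scale scale factors of the stance statistic.
#' @export
shoe_params <- function(stance_window_s = 0.3, threshold = 9.0,
                        min_step_interval_s = 0.35, accel_weight = 0.7,
                        gyro_weight = 0.3, var_scale = 1000, gyro_scale = 30,
                        smooth_window_s = 0.5, sg_order = 3L) {
  stopifnot(stance_window_s > 0, threshold > 0, min_step_interval_s > 0,
            accel_weight >= 0, gyro_weight >= 0,
            abs(accel_weight + gyro_weight - 1) < 1e-9,
            var_scale > 0, gyro_scale > 0, smooth_window_s > 0, sg_order >= 1)
  new_detector_params("shoe", list(
    stance_window_s = stance_window_s, threshold = threshold,
    min_step_interval_s = min_step_interval_s, accel_weight = accel_weight,
    gyro_weight = gyro_weight, var_scale = var_scale,
    gyro_scale = gyro_scale, smooth_window_s = smooth_window_s,
    sg_order = as.integer(sg_order)))
}

#' @export
print.detector_params <- function(x, ...) {
  cat(sprintf("<%s_params>\n", x$algorithm))
  for (nm in setdiff(names(x), "algorithm")) {
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

default_params <- function(algorithm) {
  switch(algorithm,
         peak = peak_params(),
         zero_crossing = zero_crossing_params(),
         spectral = spectral_params(),
         adaptive = adaptive_params(),
         shoe = shoe_params(),
         stop(sprintf("unknown algorithm '%s'", algorithm), call. = FALSE))
}

#' Names of the available detection algorithms
#' @return Character vector of algorithm identifiers.
#' @export
algorithm_names <- function() {
  c("peak", "zero_crossing", "spectral", "adaptive", "shoe")
}
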