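#' IMU recording object
#'
#' Container for a uniformly sampled multi-axis inertial time series. The
#' accelerometer is mandatory and includes gravity; gyroscope and
#' magnetometer channels are optional. Timestamps are seconds from the start
#' of the recording and must be near-uniform: the median inter-sample
#' interval has to agree with `1/sampling_rate` to within 5%.
#'
#' @param timestamps numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param accel N x 3 numeric matrix of accelerometer readings in m/s^2
#'   (gravity included), columns x, y, z.
#' @param gyro optional N x 3 matrix of gyroscope readings in deg/s.
#' @param mag optional N x 3 matrix of magnetometer readings (unused by the
#'   detectors, carried for completeness).
#' @param sampling_rate sampling frequency in Hz.
#' @param meta named list of free-form metadata (sensor id, mounting
#'   location, scenario label, ...).
#'
#' @return An object of class `imu_recording`.
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' acc <- cbind(0, 0, 9.81 + sin(2 * pi * 1.6 * t))
#' rec <- imu_recording(t, acc, sampling_rate = 100)
#' rec
#' @export
imu_recording <- function(timestamps, accel, gyro = NULL, mag = NULL,
                          sampling_rate, meta = list()) {
  timestamps <- as.numeric(timestamps)
  accel <- as_channel_matrix(accel, "accel")
  n <- length(timestamps)
  if (n < 1L) stop("recording must contain at least one sample", call. = FALSE)
  if (!all(is.finite(timestamps))) {
    stop("timestamps must be finite", call. = FALSE)
  }
  if (nrow(accel) != n) {
    stop("accel must have one row per timestamp", call. = FALSE)
  }
  if (!all(is.finite(accel))) stop("accel values must be finite", call. = FALSE)
  if (!is.null(gyro)) {
    gyro <- as_channel_matrix(gyro, "gyro")
    if (nrow(gyro) != n) stop("gyro must have one row per timestamp", call. = FALSE)
    if (!all(is.finite(gyro))) stop("gyro values must be finite", call. = FALSE)
  }
  if (!is.null(mag)) {
    mag <- as_channel_matrix(mag, "mag")
    if (nrow(mag) != n) stop("mag must have one row per timestamp", call. = FALSE)
    if (!all(is.finite(mag))) stop("mag values must be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number", call. = FALSE)
  }
  if (n > 1L) {
    dt <- diff(timestamps)
    if (any(dt <= 0)) {
      stop("timestamps must be strictly increasing", call. = FALSE)
    }
    if (abs(median(dt) - 1 / sampling_rate) > 0.05 / sampling_rate) {
      stop("median inter-sample interval deviates more than 5% from 1/sampling_rate",
           call. = FALSE)
    }
  }
  structure(
    list(timestamps = timestamps, accel = accel, gyro = gyro, mag = mag,
         sampling_rate = sampling_rate, meta = meta),
    class = "imu_recording"
  )
}

as_channel_matrix <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) {
    stop(sprintf("%s must have 3 columns (x, y, z)", what), call. = FALSE)
  }
  storage.mode(x) <- "double"
  colnames(x) <- c("x", "y", "z")
  x
}

#' @export
print.imu_recording <- function(x, ...) {
  n <- length(x$timestamps)
  cat(sprintf("<imu_recording> %d samples @ %.6g Hz (%.2f s)\n",
              n, x$sampling_rate, x$timestamps[n] - x$timestamps[1]))
  cat(sprintf("  channels: accel%s%s\n",
              if (!is.null(x$gyro)) " + gyro" else "",
              if (!is.null(x$mag)) " + mag" else ""))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ground-truth step annotations
#'
#' Reference step times for one recording, either manually annotated or
#' produced by the simulator.
#'
#' @param step_times numeric vector of step times in seconds, strictly
#'   increasing.
#' @param source one of `"manual_annotation"` or `"simulated"`.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(step_times, source = c("manual_annotation", "simulated")) {
  source <- match.arg(source)
  step_times <- as.numeric(step_times)
  if (length(step_times)) {
    if (!all(is.finite(step_times))) {
      stop("ground-truth step times must be finite", call. = FALSE)
    }
    if (any(diff(step_times) <= 0)) {
      stop("ground-truth step times must be strictly increasing", call. = FALSE)
    }
  }
  structure(list(step_times = step_times, source = source),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d steps (%s)\n",
              length(x$step_times), x$source))
  invisible(x)
}

# Internal constructor shared by all detectors; enforces the common result
# invariants (ordering, span containment).
new_step_result <- function(step_times, algorithm, params_used, rec,
                            warnings = character()) {
  step_times <- as.numeric(step_times)
  if (length(step_times)) {
    if (any(diff(step_times) <= 0)) {
      stop("internal error: step times not strictly increasing", call. = FALSE)
    }
    t0 <- rec$timestamps[1]
    t1 <- rec$timestamps[length(rec$timestamps)]
    if (step_times[1] < t0 - 1e-9 || step_times[length(step_times)] > t1 + 1e-9) {
      stop("internal error: step time outside recording span", call. = FALSE)
    }
  }
  structure(
    list(step_times = step_times, count = length(step_times),
         algorithm = algorithm, params_used = params_used,
         warnings = warnings),
    class = "step_result"
  )
}

#' @export
print.step_result <- function(x, ...) {
  cat(sprintf("<step_result> %s: %d steps\n", x$algorithm, x$count))
  if (x$count) {
    shown <- head(x$step_times, 6L)
    cat("  times:", paste(sprintf("%.2f", shown), collapse = ", "),
        if (x$count > 6L) "...\n" else "\n")
  }
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
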