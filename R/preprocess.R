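#' Acceleration vector magnitude
#'
#' Element-wise Euclidean norm of the three accelerometer axes, giving an
#' orientation-independent scalar signal.
#'
#' @param accel N x 3 numeric matrix in m/s^2.
#' @return Numeric vector of length N, nonnegative.
#' @examples
#' accel_magnitude(rbind(c(3, 4, 0)))  # 5
#' @export
accel_magnitude <- function(accel) {
  accel <- as_channel_matrix(accel, "accel")
  if (nrow(accel) < 1L) stop("accel must contain at least one sample", call. = FALSE)
  if (!all(is.finite(accel))) stop("accel values must be finite", call. = FALSE)
  sqrt(rowSums(accel^2))
}

#' Median gravity compensation
#'
#' Subtracts the median of the signal, isolating the dynamic acceleration
#' component. The median is used rather than the mean because it is robust
#' to transient high-amplitude events such as heel-strike impacts.
#'
#' @param signal numeric vector (typically an acceleration magnitude).
#' @return The centred signal, `signal - median(signal)`.
#' @export
remove_gravity <- function(signal) {
  signal <- as.numeric(signal)
  if (length(signal) < 1L) stop("signal must be non-empty", call. = FALSE)
  if (!all(is.finite(signal))) stop("signal must be finite", call. = FALSE)
  signal - median(signal)
}

#' Savitzky-Golay smoothing
#'
#' Low-pass filters a signal with a Savitzky-Golay polynomial filter, which
#' preserves peak amplitudes and locations better than a conventional
#' moving-average or Butterworth low-pass. The window length in samples is
#' `round(window_s * rate)`, incremented by one if even (the filter requires
#' an odd window), and shrunk to the signal length when the signal is
#' shorter than the window.
#'
#' Signal edges are handled by mirror reflection rather than the filter's
#' polynomial startup fit: the left-edge least-squares extrapolation can
#' overshoot badly when gait activity begins within the first half window,
#' which would fabricate threshold crossings at the recording boundary.
#'
#' @param signal numeric vector.
#' @param window_s window length in seconds.
#' @param rate sampling rate in Hz.
#' @param order polynomial order; 3 by default.
#' @return Smoothed signal, same length as the input.
#' @export
sg_smooth <- function(signal, window_s, rate, order = 3L) {
  signal <- as.numeric(signal)
  n <- length(signal)
  n_samp <- round(window_s * rate)
  if (n_samp %% 2 == 0) n_samp <- n_samp + 1
  if (n_samp > n) {
    n_samp <- n - (1 - n %% 2)
  }
  if (n_samp < order + 2) {
    stop(sprintf("smoothing window of %d samples is too short for order %d (need >= %d)",
                 n_samp, order, order + 2), call. = FALSE)
  }
  h <- (n_samp - 1L) %/% 2L
  if (h > 0 && n > h + 1L) {
    padded <- c(signal[(h + 1L):2L], signal, signal[(n - 1L):(n - h)])
    signal::sgolayfilt(padded, p = order, n = n_samp)[(h + 1L):(h + n)]
  } else {
    signal::sgolayfilt(signal, p = order, n = n_samp)
  }
}

# Shared preprocessing chain: magnitude -> Savitzky-Golay smoothing ->
# median centring. Every time-domain detector consumes this signal.
preprocess_signal <- function(rec, smooth_window_s, order = 3L) {
  mag <- accel_magnitude(rec$accel)
  if (length(mag) >= order + 2) {
    mag <- sg_smooth(mag, smooth_window_s, rec$sampling_rate, order)
  }
  mag - median(mag)
}

# Centred rolling mean with shrink-at-edge windows, via cumulative sums.
rolling_mean <- function(x, width) {
  n <- length(x)
  h <- max(0L, (as.integer(width) - 1L) %/% 2L)
  cs <- cumsum(x)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1L)
}

# Centred rolling sample variance (n-1 denominator), shrink-at-edge.
# Single-sample windows give 0.
rolling_var <- function(x, width) {
  n <- length(x)
  h <- max(0L, (as.integer(width) - 1L) %/% 2L)
  cs <- cumsum(x)
  cs2 <- cumsum(x^2)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  m <- hi - lo + 1L
  s <- cs[hi] - c(0, cs)[lo]
  s2 <- cs2[hi] - c(0, cs2)[lo]
  v <- (s2 - s^2 / m) / pmax(m - 1L, 1L)
  v[m == 1L] <- 0
  pmax(v, 0)  # guard tiny negative values from cancellation
}

rolling_sd <- function(x, width) sqrt(rolling_var(x, width))

# Indices of local maxima (strict rise into the peak, non-strict fall out,
# so a flat-topped peak is reported once at its first sample).
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  i <- 2:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

# Topographic prominence of each peak: walk outwards until a higher sample
# (or the signal end), take the minimum on each side, and measure the peak
# height above the higher of the two minima.
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    v <- x[p]
    lmin <- v
    i <- p - 1L
    while (i >= 1L && x[i] <= v) {
      if (x[i] < lmin) lmin <- x[i]
      i <- i - 1L
    }
    rmin <- v
    i <- p + 1L
    while (i <= length(x) && x[i] <= v) {
      if (x[i] < rmin) rmin <- x[i]
      i <- i + 1L
    }
    v - max(lmin, rmin)
  }, numeric(1))
}

# Greedy minimum-spacing thinning: candidates are visited in decreasing
# priority (ties broken towards the earlier sample) and kept when at least
# `min_gap` from every already-kept candidate. Returns kept indices sorted.
thin_by_spacing <- function(times, priority, min_gap) {
  ord <- order(-priority, times)
  kept <- numeric(0)
  kept_idx <- integer(0)
  for (k in ord) {
    if (!length(kept) || all(abs(kept - times[k]) >= min_gap)) {
      kept <- c(kept, times[k])
      kept_idx <- c(kept_idx, k)
    }
  }
  sort(kept_idx)
}
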