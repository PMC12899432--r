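#' Match detected steps to reference steps within a tolerance window
#'
#' Computes a maximum-cardinality one-to-one matching between detected and
#' reference step times under the constraint
#' `|detected - reference| <= tolerance_s`, by greedy leftmost pairing over
#' the two sorted sequences (optimal for a uniform window on a line).
#' Matched pairs are true positives; unmatched detections are false
#' positives and unmatched references false negatives.
#'
#' @param detected numeric vector of detected step times (sorted), or a
#'   `step_result`.
#' @param reference numeric vector of reference step times (sorted), or a
#'   `ground_truth`.
#' @param tolerance_s matching tolerance in seconds; default 0.3 s, about
#'   1.5x a typical manual-annotation reaction time.
#' @return An object of class `match_result` with counts `TP`, `FP`, `FN`,
#'   the matched `pairs` (two-column matrix of detected/reference times),
#'   `precision`, `recall`, `f1` and `tolerance_s`. All three metrics use
#'   the 0/0 -> 0 convention.
#' @examples
#' match_steps(c(1.1, 2.5, 2.9, 5.0), c(1.0, 2.0, 3.0))
#' @export
match_steps <- function(detected, reference, tolerance_s = 0.3) {
  if (inherits(detected, "step_result")) detected <- detected$step_times
  if (inherits(reference, "ground_truth")) reference <- reference$step_times
  detected <- as.numeric(detected)
  reference <- as.numeric(reference)
  if (is.unsorted(detected, strictly = FALSE) ||
      is.unsorted(reference, strictly = FALSE)) {
    stop("detected and reference step times must be sorted", call. = FALSE)
  }
  if (!is.numeric(tolerance_s) || length(tolerance_s) != 1L || tolerance_s <= 0) {
    stop("tolerance_s must be a single positive number", call. = FALSE)
  }
  i <- 1L
  j <- 1L
  pairs <- matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("detected", "reference")))
  while (i <= length(detected) && j <= length(reference)) {
    d <- detected[i] - reference[j]
    if (abs(d) <= tolerance_s) {
      pairs <- rbind(pairs, c(detected[i], reference[j]))
      i <- i + 1L
      j <- j + 1L
    } else if (d < 0) {
      i <- i + 1L  # detection too early to match anything remaining
    } else {
      j <- j + 1L  # reference missed
    }
  }
  tp <- nrow(pairs)
  fp <- length(detected) - tp
  fn <- length(reference) - tp
  m <- prf(tp, fp, fn)
  structure(
    list(TP = tp, FP = fp, FN = fn, pairs = pairs,
         precision = m[["precision"]], recall = m[["recall"]],
         f1 = m[["f1"]], tolerance_s = tolerance_s),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP=%d FP=%d FN=%d (tol %.2g s)\n",
              x$TP, x$FP, x$FN, x$tolerance_s))
  cat(sprintf("  precision %.4f | recall %.4f | F1 %.4f\n",
              x$precision, x$recall, x$f1))
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `f1 = 2PR/(P+R)`; any 0/0 evaluates to 0 so degenerate detector outputs
#' score zero instead of crashing batch runs.
#'
#' @param tp,fp,fn nonnegative integer counts of true positives, false
#'   positives and false negatives.
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
prf <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be nonnegative", call. = FALSE)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  c(precision = precision, recall = recall, f1 = f1)
}

# Nearest-rank percentile: the smallest value with at least p% of the
# sample at or below it. Matches integer-valued step-count summaries.
nearest_rank <- function(x, p) {
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

#' Clinical plausibility screen for step counts
#'
#' Summarizes a batch of per-recording step counts and reports which
#' fraction falls inside a physiologically credible range (inclusive at
#' both ends). For Timed Up and Go recordings the conventional range is
#' 4-20 steps: the lower bound flags near-zero detection failures, the
#' upper accommodates the short strides of mobility-impaired walkers over
#' the 6 m course. Percentiles use the nearest-rank method.
#'
#' @param counts vector of nonnegative integer step counts.
#' @param lo,hi inclusive bounds of the plausible range.
#' @return An object of class `plausibility_summary` with `n`, `median`,
#'   `p10`, `p90`, `p99`, `pct_plausible` (in percent) and `range`.
#' @examples
#' plausibility_screen(c(2, 10, 300, 15))  # 50% plausible
#' @export
plausibility_screen <- function(counts, lo = 4, hi = 20) {
  counts <- as.numeric(counts)
  if (!length(counts)) stop("counts must be non-empty", call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  if (lo > hi) stop("lo must not exceed hi", call. = FALSE)
  structure(
    list(n = length(counts),
         median = nearest_rank(counts, 50),
         p10 = nearest_rank(counts, 10),
         p90 = nearest_rank(counts, 90),
         p99 = nearest_rank(counts, 99),
         pct_plausible = 100 * mean(counts >= lo & counts <= hi),
         range = c(lo, hi)),
    class = "plausibility_summary"
  )
}

#' @export
print.plausibility_summary <- function(x, ...) {
  cat(sprintf("<plausibility_summary> n=%d | median %g | P10 %g | P90 %g | P99 %g | %.1f%% in [%g, %g]\n",
              x$n, x$median, x$p10, x$p90, x$p99, x$pct_plausible,
              x$range[1], x$range[2]))
  invisible(x)
}

#' Bilateral left/right step-count consistency
#'
#' Agreement between step counts from paired left and right sensors, an
#' indirect validity check when no ground truth exists. Reports the mean
#' and sample standard deviation (n-1 denominator) of the per-pair
#' absolute differences; a single pair yields SD 0 with a warning.
#'
#' @param left_counts,right_counts equal-length numeric vectors of paired
#'   step counts.
#' @return Named numeric vector `c(mean_abs_diff, sd_abs_diff)`.
#' @export
bilateral_consistency <- function(left_counts, right_counts) {
  left_counts <- as.numeric(left_counts)
  right_counts <- as.numeric(right_counts)
  if (length(left_counts) != length(right_counts)) {
    stop("left and right count vectors must have the same length", call. = FALSE)
  }
  if (!length(left_counts)) stop("count vectors must be non-empty", call. = FALSE)
  d <- abs(left_counts - right_counts)
  s <- if (length(d) > 1L) sd(d) else {
    warning("single bilateral pair: SD reported as 0")
    0
  }
  c(mean_abs_diff = mean(d), sd_abs_diff = s)
}

#' Write a per-algorithm plausibility report
#'
#' Renders a table of plausibility summaries (one row per algorithm, with
#' median/P10/P90/P99/% plausible columns) as CSV and as an aligned text
#' table.
#'
#' @param summaries named list of `plausibility_summary` objects, names are
#'   algorithm labels.
#' @param csv_path,txt_path output paths; `NULL` skips that format.
#' @return The report data frame, invisibly.
#' @export
write_plausibility_report <- function(summaries, csv_path = NULL,
                                      txt_path = NULL) {
  stopifnot(length(summaries) > 0, !is.null(names(summaries)))
  df <- do.call(rbind, lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    data.frame(algorithm = nm, n = s$n, median = s$median, p10 = s$p10,
               p90 = s$p90, p99 = s$p99, pct_plausible = s$pct_plausible)
  }))
  if (!is.null(csv_path)) {
    write_csv_plain(df, csv_path)
  }
  if (!is.null(txt_path)) {
    fmt <- sprintf("%-18s %6s %6s %6s %6s %6s %12s",
                   "Algorithm", "n", "Median", "P10", "P90", "P99",
                   "% Plausible")
    lines <- c(fmt, vapply(seq_len(nrow(df)), function(i) {
      sprintf("%-18s %6d %6g %6g %6g %6g %12.1f",
              df$algorithm[i], df$n[i], df$median[i], df$p10[i], df$p90[i],
              df$p99[i], df$pct_plausible[i])
    }, character(1)))
    writeLines(lines, txt_path)
  }
  invisible(df)
}

# Deterministic minimal CSV writer (RFC 4180 style, "." decimal separator).
write_csv_plain <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  esc <- function(v) {
    v <- as.character(v)
    needs <- grepl('[",\n]', v)
    v[needs] <- paste0('"', gsub('"', '""', v[needs]), '"')
    v
  }
  writeLines(paste(esc(names(df)), collapse = ","), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.9g", col) else esc(col)
    })
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}
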