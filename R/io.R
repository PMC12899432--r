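# Canonical CSV schema: one header row with
#   time_s, s1_ax..s1_mz, s2_ax..s2_mz, step_marker
# Timestamps are seconds from recording start (0-based), accelerometer in
# m/s^2, gyroscope in deg/s; step_marker is 0/1 and marks ground-truth
# rows. Columns of an absent channel are written as empty fields and read
# back as absent.

canonical_columns <- function() {
  axes <- c("ax", "ay", "az", "gx", "gy", "gz", "mx", "my", "mz")
  c("time_s", paste0("s1_", axes), paste0("s2_", axes), "step_marker")
}

#' Column mapping for external CSV dialects
#'
#' Describes how a foreign CSV (different column names, units, timestamp
#' conventions) maps onto the canonical recording schema, so heterogeneous
#' sensor exports can be ingested without bespoke readers.
#'
#' @param columns named character vector mapping canonical field names
#'   (`time`, `ax`, `ay`, `az`, and optionally `gx`..`gz`, `mx`..`mz`,
#'   `step_marker`) to source column names. All three accelerometer axes
#'   must be mapped; `time` may be omitted when `time_unit =
#'   "sample-index"`.
#' @param accel_unit `"m/s2"` or `"g"` (converted by the standard gravity
#'   9.80665).
#' @param gyro_unit `"deg/s"` or `"rad/s"`.
#' @param time_unit `"seconds"`, `"milliseconds"` or `"sample-index"`.
#' @param sampling_rate source rate in Hz; required for
#'   `"sample-index"` timestamps, otherwise inferred from the data when
#'   `NULL`.
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(columns, accel_unit = c("m/s2", "g"),
                           gyro_unit = c("deg/s", "rad/s"),
                           time_unit = c("seconds", "milliseconds",
                                         "sample-index"),
                           sampling_rate = NULL) {
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  time_unit <- match.arg(time_unit)
  columns <- unlist(columns)
  need <- c("ax", "ay", "az")
  missing_axes <- setdiff(need, names(columns))
  if (length(missing_axes)) {
    stop("column mapping must map every accelerometer axis; missing: ",
         paste(missing_axes, collapse = ", "), call. = FALSE)
  }
  if (time_unit == "sample-index" && is.null(sampling_rate)) {
    stop("sample-index timestamps require sampling_rate", call. = FALSE)
  }
  if (time_unit != "sample-index" && !"time" %in% names(columns)) {
    stop("column mapping must map 'time' unless time_unit is 'sample-index'",
         call. = FALSE)
  }
  structure(list(columns = columns, accel_unit = accel_unit,
                 gyro_unit = gyro_unit, time_unit = time_unit,
                 sampling_rate = sampling_rate),
            class = "column_mapping")
}

#' Read a recording from CSV
#'
#' Without a mapping, expects the canonical schema (see
#' [write_recording()]); rows with `step_marker == 1` become ground-truth
#' step times. With a [column_mapping()], source columns are renamed, units
#' converted to m/s^2 and deg/s, and timestamps normalized to seconds from
#' the recording start. Gzip-compressed files are accepted by extension.
#'
#' @param path CSV file path (optionally `.gz`).
#' @param mapping optional [column_mapping()] for foreign dialects.
#' @param sensor which sensor block of the canonical schema to read
#'   (`"s1"` or `"s2"`); ignored when a mapping is given.
#' @return List with elements `recording` ([imu_recording()]) and `truth`
#'   (a [ground_truth()] or `NULL` when the file has no markers).
#' @export
read_recording <- function(path, mapping = NULL, sensor = c("s1", "s2")) {
  sensor <- match.arg(sensor)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, check.names = FALSE)
  if (is.null(mapping)) {
    read_canonical(df, sensor, path)
  } else {
    read_mapped(df, mapping, path)
  }
}

pick_block <- function(df, cols, what, path, required = TRUE) {
  present <- cols %in% names(df)
  if (!all(present)) {
    if (required) {
      stop(sprintf("%s: missing mandatory column '%s'", path,
                   cols[!present][1]), call. = FALSE)
    }
    return(NULL)
  }
  m <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(m) <- "double"
  if (all(is.na(m))) return(NULL)  # written as empty fields = channel absent
  if (anyNA(m)) {
    stop(sprintf("%s: %s channel contains missing values", path, what),
         call. = FALSE)
  }
  m
}

read_canonical <- function(df, sensor, path) {
  if (!"time_s" %in% names(df)) {
    stop(sprintf("%s: missing mandatory column 'time_s'", path),
         call. = FALSE)
  }
  time_s <- as.numeric(df$time_s)
  if (any(diff(time_s) <= 0)) {
    stop(sprintf("%s: timestamps are not strictly increasing", path),
         call. = FALSE)
  }
  accel <- pick_block(df, paste0(sensor, "_", c("ax", "ay", "az")),
                      "accelerometer", path, required = TRUE)
  gyro <- pick_block(df, paste0(sensor, "_", c("gx", "gy", "gz")),
                     "gyroscope", path, required = FALSE)
  mag <- pick_block(df, paste0(sensor, "_", c("mx", "my", "mz")),
                    "magnetometer", path, required = FALSE)
  rate <- 1 / median(diff(time_s))
  rec <- imu_recording(time_s, accel, gyro, mag, sampling_rate = rate,
                       meta = list(source_file = basename(path),
                                   sensor = sensor))
  truth <- NULL
  if ("step_marker" %in% names(df)) {
    marks <- time_s[!is.na(df$step_marker) & df$step_marker == 1]
    if (length(marks)) {
      truth <- ground_truth(marks, source = "manual_annotation")
    }
  }
  list(recording = rec, truth = truth)
}

read_mapped <- function(df, mapping, path) {
  if (!inherits(mapping, "column_mapping")) {
    stop("mapping must be a column_mapping", call. = FALSE)
  }
  cols <- mapping$columns
  get_col <- function(field) {
    src <- cols[[field]]
    if (!src %in% names(df)) {
      stop(sprintf("%s: mapped column '%s' (for %s) not found in file",
                   path, src, field), call. = FALSE)
    }
    as.numeric(df[[src]])
  }
  n <- nrow(df)
  if (mapping$time_unit == "sample-index") {
    time_s <- (seq_len(n) - 1) / mapping$sampling_rate
    if ("time" %in% names(cols)) {
      time_s <- (get_col("time") - get_col("time")[1]) / mapping$sampling_rate
    }
  } else {
    time_s <- get_col("time")
    if (mapping$time_unit == "milliseconds") time_s <- time_s / 1000
    time_s <- time_s - time_s[1]
  }
  if (any(diff(time_s) <= 0)) {
    stop(sprintf("%s: timestamps are not strictly increasing", path),
         call. = FALSE)
  }
  accel <- cbind(get_col("ax"), get_col("ay"), get_col("az"))
  if (mapping$accel_unit == "g") accel <- accel * STANDARD_GRAVITY
  gyro <- NULL
  if (all(c("gx", "gy", "gz") %in% names(cols))) {
    gyro <- cbind(get_col("gx"), get_col("gy"), get_col("gz"))
    if (mapping$gyro_unit == "rad/s") gyro <- gyro * 180 / pi
  }
  mag <- NULL
  if (all(c("mx", "my", "mz") %in% names(cols))) {
    mag <- cbind(get_col("mx"), get_col("my"), get_col("mz"))
  }
  rate <- if (!is.null(mapping$sampling_rate)) mapping$sampling_rate else {
    1 / median(diff(time_s))
  }
  rec <- imu_recording(time_s, accel, gyro, mag, sampling_rate = rate,
                       meta = list(source_file = basename(path)))
  truth <- NULL
  if ("step_marker" %in% names(cols)) {
    mk <- get_col("step_marker")
    if (any(mk == 1)) {
      truth <- ground_truth(time_s[mk == 1], source = "manual_annotation")
    }
  }
  list(recording = rec, truth = truth)
}

#' Write a recording to canonical CSV
#'
#' Deterministic writer: fixed column order, values at 10 significant
#' digits (nine plus a guard digit, so numeric round trips stay within
#' 1e-9 relative error), byte identical across repeated calls. The recording fills the `s1` sensor
#' block; `s2` and absent channels are written as empty fields. Ground
#' truth is stored in the `step_marker` column by flagging the sample row
#' nearest each step time (times are therefore quantized to the sample
#' grid, at most half a sample period away).
#'
#' @param rec an [imu_recording()].
#' @param path output path.
#' @param truth optional [ground_truth()] (or numeric step times).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, truth = NULL) {
  if (!inherits(rec, "imu_recording")) {
    stop("rec must be an imu_recording", call. = FALSE)
  }
  n <- length(rec$timestamps)
  marker <- integer(n)
  if (!is.null(truth)) {
    tt <- if (inherits(truth, "ground_truth")) truth$step_times else
      as.numeric(truth)
    for (s in tt) {
      marker[which.min(abs(rec$timestamps - s))] <- 1L
    }
  }
  num <- function(x) sprintf("%.10g", x)
  blk <- function(m) {
    if (is.null(m)) {
      matrix("", nrow = n, ncol = 3)
    } else {
      cbind(num(m[, 1]), num(m[, 2]), num(m[, 3]))
    }
  }
  cells <- cbind(num(rec$timestamps), blk(rec$accel), blk(rec$gyro),
                 blk(rec$mag),
                 matrix("", nrow = n, ncol = 9),  # s2 block unused
                 as.character(marker))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(canonical_columns(), collapse = ","), con)
  writeLines(apply(cells, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Resample a recording onto a uniform grid
#'
#' Linearly interpolates every channel onto a uniform grid at `target_hz`
#' spanning the original first and last timestamps; the grid is
#' `first + k/target_hz` for `k = 0..floor(span * target_hz)`, so an
#' already-uniform recording resampled at its own rate is returned
#' unchanged (to numerical precision).
#'
#' @param rec an [imu_recording()].
#' @param target_hz target sampling rate, > 0.
#' @return A new [imu_recording()] at `target_hz`.
#' @export
resample_recording <- function(rec, target_hz) {
  if (!inherits(rec, "imu_recording")) {
    stop("rec must be an imu_recording", call. = FALSE)
  }
  if (!is.numeric(target_hz) || target_hz <= 0) {
    stop("target_hz must be positive", call. = FALSE)
  }
  n <- length(rec$timestamps)
  if (n < 2L) stop("resampling requires at least 2 samples", call. = FALSE)
  span <- rec$timestamps[n] - rec$timestamps[1]
  grid <- rec$timestamps[1] + (0:floor(span * target_hz + 1e-9)) / target_hz
  interp <- function(m) {
    if (is.null(m)) return(NULL)
    out <- vapply(1:3, function(j) {
      approx(rec$timestamps, m[, j], xout = grid, rule = 2)$y
    }, numeric(length(grid)))
    colnames(out) <- c("x", "y", "z")
    out
  }
  imu_recording(grid, interp(rec$accel), interp(rec$gyro), interp(rec$mag),
                sampling_rate = target_hz, meta = rec$meta)
}
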