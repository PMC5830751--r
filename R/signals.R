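#' Construct a sensor recording
#'
#' @param df Data frame with columns `t` (s), `ax`, `ay`, `az` (g) and `gx`,
#'   `gy`, `gz` (deg/s) on a uniform time grid.
#' @param fs Sampling frequency in Hz; inferred from `t` when `NULL`.
#' @param position Sensor position tag, `"ear"` or `"collar"`.
#' @return A `sensor_recording` data frame with `fs` and `position`
#'   attributes.
#' @export
sensor_recording <- function(df, fs = NULL, position = "ear") {
  needed <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("recording is missing column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[needed]
  if (anyNA(df)) stop("recording contains non-numeric or missing values")
  n <- nrow(df)
  if (n >= 2) {
    dt <- diff(df$t)
    if (any(dt <= 0))
      stop("non-monotonic timestamps at row ", which(dt <= 0)[1] + 1L)
    if (is.null(fs)) fs <- 1 / dt[1]
    if (any(abs(dt - 1 / fs) > 1e-9))
      stop("timestamps are not on a uniform 1/fs grid (row ",
           which(abs(dt - 1 / fs) > 1e-9)[1] + 1L, ")")
  } else if (is.null(fs)) {
    stop("fs must be given for recordings shorter than 2 samples")
  }
  structure(df, fs = fs, position = match.arg(position, c("ear", "collar")),
            class = c("sensor_recording", "data.frame"))
}

#' Construct / validate an annotation track
#'
#' @param df Data frame with columns `start_s`, `end_s`, `behaviour`;
#'   intervals are half-open `[start_s, end_s)`, ordered, non-overlapping,
#'   with behaviours from [SHEEP_BEHAVIOURS].
#' @return An `annotation_track` data frame.
#' @export
annotation_track <- function(df) {
  needed <- c("start_s", "end_s", "behaviour")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  df <- as.data.frame(df)[needed]
  bad <- which(!df$behaviour %in% SHEEP_BEHAVIOURS)
  if (length(bad) > 0)
    stop("unknown behaviour label '", df$behaviour[bad[1]], "' at row ", bad[1])
  bad <- which(!(df$start_s < df$end_s))
  if (length(bad) > 0) stop("empty or inverted interval at row ", bad[1])
  if (nrow(df) >= 2) {
    bad <- which(df$start_s[-1] < df$end_s[-nrow(df)] - 1e-12)
    if (length(bad) > 0) stop("overlapping or unordered intervals at row ", bad[1] + 1L)
  }
  structure(df, class = c("annotation_track", "data.frame"))
}

#' Read a sensor recording from CSV
#'
#' Expects the dialect written by [write_dataset()]: header
#' `t,ax,ay,az,gx,gy,gz`, time in seconds on a uniform grid, acceleration in
#' g, gyroscope rates in deg/s. Malformed rows are rejected with an error
#' naming the row, never silently skipped.
#'
#' @param path CSV file path.
#' @param position Sensor position tag to attach.
#' @param fs Sampling frequency; inferred from the time column when `NULL`.
#' @return A `sensor_recording`.
#' @export
read_recording <- function(path, position = "ear", fs = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  needed <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("recording file is missing column(s): ", paste(missing, collapse = ", "))
  num <- suppressWarnings(lapply(df[needed], as.numeric))
  for (col in needed) {
    bad <- which(is.na(num[[col]]))
    if (length(bad) > 0)
      stop("non-numeric value in column '", col, "' at data row ", bad[1])
  }
  sensor_recording(as.data.frame(num), fs = fs, position = position)
}

#' Read a behaviour annotation track from CSV
#'
#' Expects header `start_s,end_s,behaviour` with half-open intervals and
#' behaviours from the three-class ethogram.
#'
#' @param path CSV file path.
#' @return An `annotation_track`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  needed <- c("start_s", "end_s", "behaviour")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0)
    stop("annotation file is missing column(s): ", paste(missing, collapse = ", "))
  for (col in c("start_s", "end_s")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad) > 0 || anyNA(v))
      stop("non-numeric value in column '", col, "' at data row ",
           if (length(bad) > 0) bad[1] else which(is.na(v))[1])
    df[[col]] <- v
  }
  annotation_track(df)
}

#' Euclidean magnitude of a tri-axial signal
#'
#' The per-sample vector magnitude `sqrt(x^2 + y^2 + z^2)`, the
#' orientation-free summary used for both the accelerometer and gyroscope
#' streams.
#'
#' @param x,y,z Equal-length numeric series (the three sensor axes).
#' @return Non-negative numeric series of the same length.
#' @export
magnitude <- function(x, y, z) {
  if (length(x) != length(y) || length(y) != length(z))
    stop("axis series must have equal length")
  sqrt(x^2 + y^2 + z^2)
}

#' Rate of change of a magnitude series
#'
#' First differences `m[i+1] - m[i]`; the result is one sample shorter than
#' the input. By default the difference is per sample; `scale =
#' "per_second"` multiplies by `fs`.
#'
#' @param m Numeric series, length >= 2.
#' @param scale `"per_sample"` (default) or `"per_second"`.
#' @param fs Sampling frequency, required for `"per_second"`.
#' @return Numeric series of length `length(m) - 1`.
#' @export
rate_of_change <- function(m, scale = c("per_sample", "per_second"), fs = NULL) {
  scale <- match.arg(scale)
  if (length(m) < 2) stop("rate_of_change needs at least 2 samples")
  d <- diff(m)
  if (scale == "per_second") {
    if (is.null(fs)) stop("fs required for per_second scaling")
    d <- d * fs
  }
  d
}

#' Align behaviour annotations to recorded samples
#'
#' Each sample whose timestamp falls inside a half-open annotation interval
#' `[start_s, end_s)` receives that interval's behaviour; samples outside
#' every interval are left unlabelled (`NA`) and are later excluded from
#' windowing. The four analysis streams are derived here: accelerometer
#' magnitude, gyroscope magnitude, and their per-sample rates of change.
#'
#' @param recording A `sensor_recording`.
#' @param annotation An `annotation_track` (gaps are legal).
#' @param derivative_scale Passed to [rate_of_change()].
#' @return A `labelled_samples` list: `accel_mag`, `gyro_mag` (length N),
#'   `d_accel_mag`, `d_gyro_mag` (length N-1), `labels` (length N, `NA` =
#'   unlabelled), `fs`, `position`.
#' @export
align <- function(recording, annotation,
                  derivative_scale = c("per_sample", "per_second")) {
  stopifnot(inherits(recording, "sensor_recording"))
  annotation <- annotation_track(annotation)
  fs <- attr(recording, "fs")
  labels <- rep(NA_character_, nrow(recording))
  if (nrow(annotation) > 0) {
    idx <- findInterval(recording$t, annotation$start_s)
    inside <- idx > 0 & recording$t < annotation$end_s[pmax(idx, 1L)]
    labels[inside] <- annotation$behaviour[idx[inside]]
  }
  amag <- magnitude(recording$ax, recording$ay, recording$az)
  gmag <- magnitude(recording$gx, recording$gy, recording$gz)
  structure(list(
    accel_mag = amag, gyro_mag = gmag,
    d_accel_mag = rate_of_change(amag, derivative_scale, fs = fs),
    d_gyro_mag = rate_of_change(gmag, derivative_scale, fs = fs),
    labels = labels, fs = fs, position = attr(recording, "position")),
    class = "labelled_samples")
}
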