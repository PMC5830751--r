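#' Moment and range statistics of a window
#'
#' Mean, sample standard deviation, minimum, maximum, interquartile range
#' (type-7 linear-interpolation percentiles) and population excess kurtosis
#' `m4/m2^2 - 3` (0 by convention for a constant window).
#'
#' @param w Numeric window, length >= 2.
#' @return Named list: `mean`, `std`, `min`, `max`, `iqr`, `kurtosis`.
#' @export
basic_stats <- function(w) {
  if (length(w) < 2) stop("window too short for basic_stats")
  m <- mean(w)
  d <- w - m
  m2 <- mean(d^2)
  kurt <- if (m2 == 0) 0 else mean(d^4) / m2^2 - 3
  list(mean = m, std = stats::sd(w), min = min(w), max = max(w),
       iqr = unname(stats::quantile(w, 0.75, type = 7) -
                    stats::quantile(w, 0.25, type = 7)),
       kurtosis = kurt)
}

#' Count zero crossings of a mean-centred window
#'
#' The window mean is subtracted, then adjacent pairs with a strict sign
#' change are counted. Samples that are exactly zero after centring inherit
#' the previous nonzero sign (leading zeros take the first nonzero sign), so
#' a touch of zero without a sign reversal is not a crossing.
#'
#' @param w Numeric window, length >= 2.
#' @return Integer crossing count in `[0, length(w) - 1]`.
#' @export
zero_crossings <- function(w) {
  if (length(w) < 2) stop("window too short for zero_crossings")
  s <- sign(w - mean(w))
  nz <- s != 0
  if (!any(nz)) return(0L)
  # propagate previous nonzero sign into zeros; leading zeros take first sign
  last_nz <- cummax(ifelse(nz, seq_along(s), 0L))
  last_nz[last_nz == 0L] <- which(nz)[1]
  filled <- s[last_nz]
  sum(filled[-1] != filled[-length(filled)])
}

# one-sided periodogram: squared modulus of the DFT at bins 0..floor(n/2)
one_sided_psd <- function(w) {
  n <- length(w)
  Mod(stats::fft(w)[seq_len(n %/% 2 + 1L)])^2
}

#' Spectral entropy of a window
#'
#' The one-sided power spectral density `|X(f)|^2` of the raw window (no
#' taper, no detrending) is normalized to a probability distribution over
#' frequency bins and its Shannon entropy (natural log) returned. Low for
#' tonal signals, high for noise-like signals; an identically zero window
#' has entropy 0 by convention.
#'
#' @param w Numeric window, length >= 2.
#' @param exclude_dc Drop the DC bin before normalizing? Default `FALSE`
#'   (the plain formula).
#' @return Entropy in nats, in `[0, log(#bins)]`.
#' @export
spectral_entropy <- function(w, exclude_dc = FALSE) {
  if (length(w) < 2) stop("window too short for spectral_entropy")
  psd <- one_sided_psd(w)
  if (exclude_dc) psd <- psd[-1]
  tot <- sum(psd)
  if (tot == 0) return(0)
  p <- psd / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Dominant frequency of a window
#'
#' The bin-centre frequency at which the one-sided periodogram is maximal.
#' The DC bin is excluded by default: magnitude streams carry a ~1 g static
#' offset that would otherwise make DC dominant for every window and the
#' feature uninformative. Ties resolve to the lowest frequency; a window
#' with no off-DC power returns 0 Hz.
#'
#' @param w Numeric window, length >= 2.
#' @param fs Sampling frequency in Hz.
#' @param exclude_dc Exclude the DC bin? Default `TRUE`.
#' @return Frequency in Hz, in `[0, fs/2]`.
#' @export
dominant_frequency <- function(w, fs, exclude_dc = TRUE) {
  if (length(w) < 2) stop("window too short for dominant_frequency")
  n <- length(w)
  psd <- one_sided_psd(w)
  freqs <- (seq_along(psd) - 1L) * fs / n
  if (exclude_dc) { psd <- psd[-1]; freqs <- freqs[-1] }
  if (length(psd) == 0 || sum(psd) == 0) return(0)
  freqs[which.max(psd)]
}

#' Signal area and absolute signal area
#'
#' `SA = sum(w) / fs` and `ASA = sum(|w|) / fs`: the window sum scaled by
#' the sampling interval, i.e. a rectangle-rule integral of the stream over
#' the window. Equal for non-negative streams such as magnitudes.
#'
#' @param w Numeric window, length >= 1.
#' @param fs Sampling frequency in Hz.
#' @return Named list: `signal_area`, `abs_signal_area`.
#' @export
signal_areas <- function(w, fs) {
  list(signal_area = sum(w) / fs, abs_signal_area = sum(abs(w)) / fs)
}

FEATURE_NAMES <- c("abs_signal_area", "dominant_frequency_hz", "iqr",
                   "kurtosis", "max", "mean", "min", "signal_area",
                   "spectral_entropy", "std", "zero_crossings")
STREAM_NAMES <- c("accel_mag", "gyro_mag", "d_accel_mag", "d_gyro_mag")

# 11 feature characteristics of a single stream segment
stream_features <- function(w, fs) {
  bs <- basic_stats(w)
  sa <- signal_areas(w, fs)
  c(abs_signal_area = sa$abs_signal_area,
    dominant_frequency_hz = dominant_frequency(w, fs),
    iqr = bs$iqr, kurtosis = bs$kurtosis, max = bs$max, mean = bs$mean,
    min = bs$min, signal_area = sa$signal_area,
    spectral_entropy = spectral_entropy(w), std = bs$std,
    zero_crossings = as.numeric(zero_crossings(w)))
}

#' Extract the 44-dimensional feature vector of one window
#'
#' The 11 feature characteristics are computed on each of the four streams
#' (accelerometer magnitude, gyroscope magnitude and their rates of change),
#' yielding 44 values named `<feature>__<stream>` in fixed alphabetical
#' order so that trained models are portable across runs.
#'
#' @param window A `labelled_window` from [segment()].
#' @param fs Sampling frequency in Hz.
#' @return Named numeric vector of length 44 with attributes `label` and
#'   `mixed`.
#' @export
extract_features <- function(window, fs) {
  stopifnot(inherits(window, "labelled_window"))
  vals <- unlist(lapply(STREAM_NAMES, function(s) {
    v <- stream_features(window$streams[[s]], fs)
    names(v) <- paste0(names(v), "__", s)
    v
  }))
  vals <- vals[order(names(vals))]
  attr(vals, "label") <- window$label
  attr(vals, "mixed") <- window$mixed
  vals
}

#' Feature names of the 44-dimensional vector
#' @return Character vector of 44 `<feature>__<stream>` names, sorted.
#' @export
feature_names <- function() {
  sort(as.vector(outer(FEATURE_NAMES, STREAM_NAMES, paste, sep = "__")))
}

#' Build a feature table for a set of windows
#'
#' One row per window: the 44 features plus `label`, `mixed`, and the
#' provenance columns `fs`, `window_s`, `position`, `start_sample`.
#'
#' @param windows List of `labelled_window` objects.
#' @param fs Sampling frequency in Hz.
#' @param window_seconds Window length in seconds (provenance).
#' @param position Sensor position tag (provenance).
#' @return Data frame with 44 feature columns and 5 metadata columns.
#' @export
feature_table <- function(windows, fs, window_seconds = NA, position = NA) {
  if (length(windows) == 0) stop("no windows to featurize")
  mat <- t(vapply(windows, function(w) as.numeric(extract_features(w, fs)),
                  numeric(44)))
  colnames(mat) <- feature_names()
  df <- as.data.frame(mat)
  df$label <- vapply(windows, function(w) w$label, character(1))
  df$mixed <- vapply(windows, function(w) w$mixed, logical(1))
  df$fs <- fs
  df$window_s <- window_seconds
  df$position <- position
  df$start_sample <- vapply(windows, function(w) w$start_sample, numeric(1))
  df
}
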