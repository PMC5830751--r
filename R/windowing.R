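#' Assign the collective label of one window
#'
#' A window whose samples all share one behaviour keeps that behaviour and is
#' non-mixed. A window spanning a bout boundary is flagged mixed and receives
#' its predominant (modal) label; a tie is broken in favour of the label that
#' appears first in time within the window.
#'
#' @param sample_labels Character vector of per-sample behaviours, no `NA`.
#' @return List with `label` and `mixed`.
#' @export
label_window <- function(sample_labels) {
  if (length(sample_labels) == 0) stop("empty window")
  if (anyNA(sample_labels)) stop("window contains unlabelled samples")
  # levels in first-occurrence order => which.max tie-break = temporally first
  counts <- table(factor(sample_labels, levels = unique(sample_labels)))
  list(label = names(counts)[which.max(counts)], mixed = length(counts) > 1L)
}

#' Discretize labelled streams into overlapping windows
#'
#' Fixed-length windows of `window_seconds` with 50% overlap: starts at
#' samples 0, n/2, n, ... where `n = window_seconds * fs`. The trailing
#' partial window is discarded, as is any window containing an unlabelled
#' sample (windows never span annotation gaps). Each window carries segments
#' of the four analysis streams; the derivative segment holds the `n - 1`
#' differences interior to the window.
#'
#' @param samples A `labelled_samples` object from [align()].
#' @param window_seconds Window length in seconds; `window_seconds * fs`
#'   must be an integer >= 2.
#' @return List of `labelled_window` objects with fields `index`,
#'   `start_sample` (0-based), `n`, `label`, `mixed` and `streams`.
#' @export
segment <- function(samples, window_seconds) {
  stopifnot(inherits(samples, "labelled_samples"))
  n_real <- window_seconds * samples$fs
  n <- round(n_real)
  if (abs(n_real - n) > 1e-9 || n < 2)
    stop("window_seconds * fs must be an integer >= 2, got ", n_real)
  step <- n %/% 2L
  N <- length(samples$accel_mag)
  if (N < n) return(list())
  starts <- seq.int(1L, N - n + 1L, by = step)
  out <- vector("list", length(starts))
  kept <- 0L
  for (s in starts) {
    lab <- samples$labels[s:(s + n - 1L)]
    if (anyNA(lab)) next
    lw <- label_window(lab)
    kept <- kept + 1L
    out[[kept]] <- structure(list(
      index = kept, start_sample = s - 1L, n = n,
      label = lw$label, mixed = lw$mixed,
      streams = list(
        accel_mag = samples$accel_mag[s:(s + n - 1L)],
        gyro_mag = samples$gyro_mag[s:(s + n - 1L)],
        d_accel_mag = samples$d_accel_mag[s:(s + n - 2L)],
        d_gyro_mag = samples$d_gyro_mag[s:(s + n - 2L)])),
      class = "labelled_window")
  }
  out[seq_len(kept)]
}

#' Percentage of non-mixed and mixed windows
#'
#' @param windows List of `labelled_window` objects (one configuration).
#' @return Data frame with `pct_non_mixed` and `pct_mixed`, summing to 100.
#' @export
mixed_summary <- function(windows) {
  if (length(windows) == 0) stop("mixed_summary is undefined for zero windows")
  mixed <- vapply(windows, function(w) w$mixed, logical(1))
  data.frame(pct_non_mixed = 100 * mean(!mixed), pct_mixed = 100 * mean(mixed))
}
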