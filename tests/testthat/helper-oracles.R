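# Independent brute-force oracles used to pin down the spectral and
# counting features; deliberately O(n^2) / naive so they share no code with
# the implementation.

oracle_psd <- function(w) {
  n <- length(w)
  ks <- 0:(n %/% 2)
  vapply(ks, function(k) {
    Mod(sum(w * exp(-2i * pi * k * (0:(n - 1)) / n)))^2
  }, numeric(1))
}

oracle_spectral_entropy <- function(w) {
  psd <- oracle_psd(w)
  if (sum(psd) == 0) return(0)
  p <- psd / sum(psd)
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_dominant_frequency <- function(w, fs) {
  psd <- oracle_psd(w)[-1]
  if (length(psd) == 0 || sum(psd) == 0) return(0)
  freqs <- seq_along(psd) * fs / length(w)
  freqs[which.max(psd)]
}

oracle_zero_crossings <- function(w) {
  x <- w - mean(w)
  count <- 0L
  prev <- 0
  for (v in x) {
    s <- sign(v)
    if (s != 0) {
      if (prev != 0 && s != prev) count <- count + 1L
      prev <- s
    }
  }
  count
}

# tiny labelled-samples fixture built directly (no generator involvement)
make_samples <- function(accel_mag, gyro_mag = accel_mag, labels, fs = 16,
                         position = "ear") {
  structure(list(
    accel_mag = accel_mag, gyro_mag = gyro_mag,
    d_accel_mag = diff(accel_mag), d_gyro_mag = diff(gyro_mag),
    labels = labels, fs = fs, position = position),
    class = "labelled_samples")
}

make_window <- function(accel_mag, fs = 16, label = "lying", mixed = FALSE) {
  structure(list(index = 1L, start_sample = 0L, n = length(accel_mag),
                 label = label, mixed = mixed,
                 streams = list(accel_mag = accel_mag, gyro_mag = accel_mag,
                                d_accel_mag = diff(accel_mag),
                                d_gyro_mag = diff(accel_mag))),
            class = "labelled_window")
}

default_samples <- function(duration_s = 600, fs = 16, seed = 42,
                            position = "ear") {
  cfg <- synthetic_config(duration_s = duration_s, fs = fs, seed = seed,
                          position = position)
  ann <- generate_bout_sequence(cfg)
  align(synthesize_recording(ann, cfg), ann)
}
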