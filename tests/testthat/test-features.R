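test_that("moment statistics follow the documented conventions", {
  bs <- basic_stats(c(1, 2, 3, 4))
  expect_equal(bs$mean, 2.5)
  expect_equal(bs$min, 1)
  expect_equal(bs$max, 4)
  expect_equal(bs$iqr, unname(diff(quantile(1:4, c(0.25, 0.75)))))
  # population excess kurtosis: m2 = 1, m4 = 1 => -2
  expect_equal(basic_stats(c(1, 1, -1, -1))$kurtosis, -2)
  cst <- basic_stats(rep(3.7, 10))
  expect_equal(cst$std, 0)
  expect_equal(cst$iqr, 0)
  expect_equal(cst$kurtosis, 0)  # degenerate-window convention
  expect_error(basic_stats(1), "too short")
})

test_that("zero crossings count strict sign changes after centring", {
  expect_equal(zero_crossings(c(1, -1, 1, -1)), 3)
  expect_equal(zero_crossings(rep(2, 10)), 0L)
  # one sampled cycle crosses once (down at half period); the up-crossing at
  # the full period is the first sample of the next cycle — the naive loop
  # oracle agrees
  full_cycle <- sin(2 * pi * (0:15) / 16)
  expect_equal(zero_crossings(full_cycle), oracle_zero_crossings(full_cycle))
  expect_equal(zero_crossings(full_cycle), 1)
  # 1.5 cycles: the nonzero mean shifts the centre line, giving a third
  # crossing on top of down-and-up (naive-loop verified)
  expect_equal(zero_crossings(sin(2 * pi * 1.5 * (0:15) / 16)), 3)
  # exact zeros inherit the previous sign: no crossing without reversal
  expect_equal(zero_crossings(c(-1, 0, 1, 1) - 0.25), 1)
  set.seed(7)
  for (i in 1:50) {
    w <- sample(c(rnorm(20), rep(0, 5)))
    w <- w - mean(w) + sample(c(0, 0.3), 1)
    expect_equal(zero_crossings(w), oracle_zero_crossings(w))
  }
})

test_that("spectral entropy matches its closed forms and the DFT oracle", {
  # pure sinusoid at an exact bin: single-bin spectrum, entropy ~ 0
  w <- sin(2 * pi * 4 * (0:63) / 64)
  expect_lt(spectral_entropy(w), 1e-10)
  # unit impulse: perfectly flat spectrum, entropy = log(#bins)
  impulse <- c(1, rep(0, 63))
  expect_equal(spectral_entropy(impulse), log(33), tolerance = 1e-12)
  expect_equal(spectral_entropy(rep(0, 32)), 0)
  set.seed(112)
  w <- rnorm(112)
  expect_equal(spectral_entropy(w), oracle_spectral_entropy(w),
               tolerance = 1e-10)
})

test_that("dominant frequency picks the strongest off-DC bin", {
  t <- (0:111) / 16
  expect_equal(dominant_frequency(sin(2 * pi * 2 * t), 16), 2)
  expect_equal(dominant_frequency(rep(5, 48), 16), 0)
  t <- (0:159) / 32
  w <- sin(2 * pi * 1 * t) + 2 * sin(2 * pi * 3 * t)
  expect_equal(dominant_frequency(w, 32), 3)
  expect_equal(dominant_frequency(w, 32), oracle_dominant_frequency(w, 32))
  # a DC offset does not move the dominant frequency
  expect_equal(dominant_frequency(w + 10, 32), 3)
})

test_that("signal areas are rectangle-rule integrals", {
  sa <- signal_areas(rep(1, 24), 8)
  expect_equal(sa$signal_area, 3)
  expect_equal(sa$abs_signal_area, 3)
  sa <- signal_areas(c(-1, 1), 1)
  expect_equal(sa$signal_area, 0)
  expect_equal(sa$abs_signal_area, 2)
  mag <- abs(rnorm(50))
  sa <- signal_areas(mag, 16)
  expect_equal(sa$signal_area, sa$abs_signal_area)
})

test_that("a window yields a deterministic, named 44-feature vector", {
  set.seed(3)
  win <- make_window(rnorm(112) + 1, fs = 16, label = "standing")
  fv <- extract_features(win, 16)
  expect_length(fv, 44)
  expect_identical(names(fv), feature_names())
  expect_identical(names(fv), sort(names(fv)))
  expect_equal(attr(fv, "label"), "standing")
  expect_identical(as.numeric(fv), as.numeric(extract_features(win, 16)))
  expect_true(all(is.finite(fv)))
})

test_that("features scale or stay invariant under positive rescaling", {
  set.seed(9)
  for (i in 1:10) {
    w <- rnorm(96) + 1
    c_ <- runif(1, 0.5, 5)
    f1 <- extract_features(make_window(w, fs = 16), 16)
    f2 <- extract_features(make_window(c_ * w, fs = 16), 16)
    equivariant <- grep("^(mean|std|min|max|iqr|signal_area|abs_signal_area)__",
                        names(f1))
    invariant <- grep("^(zero_crossings|dominant_frequency_hz|spectral_entropy|kurtosis)__",
                      names(f1))
    expect_equal(as.numeric(f2[equivariant]), c_ * as.numeric(f1[equivariant]),
                 tolerance = 1e-10)
    expect_equal(as.numeric(f2[invariant]), as.numeric(f1[invariant]),
                 tolerance = 1e-10)
  }
})

test_that("spectral features agree with the brute-force DFT oracle", {
  set.seed(64)
  for (i in 1:40) {
    n <- sample(c(24, 48, 80, 112, 160, 224, 256), 1)
    w <- rnorm(n) + sample(c(0, 1), 1) +
      runif(1, 0, 2) * sin(2 * pi * runif(1, 0.5, 3) * (0:(n - 1)) / 16)
    se <- spectral_entropy(w)
    expect_equal(se, oracle_spectral_entropy(w),
                 tolerance = 1e-10 * max(1, abs(se)))
    expect_equal(dominant_frequency(w, 16), oracle_dominant_frequency(w, 16))
  }
})

test_that("mean accelerometer magnitude separates lying from walking windows", {
  s <- default_samples(duration_s = 1800, fs = 16, seed = 23)
  ft <- feature_table(segment(s, 7), 16, 7, "ear")
  lying <- ft$mean__accel_mag[ft$label == "lying"]
  walking <- ft$mean__accel_mag[ft$label == "walking"]
  pooled <- sqrt((var(lying) * (length(lying) - 1) +
                  var(walking) * (length(walking) - 1)) /
                 (length(lying) + length(walking) - 2))
  effect <- abs(mean(lying) - mean(walking)) / pooled
  sa_l <- ft$signal_area__accel_mag[ft$label == "lying"]
  sa_w <- ft$signal_area__accel_mag[ft$label == "walking"]
  pooled_sa <- sqrt((var(sa_l) * (length(sa_l) - 1) +
                     var(sa_w) * (length(sa_w) - 1)) /
                    (length(sa_l) + length(sa_w) - 2))
  expect_gt(effect, 2)
  expect_gt(abs(mean(sa_l) - mean(sa_w)) / pooled_sa, 2)
})

test_that("walking windows hold more gait-band power than lying windows", {
  s <- default_samples(duration_s = 1800, fs = 16, seed = 29)
  windows <- segment(s, 7)
  gait_power <- function(w) {
    psd <- Mod(fft(w$streams$accel_mag))[2:(w$n %/% 2 + 1)]^2
    freqs <- (1:(w$n %/% 2)) * 16 / w$n
    sum(psd[abs(freqs - 1.5) < 0.25])
  }
  lab <- vapply(windows, function(w) w$label, character(1))
  pw <- vapply(windows, gait_power, numeric(1))
  expect_gt(mean(pw[lab == "walking"]), mean(pw[lab == "lying"]))
})
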