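test_that("bout sequences are contiguous, alternating and cover the duration", {
  cfg <- synthetic_config(duration_s = 3600, fs = 8, seed = 3)
  ann <- generate_bout_sequence(cfg)
  expect_equal(ann$start_s[1], 0)
  expect_equal(ann$end_s[nrow(ann)], 3600)
  expect_equal(ann$start_s[-1], ann$end_s[-nrow(ann)])
  expect_true(all(ann$behaviour[-1] != ann$behaviour[-nrow(ann)]))
  expect_setequal(unique(ann$behaviour), SHEEP_BEHAVIOURS)
})

test_that("zero-duration config yields an empty track and negative durations error", {
  cfg <- synthetic_config(duration_s = 0, fs = 16, seed = 1)
  expect_equal(nrow(generate_bout_sequence(cfg)), 0)
  expect_error(synthetic_config(duration_s = -5, fs = 16), "invalid config")
})

test_that("behaviour time shares match an independent bout-process simulation", {
  # exponential bout lengths have sd = mean, so per-behaviour time shares of
  # a single 1 h track scatter by >10%; the comparison is run at 160 h where
  # the Monte-Carlo error of both sides is ~1-2%
  dur <- 576000
  cfg <- synthetic_config(duration_s = dur, fs = 8, seed = 11)
  ann <- generate_bout_sequence(cfg)
  share <- vapply(SHEEP_BEHAVIOURS, function(b)
    sum(ann$end_s[ann$behaviour == b] - ann$start_s[ann$behaviour == b]) / dur,
    numeric(1))
  # brute-force oracle: simulate the alternating-exponential process afresh
  # with independent code
  means <- c(lying = 240, standing = 120, walking = 60)
  set.seed(99)
  tot <- c(lying = 0, standing = 0, walking = 0)
  t <- 0; cur <- "standing"
  while (t < dur) {
    d <- rexp(1, 1 / means[[cur]])
    tot[[cur]] <- tot[[cur]] + min(d, dur - t)
    t <- t + d
    cur <- sample(setdiff(names(means), cur), 1)
  }
  oracle_share <- tot / sum(tot)
  expect_lt(max(abs(share - oracle_share[names(share)])), 0.05)
})

test_that("time shares converge to the analytic means-weighted shares", {
  # alternation kernel is symmetric, so bout types are equifrequent and the
  # law of large numbers drives time shares to mean_b / sum(means)
  dur <- 1e6
  cfg <- synthetic_config(duration_s = dur, fs = 8, seed = 5)
  ann <- generate_bout_sequence(cfg)
  share <- vapply(SHEEP_BEHAVIOURS, function(b)
    sum(ann$end_s[ann$behaviour == b] - ann$start_s[ann$behaviour == b]) / dur,
    numeric(1))
  means <- vapply(cfg$behaviour_models, function(m) m$mean_bout_s, numeric(1))
  expect_lt(max(abs(share - means / sum(means))), 0.02)
})

test_that("recordings are bit-reproducible and sized duration x fs", {
  cfg <- synthetic_config(duration_s = 60, fs = 16, seed = 8)
  ann <- generate_bout_sequence(cfg)
  r1 <- synthesize_recording(ann, cfg)
  r2 <- synthesize_recording(ann, cfg)
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 60 * 16)
})

test_that("noise-free lying bouts give an accelerometer magnitude of exactly 1 g", {
  models <- default_behaviour_models()
  models$lying$accel_noise_sd <- 0
  models$lying$gyro_noise_sd <- 0
  cfg <- synthetic_config(duration_s = 30, fs = 16, seed = 2,
                          behaviour_models = models)
  ann <- annotation_track(data.frame(start_s = 0, end_s = 30,
                                     behaviour = "lying"))
  rec <- synthesize_recording(ann, cfg)
  expect_equal(magnitude(rec$ax, rec$ay, rec$az), rep(1, 480), tolerance = 1e-12)
})

test_that("walking bouts carry more magnitude variance than lying bouts", {
  cfg <- synthetic_config(duration_s = 14400, fs = 8, seed = 21)
  ann <- generate_bout_sequence(cfg)
  rec <- synthesize_recording(ann, cfg)
  amag <- magnitude(rec$ax, rec$ay, rec$az)
  bout_sd <- function(b) {
    rows <- which(ann$behaviour == b)
    vapply(rows, function(i) {
      idx <- which(rec$t >= ann$start_s[i] & rec$t < ann$end_s[i])
      if (length(idx) < 4) NA_real_ else sd(amag[idx])
    }, numeric(1))
  }
  walk <- bout_sd("walking"); lie <- bout_sd("lying")
  expect_gte(length(ann$behaviour), 100)  # enough bouts for a stable contrast
  expect_gt(mean(walk, na.rm = TRUE), mean(lie, na.rm = TRUE))
  # analytic moments: walking sinusoid alone contributes amp/sqrt(2) sd
  expect_gt(mean(walk, na.rm = TRUE), 0.35 / sqrt(2) * 0.8)
  expect_lt(mean(lie, na.rm = TRUE), 0.05)
})

test_that("ear gyroscope variance exceeds collar variance at identical seeds", {
  base <- synthetic_config(duration_s = 300, fs = 16, seed = 13, position = "ear")
  ann <- generate_bout_sequence(base)
  ear <- synthesize_recording(ann, base)
  collar_cfg <- base
  collar_cfg$position <- "collar"
  collar <- synthesize_recording(ann, collar_cfg)
  gvar <- function(r) var(magnitude(r$gx, r$gy, r$gz))
  expect_gt(gvar(ear), gvar(collar))
  # same sub-stream, scaled draws: ear gyro = gain x collar gyro exactly
  expect_equal(ear$gx, 2 * collar$gx, tolerance = 1e-12)
  # accelerometer is unaffected by position gain
  expect_identical(ear$ax, collar$ax)
})

test_that("datasets round-trip losslessly through the CSV readers", {
  cfg <- synthetic_config(duration_s = 600, fs = 16, seed = 4)
  ann <- generate_bout_sequence(cfg)
  rec <- synthesize_recording(ann, cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(rec, ann, dir)
  rec2 <- read_recording(paths[["recording"]], position = "ear")
  ann2 <- read_annotations(paths[["annotation"]])
  expect_equal(nrow(rec2), 9600)
  for (col in names(rec)) expect_identical(rec2[[col]], rec[[col]])
  expect_identical(ann2$behaviour, ann$behaviour)
  expect_identical(ann2$start_s, ann$start_s)
  expect_identical(ann2$end_s, ann$end_s)
})

test_that("an empty annotation writes a header-only file", {
  empty <- annotation_track(data.frame(start_s = numeric(0),
                                       end_s = numeric(0),
                                       behaviour = character(0)))
  cfg <- synthetic_config(duration_s = 0, fs = 16, seed = 1)
  rec <- synthesize_recording(empty, cfg)
  dir <- withr::local_tempdir()
  paths <- write_dataset(rec, empty, dir)
  expect_identical(readLines(paths[["annotation"]]), "start_s,end_s,behaviour")
})

test_that("annotation gaps are rejected by the synthesizer", {
  cfg <- synthetic_config(duration_s = 20, fs = 16, seed = 1)
  gappy <- annotation_track(data.frame(start_s = c(0, 12), end_s = c(10, 20),
                                       behaviour = c("lying", "walking")))
  expect_error(synthesize_recording(gappy, cfg), "gaps")
})

test_that("a YAML config round-trips through read_synthetic_config", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.yaml")
  yaml::write_yaml(list(duration_s = 120, fs = 32, position = "collar",
                        position_gain = list(ear = 2, collar = 1),
                        seed = 7), path)
  cfg <- read_synthetic_config(path)
  expect_s3_class(cfg, "synthetic_config")
  expect_equal(cfg$fs, 32)
  expect_equal(cfg$position, "collar")
  expect_equal(cfg$seed, 7L)
})
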