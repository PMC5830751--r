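#' Behaviour classes of the ethogram
#'
#' The three mutually exclusive behaviour states the classifier
#' distinguishes, in the fixed class order used throughout the package
#' (confusion matrices, kappa weighting, argmax tie-breaks).
#'
#' @format Character vector of length 3: `"lying"`, `"standing"`, `"walking"`.
#' @export
SHEEP_BEHAVIOURS <- c("lying", "standing", "walking")

#' Describe the signal statistics of one behaviour
#'
#' A `behaviour_model` parameterizes how the synthetic generator renders one
#' behaviour state: how long its bouts last on average, the static gravity
#' projection and noise level on the accelerometer, an optional periodic gait
#' component, and the gyroscope noise/oscillation amplitudes.
#'
#' @param behaviour One of [SHEEP_BEHAVIOURS].
#' @param mean_bout_s Mean bout duration in seconds (> 0); bout lengths are
#'   drawn i.i.d. exponential with this mean.
#' @param accel_base Static gravity-projection magnitude in g.
#' @param accel_noise_sd Per-axis accelerometer noise s.d. in g.
#' @param gait_freq_hz Gait oscillation frequency in Hz; 0 for non-walking
#'   behaviours.
#' @param gait_amp Gait oscillation amplitude in g (accelerometer).
#' @param gyro_noise_sd Per-axis gyroscope noise s.d. in deg/s (before the
#'   sensor-position gain is applied).
#' @param gyro_amp Gyroscope gait-oscillation amplitude in deg/s (before gain).
#' @return A `behaviour_model` list.
#' @export
behaviour_model <- function(behaviour, mean_bout_s, accel_base, accel_noise_sd,
                            gait_freq_hz = 0, gait_amp = 0,
                            gyro_noise_sd = 0, gyro_amp = 0) {
  behaviour <- match.arg(behaviour, SHEEP_BEHAVIOURS)
  stopifnot(mean_bout_s > 0, accel_base >= 0, accel_noise_sd >= 0,
            gait_freq_hz >= 0, gait_amp >= 0, gyro_noise_sd >= 0,
            gyro_amp >= 0)
  if (behaviour == "walking" && gait_freq_hz <= 0)
    stop("walking model must have gait_freq_hz > 0")
  structure(list(behaviour = behaviour, mean_bout_s = mean_bout_s,
                 accel_base = accel_base, accel_noise_sd = accel_noise_sd,
                 gait_freq_hz = gait_freq_hz, gait_amp = gait_amp,
                 gyro_noise_sd = gyro_noise_sd, gyro_amp = gyro_amp),
            class = "behaviour_model")
}

#' Default behaviour models
#'
#' Defaults reproduce the qualitative signal ordering seen on pastured sheep:
#' lying is a near-constant 1 g projection with very little noise, standing
#' has moderate noise plus occasional head-movement transients (added by
#' [synthesize_recording()]), and walking carries a 1.5 Hz gait oscillation
#' with the largest amplitudes on both sensors.
#'
#' @return Named list of three [behaviour_model()] objects.
#' @export
default_behaviour_models <- function() {
  list(
    lying    = behaviour_model("lying",    mean_bout_s = 240, accel_base = 1,
                               accel_noise_sd = 0.02, gyro_noise_sd = 5),
    standing = behaviour_model("standing", mean_bout_s = 120, accel_base = 1,
                               accel_noise_sd = 0.08, gyro_noise_sd = 20),
    walking  = behaviour_model("walking",  mean_bout_s = 60,  accel_base = 1,
                               accel_noise_sd = 0.10, gait_freq_hz = 1.5,
                               gait_amp = 0.35, gyro_noise_sd = 60,
                               gyro_amp = 100)
  )
}

#' Configuration for the synthetic IMU data generator
#'
#' @param duration_s Total simulated duration in seconds (>= 0);
#'   `duration_s * fs` must be a whole number of samples.
#' @param fs Sampling frequency in Hz; the study grid uses 8, 16 and 32 Hz
#'   but any positive rate is accepted.
#' @param position Sensor position, `"ear"` or `"collar"`. Ear-mounted
#'   sensors move much more freely than collar-mounted ones, so their
#'   gyroscope amplitudes are scaled up by `position_gain`.
#' @param position_gain Named numeric multipliers on gyroscope amplitudes per
#'   position; the ear gain must exceed the collar gain.
#' @param behaviour_models Named list with exactly one [behaviour_model()]
#'   per behaviour.
#' @param transient_rate_hz Poisson rate of head-movement transients within
#'   standing bouts (events per second).
#' @param transient_amp_g Accelerometer amplitude of one transient, in g.
#' @param transient_gyro_amp Gyroscope amplitude of one transient, in deg/s
#'   (before gain).
#' @param transient_dur_s Duration of one half-sine transient, in seconds.
#' @param seed Integer seed; bout sampling and signal noise draw from
#'   independent sub-streams derived from it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(duration_s = 7200, fs = 16, position = "ear",
                             position_gain = c(ear = 2, collar = 1),
                             behaviour_models = default_behaviour_models(),
                             transient_rate_hz = 0.2, transient_amp_g = 0.2,
                             transient_gyro_amp = 40, transient_dur_s = 0.5,
                             seed = 1L) {
  position <- match.arg(position, c("ear", "collar"))
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s < 0)
    stop("invalid config: duration_s must be a single non-negative number")
  if (!is.numeric(fs) || fs <= 0) stop("invalid config: fs must be positive")
  n <- duration_s * fs
  if (abs(n - round(n)) > 1e-9)
    stop("invalid config: duration_s * fs must be a whole number of samples")
  if (!setequal(names(behaviour_models), SHEEP_BEHAVIOURS))
    stop("invalid config: need exactly one behaviour model per behaviour")
  if (!all(c("ear", "collar") %in% names(position_gain)))
    stop("invalid config: position_gain needs named 'ear' and 'collar' entries")
  structure(list(duration_s = duration_s, fs = fs, position = position,
                 position_gain = position_gain,
                 behaviour_models = behaviour_models[SHEEP_BEHAVIOURS],
                 transient_rate_hz = transient_rate_hz,
                 transient_amp_g = transient_amp_g,
                 transient_gyro_amp = transient_gyro_amp,
                 transient_dur_s = transient_dur_s,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Read a generator configuration from YAML
#'
#' The YAML file mirrors the [synthetic_config()] field names; behaviour
#' models are given as a mapping from behaviour name to model fields.
#'
#' @param path Path to a YAML file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[setdiff(names(raw), "behaviour_models")]
  if (!is.null(raw$behaviour_models)) {
    args$behaviour_models <- lapply(names(raw$behaviour_models), function(b) {
      do.call(behaviour_model, c(list(behaviour = b), raw$behaviour_models[[b]]))
    })
    names(args$behaviour_models) <- names(raw$behaviour_models)
  }
  if (!is.null(args$position_gain)) args$position_gain <- unlist(args$position_gain)
  do.call(synthetic_config, args)
}

# Independent RNG sub-streams from one root seed, so the annotation track and
# the signal noise are separately reproducible.
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Simulate a behaviour bout sequence
#'
#' Draws an alternating sequence of behaviour bouts covering
#' `[0, duration_s)`. Bout durations are i.i.d. exponential with each
#' behaviour's mean; successive bouts never repeat a behaviour (the next
#' state is chosen uniformly among the other two).
#'
#' @param config A [synthetic_config()].
#' @return An `annotation_track`: a data frame with columns `start_s`,
#'   `end_s` (half-open intervals) and `behaviour`, contiguous and ordered.
#' @export
generate_bout_sequence <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$duration_s == 0)
    return(annotation_track(data.frame(start_s = numeric(0), end_s = numeric(0),
                                       behaviour = character(0))))
  seeds <- derive_seeds(config$seed, 2L)
  set.seed(seeds[1])
  means <- vapply(config$behaviour_models, function(m) m$mean_bout_s, 0)
  starts <- list(); durs <- list(); labs <- list()
  t <- 0; i <- 0L
  current <- sample(SHEEP_BEHAVIOURS, 1)
  while (t < config$duration_s) {
    d <- stats::rexp(1, rate = 1 / means[[current]])
    d <- min(d, config$duration_s - t)
    i <- i + 1L
    starts[[i]] <- t; durs[[i]] <- d; labs[[i]] <- current
    t <- t + d
    current <- sample(setdiff(SHEEP_BEHAVIOURS, current), 1)
  }
  starts <- unlist(starts); durs <- unlist(durs)
  annotation_track(data.frame(start_s = starts, end_s = starts + durs,
                              behaviour = unlist(labs),
                              stringsAsFactors = FALSE))
}

# half-sine head-movement transients added within standing bouts
add_transients <- function(n_samples, fs, rate_hz, amp, dur_s) {
  out <- numeric(n_samples)
  if (n_samples == 0 || rate_hz <= 0) return(out)
  n_ev <- stats::rpois(1, rate_hz * n_samples / fs)
  if (n_ev == 0) return(out)
  starts <- sample.int(n_samples, n_ev, replace = TRUE)
  len <- max(2L, round(dur_s * fs))
  shape <- sin(pi * seq(0, 1, length.out = len))
  for (s in starts) {
    idx <- s:min(n_samples, s + len - 1L)
    out[idx] <- out[idx] + amp * shape[seq_along(idx)]
  }
  out
}

#' Render tri-axial IMU signals for an annotated bout sequence
#'
#' For every bout, a gravity orientation is drawn uniformly on the unit
#' sphere and held fixed for the bout. The accelerometer output is the
#' gravity projection (plus, during walking, a gait sinusoid along the
#' gravity axis) with i.i.d. Gaussian per-axis noise; the gyroscope output is
#' a gait oscillation plus Gaussian noise, both scaled by the sensor-position
#' gain. Standing bouts additionally receive occasional half-sine
#' head-movement transients. Output is bit-reproducible given the config seed.
#'
#' @param annotation An `annotation_track` covering `[0, duration_s)` with no
#'   gaps.
#' @param config A [synthetic_config()].
#' @return A `sensor_recording`: data frame columns `t`, `ax`, `ay`, `az`
#'   (g), `gx`, `gy`, `gz` (deg/s), with `fs` and `position` attributes.
#' @export
synthesize_recording <- function(annotation, config) {
  stopifnot(inherits(config, "synthetic_config"))
  annotation <- annotation_track(annotation)
  n <- round(config$duration_s * config$fs)
  if (nrow(annotation) > 0) {
    gaps <- c(annotation$start_s[1] > 1e-9,
              abs(annotation$start_s[-1] - annotation$end_s[-nrow(annotation)]) > 1e-9,
              annotation$end_s[nrow(annotation)] < config$duration_s - 1e-9)
    if (any(gaps)) stop("annotation does not cover [0, duration_s) without gaps")
  } else if (n > 0) stop("annotation does not cover [0, duration_s) without gaps")
  seeds <- derive_seeds(config$seed, 2L)
  set.seed(seeds[2])
  gain <- unname(config$position_gain[[config$position]])
  t <- (seq_len(n) - 1) / config$fs
  acc <- matrix(0, n, 3); gyr <- matrix(0, n, 3)
  bout_of <- findInterval(t, annotation$start_s)
  for (b in seq_len(nrow(annotation))) {
    idx <- which(bout_of == b)
    if (length(idx) == 0) next
    m <- config$behaviour_models[[annotation$behaviour[b]]]
    # fixed gravity orientation for the bout
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    v <- stats::rnorm(3)
    v <- v / sqrt(sum(v^2))
    tb <- t[idx]
    amag <- m$accel_base +
      if (m$gait_freq_hz > 0) m$gait_amp * sin(2 * pi * m$gait_freq_hz * tb) else 0
    gmag <- if (m$gait_freq_hz > 0)
      gain * m$gyro_amp * sin(2 * pi * m$gait_freq_hz * tb) else numeric(length(idx))
    if (annotation$behaviour[b] == "standing") {
      bump <- add_transients(length(idx), config$fs, config$transient_rate_hz,
                             1, config$transient_dur_s)
      amag <- amag + config$transient_amp_g * bump
      gmag <- gmag + gain * config$transient_gyro_amp * bump
    }
    for (k in 1:3) {
      acc[idx, k] <- amag * u[k] +
        m$accel_noise_sd * stats::rnorm(length(idx))
      gyr[idx, k] <- gmag * v[k] +
        gain * m$gyro_noise_sd * stats::rnorm(length(idx))
    }
  }
  sensor_recording(data.frame(t = t, ax = acc[, 1], ay = acc[, 2], az = acc[, 3],
                              gx = gyr[, 1], gy = gyr[, 2], gz = gyr[, 3]),
                   fs = config$fs, position = config$position)
}

#' Write a recording and its annotation track to CSV
#'
#' Values are written with 17 significant digits so that the round trip
#' through [read_recording()] / [read_annotations()] is exact per sample.
#'
#' @param recording A `sensor_recording`.
#' @param annotation An `annotation_track`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the two file paths.
#' @export
write_dataset <- function(recording, annotation, out_dir) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  rec_path <- file.path(out_dir, "recording.csv")
  ann_path <- file.path(out_dir, "annotation.csv")
  fmt <- function(x) sprintf("%.17g", x)
  rec <- data.frame(lapply(recording[c("t", "ax", "ay", "az", "gx", "gy", "gz")], fmt))
  utils::write.csv(rec, rec_path, row.names = FALSE, quote = FALSE)
  ann <- data.frame(start_s = fmt(annotation$start_s), end_s = fmt(annotation$end_s),
                    behaviour = annotation$behaviour)
  utils::write.csv(ann, ann_path, row.names = FALSE, quote = FALSE)
  c(recording = rec_path, annotation = ann_path)
}
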