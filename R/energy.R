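#' Embedded device profile for the energy budget
#'
#' Describes the wearable's storage and energy characteristics. The
#' per-event energy constants are calibrated: least-squares fits of the
#' published per-hour energy figures against the corresponding event counts
#' (about 0.2777 uA h per sample acquisition and 0.2611 uA h per flash
#' write); they are configuration values, not measured constants.
#'
#' @param sram_buffer_bytes SRAM buffer capacity in bytes.
#' @param classification_record_bytes Size of one classification record.
#' @param bytes_per_sample Bytes stored per IMU sample (14 = 7 channels x
#'   16 bit).
#' @param energy_per_acquisition uA h per sample-batch acquisition.
#' @param energy_per_flash_write uA h per flash write.
#' @param processing_energy_per_hour uA h of data-processing energy per hour
#'   (independent of window size).
#' @param battery_capacity_mAh Battery capacity in mA h.
#' @param hours_per_year Hours per year used in battery projections (8766 =
#'   365.25 days).
#' @return A `device_profile` list.
#' @export
device_profile <- function(sram_buffer_bytes = 256,
                           classification_record_bytes = 8,
                           bytes_per_sample = 14,
                           energy_per_acquisition = 0.277650,
                           energy_per_flash_write = 0.261104,
                           processing_energy_per_hour = 1000,
                           battery_capacity_mAh = 270,
                           hours_per_year = 8766) {
  vals <- c(sram_buffer_bytes, classification_record_bytes, bytes_per_sample,
            energy_per_acquisition, energy_per_flash_write,
            processing_energy_per_hour, battery_capacity_mAh, hours_per_year)
  if (any(vals <= 0)) stop("all device profile values must be positive")
  if (classification_record_bytes > sram_buffer_bytes)
    stop("classification record does not fit in the SRAM buffer")
  structure(list(sram_buffer_bytes = sram_buffer_bytes,
                 classification_record_bytes = classification_record_bytes,
                 bytes_per_sample = bytes_per_sample,
                 energy_per_acquisition = energy_per_acquisition,
                 energy_per_flash_write = energy_per_flash_write,
                 processing_energy_per_hour = processing_energy_per_hour,
                 battery_capacity_mAh = battery_capacity_mAh,
                 hours_per_year = hours_per_year),
            class = "device_profile")
}

round_half_up <- function(x) floor(x + 0.5)

#' Duty-cycle counts and energy budget for one configuration
#'
#' Normalized to one hour of classification-mode operation: the sampling
#' rate (hence bytes sampled per hour and data-processing energy) is
#' constant across window sizes; what varies is how often the processor
#' acquires a window's worth of samples and how often the SRAM buffer of
#' classification records fills and is flushed to flash.
#'
#' @param fs Sampling frequency in Hz.
#' @param window_seconds Window length in seconds.
#' @param device A [device_profile()].
#' @return An `energy_report` list: `samples_per_window`,
#'   `bytes_per_window`, `acquisitions_per_hour`, `bytes_per_hour`,
#'   `seconds_per_flush`, `writes_per_hour`, and the energy components in
#'   uA h per hour (`acquisition_energy`, `processing_energy`,
#'   `flash_energy`).
#' @export
window_energy_profile <- function(fs, window_seconds, device = device_profile()) {
  stopifnot(fs > 0, window_seconds > 0)
  samples_per_window <- fs * window_seconds
  records_per_flush <- floor(device$sram_buffer_bytes /
                             device$classification_record_bytes)
  seconds_per_flush <- records_per_flush * window_seconds
  acquisitions_per_hour <- floor(3600 / window_seconds)
  writes_per_hour <- round_half_up(3600 / seconds_per_flush)
  structure(list(
    fs = fs, window_seconds = window_seconds,
    samples_per_window = samples_per_window,
    bytes_per_window = samples_per_window * device$bytes_per_sample,
    acquisitions_per_hour = acquisitions_per_hour,
    bytes_per_hour = fs * 3600 * device$bytes_per_sample,
    seconds_per_flush = seconds_per_flush,
    writes_per_hour = writes_per_hour,
    acquisition_energy = acquisitions_per_hour * device$energy_per_acquisition,
    processing_energy = device$processing_energy_per_hour,
    flash_energy = writes_per_hour * device$energy_per_flash_write),
    class = "energy_report")
}

#' Battery life projection
#'
#' Years of operation for a given hourly drain:
#' `capacity[uA h] / drain[uA h per hour] / hours_per_year`.
#'
#' @param hourly_drain_uAh Drain in uA h per hour (> 0).
#' @param device A [device_profile()].
#' @return Battery life in years.
#' @export
battery_life_years <- function(hourly_drain_uAh, device = device_profile()) {
  if (hourly_drain_uAh <= 0) stop("hourly drain must be positive")
  device$battery_capacity_mAh * 1000 / hourly_drain_uAh / device$hours_per_year
}

#' Energy budget table over a window-size grid
#'
#' One column per window size, rows mirroring the duty-cycle and energy
#' measures of the published budget table.
#'
#' @param fs Sampling frequency in Hz.
#' @param window_seconds_set Window sizes in seconds.
#' @param device A [device_profile()].
#' @return Data frame, first column `measure`.
#' @export
energy_table <- function(fs = 16, window_seconds_set = c(3, 5, 7),
                         device = device_profile()) {
  reps <- lapply(window_seconds_set, window_energy_profile, fs = fs,
                 device = device)
  cell <- function(field) vapply(reps, function(r) r[[field]], numeric(1))
  df <- data.frame(
    measure = c("samples_per_window", "bytes_per_window",
                "acquisitions_per_hour", "acquisition_energy_uAh",
                "bytes_per_hour", "processing_energy_uAh",
                "sram_buffer_bytes", "classification_record_bytes",
                "seconds_per_flush", "writes_per_hour", "flash_energy_uAh"))
  vals <- rbind(cell("samples_per_window"), cell("bytes_per_window"),
                cell("acquisitions_per_hour"), cell("acquisition_energy"),
                cell("bytes_per_hour"), cell("processing_energy"),
                rep(device$sram_buffer_bytes, length(reps)),
                rep(device$classification_record_bytes, length(reps)),
                cell("seconds_per_flush"), cell("writes_per_hour"),
                cell("flash_energy"))
  colnames(vals) <- paste0(window_seconds_set, "s")
  cbind(df, as.data.frame(vals))
}

#' Read a device profile from YAML
#' @param path YAML file whose keys mirror [device_profile()] arguments.
#' @return A `device_profile`.
#' @export
read_device_profile <- function(path) {
  do.call(device_profile, yaml::read_yaml(path))
}
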