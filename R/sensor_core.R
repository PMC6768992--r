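#' @importFrom stats fft rnorm runif rexp rbinom sd cor
#' @importFrom utils head tail
NULL

SENSOR_IDS <- c("left_wrist", "right_wrist", "chest")
ACCEL_RANGE_G <- 8
GYRO_RANGE_DPS <- 2000

#' Construct an IMU recording
#'
#' A recording is one sensor's continuous 6-channel session: tri-axial
#' acceleration in g and tri-axial angular rate in deg/s, sampled at a
#' nominal rate. Timestamps are reconstructed from the start time and the
#' sampling rate (`start_time_ms + 1000 * i / sampling_rate_hz`); they are
#' not stored per sample. The x axis is the longitudinal axis: parallel to
#' the lower arm for the wrist sensors and parallel to the trunk for the
#' chest sensor.
#'
#' @param participant_id Participant identifier.
#' @param sensor_id One of `"left_wrist"`, `"right_wrist"`, `"chest"`.
#' @param sampling_rate_hz Nominal sampling rate in Hz (device default 200).
#' @param start_time_ms Start time, integer milliseconds since Unix epoch (UTC).
#' @param accel Numeric matrix, n x 3, acceleration in g. Physical range
#'   +/- 8 g.
#' @param gyro Numeric matrix, n x 3, angular rate in deg/s. Physical range
#'   +/- 2000 deg/s.
#' @param timezone Olson timezone name used to resolve local clock times
#'   (the wearing protocol is defined in local time).
#' @return An object of class `imu_recording`.
#' @export
imu_recording <- function(participant_id, sensor_id, sampling_rate_hz,
                          start_time_ms, accel, gyro, timezone = "UTC") {
  sensor_id <- match.arg(sensor_id, SENSOR_IDS)
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1 ||
      sampling_rate_hz <= 0) {
    stop("sampling_rate_hz must be a single positive number")
  }
  accel <- as_channel_matrix(accel, "accel")
  gyro <- as_channel_matrix(gyro, "gyro")
  if (nrow(accel) != nrow(gyro)) {
    stop("accel and gyro must have the same number of samples")
  }
  if (nrow(accel) > 0) {
    if (max(abs(accel)) > ACCEL_RANGE_G + 1e-9) {
      stop("accel samples outside the physical range of +/- 8 g; ",
           "clip before constructing (read_recording does this)")
    }
    if (max(abs(gyro)) > GYRO_RANGE_DPS + 1e-6) {
      stop("gyro samples outside the physical range of +/- 2000 deg/s")
    }
  }
  structure(
    list(participant_id = as.character(participant_id),
         sensor_id = sensor_id,
         sampling_rate_hz = as.numeric(sampling_rate_hz),
         start_time_ms = as.numeric(start_time_ms),
         accel = accel, gyro = gyro,
         timezone = timezone),
    class = "imu_recording")
}

# fast internal constructor: trusted inputs, no range validation / copies
new_imu_recording <- function(participant_id, sensor_id, sampling_rate_hz,
                              start_time_ms, accel, gyro, timezone = "UTC") {
  structure(
    list(participant_id = participant_id, sensor_id = sensor_id,
         sampling_rate_hz = sampling_rate_hz,
         start_time_ms = as.numeric(start_time_ms),
         accel = accel, gyro = gyro, timezone = timezone),
    class = "imu_recording")
}

as_channel_matrix <- function(m, what) {
  if (is.null(m) || length(m) == 0) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, paste0(substr(what, 1, 1), c("x", "y", "z")))))
  }
  m <- as.matrix(m)
  if (ncol(m) != 3) stop(what, " must have 3 columns (x, y, z)")
  storage.mode(m) <- "double"
  colnames(m) <- paste0(substr(what, 1, 1), c("x", "y", "z"))
  m
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %s / %s: %d samples @ %g Hz (%.1f s) from %s\n",
              x$participant_id, x$sensor_id, n_samples(x), x$sampling_rate_hz,
              duration_s(x),
              format(ms_to_posix(x$start_time_ms, x$timezone), "%Y-%m-%d %H:%M:%OS")))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `imu_recording`.
#' @export
n_samples <- function(rec) nrow(rec$accel)

#' Recording duration in seconds (n / fs)
#' @param rec An `imu_recording`.
#' @export
duration_s <- function(rec) n_samples(rec) / rec$sampling_rate_hz

#' Reconstructed sample timestamps in epoch milliseconds
#' @param rec An `imu_recording`.
#' @export
timestamps_ms <- function(rec) {
  n <- n_samples(rec)
  if (n == 0) return(numeric(0))
  rec$start_time_ms + (seq_len(n) - 1) * 1000 / rec$sampling_rate_hz
}

ms_to_posix <- function(ms, tz = "UTC") as.POSIXct(ms / 1000, origin = "1970-01-01", tz = tz)

posix_to_ms <- function(t) as.numeric(t) * 1000

#' Slice a recording to a half-open time interval
#'
#' Returns the samples whose reconstructed timestamp falls in `[t0_ms, t1_ms)`.
#' Half-open intervals tile gaplessly, so adjacent slices concatenate back to
#' the original. An interval with no overlap yields an empty recording.
#'
#' @param rec An `imu_recording`.
#' @param t0_ms,t1_ms Interval bounds in epoch milliseconds, `t0_ms < t1_ms`.
#' @return An `imu_recording` whose start time is the timestamp of its first
#'   retained sample (unchanged start if the slice is empty).
#' @export
slice_time <- function(rec, t0_ms, t1_ms) {
  if (!is.numeric(t0_ms) || !is.numeric(t1_ms) || t0_ms >= t1_ms) {
    stop("need t0_ms < t1_ms")
  }
  n <- n_samples(rec)
  fs <- rec$sampling_rate_hz
  # sample i (0-based) has t = start + 1000*i/fs; keep t0 <= t < t1
  i0 <- ceiling((t0_ms - rec$start_time_ms) * fs / 1000 - 1e-9)
  i1 <- ceiling((t1_ms - rec$start_time_ms) * fs / 1000 - 1e-9) - 1
  i0 <- max(i0, 0)
  i1 <- min(i1, n - 1)
  if (i1 < i0) {
    keep <- integer(0)
    new_start <- rec$start_time_ms
  } else {
    keep <- seq.int(i0 + 1, i1 + 1)
    new_start <- rec$start_time_ms + 1000 * i0 / fs
  }
  out <- rec
  out$accel <- rec$accel[keep, , drop = FALSE]
  out$gyro <- rec$gyro[keep, , drop = FALSE]
  out$start_time_ms <- new_start
  out
}

#' Construct a recording session
#'
#' A session spans charger removal to charger reconnection; the device
#' records continuously in between, whether or not it is worn. The recording
#' duration must match the session span to within one sample period.
#'
#' @param recording An `imu_recording`.
#' @param session_start_ms,session_end_ms Session bounds in epoch ms.
#'   Defaults derive from the recording itself.
#' @return An object of class `recording_session`.
#' @export
recording_session <- function(recording,
                              session_start_ms = recording$start_time_ms,
                              session_end_ms = NULL) {
  if (is.null(session_end_ms)) {
    session_end_ms <- recording$start_time_ms + 1000 * duration_s(recording)
  }
  if (session_end_ms <= session_start_ms) stop("session_end must follow session_start")
  span_s <- (session_end_ms - session_start_ms) / 1000
  if (abs(span_s - duration_s(recording)) > 1 / recording$sampling_rate_hz + 1e-9) {
    stop("recording duration does not match the session span")
  }
  structure(list(recording = recording,
                 session_start_ms = as.numeric(session_start_ms),
                 session_end_ms = as.numeric(session_end_ms)),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("<recording_session> %.1f min\n",
              (x$session_end_ms - x$session_start_ms) / 60000))
  print(x$recording)
  invisible(x)
}

metadata_path <- function(path) sub("\\.csv$", ".json", path)

#' Read an IMU recording from its CSV + JSON sidecar
#'
#' The CSV holds columns `t_ms, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps`;
#' the sidecar (same path with `.json` extension) holds `participant_id,
#' sensor_id, sampling_rate_hz, start_time_ms, timezone`. Samples outside the
#' physical ranges (+/- 8 g, +/- 2000 deg/s) are clipped to the range — real
#' sensors saturate — and the number of clipped values is returned in the
#' `n_clipped` attribute.
#'
#' @param path Path to the sensor CSV file.
#' @return An `imu_recording` with attribute `n_clipped`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  meta_file <- metadata_path(path)
  if (!file.exists(meta_file)) stop("missing sidecar metadata: ", meta_file)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  need <- c("participant_id", "sensor_id", "sampling_rate_hz", "start_time_ms")
  if (!all(need %in% names(meta))) {
    stop("sidecar metadata missing field(s): ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  }
  dt <- data.table::fread(path, colClasses = "numeric")
  cols <- c("t_ms", "ax_g", "ay_g", "az_g", "gx_dps", "gy_dps", "gz_dps")
  if (!all(cols %in% names(dt))) {
    stop("sensor CSV missing column(s): ",
         paste(setdiff(cols, names(dt)), collapse = ", "))
  }
  if (nrow(dt) > 1 && any(diff(dt$t_ms) <= 0)) {
    stop("non-monotonic timestamps in ", path)
  }
  accel <- as.matrix(dt[, c("ax_g", "ay_g", "az_g")])
  gyro <- as.matrix(dt[, c("gx_dps", "gy_dps", "gz_dps")])
  n_clipped <- sum(abs(accel) > ACCEL_RANGE_G) + sum(abs(gyro) > GYRO_RANGE_DPS)
  if (n_clipped > 0) {
    accel <- pmin(pmax(accel, -ACCEL_RANGE_G), ACCEL_RANGE_G)
    gyro <- pmin(pmax(gyro, -GYRO_RANGE_DPS), GYRO_RANGE_DPS)
    warning(n_clipped, " sample value(s) outside physical range were clipped")
  }
  rec <- imu_recording(meta$participant_id, meta$sensor_id,
                       meta$sampling_rate_hz, meta$start_time_ms,
                       accel, gyro,
                       timezone = meta$timezone %||% "UTC")
  attr(rec, "n_clipped") <- n_clipped
  rec
}

#' Write an IMU recording to CSV + JSON sidecar
#'
#' Inverse of [read_recording()]; floats are written with enough digits for a
#' lossless round trip at 6-decimal precision. An empty recording yields a
#' header-only CSV.
#'
#' @param rec An `imu_recording`.
#' @param path Destination CSV path; the metadata sidecar is written next to
#'   it with a `.json` extension.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "imu_recording"))
  dt <- data.table::data.table(
    t_ms = timestamps_ms(rec),
    ax_g = rec$accel[, 1], ay_g = rec$accel[, 2], az_g = rec$accel[, 3],
    gx_dps = rec$gyro[, 1], gy_dps = rec$gyro[, 2], gz_dps = rec$gyro[, 3])
  data.table::fwrite(dt, path)
  jsonlite::write_json(
    list(participant_id = rec$participant_id,
         sensor_id = rec$sensor_id,
         sampling_rate_hz = rec$sampling_rate_hz,
         start_time_ms = rec$start_time_ms,
         timezone = rec$timezone),
    metadata_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
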