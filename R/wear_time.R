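#' Non-wear detection and wear-time accounting
#'
#' The device records from charger removal to reconnection, so part of each
#' session is recorded but not worn (showers, the sensor on a table). Worn
#' minutes are identified from the per-minute standard deviation of the
#' longitudinal (x) acceleration: a minute is non-worn only when its own
#' standard deviation and that of both the preceding and following minutes
#' fall below 0.002 g. Wear time is reported in three categories: worn within
#' the instructed 08:00-22:00 timeframe, non-worn within it, and worn outside
#' it.
#'
#' @name wear_time
NULL

#' Per-minute standard deviation of the x acceleration
#'
#' Computes the population standard deviation of the x-axis acceleration over
#' consecutive complete 60-second blocks aligned to the session start; a
#' trailing partial minute is dropped. Gravity is not removed: a resting worn
#' sensor has a near-constant x channel including gravity, and the threshold
#' applies to the raw signal.
#'
#' @param session A `recording_session` (or bare `imu_recording`).
#' @return Data.frame `minute_start_ms, std_x` with attributes
#'   `participant_id` and `sensor_id`; zero rows for sessions under a minute.
#' @export
minute_std <- function(session) {
  rec <- if (inherits(session, "recording_session")) session$recording else session
  stopifnot(inherits(rec, "imu_recording"))
  fs <- rec$sampling_rate_hz
  spm <- round(60 * fs)
  x <- rec$accel[, 1]
  n_min <- floor(length(x) / spm)
  if (n_min == 0) {
    out <- data.frame(minute_start_ms = numeric(0), std_x = numeric(0))
  } else {
    m <- matrix(x[seq_len(n_min * spm)], nrow = spm)
    mu <- colMeans(m)
    v <- colMeans(m * m) - mu * mu
    out <- data.frame(
      minute_start_ms = rec$start_time_ms + (seq_len(n_min) - 1) * 60000,
      std_x = sqrt(pmax(v, 0)))
  }
  attr(out, "participant_id") <- rec$participant_id
  attr(out, "sensor_id") <- rec$sensor_id
  out
}

#' Classify minutes as worn / non-worn
#'
#' A minute is non-worn iff its x-acceleration standard deviation is below
#' `threshold_g` and every existing neighbouring minute is below the
#' threshold too; otherwise it is worn. Edge minutes apply the rule
#' one-sided (only the neighbours that exist must be sub-threshold), the
#' minimal consistent extension of the triple-minute rule.
#'
#' @param std_x Numeric vector of per-minute standard deviations in g (or a
#'   data.frame from [minute_std()]).
#' @param threshold_g Threshold in g; the empirically determined device value
#'   is 0.002 g.
#' @return Logical vector, `TRUE` = worn.
#' @export
classify_worn <- function(std_x, threshold_g = 0.002) {
  if (is.data.frame(std_x)) std_x <- std_x$std_x
  if (threshold_g <= 0) stop("threshold_g must be positive")
  n <- length(std_x)
  if (n == 0) return(logical(0))
  below <- std_x < threshold_g
  prev_ok <- c(TRUE, below[-n])   # missing neighbour counts as satisfied
  next_ok <- c(below[-1], TRUE)
  !(below & prev_ok & next_ok)
}

#' Summarize one sensor-day of wear flags into the three categories
#'
#' `worn_within_min` counts worn minutes whose minute block starts inside the
#' instructed timeframe (default local 08:00-22:00, 840 minutes);
#' `worn_outside_min` counts worn minutes outside it; `nonworn_within_min` is
#' the frame length minus `worn_within_min`, so charging or otherwise
#' unrecorded time counts as non-worn.
#'
#' @param worn Logical worn flag per minute (from [classify_worn()]).
#' @param minute_start_ms Start of each minute block, epoch ms.
#' @param tz Timezone resolving the local timeframe.
#' @param frame Length-2 local clock times bounding the instructed timeframe.
#' @return Named numeric: `worn_within_min, nonworn_within_min,
#'   worn_outside_min`.
#' @export
summarize_wear <- function(worn, minute_start_ms, tz = "UTC",
                           frame = c("08:00", "22:00")) {
  stopifnot(length(worn) == length(minute_start_ms))
  hhmm_min <- function(s) {
    p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
    p[1] * 60 + p[2]
  }
  f0 <- hhmm_min(frame[1]); f1 <- hhmm_min(frame[2])
  frame_len <- f1 - f0
  if (length(worn) == 0) {
    return(c(worn_within_min = 0, nonworn_within_min = frame_len,
             worn_outside_min = 0))
  }
  lt <- as.POSIXlt(ms_to_posix(minute_start_ms, tz))
  mins_of_day <- lt$hour * 60 + lt$min + lt$sec / 60
  within <- mins_of_day >= f0 & mins_of_day < f1
  worn_within <- sum(worn & within)
  c(worn_within_min = worn_within,
    nonworn_within_min = frame_len - worn_within,
    worn_outside_min = sum(worn & !within))
}

#' Worn-time intervals for a sensor-day
#'
#' Converts minute-level worn flags into merged half-open time intervals in
#' epoch ms, the availability input expected by [has_sensor_coverage()].
#'
#' @inheritParams summarize_wear
#' @return Two-column matrix (`start`, `end`).
#' @export
worn_intervals <- function(worn, minute_start_ms) {
  keep <- which(worn)
  if (length(keep) == 0) return(cbind(start = numeric(0), end = numeric(0)))
  merge_intervals(minute_start_ms[keep], minute_start_ms[keep] + 60000)
}

#' Aggregate wear summaries across sensors, days and participants
#'
#' Minutes are averaged first over the three sensors within a participant-day,
#' then over days within a participant, then over participants, and reported
#' both in minutes and as percentages of the instructed frame.
#'
#' @param summaries Data.frame with columns `participant_id, day_index,
#'   sensor_id, worn_within_min, nonworn_within_min, worn_outside_min`.
#' @param frame_min Instructed timeframe length in minutes.
#' @return List with `mean_min` (named means of the three categories plus
#'   `total_worn`) and `percent_of_frame`.
#' @export
aggregate_wear <- function(summaries, frame_min = 840) {
  stopifnot(nrow(summaries) > 0)
  cats <- c("worn_within_min", "nonworn_within_min", "worn_outside_min")
  per_day <- stats::aggregate(summaries[cats],
    by = summaries[c("participant_id", "day_index")], FUN = mean)
  per_part <- stats::aggregate(per_day[cats],
    by = per_day["participant_id"], FUN = mean)
  mean_min <- colMeans(per_part[cats])
  mean_min <- c(mean_min, total_worn = unname(
    mean_min["worn_within_min"] + mean_min["worn_outside_min"]))
  list(mean_min = mean_min,
       percent_of_frame = 100 * mean_min[cats] / frame_min)
}
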