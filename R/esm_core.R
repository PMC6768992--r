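#' ESM protocol engine
#'
#' The experience sampling method (ESM) protocol issues, per day, seven
#' "continuous" questionnaires (26 items) at semi-random moments — one inside
#' each 2-hour block between 08:00 and 22:00 local time — plus one morning
#' (5 items) and one evening (8 items) questionnaire available in fixed
#' windows. A continuous questionnaire must be opened within 15 minutes of
#' the beep to count.
#'
#' @name esm
NULL

ESM_N_ITEMS <- c(continuous = 26L, morning = 5L, evening = 8L)
ESM_DAY_START <- "08:00"
ESM_N_BLOCKS <- 7L
ESM_BLOCK_H <- 2
ESM_OPEN_DEADLINE_MIN <- 15

local_ms <- function(date, hhmm, tz) {
  posix_to_ms(as.POSIXct(paste(as.Date(date), hhmm), tz = tz))
}

#' Generate an ESM beep schedule
#'
#' Draws, for each day, one continuous beep uniformly inside each of the
#' seven 2-hour blocks spanning 08:00-22:00 local time, subject to a minimum
#' gap between consecutive beeps (redrawn on violation, so beeps are never
#' back-to-back across a block boundary); plus one morning and one evening
#' event. Deterministic given `seed`.
#'
#' @param n_days Number of protocol days (the study protocol uses 14).
#' @param start_date First protocol day (anything `as.Date` accepts).
#' @param seed Integer seed; the same seed reproduces the schedule exactly.
#' @param tz Olson timezone of the participant.
#' @param min_gap_min Minimum gap between consecutive continuous beeps, minutes.
#' @param morning_window,evening_window Length-2 character vectors of local
#'   clock times bounding availability of the morning and evening
#'   questionnaires. The evening window may cross midnight conceptually; the
#'   default ends at 24:00.
#' @return A data.frame of events: `event_id, kind, day_index, block_index,
#'   scheduled_ms, deadline_ms` (`block_index` is `NA` for morning/evening).
#'   For continuous events `deadline_ms = scheduled_ms + 15 min`; for
#'   morning/evening it is the end of the availability window.
#' @export
generate_schedule <- function(n_days, start_date, seed, tz = "UTC",
                              min_gap_min = 15,
                              morning_window = c("06:00", "12:00"),
                              evening_window = c("18:00", "24:00")) {
  if (!is.numeric(n_days) || n_days < 1) stop("n_days must be >= 1")
  n_days <- as.integer(n_days)
  start_date <- as.Date(start_date)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  rows <- vector("list", n_days)
  block_ms <- ESM_BLOCK_H * 3600 * 1000
  gap_ms <- min_gap_min * 60 * 1000
  for (d in seq_len(n_days)) {
    date_d <- start_date + (d - 1)
    day0 <- local_ms(date_d, ESM_DAY_START, tz)
    beeps <- numeric(ESM_N_BLOCKS)
    prev <- -Inf
    for (b in seq_len(ESM_N_BLOCKS)) {
      lo <- day0 + (b - 1) * block_ms
      hi <- lo + block_ms
      repeat {
        t <- lo + runif(1) * block_ms
        if (t - prev >= gap_ms) break
        # infeasible only if prev + gap >= hi, impossible for gap < block
        if (prev + gap_ms >= hi) { t <- hi - 1; break }
      }
      beeps[b] <- t
      prev <- t
    }
    # evening window ending 24:00 = start of next day
    ev_end <- if (evening_window[2] == "24:00") {
      local_ms(date_d + 1, "00:00", tz)
    } else {
      local_ms(date_d, evening_window[2], tz)
    }
    rows[[d]] <- data.frame(
      event_id = c(sprintf("d%02db%d", d, seq_len(ESM_N_BLOCKS)),
                   sprintf("d%02dM", d), sprintf("d%02dE", d)),
      kind = c(rep("continuous", ESM_N_BLOCKS), "morning", "evening"),
      day_index = d,
      block_index = c(seq_len(ESM_N_BLOCKS), NA_integer_, NA_integer_),
      scheduled_ms = c(beeps,
                       local_ms(date_d, morning_window[1], tz),
                       local_ms(date_d, evening_window[1], tz)),
      deadline_ms = c(beeps + ESM_OPEN_DEADLINE_MIN * 60 * 1000,
                      local_ms(date_d, morning_window[2], tz),
                      ev_end),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

answer_cols <- function(n = max(ESM_N_ITEMS)) sprintf("a%02d", seq_len(n))

#' Build an empty ESM response table for a schedule
#'
#' One row per event with `opened_ms/started_ms/ended_ms` and answer columns
#' `a01..a26` all `NA` (an unanswered beep). Items beyond a kind's item count
#' (26 continuous, 5 morning, 8 evening) stay `NA` by convention.
#'
#' @param events Schedule data.frame from [generate_schedule()].
#' @return A response data.frame.
#' @export
empty_responses <- function(events) {
  out <- data.frame(event_id = events$event_id, kind = events$kind,
                    opened_ms = NA_real_, started_ms = NA_real_,
                    ended_ms = NA_real_, stringsAsFactors = FALSE)
  for (cl in answer_cols()) out[[cl]] <- NA_real_
  out
}

#' Is a response fully completed?
#'
#' Only fully completed questionnaires count as completed: every one of the
#' kind's items (26 continuous, 5 morning, 8 evening) must carry an answer.
#'
#' @param responses Response data.frame (rows are responses; must carry a
#'   `kind` column and answer columns `a01..`).
#' @return Logical vector, one value per response row.
#' @export
is_complete <- function(responses) {
  n_items <- ESM_N_ITEMS[responses$kind]
  if (anyNA(n_items)) stop("unknown questionnaire kind")
  ans <- as.matrix(responses[, answer_cols(), drop = FALSE])
  answered <- !is.na(ans)
  in_range <- col(ans) <= as.vector(n_items)  # recycles per row (column-major)
  unname(rowSums(answered & in_range) == n_items & rowSums(answered) == n_items)
}

#' Completion report for one participant
#'
#' Per questionnaire kind: number issued, number completed (fully answered
#' and, for continuous questionnaires, opened no later than 15 minutes after
#' the beep), and the completion rate in percent. The validity flag is true
#' when at least one third of the continuous questionnaires were completed —
#' the usual threshold for valid ESM data.
#'
#' @param events Schedule data.frame from [generate_schedule()].
#' @param responses Response data.frame referencing those events.
#' @return A list with `by_kind` (data.frame `kind, n_issued, n_completed,
#'   rate_percent`) and `validity_flag`.
#' @export
completion_report <- function(events, responses) {
  if (nrow(events) == 0) stop("no events issued; completion rate undefined")
  if (!all(responses$event_id %in% events$event_id)) {
    stop("responses reference unknown events")
  }
  idx <- match(responses$event_id, events$event_id)
  responses$kind <- events$kind[idx]
  deadline <- events$deadline_ms[idx]
  comp <- is_complete(responses)
  on_time <- is.na(responses$opened_ms) | responses$opened_ms <= deadline
  comp <- comp & on_time
  kinds <- c("continuous", "morning", "evening")
  by_kind <- data.frame(kind = kinds,
                        n_issued = vapply(kinds, function(k) sum(events$kind == k), 0),
                        n_completed = vapply(kinds, function(k) sum(comp[responses$kind == k]), 0),
                        stringsAsFactors = FALSE)
  if (any(by_kind$n_issued == 0)) {
    by_kind <- by_kind[by_kind$n_issued > 0, , drop = FALSE]
  }
  if (nrow(by_kind) == 0) stop("no events issued; completion rate undefined")
  by_kind$rate_percent <- 100 * by_kind$n_completed / by_kind$n_issued
  cont <- by_kind[by_kind$kind == "continuous", ]
  validity <- nrow(cont) == 1 && cont$n_completed / cont$n_issued >= 1 / 3
  list(by_kind = by_kind, validity_flag = validity)
}

#' Aggregate completion reports across participants
#'
#' Counts are first averaged per participant, then across participants, and
#' the group rate is the ratio of mean completed to mean issued (so a mean of
#' 77.5 completed out of 98 issued reports as 79.1%).
#'
#' @param reports List of per-participant results from [completion_report()].
#' @return Data.frame `kind, mean_issued, mean_completed, rate_percent`.
#' @export
aggregate_completion <- function(reports) {
  stopifnot(length(reports) > 0)
  tabs <- lapply(reports, `[[`, "by_kind")
  kinds <- unique(unlist(lapply(tabs, `[[`, "kind")))
  out <- do.call(rbind, lapply(kinds, function(k) {
    iss <- vapply(tabs, function(t) {
      v <- t$n_issued[t$kind == k]; if (length(v)) v else NA_real_
    }, 0)
    comp <- vapply(tabs, function(t) {
      v <- t$n_completed[t$kind == k]; if (length(v)) v else NA_real_
    }, 0)
    data.frame(kind = k,
               mean_issued = mean(iss, na.rm = TRUE),
               mean_completed = mean(comp, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  out$rate_percent <- 100 * out$mean_completed / out$mean_issued
  out
}

merge_intervals <- function(start, end) {
  if (length(start) == 0) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(outs, ms), end = c(oute, me))
}

coverage_ms <- function(intervals, t0, t1) {
  if (nrow(intervals) == 0) return(0)
  s <- pmax(intervals[, 1], t0)
  e <- pmin(intervals[, 2], t1)
  sum(pmax(e - s, 0))
}

as_sensor_intervals <- function(x) {
  if (inherits(x, "recording_session")) {
    return(cbind(start = x$session_start_ms, end = x$session_end_ms))
  }
  if (is.list(x) && length(x) && all(vapply(x, inherits, TRUE, "recording_session"))) {
    return(merge_intervals(vapply(x, `[[`, 0, "session_start_ms"),
                           vapply(x, `[[`, 0, "session_end_ms")))
  }
  m <- as.matrix(as.data.frame(x)[, 1:2])
  merge_intervals(m[, 1], m[, 2])
}

#' Pre-questionnaire sensor coverage check
#'
#' A completed questionnaire is usable for sensor analysis only when all
#' three sensor positions have data for the full window before the moment the
#' questionnaire was opened (default 15 minutes). Availability intervals may
#' be recording sessions or — after non-wear filtering — worn-time intervals.
#' A cumulative gap of up to `gap_tol_s` inside the window is tolerated so
#' single-sample seams do not fail the check.
#'
#' @param opened_ms Time the questionnaire was opened, epoch ms.
#' @param sensors Named list with entries `left_wrist`, `right_wrist`,
#'   `chest`; each entry is a `recording_session`, a list of sessions, or a
#'   two-column (start, end) structure of availability intervals in epoch ms.
#' @param window_min Pre-questionnaire window length in minutes.
#' @param gap_tol_s Cumulative gap tolerance in seconds.
#' @return `TRUE` if every sensor covers the window, else `FALSE`.
#' @export
has_sensor_coverage <- function(opened_ms, sensors, window_min = 15,
                                gap_tol_s = 1) {
  if (is.na(opened_ms)) stop("opened_ms is absent; coverage undefined")
  if (!all(SENSOR_IDS %in% names(sensors))) {
    stop("sensors must name all of: ", paste(SENSOR_IDS, collapse = ", "))
  }
  t0 <- opened_ms - window_min * 60 * 1000
  need <- window_min * 60 * 1000 - gap_tol_s * 1000
  for (sid in SENSOR_IDS) {
    iv <- as_sensor_intervals(sensors[[sid]])
    if (coverage_ms(iv, t0, opened_ms) < need) return(FALSE)
  }
  TRUE
}

#' Write / read ESM schedule and response CSVs
#'
#' Plain-text schemas: events `event_id, kind, day_index, block_index,
#' scheduled_ms, deadline_ms`; responses `event_id, kind, opened_ms,
#' started_ms, ended_ms, a01..a26` (empty cell = unanswered).
#'
#' @param events,responses Data.frames as produced by [generate_schedule()]
#'   and [empty_responses()]/[simulate_responses()].
#' @param path CSV destination / source.
#' @name esm_io
#' @export
write_esm_events <- function(events, path) {
  data.table::fwrite(events, path)
  invisible(path)
}

#' @rdname esm_io
#' @export
read_esm_events <- function(path) {
  as.data.frame(data.table::fread(path,
    colClasses = list(character = c("event_id", "kind"))))
}

#' @rdname esm_io
#' @export
write_esm_responses <- function(responses, path) {
  data.table::fwrite(responses, path)
  invisible(path)
}

#' @rdname esm_io
#' @export
read_esm_responses <- function(path) {
  as.data.frame(data.table::fread(path,
    colClasses = list(character = c("event_id", "kind"))))
}
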