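#' Synthetic cohort generator
#'
#' Generates a full synthetic monitoring cohort — three-sensor IMU days with
#' a latent ON/OFF state trajectory, planted non-wear intervals, and ESM
#' responses — so every downstream stage (non-wear detection, coverage
#' accounting, feature extraction, OFF prediction) can be exercised without
#' any real recordings. The latent state is a two-state alternating-renewal
#' process with exponential dwell times; tremor is a single-frequency
#' sinusoid in the classic 4-6 Hz rest-tremor band whose amplitude switches
#' with the state, voluntary activity is band-limited (< 3 Hz) noise scaled
#' down during OFF, and non-wear replaces the signal by constant gravity
#' plus a noise floor far below the 0.002 g detection threshold.
#'
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults mirror the monitoring protocol: 20 participants, 14 days,
#' 200 Hz sampling, sensors worn 08:00-22:00 local time, 79% continuous-
#' questionnaire compliance, and a mean completion time of 219 s. Non-wear
#' defaults (2 removal events/day of mean 26 min, simultaneous on all three
#' sensors) give an expected 52 non-worn minutes per day inside the frame.
#'
#' @param n_participants,n_days Cohort dimensions.
#' @param sampling_rate_hz IMU sampling rate (device: 200 Hz).
#' @param off_mean_duration_min,on_mean_duration_min Mean dwell times of the
#'   alternating OFF/ON renewal process, minutes. A zero mean removes that
#'   state entirely.
#' @param tremor_freq_hz Tremor frequency, inside 4-6 Hz.
#' @param tremor_amp_off_g,tremor_amp_on_g Tremor sinusoid amplitude (g)
#'   during OFF / ON segments.
#' @param activity_amp_g Standard deviation (g) of the band-limited (< 3 Hz)
#'   voluntary-activity component during ON.
#' @param activity_scale_off Multiplier on activity amplitude during OFF
#'   (bradykinesia: less movement when OFF).
#' @param noise_std_g Wide-band sensor/body noise while worn, g.
#' @param gyro_noise_dps Wide-band gyroscope noise while worn, deg/s.
#' @param gyro_scale_dps_per_g Fixed conversion applied to the activity and
#'   tremor amplitudes on the gyroscope channels, deg/s per g.
#' @param nonwear_events_per_day Poisson mean of daily removal events.
#' @param nonwear_mean_duration_min Mean (exponential) removal duration, min.
#' @param nonwear_noise_g Acceleration noise floor while off-body, g; well
#'   below the 0.002 g non-wear threshold.
#' @param wear_start,wear_end Local clock span of the daily recording
#'   session (charger removal / reconnection).
#' @param tz Olson timezone.
#' @param compliance_open_prob Probability a continuous questionnaire is
#'   opened (in time) and completed.
#' @param compliance_morning_prob,compliance_evening_prob Same for the
#'   morning / evening questionnaires.
#' @param completion_duration_mean_s Mean time to complete the continuous
#'   questionnaire, seconds.
#' @param off_item_index Index of the designated OFF item among the 26.
#' @param off_item_mean_off,off_item_mean_on,off_item_sd Gaussian answer
#'   model for the designated item: Likert = clamped round of a draw around
#'   the state-dependent mean.
#' @param rng_seed Master seed; every derived stream is a pure function of
#'   it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 20, n_days = 14,
                       sampling_rate_hz = 200,
                       off_mean_duration_min = 50, on_mean_duration_min = 100,
                       tremor_freq_hz = 5,
                       tremor_amp_off_g = 0.2, tremor_amp_on_g = 0.02,
                       activity_amp_g = 0.1, activity_scale_off = 0.5,
                       noise_std_g = 0.02, gyro_noise_dps = 1,
                       gyro_scale_dps_per_g = 50,
                       nonwear_events_per_day = 2,
                       nonwear_mean_duration_min = 26,
                       nonwear_noise_g = 5e-4,
                       wear_start = "08:00", wear_end = "22:00", tz = "UTC",
                       compliance_open_prob = 0.79,
                       compliance_morning_prob = 0.97,
                       compliance_evening_prob = 0.94,
                       completion_duration_mean_s = 219,
                       off_item_index = 1,
                       off_item_mean_off = 6, off_item_mean_on = 2,
                       off_item_sd = 0.8,
                       rng_seed = 1) {
  cfg <- as.list(environment())
  nonneg <- c("off_mean_duration_min", "on_mean_duration_min",
              "tremor_amp_off_g", "tremor_amp_on_g", "activity_amp_g",
              "activity_scale_off", "noise_std_g", "gyro_noise_dps",
              "nonwear_events_per_day", "nonwear_mean_duration_min",
              "nonwear_noise_g", "completion_duration_mean_s")
  for (f in nonneg) if (cfg[[f]] < 0) stop(f, " must be nonnegative")
  for (f in c("compliance_open_prob", "compliance_morning_prob",
              "compliance_evening_prob")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be a probability")
  }
  if (cfg$sampling_rate_hz <= 0) stop("sampling_rate_hz must be positive")
  if (cfg$tremor_freq_hz < 4 || cfg$tremor_freq_hz > 6) {
    stop("tremor_freq_hz must lie in the 4-6 Hz rest-tremor band")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic sub-seed derivation: a small LCG over the master seed and a
# stream of integer tags, exact in double arithmetic, result in [1, 2^31-2].
mix_seed <- function(seed, ...) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m)
  for (k in c(...)) x <- (x * 69069 + as.numeric(k) + 1) %% m
  as.integer(x %% (m - 1)) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)
  expr
}

day_bounds_ms <- function(cfg, start_date, day) {
  date_d <- as.Date(start_date) + (day - 1)
  c(start = local_ms(date_d, cfg$wear_start, cfg$tz),
    end = local_ms(date_d, cfg$wear_end, cfg$tz))
}

#' Simulate one day's latent ON/OFF trajectory
#'
#' Alternating-renewal two-state process: exponential dwell times with the
#' configured means, clipped to the waking day; the initial state is drawn
#' with the stationary OFF probability. A zero mean duration removes that
#' state (an all-ON day for `off_mean_duration_min = 0`).
#'
#' @param cfg A `sim_config`.
#' @param day_start_ms,day_end_ms Day bounds, epoch ms.
#' @param seed Optional seed; `NULL` uses (and advances) the current RNG
#'   stream.
#' @return Data.frame of class `latent_state`: `t_start_ms, t_end_ms,
#'   off_flag, tremor_amp_g, activity_scale` tiling the day.
#' @export
simulate_state_trajectory <- function(cfg, day_start_ms, day_end_ms,
                                      seed = NULL) {
  gen <- function() {
    mu_off <- cfg$off_mean_duration_min * 60000
    mu_on <- cfg$on_mean_duration_min * 60000
    if (mu_off == 0 && mu_on == 0) {
      segs <- data.frame(t_start_ms = day_start_ms, t_end_ms = day_end_ms,
                         off_flag = 0L)
    } else if (mu_off == 0 || mu_on == 0) {
      segs <- data.frame(t_start_ms = day_start_ms, t_end_ms = day_end_ms,
                         off_flag = as.integer(mu_on == 0))
    } else {
      p_off <- mu_off / (mu_off + mu_on)
      state <- as.integer(runif(1) < p_off)
      t <- day_start_ms
      ts <- numeric(0); te <- numeric(0); fl <- integer(0)
      while (t < day_end_ms) {
        mu <- if (state == 1) mu_off else mu_on
        dur <- rexp(1, 1 / mu)
        ts <- c(ts, t); te <- c(te, min(t + dur, day_end_ms)); fl <- c(fl, state)
        t <- t + dur
        state <- 1L - state
      }
      segs <- data.frame(t_start_ms = ts, t_end_ms = te, off_flag = fl)
    }
    segs$tremor_amp_g <- ifelse(segs$off_flag == 1,
                                cfg$tremor_amp_off_g, cfg$tremor_amp_on_g)
    segs$activity_scale <- ifelse(segs$off_flag == 1, cfg$activity_scale_off, 1)
    class(segs) <- c("latent_state", "data.frame")
    segs
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Latent OFF flag at given times
#' @param state A `latent_state`.
#' @param t_ms Times to query, epoch ms.
#' @return Integer 0/1 vector (`NA` outside the day).
#' @export
state_at <- function(state, t_ms) {
  i <- findInterval(t_ms, state$t_start_ms)
  out <- rep(NA_integer_, length(t_ms))
  ok <- i >= 1 & t_ms < state$t_end_ms[pmax(i, 1)]
  out[ok] <- state$off_flag[i[ok]]
  out
}

simulate_nonwear <- function(cfg, day_start_ms, day_end_ms, seed = NULL) {
  gen <- function() {
    n <- stats::rpois(1, cfg$nonwear_events_per_day)
    if (n == 0 || cfg$nonwear_mean_duration_min == 0) {
      return(cbind(start = numeric(0), end = numeric(0)))
    }
    s <- sort(day_start_ms + runif(n) * (day_end_ms - day_start_ms))
    d <- rexp(n, 1 / (cfg$nonwear_mean_duration_min * 60000))
    merge_intervals(s, pmin(s + d, day_end_ms))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# value per sample from piecewise-constant segments over the day
per_sample_value <- function(breaks_start, breaks_end, values,
                             day_start_ms, n, fs) {
  idx0 <- pmax(0, pmin(n, round((breaks_start - day_start_ms) / 1000 * fs)))
  idx1 <- pmax(0, pmin(n, round((breaks_end - day_start_ms) / 1000 * fs)))
  out <- numeric(n)
  for (i in seq_along(values)) {
    if (idx1[i] > idx0[i]) out[seq.int(idx0[i] + 1, idx1[i])] <- values[i]
  }
  out
}

band_limited_noise <- function(n, fs, cutoff_hz = 3) {
  w <- rnorm(n)
  filt <- butter_lowpass(fs, cutoff_hz, order = 4)
  y <- iir_filter(filt, w)
  s <- sd(y)
  if (s > 0) y / s else y
}

clip_range <- function(x, lim) {
  r <- range(x)
  if (r[1] < -lim || r[2] > lim) pmin(pmax(x, -lim), lim) else x
}

#' Simulate one sensor's recording day
#'
#' Acceleration = constant gravity (a random unit orientation held for the
#' day) + band-limited (< 3 Hz) voluntary-activity noise scaled by the
#' latent state + a tremor sinusoid whose amplitude follows the state +
#' white noise; gyroscope channels are analogous without gravity, with
#' amplitudes scaled by `gyro_scale_dps_per_g`. One activity process is
#' shared across a sensor's six channels with random per-channel gains —
#' limb movement moves every axis of a rigidly attached sensor at once,
#' which is what gives the accelerometer x gyroscope cross-correlation
#' features their structure. Inside planted non-wear intervals the signal
#' collapses to constant gravity plus the off-body noise floor. All samples
#' are clipped to the physical ranges.
#'
#' @param cfg A `sim_config`.
#' @param state A `latent_state` for the day.
#' @param nonwear Two-column (start, end) matrix of non-wear intervals.
#' @param sensor_id Sensor position.
#' @param participant_id Participant identifier.
#' @param day_start_ms,day_end_ms Session bounds, epoch ms.
#' @param seed Optional seed (`NULL` = current RNG stream).
#' @return A `recording_session`.
#' @export
simulate_imu_day <- function(cfg, state, nonwear, sensor_id, participant_id,
                             day_start_ms, day_end_ms, seed = NULL) {
  gen <- function() {
    fs <- cfg$sampling_rate_hz
    n <- round((day_end_ms - day_start_ms) / 1000 * fs)
    g <- rnorm(3)
    g <- g / sqrt(sum(g^2))               # gravity orientation, 1 g total
    amp_t <- per_sample_value(state$t_start_ms, state$t_end_ms,
                              state$tremor_amp_g, day_start_ms, n, fs)
    act_t <- per_sample_value(state$t_start_ms, state$t_end_ms,
                              state$activity_scale, day_start_ms, n, fs)
    nw <- if (nrow(nonwear)) {
      per_sample_value(nonwear[, 1], nonwear[, 2], rep(1, nrow(nonwear)),
                       day_start_ms, n, fs) > 0
    } else rep(FALSE, n)
    n_nw <- sum(nw)
    # one tremor oscillation per sensor; per-channel phase via the shift
    # identity sin(wt + phi) = sin(wt) cos(phi) + cos(wt) sin(phi)
    wt <- 2 * pi * cfg$tremor_freq_hz * (seq_len(n) - 1) / fs
    trem_s <- amp_t * sin(wt)
    trem_c <- amp_t * cos(wt)
    act <- act_t * (cfg$activity_amp_g * band_limited_noise(n, fs))
    accel <- matrix(0, n, 3)
    gyro <- matrix(0, n, 3)
    for (j in 1:3) {
      phase <- runif(1, 0, 2 * pi)
      gain <- runif(1, 0.6, 1.4)
      a <- g[j] + gain * act +
        cos(phase) * trem_s + sin(phase) * trem_c +
        rnorm(n, 0, cfg$noise_std_g)
      if (n_nw) a[nw] <- g[j] + rnorm(n_nw, 0, cfg$nonwear_noise_g)
      accel[, j] <- clip_range(a, ACCEL_RANGE_G)

      phase_g <- runif(1, 0, 2 * pi)
      gain_g <- runif(1, 0.6, 1.4)
      gg <- cfg$gyro_scale_dps_per_g *
        (gain_g * act + cos(phase_g) * trem_s + sin(phase_g) * trem_c) +
        rnorm(n, 0, cfg$gyro_noise_dps)
      if (n_nw) gg[nw] <- rnorm(n_nw, 0, cfg$nonwear_noise_g * cfg$gyro_scale_dps_per_g)
      gyro[, j] <- clip_range(gg, GYRO_RANGE_DPS)
    }
    colnames(accel) <- c("ax", "ay", "az")
    colnames(gyro) <- c("gx", "gy", "gz")
    rec <- new_imu_recording(participant_id, sensor_id, fs, day_start_ms,
                             accel, gyro, timezone = cfg$tz)
    recording_session(rec, day_start_ms, day_end_ms)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

clamp_likert <- function(x) pmin(pmax(round(x), 1), 7)

#' Simulate ESM responses for a schedule
#'
#' Each continuous questionnaire is opened (within its 15-minute deadline)
#' and fully completed with probability `compliance_open_prob`; morning and
#' evening questionnaires follow their own compliance. When completed, the
#' designated OFF item is a clamped, rounded Gaussian around the
#' state-dependent mean (high during latent OFF, low during ON) and the
#' remaining Likert items are neutral noise; the completion duration has the
#' configured mean.
#'
#' @param cfg A `sim_config`.
#' @param events Schedule from [generate_schedule()].
#' @param states List of `latent_state` objects indexed by day.
#' @param seed Optional seed (`NULL` = current RNG stream).
#' @return Response data.frame (schema of [empty_responses()]).
#' @export
simulate_responses <- function(cfg, events, states, seed = NULL) {
  gen <- function() {
    resp <- empty_responses(events)
    acl <- answer_cols()
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      p_open <- switch(ev$kind,
                       continuous = cfg$compliance_open_prob,
                       morning = cfg$compliance_morning_prob,
                       evening = cfg$compliance_evening_prob)
      if (runif(1) >= p_open) next
      if (ev$kind == "continuous") {
        opened <- ev$scheduled_ms + runif(1, 0, 0.93 * ESM_OPEN_DEADLINE_MIN) * 60000
      } else {
        opened <- ev$scheduled_ms +
          runif(1, 0, 0.5) * (ev$deadline_ms - ev$scheduled_ms)
      }
      started <- opened + runif(1, 2, 20) * 1000
      dur_s <- max(30, rnorm(1, cfg$completion_duration_mean_s,
                             0.2 * cfg$completion_duration_mean_s))
      resp$opened_ms[i] <- opened
      resp$started_ms[i] <- started
      resp$ended_ms[i] <- started + dur_s * 1000
      n_items <- ESM_N_ITEMS[[ev$kind]]
      ans <- clamp_likert(rnorm(n_items, 4, 1.2))
      if (ev$kind == "continuous") {
        off <- state_at(states[[ev$day_index]], opened)
        if (is.na(off)) off <- 0L
        mu <- if (off == 1) cfg$off_item_mean_off else cfg$off_item_mean_on
        ans[cfg$off_item_index] <- clamp_likert(rnorm(1, mu, cfg$off_item_sd))
      }
      resp[i, acl[seq_len(n_items)]] <- as.list(ans)
    }
    resp
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

simulate_participant_meta <- function(cfg, participant, start_date) {
  events <- generate_schedule(cfg$n_days, start_date,
                              seed = mix_seed(cfg$rng_seed, participant, 777),
                              tz = cfg$tz)
  states <- vector("list", cfg$n_days)
  nonwear <- vector("list", cfg$n_days)
  for (d in seq_len(cfg$n_days)) {
    db <- day_bounds_ms(cfg, start_date, d)
    states[[d]] <- simulate_state_trajectory(
      cfg, db["start"], db["end"], seed = mix_seed(cfg$rng_seed, participant, d, 1))
    nonwear[[d]] <- simulate_nonwear(
      cfg, db["start"], db["end"], seed = mix_seed(cfg$rng_seed, participant, d, 2))
  }
  responses <- simulate_responses(cfg, events, states,
                                  seed = mix_seed(cfg$rng_seed, participant, 999))
  list(participant_id = sprintf("P%02d", participant),
       events = events, responses = responses,
       states = states, nonwear = nonwear)
}

participant_truth <- function(cfg, meta, start_date) {
  rows <- lapply(seq_len(cfg$n_days), function(d) {
    st <- meta$states[[d]]
    nw <- meta$nonwear[[d]]
    rbind(
      data.frame(participant_id = meta$participant_id,
                 t_start_ms = st$t_start_ms, t_end_ms = st$t_end_ms,
                 off_flag = st$off_flag, nonwear_flag = 0L),
      if (nrow(nw)) data.frame(participant_id = meta$participant_id,
                               t_start_ms = nw[, 1], t_end_ms = nw[, 2],
                               off_flag = NA_integer_, nonwear_flag = 1L))
  })
  do.call(rbind, rows)
}

#' Simulate a full cohort
#'
#' Generates every participant's schedule, latent states, non-wear
#' intervals, ESM responses, and (optionally) all sensor recording sessions.
#' Fully reproducible: every stream derives deterministically from
#' `cfg$rng_seed`. With `out_dir`, sensor CSVs (`P01_d01_left_wrist.csv` +
#' JSON sidecars), ESM CSVs and `truth.csv` are written and the heavyweight
#' recordings are not kept in memory; without it, recordings are returned
#' in-memory, which is only sensible for small configurations.
#'
#' @param cfg A `sim_config`.
#' @param start_date First protocol day.
#' @param out_dir Optional output directory.
#' @param keep_recordings Keep `recording_session`s in the returned object
#'   (default: only when `out_dir` is NULL).
#' @return List of class `sim_cohort` with `config`, `start_date`, and
#'   per-participant entries (`events`, `responses`, `states`, `nonwear`,
#'   `truth`, optionally `sessions[[day]][[sensor]]`).
#' @export
simulate_cohort <- function(cfg, start_date = "2020-01-06", out_dir = NULL,
                            keep_recordings = is.null(out_dir)) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  participants <- vector("list", cfg$n_participants)
  truth_all <- list()
  for (p in seq_len(cfg$n_participants)) {
    meta <- simulate_participant_meta(cfg, p, start_date)
    truth <- participant_truth(cfg, meta, start_date)
    truth_all[[p]] <- truth
    sessions <- NULL
    if (keep_recordings || !is.null(out_dir)) {
      sessions <- vector("list", cfg$n_days)
      for (d in seq_len(cfg$n_days)) {
        db <- day_bounds_ms(cfg, start_date, d)
        day_sessions <- lapply(seq_along(SENSOR_IDS), function(s) {
          simulate_imu_day(cfg, meta$states[[d]], meta$nonwear[[d]],
                           SENSOR_IDS[s], meta$participant_id,
                           db["start"], db["end"],
                           seed = mix_seed(cfg$rng_seed, p, d, 10 + s))
        })
        names(day_sessions) <- SENSOR_IDS
        if (!is.null(out_dir)) {
          for (s in SENSOR_IDS) {
            write_recording(day_sessions[[s]]$recording,
                            file.path(out_dir, sprintf("%s_d%02d_%s.csv",
                                                       meta$participant_id, d, s)))
          }
        }
        if (keep_recordings) sessions[[d]] <- day_sessions
      }
    }
    if (!is.null(out_dir)) {
      write_esm_events(meta$events,
                       file.path(out_dir, paste0(meta$participant_id, "_events.csv")))
      write_esm_responses(meta$responses,
                          file.path(out_dir, paste0(meta$participant_id, "_responses.csv")))
    }
    participants[[p]] <- c(meta, list(truth = truth, sessions = sessions))
  }
  if (!is.null(out_dir)) {
    data.table::fwrite(do.call(rbind, truth_all), file.path(out_dir, "truth.csv"))
  }
  structure(list(config = cfg, start_date = as.Date(start_date),
                 participants = participants),
            class = "sim_cohort")
}
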