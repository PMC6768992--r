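day_ms <- function(h) as.numeric(as.POSIXct("2020-01-06 00:00", tz = "UTC")) * 1000 + h * 3600 * 1000

test_that("latent trajectories tile the day and honour degenerate means", {
  cfg <- sim_config(n_participants = 1, n_days = 1, rng_seed = 1)
  st <- simulate_state_trajectory(cfg, day_ms(8), day_ms(22), seed = 3)
  expect_equal(st$t_start_ms[1], day_ms(8))
  expect_equal(st$t_end_ms[nrow(st)], day_ms(22))
  expect_equal(st$t_start_ms[-1], st$t_end_ms[-nrow(st)])
  expect_true(all(st$off_flag %in% 0:1))
  # zero OFF dwell time: the whole day is ON
  cfg_on <- sim_config(off_mean_duration_min = 0, rng_seed = 1)
  st_on <- simulate_state_trajectory(cfg_on, day_ms(8), day_ms(22), seed = 3)
  expect_equal(st_on$off_flag, 0L)
  # determinism
  expect_identical(st, simulate_state_trajectory(cfg, day_ms(8), day_ms(22), seed = 3))
})

test_that("equal dwell means give an OFF fraction near one half", {
  cfg <- sim_config(off_mean_duration_min = 30, on_mean_duration_min = 30,
                    rng_seed = 1)
  # a long horizon stands in for many days: renewal-theory limit is 1/2
  frac <- replicate(8, {
    st <- simulate_state_trajectory(cfg, 0, 14 * 24 * 3600 * 1000)
    sum((st$t_end_ms - st$t_start_ms) * st$off_flag) / (14 * 24 * 3600 * 1000)
  })
  expect_equal(mean(frac), 0.5, tolerance = 0.05)
})

test_that("OFF segments carry a tremor-band spectral peak, ON segments do not", {
  cfg <- sim_config(sampling_rate_hz = 32, rng_seed = 5)
  st <- data.frame(t_start_ms = c(day_ms(8), day_ms(10)),
                   t_end_ms = c(day_ms(10), day_ms(12)),
                   off_flag = c(1L, 0L))
  st$tremor_amp_g <- ifelse(st$off_flag == 1, cfg$tremor_amp_off_g, cfg$tremor_amp_on_g)
  st$activity_scale <- ifelse(st$off_flag == 1, cfg$activity_scale_off, 1)
  sess <- simulate_imu_day(cfg, st, cbind(start = numeric(0), end = numeric(0)),
                           "left_wrist", "P01", day_ms(8), day_ms(12), seed = 6)
  off_x <- slice_time(sess$recording, day_ms(8.5), day_ms(9.5))$accel[, 1]
  on_x <- slice_time(sess$recording, day_ms(10.5), day_ms(11.5))$accel[, 1]
  d_off <- dominant_frequency(off_x - mean(off_x), 32)
  expect_equal(unname(d_off["f_dom_hz"]), cfg$tremor_freq_hz, tolerance = 0.1)
  expect_gt(log_band_energy(off_x, 32), log_band_energy(on_x, 32) + 2)
})

test_that("planted non-wear sits below the 0.002 g threshold, worn signal above", {
  cfg <- sim_config(sampling_rate_hz = 32, rng_seed = 7)
  st <- simulate_state_trajectory(cfg, day_ms(8), day_ms(12), seed = 8)
  nonwear <- cbind(start = day_ms(9), end = day_ms(10))
  sess <- simulate_imu_day(cfg, st, nonwear, "chest", "P01",
                           day_ms(8), day_ms(12), seed = 9)
  ms <- minute_std(sess)
  in_nw <- ms$minute_start_ms >= day_ms(9) & ms$minute_start_ms + 60000 <= day_ms(10)
  expect_true(all(ms$std_x[in_nw] < 0.002))
  expect_true(all(ms$std_x[!in_nw & ms$minute_start_ms + 60000 <= day_ms(9) |
                             ms$minute_start_ms >= day_ms(10)] > 0.002))
  # a silent configuration yields a constant-gravity channel
  cfg0 <- sim_config(noise_std_g = 0, activity_amp_g = 0, tremor_amp_off_g = 0,
                     tremor_amp_on_g = 0, gyro_noise_dps = 0,
                     sampling_rate_hz = 32, rng_seed = 7)
  st0 <- simulate_state_trajectory(cfg0, day_ms(8), day_ms(9), seed = 1)
  s0 <- simulate_imu_day(cfg0, st0, cbind(start = numeric(0), end = numeric(0)),
                         "chest", "P01", day_ms(8), day_ms(9), seed = 2)
  expect_equal(amplitude_range(s0$recording$accel[, 1]), 0)
  expect_equal(sqrt(sum(s0$recording$accel[1, ]^2)), 1)  # 1 g of gravity
})

test_that("simulated responses obey the compliance probability and the answer model", {
  cfg1 <- sim_config(compliance_open_prob = 1, off_item_sd = 0, rng_seed = 3)
  ev <- generate_schedule(14, "2020-01-06", seed = 2)
  states <- lapply(1:14, function(d) {
    db <- day_ms(8) + (d - 1) * 24 * 3600 * 1000
    simulate_state_trajectory(cfg1, db, db + 14 * 3600 * 1000, seed = d)
  })
  resp <- simulate_responses(cfg1, ev, states, seed = 4)
  rep1 <- completion_report(ev, resp)
  expect_equal(rep1$by_kind$rate_percent[rep1$by_kind$kind == "continuous"], 100)
  # zero answer noise: designated item equals the state mean exactly
  cont <- which(ev$kind == "continuous" & !is.na(resp$opened_ms))
  off_truth <- vapply(cont, function(i)
    state_at(states[[ev$day_index[i]]], resp$opened_ms[i]), integer(1))
  off_truth[is.na(off_truth)] <- 0L   # opened past 22:00: the day is over, ON
  expect_equal(resp$a01[cont],
               ifelse(off_truth == 1, cfg1$off_item_mean_off, cfg1$off_item_mean_on))
  # completion rate is binomial around the compliance probability
  cfg2 <- sim_config(compliance_open_prob = 0.79, rng_seed = 3)
  rates <- vapply(1:12, function(s) {
    r <- simulate_responses(cfg2, ev, states, seed = 100 + s)
    rp <- completion_report(ev, r)$by_kind
    rp$rate_percent[rp$kind == "continuous"]
  }, 0)
  se <- 100 * sqrt(0.79 * 0.21 / (98 * 12))
  expect_equal(mean(rates), 79, tolerance = 4 * se / 79 * 100)
})

test_that("cohorts are reproducible and have the protocol's dimensions", {
  cfg <- sim_config(n_participants = 2, n_days = 2, sampling_rate_hz = 16,
                    rng_seed = 21)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_length(co1$participants, 2)
  p1 <- co1$participants[[1]]
  expect_equal(sum(p1$events$kind == "continuous"), 14)    # 7 per day
  expect_length(p1$sessions, 2)
  expect_named(p1$sessions[[1]], c("left_wrist", "right_wrist", "chest"))
  expect_identical(co1$participants[[1]]$sessions[[1]]$chest$recording$accel,
                   co2$participants[[1]]$sessions[[1]]$chest$recording$accel)
  expect_identical(p1$responses, co2$participants[[1]]$responses)
  # a different seed changes the signal
  cfg_b <- sim_config(n_participants = 2, n_days = 2, sampling_rate_hz = 16,
                      rng_seed = 22)
  co3 <- simulate_cohort(cfg_b)
  expect_false(identical(co1$participants[[1]]$sessions[[1]]$chest$recording$accel,
                         co3$participants[[1]]$sessions[[1]]$chest$recording$accel))
})

test_that("written cohorts land on disk in the documented schemas", {
  cfg <- sim_config(n_participants = 1, n_days = 1, sampling_rate_hz = 16,
                    rng_seed = 31)
  d <- file.path(tempdir(), "cohort_out")
  simulate_cohort(cfg, out_dir = d, keep_recordings = FALSE)
  expect_true(file.exists(file.path(d, "P01_d01_chest.csv")))
  expect_true(file.exists(file.path(d, "P01_events.csv")))
  expect_true(file.exists(file.path(d, "truth.csv")))
  rec <- read_recording(file.path(d, "P01_d01_left_wrist.csv"))
  expect_equal(duration_s(rec), 14 * 3600)
  truth <- as.data.frame(data.table::fread(file.path(d, "truth.csv")))
  expect_true(all(c("participant_id", "t_start_ms", "t_end_ms",
                    "off_flag", "nonwear_flag") %in% names(truth)))
  unlink(d, recursive = TRUE)
})
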