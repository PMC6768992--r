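test_that("band energy of a pure in-band tone equals its Parseval power", {
  fs <- 200
  t <- (0:(fs * 4 - 1)) / fs
  for (A in c(0.1, 1, 3)) {
    x <- A * sin(2 * pi * 5 * t)
    # whole-second 5 Hz tone: all power in one bin inside 3.5-7.5 Hz
    total <- mean((x - mean(x))^2)
    expect_equal(log_band_energy(x, fs), log(total), tolerance = 0.01)
  }
  # out-of-band tone leaves only the floor
  x10 <- sin(2 * pi * 10 * t)
  expect_lt(log_band_energy(x10, fs), log(1e-12) + 1)
  # silent signal sits exactly on the floor
  expect_equal(log_band_energy(numeric(400) , fs), log(1e-12))
  expect_error(log_band_energy(sin(1:100), fs = 14), "band")
})

test_that("low-pass RMS passes DC and 1 Hz, rejects 10 Hz", {
  fs <- 200
  t <- (0:(fs * 4 - 1)) / fs
  expect_equal(rms_lowpass(rep(0.7, 800), fs), 0.7, tolerance = 0.01)
  for (A in c(0.2, 1)) {
    expect_equal(rms_lowpass(A * sin(2 * pi * 1 * t), fs), A / sqrt(2),
                 tolerance = 0.02)
    expect_lt(rms_lowpass(A * sin(2 * pi * 10 * t), fs), 0.1 * A / sqrt(2))
  }
  expect_error(rms_lowpass(1:5, fs), "short")
})

test_that("dominant frequency finds the strongest component and its share", {
  fs <- 200
  t <- (0:(fs * 2 - 1)) / fs
  d <- dominant_frequency(sin(2 * pi * 5 * t), fs)
  expect_equal(unname(d["f_dom_hz"]), 5)
  expect_gt(d["energy_ratio"], 0.99)
  # 2 Hz amplitude 2 vs 6 Hz amplitude 1: powers 4:1 so the ratio is 4/5
  d2 <- dominant_frequency(2 * sin(2 * pi * 2 * t) + sin(2 * pi * 6 * t), fs)
  expect_equal(unname(d2["f_dom_hz"]), 2)
  expect_equal(unname(d2["energy_ratio"]), 0.8, tolerance = 1e-6)
  # white noise spreads power: tiny ratio for a long window
  set.seed(9)
  d3 <- dominant_frequency(rnorm(4096), fs)
  expect_lt(d3["energy_ratio"], 0.02)
  expect_warning(d0 <- dominant_frequency(rep(1, 100), fs), "constant")
  expect_equal(unname(d0), c(0, 0))
})

test_that("amplitude range is max minus min of the raw window", {
  expect_equal(amplitude_range(rep(3, 10)), 0)
  expect_equal(amplitude_range(c(-1, 0.5, 2)), 3)
  t <- (0:999) / 1000
  expect_equal(amplitude_range(1.5 * sin(2 * pi * 5 * t)), 3, tolerance = 1e-3)
  expect_error(amplitude_range(numeric(0)), "empty")
})

test_that("cross-correlation recovers identity, delay and sign flips", {
  set.seed(11)
  fs <- 100
  a <- rnorm(1000)
  expect_equal(max_norm_xcorr(a, a, fs), c(r = 1, lag_s = 0))
  expect_equal(max_norm_xcorr(a, -a, fs), c(r = -1, lag_s = 0))
  for (d in c(-30, -7, 4, 25)) {
    b <- if (d >= 0) c(rep(0, d), a)[1:1000] else c(a[(-d + 1):1000], rep(0, -d))
    res <- max_norm_xcorr(a, b, fs)
    expect_equal(unname(res["lag_s"]), d / fs)
    expect_gt(res["r"], 0.95)
    # time reversal flips the lag sign
    rev_res <- max_norm_xcorr(rev(a), rev(b), fs)
    expect_equal(unname(rev_res["lag_s"]), -d / fs)
  }
  expect_warning(z <- max_norm_xcorr(rep(1, 500), a[1:500], fs), "variance")
  expect_equal(unname(z), c(0, 0))
  expect_error(max_norm_xcorr(a[1:100], a[1:99], fs), "equal length")
})

test_that("spectral features match a direct-summation DFT oracle", {
  set.seed(12)
  fs <- 128
  for (n in c(256, 500, 1024)) {
    t <- (0:(n - 1)) / fs
    signals <- list(
      tone = sin(2 * pi * 5 * t),
      mix = 0.4 * sin(2 * pi * 4.25 * t) + sin(2 * pi * 1.5 * t + 1),
      noise = rnorm(n),
      trend = seq(0, 1, length.out = n) + 0.3 * sin(2 * pi * 6 * t))
    for (x in signals) {
      expect_equal(log_band_energy(x, fs), oracle_log_band_energy(x, fs),
                   tolerance = 1e-6)
      expect_equal(unname(dominant_frequency(x, fs)),
                   oracle_dominant_frequency(x, fs), tolerance = 1e-6)
    }
  }
})

test_that("features scale as dictated by amplitude scaling", {
  set.seed(13)
  fs <- 100
  x <- rnorm(800) + sin(2 * pi * 5 * (0:799) / fs)
  y <- 0.3 * rnorm(800) + x
  for (c0 in c(0.5, 4)) {
    expect_equal(log_band_energy(c0 * x, fs),
                 log_band_energy(x, fs) + 2 * log(c0), tolerance = 1e-8)
    expect_equal(rms_lowpass(c0 * x, fs), c0 * rms_lowpass(x, fs),
                 tolerance = 1e-8)
    expect_equal(amplitude_range(c0 * x), c0 * amplitude_range(x))
    expect_equal(dominant_frequency(c0 * x, fs), dominant_frequency(x, fs))
    expect_equal(max_norm_xcorr(c0 * x, y, fs), max_norm_xcorr(x, y, fs),
                 tolerance = 1e-12)
  }
})

test_that("window segmentation drops the trailing remainder", {
  expect_length(segment_windows(900 * 20, 20, 60), 15)
  expect_length(segment_windows(900 * 20, 20, 900), 1)
  expect_length(segment_windows(900 * 20, 20, 59), 15)
  expect_warning(w <- segment_windows(100, 20, 60), "whole segment")
  expect_length(w, 1)
  expect_error(segment_windows(100, 20, 0), "positive")
})

test_that("segment extraction takes exactly the pre-opening window", {
  fs <- 20
  n <- fs * 3600
  recs <- lapply(c("left_wrist", "right_wrist", "chest"), function(s)
    make_recording(n, fs = fs, accel_x = rnorm(n, 0, 0.05), sensor = s))
  names(recs) <- c("left_wrist", "right_wrist", "chest")
  opened <- 3600 * 1000
  seg <- extract_segment(opened, recs, window_min = 15)
  for (s in names(recs)) {
    expect_equal(n_samples(seg[[s]]), 15 * 60 * fs)
    ts <- timestamps_ms(seg[[s]])
    expect_gte(ts[1], opened - 15 * 60 * 1000)
    expect_lt(ts[length(ts)], opened)
  }
  seg1 <- extract_segment(opened, recs, window_min = 1)
  expect_equal(n_samples(seg1$chest), 60 * fs)
  # missing coverage on one sensor is an error naming it
  short <- recs
  short$chest <- slice_time(short$chest, opened - 5 * 60 * 1000, opened)
  expect_error(extract_segment(opened, short, 15), "chest")
  # questionnaire completion must not precede its opening
  expect_error(extract_segment(opened, recs, 15, started_ms = opened - 1),
               "inconsistent")
})

test_that("instance vectors have 144 named features and behave at the edges", {
  fs <- 20
  n <- fs * 900
  recs <- lapply(c("left_wrist", "right_wrist", "chest"), function(s)
    make_recording(n, fs = fs, accel_x = rnorm(n, 0, 0.05), sensor = s))
  names(recs) <- c("left_wrist", "right_wrist", "chest")
  seg <- extract_segment(900 * 1000, recs, 15)
  fv <- build_instance(seg, w_s = 60)
  expect_length(fv, 144)
  expect_false(any(duplicated(names(fv))))
  expect_true(all(abs(fv[grep("max_xcorr", names(fv))]) <= 1))
  ratio <- fv[grep("dominant_energy_ratio", names(fv))]
  expect_true(all(ratio >= 0 & ratio <= 1))
  # a single full-segment window makes aggregation the identity
  fv_full <- build_instance(seg, w_s = 900)
  expect_length(fv_full, 144)
  # all-zero segment maps to the degenerate constants
  zero <- lapply(names(recs), function(s) make_recording(n, fs = fs, sensor = s))
  names(zero) <- names(recs)
  fz <- build_instance(extract_segment(900 * 1000, zero, 15), w_s = 60)
  expect_equal(unname(fz["chest_ax_log_band_energy"]), log(1e-12))
  expect_equal(unname(fz["chest_ax_amplitude_range"]), 0)
  expect_equal(unname(fz["chest_ax_gx_max_xcorr"]), 0)
})

test_that("fast pairwise cross-correlation equals the reference implementation", {
  set.seed(14)
  fs <- 20
  for (i in 1:5) {
    A <- lapply(1:3, function(j) rnorm(600))
    G <- lapply(1:3, function(j) 0.5 * c(rep(0, 3), A[[j]])[1:600] + rnorm(600))
    fast <- wearesm:::xcorr_pairs(A, G, fs, 1)
    k <- 1
    for (ii in 1:3) for (jj in 1:3) {
      ref <- max_norm_xcorr(A[[ii]], G[[jj]], fs, 1)
      expect_equal(fast[k], unname(ref["r"]), tolerance = 1e-9)
      expect_equal(fast[k + 1], unname(ref["lag_s"]))
      k <- k + 2
    }
  }
})
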