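#' Pre-questionnaire window extraction and signal features
#'
#' For each completed questionnaire with full sensor coverage, the 15 minutes
#' of sensor data before the moment it was opened are extracted (the time
#' spent answering is after `opened_at`, so it is excluded by construction),
#' divided into fixed-length sub-windows, and summarized by five feature
#' families per channel — tremor-band (3.5-7.5 Hz) log energy, RMS of the
#' 3 Hz low-pass-filtered series, dominant frequency with its energy ratio,
#' raw amplitude range — plus the maximum normalized cross-correlation and
#' its lag for every within-sensor accelerometer x gyroscope channel pair.
#'
#' @name features
NULL

LOG_ENERGY_EPS <- 1e-12

#' Extract the three-sensor pre-questionnaire segment
#'
#' @param opened_ms Time the questionnaire was opened, epoch ms.
#' @param recordings Named list (`left_wrist`, `right_wrist`, `chest`) of
#'   `imu_recording`s covering the window.
#' @param window_min Window length in minutes before `opened_ms`.
#' @param started_ms Optional questionnaire start time; asserted to lie at or
#'   after `opened_ms` so answering time can never leak into the window.
#' @param gap_tol_s Allowed shortfall of each slice, seconds.
#' @return List of per-sensor `imu_recording` slices, class
#'   `analysis_segment`, with attributes `opened_ms` and `window_min`.
#' @export
extract_segment <- function(opened_ms, recordings, window_min = 15,
                            started_ms = NULL, gap_tol_s = 1) {
  if (!all(SENSOR_IDS %in% names(recordings))) {
    stop("recordings must name all of: ", paste(SENSOR_IDS, collapse = ", "))
  }
  if (!is.null(started_ms) && !is.na(started_ms) && started_ms < opened_ms) {
    stop("questionnaire started before it was opened; timestamps inconsistent")
  }
  t0 <- opened_ms - window_min * 60 * 1000
  out <- lapply(SENSOR_IDS, function(sid) {
    sl <- slice_time(recordings[[sid]], t0, opened_ms)
    if (duration_s(sl) < window_min * 60 - gap_tol_s) {
      stop("sensor ", sid, " does not cover the ", window_min,
           "-min window before the questionnaire")
    }
    sl
  })
  names(out) <- SENSOR_IDS
  structure(out, class = "analysis_segment",
            opened_ms = opened_ms, window_min = window_min)
}

#' Split a segment (or sample count) into fixed-length windows
#'
#' Non-overlapping, contiguous windows of `w_s` seconds from the start; a
#' trailing remainder shorter than `w_s` is dropped. If `w_s` exceeds the
#' segment length a single window holding everything is returned with a
#' warning.
#'
#' @param n Number of samples available.
#' @param fs Sampling rate, Hz.
#' @param w_s Window length, seconds.
#' @return List of integer index vectors, one per window.
#' @export
segment_windows <- function(n, fs, w_s) {
  if (w_s <= 0) stop("w_s must be positive")
  spw <- round(w_s * fs)
  if (spw > n) {
    warning("window length exceeds the segment; using the whole segment")
    return(list(seq_len(n)))
  }
  k <- floor(n / spw)
  lapply(seq_len(k), function(i) seq.int((i - 1) * spw + 1, i * spw))
}

# Two-sided mean-removed periodogram, normalized so that the sum of power
# over all bins equals the mean square of the demeaned signal (Parseval).
periodogram_power <- function(x) {
  n <- length(x)
  Mod(fft(x - mean(x)))^2 / n^2
}

one_sided_power <- function(x, fs) {
  n <- length(x)
  p <- periodogram_power(x)
  kmax <- floor(n / 2)
  k <- seq_len(kmax)                     # positive frequencies, excl. DC
  pw <- p[k + 1]
  dbl <- if (n %% 2 == 0) c(rep(2, kmax - 1), 1) else rep(2, kmax)
  list(freq = k * fs / n, power = pw * dbl)
}

#' Logarithmic signal energy in a frequency band
#'
#' Natural log of the mean-removed periodogram power summed over bins with
#' `f_lo <= f < f_hi` (default the 3.5-7.5 Hz tremor band), floored at
#' `1e-12` so an empty band or silent signal maps to `log(1e-12)`.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz; must exceed `2 * f_hi` so the band is
#'   resolvable.
#' @param f_lo,f_hi Band edges in Hz, half-open `[f_lo, f_hi)`.
#' @return Log band power (signal units squared, natural log).
#' @export
log_band_energy <- function(x, fs, f_lo = 3.5, f_hi = 7.5) {
  if (length(x) < 2) stop("need at least 2 samples")
  if (fs <= 2 * f_hi) stop("sampling rate too low to resolve the band")
  os <- one_sided_power(x, fs)
  sel <- os$freq >= f_lo & os$freq < f_hi
  log(LOG_ENERGY_EPS + sum(os$power[sel]))
}

butter_lowpass <- function(fs, cutoff_hz, order = 4) {
  signal::butter(order, cutoff_hz / (fs / 2), type = "low")
}

# Zero-initial-state IIR filter (direct form, identical output to
# signal::filter) built from the fast C routines in stats::filter.
iir_filter <- function(filt, x) {
  nb <- length(filt$b)
  y <- as.numeric(stats::filter(c(rep(0, nb - 1), x), filt$b,
                                method = "convolution",
                                sides = 1))[nb:(length(x) + nb - 1)]
  as.numeric(stats::filter(y, -filt$a[-1], method = "recursive"))
}

# Zero-phase filtering with reflective edge padding (forward-backward pass
# over the signal extended by mirrored ends), so short windows do not pick up
# start-up transients. The padding must outlast the filter's settling time,
# which for a low normalized cutoff is far longer than the coefficient
# count: use the slowest pole's 1% decay length.
settle_len <- function(filt) {
  rmax <- max(Mod(polyroot(rev(filt$a))))
  if (rmax >= 1) return(1000L)
  as.integer(ceiling(log(0.01) / log(rmax)))
}

filtfilt_refl <- function(filt, x) {
  n <- length(x)
  npad <- min(n - 1, max(3 * (length(filt$a) + length(filt$b)), settle_len(filt)))
  # symmetric (even) reflection: keeps the pad's local mean equal to the
  # signal's, so no in-band step is created for a low-pass filter
  pre <- x[seq(npad + 1, 2)]
  post <- x[seq(n - 1, n - npad)]
  y <- c(pre, x, post)
  y <- iir_filter(filt, y)
  y <- rev(iir_filter(filt, rev(y)))
  y[seq(npad + 1, npad + n)]
}

#' RMS of the low-pass-filtered signal
#'
#' Root mean square of the signal after a zero-phase 4th-order Butterworth
#' low-pass at `cutoff_hz` (default 3 Hz), capturing voluntary-movement
#' energy below the tremor band.
#'
#' @param x Numeric signal, at least a couple of dozen samples (filter
#'   warm-up).
#' @param fs Sampling rate, Hz; must exceed `2 * cutoff_hz`.
#' @param cutoff_hz Low-pass cutoff, Hz.
#' @return RMS in the signal's units.
#' @export
rms_lowpass <- function(x, fs, cutoff_hz = 3) {
  if (fs <= 2 * cutoff_hz) stop("sampling rate too low for the cutoff")
  if (length(x) < 24) stop("signal too short for the filter warm-up")
  y <- filtfilt_refl(butter_lowpass(fs, cutoff_hz), x)
  sqrt(mean(y^2))
}

#' Dominant frequency and dominant energy ratio
#'
#' The dominant frequency is the positive-frequency periodogram maximum of
#' the demeaned signal; the energy ratio is the power in that bin plus one
#' neighbouring bin on each side, divided by the total non-DC power. An
#' all-constant signal returns `(0, 0)` with a warning.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate, Hz.
#' @return Named numeric `c(f_dom_hz, energy_ratio)`.
#' @export
dominant_frequency <- function(x, fs) {
  if (length(x) < 2) stop("need at least 2 samples")
  os <- one_sided_power(x, fs)
  tot <- sum(os$power)
  if (tot <= 0) {
    warning("constant signal: dominant frequency undefined, returning 0")
    return(c(f_dom_hz = 0, energy_ratio = 0))
  }
  k <- which.max(os$power)
  nb <- seq(max(1, k - 1), min(length(os$power), k + 1))
  c(f_dom_hz = os$freq[k], energy_ratio = sum(os$power[nb]) / tot)
}

#' Amplitude range of the raw window
#'
#' `max(x) - min(x)` on the raw, unfiltered samples.
#'
#' @param x Nonempty numeric signal.
#' @return Nonnegative range in the signal's units.
#' @export
amplitude_range <- function(x) {
  if (length(x) == 0) stop("empty signal")
  max(x) - min(x)
}

#' Maximum normalized cross-correlation and its temporal offset
#'
#' Pearson correlation between `a` and `b` at every integer-sample lag in
#' `[-max_lag_s, +max_lag_s]` (at lag d, `a[t]` is paired with `b[t + d]`, so
#' a copy of `a` delayed by d samples peaks at lag `+d/fs`). Returns the
#' signed correlation at the lag maximizing `|r|`; ties break toward the
#' smaller `|lag|`, then toward the negative lag. Zero-variance input yields
#' `(0, 0)` with a warning.
#'
#' @param a,b Equal-length numeric signals (same sensor, any channel pair).
#' @param fs Sampling rate, Hz.
#' @param max_lag_s Maximum absolute lag searched, seconds.
#' @return Named numeric `c(r, lag_s)`.
#' @export
max_norm_xcorr <- function(a, b, fs, max_lag_s = 1) {
  n <- length(a)
  if (length(b) != n) stop("signals must have equal length")
  L <- round(max_lag_s * fs)
  if (n <= 2 * L) stop("signals too short for the requested maximum lag")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero-variance signal: cross-correlation undefined, returning 0")
    return(c(r = 0, lag_s = 0))
  }
  lags <- -L:L
  # Pearson r per lag from prefix sums; only the cross product needs a pass
  sa <- cumsum(a); sa2 <- cumsum(a * a)
  sb <- cumsum(b); sb2 <- cumsum(b * b)
  pearson_at <- function(d) {
    m <- n - abs(d)
    if (d >= 0) {       # pair a[t] with b[t + d]
      Sa <- sa[m]; Sa2 <- sa2[m]
      Sb <- sb[n] - if (d > 0) sb[d] else 0
      Sb2 <- sb2[n] - if (d > 0) sb2[d] else 0
      cross <- sum(a[seq_len(m)] * b[seq.int(d + 1, n)])
    } else {
      Sa <- sa[n] - sa[-d]; Sa2 <- sa2[n] - sa2[-d]
      Sb <- sb[m]; Sb2 <- sb2[m]
      cross <- sum(a[seq.int(-d + 1, n)] * b[seq_len(m)])
    }
    va <- Sa2 - Sa^2 / m
    vb <- Sb2 - Sb^2 / m
    if (va <= 0 || vb <= 0) return(0)
    (cross - Sa * Sb / m) / sqrt(va * vb)
  }
  r <- vapply(lags, pearson_at, 0)
  # tie-break: smaller |lag|, then negative lag
  o <- order(-abs(r), abs(lags), lags)
  best <- o[1]
  c(r = r[best], lag_s = lags[best] / fs)
}

CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

# All 9 accel x gyro pair cross-correlations for one window at once: channel
# FFTs are shared across pairs and the lag-dependent Pearson normalization
# comes from prefix sums. Agrees with max_norm_xcorr() pair by pair.
xcorr_pairs <- function(sig_a, sig_g, fs, max_lag_s = 1) {
  n <- length(sig_a[[1]])
  L <- round(max_lag_s * fs)
  m2 <- stats::nextn(n + L + 1, 2)
  lags <- -L:L
  pre <- function(x) {
    list(s = cumsum(x), s2 = cumsum(x * x),
         F = fft(c(x, numeric(m2 - n))))
  }
  A <- lapply(sig_a, pre)
  G <- lapply(sig_g, pre)
  dneg <- seq_len(L)              # |d| for negative lags -L..-1 (reversed later)
  dpos <- 0:L
  out <- numeric(0)
  for (i in 1:3) {
    for (j in 1:3) {
      a <- A[[i]]; g <- G[[j]]
      z <- Re(fft(Conj(a$F) * g$F, inverse = TRUE)) / m2
      cross <- c(z[m2 - rev(dneg) + 1], z[dpos + 1])    # lags -L..L
      # positive lags d: a[1..n-d] vs g[d+1..n]
      mp <- n - dpos
      Sa_p <- a$s[mp]; Sa2_p <- a$s2[mp]
      Sb_p <- g$s[n] - c(0, g$s[dpos[-1]])
      Sb2_p <- g$s2[n] - c(0, g$s2[dpos[-1]])
      # negative lags -d: a[d+1..n] vs g[1..n-d]
      mn <- n - rev(dneg)
      Sa_n <- a$s[n] - a$s[rev(dneg)]
      Sa2_n <- a$s2[n] - a$s2[rev(dneg)]
      Sb_n <- g$s[mn]; Sb2_n <- g$s2[mn]
      m <- c(mn, mp)
      Sa <- c(Sa_n, Sa_p); Sa2 <- c(Sa2_n, Sa2_p)
      Sb <- c(Sb_n, Sb_p); Sb2 <- c(Sb2_n, Sb2_p)
      va <- Sa2 - Sa^2 / m
      vb <- Sb2 - Sb^2 / m
      denom <- sqrt(pmax(va, 0) * pmax(vb, 0))
      r <- ifelse(denom > 0, (cross - Sa * Sb / m) / denom, 0)
      best <- order(-abs(r), abs(lags), lags)[1]
      out <- c(out, r[best], lags[best] / fs)
    }
  }
  out
}

# all five per-channel scalars for one window, sharing one periodogram and a
# pre-designed low-pass filter; identical formulas to the exported ops
window_scalars <- function(xx, fs, filt, f_lo = 3.5, f_hi = 7.5) {
  os <- one_sided_power(xx, fs)
  tot <- sum(os$power)
  lbe <- log(LOG_ENERGY_EPS + sum(os$power[os$freq >= f_lo & os$freq < f_hi]))
  if (tot <= 0) {
    fd <- 0; er <- 0
  } else {
    k <- which.max(os$power)
    nb <- seq(max(1, k - 1), min(length(os$power), k + 1))
    fd <- os$freq[k]; er <- sum(os$power[nb]) / tot
  }
  y <- filtfilt_refl(filt, xx)
  c(log_band_energy = lbe,
    rms_lowpass3 = sqrt(mean(y^2)),
    dominant_freq_hz = fd,
    dominant_energy_ratio = er,
    amplitude_range = max(xx) - min(xx))
}

channel_signal <- function(rec, ch) {
  i <- match(substr(ch, 2, 2), c("x", "y", "z"))
  if (substr(ch, 1, 1) == "a") rec$accel[, i] else rec$gyro[, i]
}

#' Feature vector for one questionnaire instance
#'
#' Computes every feature on every `w_s`-second sub-window of the segment and
#' aggregates across sub-windows with `agg` (default the mean): per sensor,
#' 6 channels x 5 scalars (log band energy, low-pass RMS, dominant frequency,
#' dominant energy ratio, amplitude range) plus 9 accelerometer x gyroscope
#' pairs x 2 scalars (max normalized cross-correlation, lag), i.e. 48 per
#' sensor and 144 in total. Accelerometer features are in g, gyroscope
#' features in deg/s; cross-correlation is scale-free.
#'
#' @param segment An `analysis_segment` from [extract_segment()].
#' @param w_s Sub-window length, seconds.
#' @param agg Aggregation function across sub-windows.
#' @param max_lag_s Cross-correlation lag bound, seconds.
#' @return Named numeric vector of length 144
#'   (`{sensor}_{channel}_{feature}` / `{sensor}_{achan}_{gchan}_{feature}`).
#' @export
build_instance <- function(segment, w_s = 60, agg = mean, max_lag_s = 1) {
  stopifnot(inherits(segment, "analysis_segment"))
  out <- numeric(0)
  for (sid in SENSOR_IDS) {
    rec <- segment[[sid]]
    fs <- rec$sampling_rate_hz
    wins <- segment_windows(n_samples(rec), fs, w_s)
    filt <- butter_lowpass(fs, 3)
    sig <- lapply(CHANNELS, channel_signal, rec = rec)
    names(sig) <- CHANNELS
    for (ch in CHANNELS) {
      x <- sig[[ch]]
      per_win <- vapply(wins, function(ix) {
        window_scalars(x[ix], fs, filt)
      }, numeric(5))
      v <- apply(per_win, 1, agg)
      names(v) <- paste(sid, ch, names(v), sep = "_")
      out <- c(out, v)
    }
    per_win <- vapply(wins, function(ix) {
      xcorr_pairs(lapply(sig[1:3], `[`, ix), lapply(sig[4:6], `[`, ix),
                  fs, max_lag_s)
    }, numeric(18))
    v <- apply(per_win, 1, agg)
    pair_names <- as.vector(t(outer(c("ax", "ay", "az"), c("gx", "gy", "gz"),
                                    paste, sep = "_")))
    names(v) <- paste(sid, rep(pair_names, each = 2),
                      c("max_xcorr", "xcorr_lag_s"), sep = "_")
    out <- c(out, v)
  }
  out
}
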