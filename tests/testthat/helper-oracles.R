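# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the DFT is a direct O(N^2) summation, the AUC a
# pair count, the non-wear rule an explicit triple-condition loop.

make_recording <- function(n, fs = 200, start_ms = 0, accel_x = numeric(n),
                           participant = "P01", sensor = "chest") {
  accel <- cbind(accel_x, numeric(n), numeric(n))
  imu_recording(participant, sensor, fs, start_ms, accel,
                matrix(0, n, 3))
}

# direct-summation one-sided power spectrum with the same Parseval
# normalization convention: sum over all bins = mean square of demeaned x
dft_onesided_oracle <- function(x, fs) {
  n <- length(x)
  x <- x - mean(x)
  kmax <- floor(n / 2)
  t <- 0:(n - 1)
  power <- vapply(seq_len(kmax), function(k) {
    re <- sum(x * cos(2 * pi * k * t / n))
    im <- -sum(x * sin(2 * pi * k * t / n))
    dbl <- if (n %% 2 == 0 && k == kmax) 1 else 2
    dbl * (re^2 + im^2) / n^2
  }, 0)
  list(freq = seq_len(kmax) * fs / n, power = power)
}

oracle_log_band_energy <- function(x, fs, f_lo = 3.5, f_hi = 7.5) {
  os <- dft_onesided_oracle(x, fs)
  log(1e-12 + sum(os$power[os$freq >= f_lo & os$freq < f_hi]))
}

oracle_dominant_frequency <- function(x, fs) {
  os <- dft_onesided_oracle(x, fs)
  k <- which.max(os$power)
  nb <- seq(max(1, k - 1), min(length(os$power), k + 1))
  c(os$freq[k], sum(os$power[nb]) / sum(os$power))
}

# Mann-Whitney pair-counting AUC, ties worth one half
auc_mw_oracle <- function(probs, labels) {
  pos <- probs[labels == 1]
  neg <- probs[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# explicit triple-condition non-wear loop
brute_classify_worn <- function(std_x, thr = 0.002) {
  n <- length(std_x)
  worn <- logical(n)
  for (m in seq_len(n)) {
    self_low <- std_x[m] < thr
    prev_low <- if (m == 1) TRUE else std_x[m - 1] < thr
    next_low <- if (m == n) TRUE else std_x[m + 1] < thr
    worn[m] <- !(self_low && prev_low && next_low)
  }
  worn
}

# schedule + responses where a given number of continuous questionnaires per
# participant are fully completed (in time), the rest untouched
responses_with_n_complete <- function(events, n_complete, seed = 1) {
  resp <- empty_responses(events)
  cont <- which(events$kind == "continuous")
  set.seed(seed)
  done <- sample(cont, n_complete)
  for (i in done) {
    resp$opened_ms[i] <- events$scheduled_ms[i] + 60 * 1000
    resp$started_ms[i] <- resp$opened_ms[i] + 5000
    resp$ended_ms[i] <- resp$started_ms[i] + 219 * 1000
    resp[i, sprintf("a%02d", 1:26)] <- as.list(rep(4, 26))
  }
  resp
}
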