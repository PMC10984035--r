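# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# recording whose EEG is a pure sinusoid (amplitude uV, freq Hz)
sine_recording <- function(freq = 2, amp = 100, duration = 60, rate = 500,
                           emg_sd = 0) {
  n <- round(rate * duration)
  t <- seq_len(n) / rate
  Recording(eeg = amp * sin(2 * pi * freq * t),
            emg = if (emg_sd > 0) rnorm(n, 0, emg_sd) else numeric(n),
            eegRate = rate, duration = duration)
}

# brute-force periodogram: direct O(n^2) DFT of the windowed epoch
oracle_psd <- function(x, rate, window = "hamming") {
  n <- length(x)
  w <- if (window == "hamming")
    0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1)) else rep(1, n)
  xw <- (x - mean(x)) * w
  n_one <- floor(n / 2)
  k <- seq_len(n_one)
  p <- vapply(k, function(kk) {
    ang <- -2 * pi * kk * seq(0, n - 1) / n
    Mod(sum(xw * complex(real = cos(ang), imaginary = sin(ang))))^2
  }, numeric(1)) / (rate * sum(w^2))
  p <- 2 * p
  if (n %% 2 == 0) p[n_one] <- p[n_one] / 2
  list(freq = rate / n * k, power = p)
}

# brute-force per-epoch artifact scan
oracle_artifacts <- function(rec, L, eeg_lim, emg_lim) {
  n_ep <- floor(recDuration(rec) / L)
  vapply(seq_len(n_ep), function(k) {
    i_e <- ((k - 1) * L * eegRate(rec) + 1):(k * L * eegRate(rec))
    i_m <- ((k - 1) * L * emgRate(rec) + 1):(k * L * emgRate(rec))
    any(abs(eeg(rec)[i_e]) > eeg_lim) || any(abs(emg(rec)[i_m]) > emg_lim)
  }, logical(1))
}

# brute-force spike scan: walk the samples, accumulate runs
oracle_spikes <- function(x, rate, thr = 200, min_ms = 1, max_ms = 200) {
  out <- NULL
  i <- 1
  n <- length(x)
  while (i <= n) {
    if (abs(x[i]) > thr) {
      j <- i
      while (j < n && abs(x[j + 1]) > thr) j <- j + 1
      dur <- (j - i + 1) / rate * 1000
      if (dur >= min_ms && dur <= max_ms)
        out <- rbind(out, data.frame(onset_s = (i - 1) / rate,
                                     duration_ms = dur,
                                     peak_uV = max(abs(x[i:j]))))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(out))
    data.frame(onset_s = numeric(0), duration_ms = numeric(0),
               peak_uV = numeric(0))
  else out
}

# enumeration oracle for spike trains: chains are the maximal blocks
# obtained by cutting at every gap outside [gmin, gmax]
oracle_trains <- function(onsets, gmin = 0.05, gmax = 0.5, min_n = 3,
                          min_span = 1) {
  if (!length(onsets)) return(integer(0))
  cuts <- which(diff(onsets) < gmin | diff(onsets) > gmax)
  blocks <- split(seq_along(onsets),
                  cumsum(seq_along(onsets) %in% (cuts + 1)))
  keep <- vapply(blocks, function(idx)
    length(idx) >= min_n &&
      onsets[idx[length(idx)]] - onsets[idx[1]] >= min_span, logical(1))
  blocks[keep]
}

# direct discrete convolution oracle for the population trace
oracle_network_activity <- function(raster, bin = 0.01, sigma = 0.1) {
  n_bins <- floor(recDuration(raster) / bin)
  times <- unlist(spikeTimes(raster))
  counts <- tabulate(pmin(floor(times / bin) + 1, n_bins), nbins = n_bins)
  half <- ceiling(4 * sigma / bin)
  kern <- dnorm(seq(-half, half) * bin, sd = sigma) * bin
  out <- numeric(n_bins)
  for (i in seq_len(n_bins)) {
    js <- max(1, i - half):min(n_bins, i + half)
    out[i] <- sum(counts[js] / bin * kern[i - js + half + 1])
  }
  data.frame(time_s = (seq_len(n_bins) - 0.5) * bin, rate_hz = out)
}

# feature rows for staging tests
feat_row <- function(d, t, m, a = 0) {
  data.frame(epoch_index = 1L, delta_ratio = d, theta_delta_ratio = t,
             emg_ratio = m, mean_activity = a, artifact = FALSE)
}
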