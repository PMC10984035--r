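#' Band-limited Gaussian noise
#'
#' Gaussian noise whose spectral support is restricted to one or more
#' frequency bands, built by drawing independent complex-Gaussian Fourier
#' coefficients inside each band (zero outside) and inverse-transforming.
#' Within each band the expected total variance equals `rms^2`; the
#' realised epoch power fluctuates with the natural chi-squared
#' variability of a finite sample, which is what makes downstream PSD
#' estimates realistically noisy (a pure sinusoid would not).
#'
#' @param n number of samples.
#' @param rate sampling rate, Hz.
#' @param lo,hi numeric vectors of band edges, Hz (recycled pairwise).
#' @param rms per-band RMS amplitude (same length as `lo`).
#' @return numeric vector of length `n`.
#' @examples
#' x <- bandNoise(5000, 500, lo = 0.5, hi = 4, rms = 20)
#' sd(x)  # ~ 20
#' @export
bandNoise <- function(n, rate, lo, hi, rms) {
  stopifnot(length(lo) == length(hi), length(rms) == length(lo))
  df <- rate / n
  n_pos <- floor((n - 1) / 2)        # strictly positive, non-Nyquist bins
  X <- complex(n)
  freqs <- df * seq_len(n_pos)
  for (b in seq_along(lo)) {
    kk <- which(freqs > lo[b] & freqs <= hi[b])
    m <- length(kk)
    if (!m) next
    sdc <- rms[b] * n / (2 * sqrt(m))
    X[kk + 1L] <- X[kk + 1L] +
      complex(real = stats::rnorm(m, 0, sdc),
              imaginary = stats::rnorm(m, 0, sdc))
  }
  X[n - seq_len(n_pos) + 1L] <- Conj(X[seq_len(n_pos) + 1L])
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Pink (1/f) noise
#'
#' Gaussian noise with spectral density proportional to 1/f across the
#' full band, scaled to the requested sample RMS. Used as a broadband
#' EEG-like background in detector recovery experiments.
#'
#' @param n number of samples.
#' @param rate sampling rate, Hz.
#' @param rms target sample standard deviation.
#' @return numeric vector of length `n`.
#' @export
pinkNoise <- function(n, rate, rms = 1) {
  df <- rate / n
  n_pos <- floor((n - 1) / 2)
  freqs <- df * seq_len(n_pos)
  amp <- 1 / sqrt(freqs)
  X <- complex(n)
  X[seq_len(n_pos) + 1L] <- complex(
    real = stats::rnorm(n_pos, 0, amp),
    imaginary = stats::rnorm(n_pos, 0, amp))
  X[n - seq_len(n_pos) + 1L] <- Conj(X[seq_len(n_pos) + 1L])
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}
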