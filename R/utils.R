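# Shared numerical helpers: analytic signal, Welch PSD, binomial intervals.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Computes the complex analytic signal `x + i * H(x)` by zeroing negative
#' frequencies of the FFT, the standard construction used for instantaneous
#' phase estimation.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  stopifnot(is.numeric(x), length(x) > 1)
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms with Hann windows. Density normalisation:
#' the rectangle-rule integral of `psd` over `freq` approximates the signal
#' variance (one-sided spectrum).
#'
#' @param x Numeric vector (one channel of one epoch).
#' @param fs Sampling rate in Hz.
#' @param seg_s Segment length in seconds (default 4).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @param demean Remove each segment's mean before windowing (default TRUE).
#' @return A tibble with columns `freq` (Hz, 0 to fs/2) and `psd`
#'   (power density, input-units squared per Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 4, overlap = 0.5, demean = TRUE) {
  stopifnot(fs > 0, seg_s > 0, overlap >= 0, overlap < 1)
  nseg <- round(seg_s * fs)
  if (length(x) < nseg) nseg <- length(x)
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  u <- sum(w^2)
  nfreq <- nseg %/% 2 + 1
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    if (demean) seg <- seg - mean(seg)
    pg <- Mod(fft(seg * w))^2
    acc <- acc + pg[seq_len(nfreq)]
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  dbl <- 2:(nfreq - if (nseg %% 2 == 0) 1 else 0)
  psd[dbl] <- 2 * psd[dbl]
  tibble::tibble(freq = (seq_len(nfreq) - 1) * fs / nseg, psd = psd)
}

#' Wilson score interval for a binomial proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(estimate, lower, upper)`; all `NA` when `n = 0`.
#' @export
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(estimate = p, lower = max(0, centre - half), upper = min(1, centre + half))
}

# centered moving average with shrinking windows at the edges
moving_average <- function(x, k) {
  k <- max(1L, as.integer(k))
  n <- length(x)
  half <- k %/% 2
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# population central moments
pop_var <- function(x) mean((x - mean(x))^2)

# draw a per-unit 31-bit seed stream from a master seed, reproducibly
derive_seeds <- function(master_seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(master_seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max - 1L, n)
}
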