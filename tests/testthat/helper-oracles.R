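# Independent brute-force oracles: every feature re-derived from its direct
# definition, sharing no code with the package implementation.

oracle_moving_env <- function(x, fs, smooth_s = 0.1) {
  k <- max(1L, round(smooth_s * fs))
  half <- k %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(abs(x[max(1, i - half):min(n, i + half)]))
  }, numeric(1))
}

oracle_bsr <- function(x, fs, thresh = 5, min_s = 0.5, smooth_s = 0.1) {
  env <- oracle_moving_env(x, fs, smooth_s)
  supp <- env <= thresh
  min_len <- round(min_s * fs)
  n <- length(x)
  keep <- logical(n)
  i <- 1
  while (i <= n) {
    if (supp[i]) {
      j <- i
      while (j < n && supp[j + 1]) j <- j + 1
      if (j - i + 1 >= min_len) keep[i:j] <- TRUE
      i <- j + 1
    } else i <- i + 1
  }
  mean(keep)
}

oracle_entropy <- function(x, bins = 64) {
  r <- range(x)
  if (r[1] == r[2]) return(0)
  idx <- pmin(bins, floor((x - r[1]) / (r[2] - r[1]) * bins) + 1)
  p <- as.vector(table(factor(idx, levels = 1:bins))) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

oracle_temporal <- function(x, fs, bins = 64) {
  n <- length(x)
  mu <- sum(x) / n
  v <- sum((x - mu)^2) / n
  if (v == 0) {
    return(c(rms = 0, activity = 0, mobility = NA, complexity = NA,
             kurtosis = NA, skewness = NA, entropy = 0))
  }
  pv <- function(u) sum((u - sum(u) / length(u))^2) / length(u)
  d1 <- (x[-1] - x[-n]) * fs
  d2 <- (d1[-1] - d1[-(n - 1)]) * fs
  mob <- sqrt(pv(d1) / v)
  c(rms = sqrt(v), activity = v, mobility = mob,
    complexity = sqrt(pv(d2) / pv(d1)) / mob,
    kurtosis = (sum((x - mu)^4) / n) / v^2,
    skewness = (sum((x - mu)^3) / n) / v^1.5,
    entropy = oracle_entropy(x, bins))
}

# frequency features recomputed by direct sums on a given (freq, psd) grid
oracle_frequency <- function(freq, psd, edge = 0.95) {
  df <- freq[2] - freq[1]
  pow <- function(lo, hi, closed) {
    s <- 0
    for (i in seq_along(freq)) {
      inb <- freq[i] >= lo && (if (closed) freq[i] <= hi else freq[i] < hi)
      if (inb) s <- s + psd[i] * df
    }
    s
  }
  d <- pow(0.5, 4, FALSE); t <- pow(4, 8, FALSE)
  a <- pow(8, 13, FALSE); b <- pow(13, 30, TRUE)
  tot <- d + t + a + b
  inb <- which(freq >= 0.5 & freq <= 30)
  f_m <- freq[inb][which.max(psd[inb])]
  cum <- cumsum(psd[inb]) / sum(psd[inb])
  f_h <- freq[inb][min(which(cum >= edge))]
  c(f_m = f_m, delta = d, theta = t, alpha = a, beta = b,
    delta_total = d / tot, theta_total = t / tot, alpha_total = a / tot,
    beta_total = b / tot, theta_delta = t / d, alpha_delta = a / d,
    beta_delta = b / d, alpha_theta = a / t, beta_theta = b / t,
    beta_alpha = b / a, f_h = f_h)
}

oracle_hilbert_phase <- function(x) {
  n <- length(x)
  mult <- rep(0, n)
  mult[1] <- 1
  if (n %% 2 == 0) {
    mult[n / 2 + 1] <- 1
    mult[2:(n / 2)] <- 2
  } else {
    mult[2:((n + 1) / 2)] <- 2
  }
  z <- fft(fft(x) * mult, inverse = TRUE) / n
  atan2(Im(z), Re(z))
}

oracle_connectivity <- function(x, y, bins = 64) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sx <- sqrt(sum((x - mx)^2) / n); sy <- sqrt(sum((y - my)^2) / n)
  pcc <- sum((x - mx) * (y - my)) / (n * sx * sy)
  ix <- pmin(bins, floor((x - min(x)) / diff(range(x)) * bins) + 1)
  iy <- pmin(bins, floor((y - min(y)) / diff(range(y)) * bins) + 1)
  pj <- as.vector(table(factor(ix, 1:bins), factor(iy, 1:bins))) / n
  pj <- pj[pj > 0]
  mi <- max(0, oracle_entropy(x, bins) + oracle_entropy(y, bins) + sum(pj * log(pj)))
  d <- oracle_hilbert_phase(x) - oracle_hilbert_phase(y)
  d <- ((d + pi) %% (2 * pi)) - pi
  c(pcc = pcc, mi = mi,
    plv = sqrt(mean(cos(d))^2 + mean(sin(d))^2),
    pli = abs(mean(sign(d))))
}

# the full 48-entry epoch feature vector by oracle: per-channel values,
# channel medians for temporal/frequency, pairwise connectivity
oracle_epoch_features <- function(m, fs, bins = 64, seg_s = 4, edge = 0.95) {
  chans <- colnames(m)
  per_ch <- lapply(chans, function(ch) {
    x <- m[, ch]
    spec <- fpqeeg::power_spectrum(x, fs, seg_s = seg_s)
    c(bsr = oracle_bsr(x, fs), oracle_temporal(x, fs, bins),
      oracle_frequency(spec$freq, spec$psd, edge))
  })
  nm <- names(per_ch[[1]])
  med <- vapply(nm, function(k) {
    median(vapply(per_ch, `[[`, numeric(1), k))
  }, numeric(1))
  pairs <- list(c("F3", "F4"), c("P3", "P4"), c("F3", "P3"),
                c("F4", "P4"), c("F3", "P4"), c("F4", "P3"))
  conn <- unlist(lapply(pairs, function(p) {
    v <- oracle_connectivity(m[, p[1]], m[, p[2]], bins)
    names(v) <- paste(names(v), tolower(p[1]), tolower(p[2]), sep = "_")
    v
  }))
  c(med, conn)
}

# small random 4-channel epoch fixture (white + slow components, uV scale)
random_epoch_matrix <- function(n = 1200, fs = 100, seed = 1, amp = 20) {
  set.seed(seed)
  m <- sapply(1:4, function(j) {
    t <- seq_len(n) / fs
    amp * (0.6 * sin(2 * pi * runif(1, 1, 12) * t + runif(1, 0, 2 * pi)) +
             0.8 * rnorm(n))
  })
  colnames(m) <- c("F3", "F4", "P3", "P4")
  m
}

# recording filled with given per-channel signals
make_recording <- function(mat, fs, subject_id = "test") {
  suppressWarnings(fpqeeg::new_recording(mat, colnames(mat), fs, subject_id,
                                         min_duration_min = 0))
}

sine_epoch <- function(freq, fs, dur_s, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq(0, dur_s - 1 / fs, by = 1 / fs) + phase)
}
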