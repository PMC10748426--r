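# Quantitative EEG features: 8 temporal, 16 frequency, 24 connectivity.

#' Burst suppression ratio
#'
#' Fraction of the epoch spent in the suppression state: samples whose
#' amplitude envelope (absolute value smoothed over `smooth_s`) stays at or
#' below `supp_thresh` uV for at least `min_supp_s` contiguous seconds.
#' The run-length requirement stops instantaneous zero crossings of
#' oscillatory activity from counting as suppression.
#'
#' @param x Numeric vector, one epoch channel in uV (zero-mean).
#' @param fs Sampling rate in Hz.
#' @param supp_thresh Suppression amplitude threshold in uV (default 5).
#' @param min_supp_s Minimum suppression run length in seconds (default 0.5).
#' @param smooth_s Envelope smoothing window in seconds (default 0.1).
#' @return Suppressed fraction in `[0, 1]`.
#' @export
burst_suppression_ratio <- function(x, fs, supp_thresh = 5,
                                    min_supp_s = 0.5, smooth_s = 0.1) {
  env <- moving_average(abs(x), round(smooth_s * fs))
  supp <- env <= supp_thresh
  runs <- rle(supp)
  min_len <- round(min_supp_s * fs)
  keep <- runs$values & runs$lengths >= min_len
  sum(runs$lengths[keep]) / length(x)
}

#' Temporal-domain features for one epoch channel
#'
#' Computes RMS (population standard deviation), Hjorth activity/mobility/
#' complexity (the first difference scaled by `fs`, so mobility is in rad/s
#' and equals `2*pi*f` for a sinusoid of frequency `f`), non-excess kurtosis
#' and skewness (standardised population moments; normal kurtosis = 3), and
#' Shannon entropy of the amplitude histogram (equal-width bins over the
#' epoch's range, natural log).
#'
#' Mobility and complexity are undefined for a constant signal and reported
#' as `NA`.
#'
#' @param x Numeric vector in uV.
#' @param fs Sampling rate in Hz.
#' @param entropy_bins Histogram bin count for the entropy estimate
#'   (default 64).
#' @return Named list: `rms`, `activity`, `mobility`, `complexity`,
#'   `kurtosis`, `skewness`, `entropy`.
#' @export
temporal_features <- function(x, fs, entropy_bins = 64) {
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) {
    return(list(rms = 0, activity = 0, mobility = NA_real_,
                complexity = NA_real_, kurtosis = NA_real_,
                skewness = NA_real_, entropy = 0))
  }
  d1 <- diff(x) * fs
  d2 <- diff(d1) * fs
  mob <- sqrt(pop_var(d1) / v)
  mob_d <- sqrt(pop_var(d2) / pop_var(d1))
  z <- x - m
  list(
    rms = sqrt(v),
    activity = v,
    mobility = mob,
    complexity = mob_d / mob,
    kurtosis = mean(z^4) / v^2,
    skewness = mean(z^3) / v^1.5,
    entropy = shannon_entropy(x, entropy_bins)
  )
}

#' Shannon entropy of the amplitude histogram
#'
#' @param x Numeric vector.
#' @param bins Number of equal-width bins over `range(x)` (default 64).
#' @return Entropy in nats; 0 for a constant signal.
#' @export
shannon_entropy <- function(x, bins = 64) {
  r <- range(x)
  if (diff(r) == 0) return(0)
  idx <- amplitude_bins(x, r, bins)
  p <- tabulate(idx, bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# equal-width bin index in 1..bins over range r
amplitude_bins <- function(x, r, bins) {
  idx <- floor((x - r[1]) / (r[2] - r[1]) * bins) + 1L
  pmin.int(idx, bins)
}

#' Power spectrum of one epoch channel
#'
#' Welch estimate with 4-second Hann segments and 50% overlap by default;
#' density-normalised so the integral over frequency approximates the
#' channel variance.
#'
#' @inheritParams welch_psd
#' @return Tibble with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
power_spectrum <- function(x, fs, seg_s = 4, overlap = 0.5) {
  welch_psd(x, fs, seg_s = seg_s, overlap = overlap)
}

#' Frequency-domain features from a power spectrum
#'
#' Band powers are PSD integrals over the classical rhythm bands
#' delta 0.5-4 Hz, theta 4-8 Hz, alpha 8-13 Hz, beta 13-30 Hz (half-open on
#' the right except beta). Total power is the sum of the four band powers, so
#' the four `/total` ratios sum to one. `f_m` is the frequency of the PSD
#' maximum within 0.5-30 Hz; `f_h` is the spectral edge frequency below which
#' `edge` (default 95%) of the 0.5-30 Hz power lies.
#'
#' @param spec Tibble from [power_spectrum()] (`freq`, `psd`).
#' @param edge Spectral-edge fraction for `f_h` (default 0.95).
#' @return Named list of the 16 frequency features (band powers in uV^2).
#'   All ratios are `NA` when total band power is zero.
#' @export
frequency_features <- function(spec, edge = 0.95) {
  freq <- spec$freq
  psd <- spec$psd
  df <- freq[2] - freq[1]
  bp <- function(lo, hi, closed = FALSE) {
    sel <- freq >= lo & (if (closed) freq <= hi else freq < hi)
    sum(psd[sel]) * df
  }
  delta <- bp(0.5, 4)
  theta <- bp(4, 8)
  alpha <- bp(8, 13)
  beta <- bp(13, 30, closed = TRUE)
  total <- delta + theta + alpha + beta
  inband <- freq >= 0.5 & freq <= 30
  f_m <- if (any(inband) && any(psd[inband] > 0)) {
    freq[inband][which.max(psd[inband])]
  } else NA_real_
  f_h <- if (any(inband) && sum(psd[inband]) > 0) {
    cum <- cumsum(psd[inband]) / sum(psd[inband])
    freq[inband][which(cum >= edge)[1]]
  } else NA_real_
  rat <- function(a, b) if (total == 0 || b == 0) NA_real_ else a / b
  list(
    f_m = f_m, delta = delta, theta = theta, alpha = alpha, beta = beta,
    delta_total = rat(delta, total), theta_total = rat(theta, total),
    alpha_total = rat(alpha, total), beta_total = rat(beta, total),
    theta_delta = rat(theta, delta), alpha_delta = rat(alpha, delta),
    beta_delta = rat(beta, delta), alpha_theta = rat(alpha, theta),
    beta_theta = rat(beta, theta), beta_alpha = rat(beta, alpha),
    f_h = f_h
  )
}

#' Connectivity metrics for one channel pair
#'
#' Pearson correlation (PCC); mutual information `H(x) + H(y) - H(x, y)` from
#' amplitude histograms (same equal-width binning policy as the entropy
#' feature, 64 x 64 by default, natural log, negative estimates clipped to 0);
#' and phase metrics from the analytic signal of each (already broadband
#' filtered) channel: PLV is the modulus of the mean unit phasor of the phase
#' difference, PLI the modulus of the mean sign of the phase difference.
#' A consistent zero phase lag gives PLV 1 but PLI 0, making PLI insensitive
#' to volume-conduction-like coupling.
#'
#' @param x,y Numeric vectors of equal length (one epoch, filtered, uV).
#' @param bins Histogram bins per axis for the MI estimate (default 64).
#' @param zx,zy Optional precomputed analytic signals of `x` and `y`
#'   (recomputed when `NULL`).
#' @return Named list `pcc`, `mi`, `plv`, `pli`. `pcc`, `plv`, `pli` are `NA`
#'   when either channel is constant.
#' @export
connectivity_pair <- function(x, y, bins = 64, zx = NULL, zy = NULL) {
  stopifnot(length(x) == length(y))
  const <- pop_var(x) == 0 || pop_var(y) == 0
  rx <- range(x); ry <- range(y)
  mi <- if (diff(rx) == 0 || diff(ry) == 0) 0 else {
    ix <- amplitude_bins(x, rx, bins)
    iy <- amplitude_bins(y, ry, bins)
    pj <- tabulate(ix + bins * (iy - 1L), bins * bins) / length(x)
    hx <- shannon_entropy(x, bins)
    hy <- shannon_entropy(y, bins)
    pj <- pj[pj > 0]
    hxy <- -sum(pj * log(pj))
    max(0, hx + hy - hxy)
  }
  if (const) {
    return(list(pcc = NA_real_, mi = mi, plv = NA_real_, pli = NA_real_))
  }
  if (is.null(zx)) zx <- analytic_signal(x)
  if (is.null(zy)) zy <- analytic_signal(y)
  dphi <- Arg(zx * Conj(zy))
  list(
    pcc = cor(x, y),
    mi = mi,
    plv = Mod(mean(exp(1i * dphi))),
    pli = abs(mean(sign(dphi)))
  )
}

#' Per-epoch feature extraction
#'
#' Computes, for every retained epoch, the temporal and frequency features of
#' each channel and the four connectivity metrics of each of the six channel
#' pairs, then collapses channels by the median (connectivity is already
#' pairwise), yielding one 48-feature row per epoch.
#'
#' @param epochs Epoch tibble from [preprocess_recording()].
#' @param supp_thresh,min_supp_s Burst-suppression settings, see
#'   [burst_suppression_ratio()].
#' @param entropy_bins Histogram bins for entropy and MI.
#' @param seg_s Welch segment length in seconds.
#' @param edge Spectral-edge fraction.
#' @return Tibble: `subject_id`, `epoch`, then the 48 feature columns.
#' @export
extract_features <- function(epochs, supp_thresh = 5, min_supp_s = 0.5,
                             entropy_bins = 64, seg_s = 4, edge = 0.95) {
  one_epoch <- function(m, fs) {
    per_ch <- lapply(seq_len(ncol(m)), function(j) {
      x <- m[, j]
      tf <- temporal_features(x, fs, entropy_bins)
      ff <- frequency_features(power_spectrum(x, fs, seg_s = seg_s), edge = edge)
      c(list(bsr = burst_suppression_ratio(x, fs, supp_thresh, min_supp_s)),
        tf, ff)
    })
    chan_med <- vapply(names(per_ch[[1]]), function(nm) {
      vals <- vapply(per_ch, function(p) p[[nm]], numeric(1))
      if (all(is.na(vals))) NA_real_ else median(vals, na.rm = TRUE)
    }, numeric(1))
    zs <- lapply(FP_CHANNELS, function(ch) analytic_signal(m[, ch]))
    names(zs) <- FP_CHANNELS
    conn <- unlist(lapply(FP_PAIRS, function(p) {
      cp <- connectivity_pair(m[, p[1]], m[, p[2]], bins = entropy_bins,
                              zx = zs[[p[1]]], zy = zs[[p[2]]])
      setNames(unlist(cp), paste(names(cp), pair_key(p[1], p[2]), sep = "_"))
    }))
    c(chan_med, conn)
  }
  rows <- purrr::map2(epochs$data, epochs$fs, one_epoch)
  out <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(
    tibble::tibble(subject_id = epochs$subject_id, epoch = epochs$epoch),
    out[, feature_names("all")]
  )
}

#' Aggregate per-epoch features to one patient row
#'
#' Channel aggregation (the median over the four channels) already happened in
#' [extract_features()]; this step averages each feature across the retained
#' epochs, excluding epoch values that are missing (e.g. mobility of a
#' degenerate epoch) and recording how many epochs contributed.
#'
#' @param epoch_features Tibble from [extract_features()] (one subject).
#' @return One-row tibble: `subject_id`, 48 features, `n_epochs_used`, and a
#'   `n_missing` attribute-free column set `missing_any` flagging features
#'   missing in all epochs.
#' @export
aggregate_patient_features <- function(epoch_features) {
  stopifnot(nrow(epoch_features) >= 1)
  feats <- feature_names("all")
  vals <- vapply(feats, function(nm) {
    v <- epoch_features[[nm]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  out <- tibble::as_tibble(as.list(vals))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = epoch_features$subject_id[1]),
    out,
    tibble::tibble(n_epochs_used = nrow(epoch_features))
  )
  miss <- feats[vapply(feats, function(nm) all(is.na(epoch_features[[nm]])), logical(1))]
  if (length(miss)) {
    warning("feature(s) missing in all epochs for ",
            out$subject_id, ": ", paste(miss, collapse = ", "))
  }
  out
}

#' Patient feature vector straight from a recording
#'
#' Convenience wrapper: preprocess, extract per-epoch features, aggregate.
#'
#' @param rec An `fp_recording`.
#' @param ... Passed to [preprocess_recording()] and [extract_features()].
#' @return One-row tibble of the 48 aggregated features.
#' @export
patient_features <- function(rec, ...) {
  args <- list(...)
  pp_names <- intersect(names(args), names(formals(preprocess_recording)))
  fx_names <- intersect(names(args), names(formals(extract_features)))
  pp <- do.call(preprocess_recording, c(list(rec), args[pp_names]))
  fx <- do.call(extract_features, c(list(pp$epochs), args[fx_names]))
  aggregate_patient_features(fx)
}
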