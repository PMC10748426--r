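# Synthetic comatose-EEG cohort generator. Emulates the statistical contrasts
# the analysis assumes between outcome groups -- raised burst suppression,
# suppressed voltage, a beta-shifted beta/alpha ratio and weakened F3-P4
# phase coupling in the unfavorable class -- not biophysically realistic EEG.

rhythm_bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                     alpha = c(8, 13), beta = c(13, 30))

# band-filtered unit-variance Gaussian noise
band_noise <- function(n, fs, band, order = 4) {
  x <- rnorm(n + 2 * fs)
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  y <- signal::filter(bf, x)
  y <- y[(fs + 1):(fs + n)]
  y / sd(y)
}

#' Patient signal profile
#'
#' Bundles the generator parameters of one synthetic patient: target
#' suppressed fraction, burst amplitude, rhythm mixture, per-pair phase
#' coupling and sensor noise.
#'
#' @param supp_frac Target suppressed fraction of the recording in `[0, 1]`.
#' @param amp_scale Burst amplitude scale in uV (channel RMS is about
#'   `amp_scale / sqrt(2)` during bursts).
#' @param band_mix Nonnegative weights for delta/theta/alpha/beta variance.
#' @param coupling Named list per channel pair (names like `"f3_p4"`), each a
#'   list with `strength` in `[0, 1]`, `lag` (radians) and `jitter`
#'   (phase-noise SD, radians).
#' @param mean_burst_s Mean burst segment duration in seconds (segment
#'   durations are exponential).
#' @param noise_sd Additive sensor noise SD in uV.
#' @param gos Optional GOS level carried along for cohort assembly.
#' @param etiology Optional etiology label.
#' @return List of class `fp_profile`.
#' @export
patient_profile <- function(supp_frac = 0.15, amp_scale = 30,
                            band_mix = c(delta = 0.85, theta = 0.06,
                                         alpha = 0.06, beta = 0.03),
                            coupling = list(), mean_burst_s = 3,
                            noise_sd = 1, gos = NA_integer_,
                            etiology = NA_character_) {
  stopifnot(supp_frac >= 0, supp_frac <= 1, amp_scale > 0,
            all(band_mix >= 0), sum(band_mix) > 0)
  for (cp in coupling) {
    stopifnot(cp$strength >= 0, cp$strength <= 1)
  }
  structure(
    list(supp_frac = supp_frac, amp_scale = amp_scale,
         band_mix = band_mix / sum(band_mix), coupling = coupling,
         mean_burst_s = mean_burst_s, noise_sd = noise_sd,
         gos = gos, etiology = etiology),
    class = "fp_profile"
  )
}

# alternating burst(TRUE)/suppression(FALSE) gate with exponential durations
bs_gate <- function(n, fs, supp_frac, mean_burst_s) {
  if (supp_frac >= 1) return(rep(FALSE, n))
  if (supp_frac <= 0) return(rep(TRUE, n))
  mean_supp_s <- mean_burst_s * supp_frac / (1 - supp_frac)
  gate <- logical(0)
  state <- runif(1) > supp_frac
  while (length(gate) < n) {
    dur <- stats::rexp(1, 1 / if (state) mean_burst_s else mean_supp_s)
    gate <- c(gate, rep(state, max(1L, round(dur * fs))))
    state <- !state
  }
  gate[seq_len(n)]
}

#' Generate a burst-suppression channel signal
#'
#' Alternating burst/suppression segments with exponential durations scaled so
#' the expected suppressed fraction equals `supp_frac`. Bursts are broadband
#' (0.5-30 Hz) noise at `amp_scale`; suppression segments are low-amplitude
#' noise clipped to 2 uV.
#'
#' @param duration_s Signal duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param supp_frac Target suppressed fraction.
#' @param amp_scale Burst amplitude in uV.
#' @param mean_burst_s Mean burst duration in seconds (default 3).
#' @param seed Integer seed; same seed, same signal.
#' @return Numeric vector of length `round(duration_s * fs)` in uV.
#' @export
gen_burst_suppression_signal <- function(duration_s, fs, supp_frac = 0.5,
                                         amp_scale = 30, mean_burst_s = 3,
                                         seed = 1) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- round(duration_s * fs)
  gate <- bs_gate(n, fs, supp_frac, mean_burst_s)
  burst <- band_noise(n, fs, c(0.5, 30)) * amp_scale / sqrt(2)
  supp <- pmax(-2, pmin(2, rnorm(n, sd = 0.5)))
  pmax(-199, pmin(199, ifelse(gate, burst, supp)))
}

#' Generate a rhythm-mixture channel signal
#'
#' Sum of band-filtered Gaussian noise components (delta/theta/alpha/beta)
#' with variances proportional to `band_mix`, scaled to an overall RMS of
#' about `amp_scale / sqrt(2)`.
#'
#' @inheritParams gen_burst_suppression_signal
#' @param band_mix Nonnegative delta/theta/alpha/beta variance weights.
#' @return Numeric vector in uV.
#' @export
gen_rhythm_signal <- function(duration_s, fs, band_mix = c(1, 1, 1, 1),
                              amp_scale = 30, seed = 1) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  stopifnot(length(band_mix) == 4, all(band_mix >= 0), sum(band_mix) > 0)
  n <- round(duration_s * fs)
  w <- band_mix / sum(band_mix)
  x <- numeric(n)
  for (b in seq_along(rhythm_bands)) {
    if (w[b] > 0) x <- x + sqrt(w[b]) * band_noise(n, fs, rhythm_bands[[b]])
  }
  x / sd(x) * amp_scale / sqrt(2)
}

# smoothed unit-SD phase-noise track
phase_jitter <- function(n, fs, sd_rad) {
  if (sd_rad <= 0) return(numeric(n))
  raw <- band_noise(n, fs, c(0.05, 1), order = 2)
  raw / sd(raw) * sd_rad
}

#' Generate a coupled four-channel recording
#'
#' Builds F3, F4, P3, P4 as rhythm mixtures; for every configured channel
#' pair, a shared narrowband source is mixed into both members with the
#' configured strength, and the second member receives it with a constant
#' phase lag plus slow phase jitter -- stronger coupling with low jitter
#' yields a higher phase-lag index for that pair. A common burst-suppression
#' gate (burst suppression in coma is typically generalised) and independent
#' sensor noise complete the channels. Output is saturated at +/-135 uV so
#' that generated physiology always passes the amplitude QC rule even after
#' filter ringing; artifacts are only present when explicitly injected.
#'
#' @param profile An [patient_profile()].
#' @param duration_s Recording duration in seconds.
#' @param fs Sampling rate in Hz (default 250).
#' @param subject_id Subject identifier.
#' @param seed Integer seed.
#' @param inject_artifact If `TRUE`, a high-amplitude (> 200 uV) transient is
#'   written into one epoch so QC rejection paths can be exercised.
#' @return An `fp_recording`.
#' @export
gen_coupled_recording <- function(profile, duration_s = 1800, fs = 250,
                                  subject_id = "synthetic", seed = 1,
                                  inject_artifact = FALSE) {
  stopifnot(inherits(profile, "fp_profile"))
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- round(duration_s * fs)
  chans <- tolower(FP_CHANNELS)

  # shared coupled fraction per channel
  shared <- setNames(numeric(4), chans)
  for (key in names(profile$coupling)) {
    ab <- strsplit(key, "_")[[1]]
    s <- profile$coupling[[key]]$strength
    shared[ab] <- shared[ab] + s
  }
  shared <- pmin(shared, 0.95)

  base <- sapply(chans, function(ch) {
    gen_rhythm_signal(duration_s, fs, profile$band_mix, amp_scale = sqrt(2),
                      seed = sample.int(.Machine$integer.max - 1L, 1))
  })
  out <- sweep(base, 2, sqrt(1 - shared), `*`)

  for (key in names(profile$coupling)) {
    cp <- profile$coupling[[key]]
    if (cp$strength <= 0) next
    ab <- strsplit(key, "_")[[1]]
    src <- band_noise(n, fs, c(2, 6))
    z <- analytic_signal(src)
    jit <- phase_jitter(n, fs, cp$jitter %||% 0)
    lagged <- Re(z * exp(1i * (cp$lag + jit)))
    lagged <- lagged / sd(lagged)
    out[, ab[1]] <- out[, ab[1]] + sqrt(cp$strength) * src
    out[, ab[2]] <- out[, ab[2]] + sqrt(cp$strength) * lagged
  }

  # scale to burst amplitude, gate, add sensor noise
  out <- out / rep(apply(out, 2, sd), each = n) * profile$amp_scale / sqrt(2)
  gate <- bs_gate(n, fs, profile$supp_frac, profile$mean_burst_s)
  gain <- ifelse(gate, 1, 1 / profile$amp_scale)
  out <- out * gain + matrix(rnorm(n * 4, sd = profile$noise_sd), n, 4)
  # amplitude ceiling: generated physiology must still pass the 200 uV QC
  # rule after zero-phase filtering, whose ringing can overshoot sharp
  # excursions; rare (>4 sigma) tail samples are saturated with that margin
  out[] <- pmax(-135, pmin(135, out))

  if (inject_artifact) {
    at <- min(n, round(30 * fs))
    out[at:min(n, at + fs), 1] <- 300
  }
  suppressWarnings(
    new_recording(out, FP_CHANNELS, fs, subject_id, min_duration_min = 0)
  )
}

#' Default outcome-class profiles
#'
#' The class contrasts follow the direction pattern expected between outcome
#' groups: the unfavorable class has a higher suppressed fraction, lower
#' amplitude, a beta-shifted alpha/beta balance and weaker, noisier F3-P4
#' coupling.
#'
#' @param outcome `"favorable"` or `"unfavorable"`.
#' @return An [patient_profile()].
#' @export
class_profile <- function(outcome = c("favorable", "unfavorable")) {
  outcome <- match.arg(outcome)
  other_pairs <- c("f3_f4", "p3_p4", "f3_p3", "f4_p4", "f4_p3")
  base_coupling <- setNames(
    rep(list(list(strength = 0.35, lag = pi / 4, jitter = 0.8)),
        length(other_pairs)),
    other_pairs
  )
  if (outcome == "favorable") {
    patient_profile(
      supp_frac = 0.12, amp_scale = 30,
      band_mix = c(delta = 0.85, theta = 0.06, alpha = 0.06, beta = 0.03),
      coupling = c(list(f3_p4 = list(strength = 0.8, lag = pi / 4, jitter = 0.25)),
                   base_coupling)
    )
  } else {
    patient_profile(
      supp_frac = 0.45, amp_scale = 14,
      band_mix = c(delta = 0.86, theta = 0.05, alpha = 0.03, beta = 0.06),
      coupling = c(list(f3_p4 = list(strength = 0.25, lag = pi / 4, jitter = 1.2)),
                   base_coupling)
    )
  }
}

# jitter a class profile into an individual one (within-class variability)
individual_profile <- function(class_prof, gos, etiology, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  p <- class_prof
  p$supp_frac <- min(0.98, max(0.01, p$supp_frac * exp(rnorm(1, sd = 0.25))))
  p$amp_scale <- p$amp_scale * exp(rnorm(1, sd = 0.2))
  mix <- p$band_mix * exp(rnorm(4, sd = 0.25))
  p$band_mix <- mix / sum(mix)
  p$coupling <- lapply(p$coupling, function(cp) {
    cp$strength <- min(0.95, max(0.02, cp$strength + rnorm(1, sd = 0.06)))
    cp$jitter <- max(0.05, cp$jitter * exp(rnorm(1, sd = 0.2)))
    cp
  })
  p$gos <- gos
  p$etiology <- etiology
  p
}

#' Cohort configuration
#'
#' @param n_per_gos Patient counts for GOS 1..5; the default mirrors a
#'   typical ICU coma cohort skewed toward poor outcome
#'   (39/20/10/7/5, 81 patients, 22 favorable / 59 unfavorable).
#' @param duration_min Recording duration per patient in minutes (default 30,
#'   the montage's standard monitoring duration).
#' @param fs Sampling rate in Hz (default 250).
#' @param master_seed Master seed; all per-patient seeds derive from it.
#' @param etiologies Etiology labels.
#' @param etiology_prob_favorable,etiology_prob_unfavorable Sampling weights
#'   of the etiologies per outcome class (defaults follow the reference
#'   cohort's marginals: hemorrhagic/ischemic stroke, TBI, post-cardiac
#'   arrest, other).
#' @return List of class `fp_cohort_config`.
#' @export
cohort_config <- function(n_per_gos = c(39, 20, 10, 7, 5),
                          duration_min = 30, fs = 250, master_seed = 1,
                          etiologies = c("hemorrhagic_stroke", "ischemic_stroke",
                                         "tbi", "post_cardiac_arrest", "other"),
                          etiology_prob_favorable = c(6, 0, 11, 1, 4),
                          etiology_prob_unfavorable = c(19, 4, 22, 9, 5)) {
  stopifnot(length(n_per_gos) == 5, sum(n_per_gos) >= 6, duration_min >= 2)
  structure(
    list(n_per_gos = n_per_gos, duration_min = duration_min, fs = fs,
         master_seed = master_seed, etiologies = etiologies,
         etiology_prob_favorable = etiology_prob_favorable,
         etiology_prob_unfavorable = etiology_prob_unfavorable),
    class = "fp_cohort_config"
  )
}

#' Generate a labelled synthetic cohort
#'
#' Draws per-patient profiles around the outcome-class defaults
#' ([class_profile()]) with within-class variability, generates each
#' four-channel recording, and assembles the metadata table (age, sex,
#' etiology, GCS, 60-day GOS). Fully reproducible from the master seed.
#'
#' @param config An [cohort_config()].
#' @param inject_artifact_in Optional integer vector of patient indices whose
#'   recordings receive a high-amplitude artifact epoch.
#' @return List of class `fp_cohort`: `recordings` (list of `fp_recording`)
#'   and `metadata` (tibble with `subject_id`, `age`, `sex`, `etiology`,
#'   `gcs`, `gos`, `outcome`).
#' @export
gen_cohort <- function(config = cohort_config(), inject_artifact_in = integer(0)) {
  stopifnot(inherits(config, "fp_cohort_config"))
  gos <- rep(1:5, times = config$n_per_gos)
  n <- length(gos)
  seeds <- derive_seeds(config$master_seed, 3 * n)
  outcome <- dichotomize_outcome(gos)

  meta <- vector("list", n)
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    fav <- outcome[i] == "favorable"
    probs <- if (fav) config$etiology_prob_favorable else config$etiology_prob_unfavorable
    etio <- sample(config$etiologies, 1, prob = probs)
    age <- round(min(90, max(18, rnorm(1, 49.3, 17.9))))
    sex <- sample(c("female", "male"), 1, prob = c(0.25, 0.75))
    gcs <- sample(3:7, 1, prob = c(0.45, 0.2, 0.15, 0.1, 0.1))
    prof <- individual_profile(class_profile(as.character(outcome[i])),
                               gos[i], etio, seeds[n + i])
    sid <- sprintf("sub%03d", i)
    recs[[i]] <- gen_coupled_recording(
      prof, duration_s = config$duration_min * 60, fs = config$fs,
      subject_id = sid, seed = seeds[2 * n + i],
      inject_artifact = i %in% inject_artifact_in
    )
    meta[[i]] <- tibble::tibble(subject_id = sid, age = age, sex = sex,
                                etiology = etio, gcs = gcs, gos = gos[i])
  }
  metadata <- dplyr::bind_rows(meta)
  metadata$outcome <- outcome
  structure(list(recordings = recs, metadata = metadata), class = "fp_cohort")
}

#' Feature table for a whole cohort
#'
#' Runs preprocessing and feature extraction for every recording and joins
#' the aggregated 48-feature rows with the cohort metadata.
#'
#' @param cohort An `fp_cohort` from [gen_cohort()].
#' @param ... Passed to [patient_features()].
#' @return Tibble: metadata columns plus the 48 features and `n_epochs_used`.
#' @export
cohort_features <- function(cohort, ...) {
  stopifnot(inherits(cohort, "fp_cohort"))
  feats <- purrr::map_dfr(cohort$recordings, patient_features, ...)
  dplyr::left_join(cohort$metadata, feats, by = "subject_id")
}
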