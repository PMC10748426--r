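# Preprocessing: recording containers, epoching, baseline calibration,
# zero-phase bandpass filtering and amplitude-based artifact rejection.

#' Construct a recording object
#'
#' A recording bundles a samples-by-channels matrix in microvolts with its
#' channel labels and sampling rate. The four frontoparietal channels
#' F3, F4, P3, P4 (referenced to Cz) must all be present; they are reordered
#' to that canonical order and extra channels are dropped.
#'
#' @param data Numeric matrix, samples in rows, channels in columns, in uV.
#' @param channels Channel labels for the columns of `data`.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param min_duration_min Minimum expected duration in minutes; shorter
#'   recordings are accepted with a warning (default 30, the montage's
#'   standard monitoring duration).
#' @return An object of class `fp_recording`.
#' @export
new_recording <- function(data, channels, fs, subject_id = "subject",
                          min_duration_min = 30) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (length(channels) != ncol(data)) {
    stop("length(channels) must equal ncol(data)")
  }
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) stop("fs must be a positive scalar")
  missing <- setdiff(FP_CHANNELS, channels)
  if (length(missing)) {
    stop("required channel(s) missing: ", paste(missing, collapse = ", "))
  }
  data <- data[, match(FP_CHANNELS, channels), drop = FALSE]
  colnames(data) <- FP_CHANNELS
  dur_min <- nrow(data) / fs / 60
  if (dur_min < min_duration_min) {
    warning(sprintf("recording '%s' lasts %.2f min (< %g min minimum)",
                    subject_id, dur_min, min_duration_min))
  }
  structure(
    list(subject_id = subject_id, channels = FP_CHANNELS, data = data, fs = fs),
    class = "fp_recording"
  )
}

#' @export
print.fp_recording <- function(x, ...) {
  cat(sprintf("<fp_recording> %s: %d channels (%s), fs = %g Hz, %.1f min\n",
              x$subject_id, length(x$channels),
              paste(x$channels, collapse = ", "),
              x$fs, nrow(x$data) / x$fs / 60))
  invisible(x)
}

#' Load a recording from EDF or delimited text
#'
#' Delimited text files are headerless numeric tables; channel order, sampling
#' rate and unit scale come from a sidecar config (a YAML/list with fields
#' `channels`, `fs` and optionally `unit_scale`, a factor converting stored
#' values to uV). EDF files carry their own header. A `channel_map` renames
#' nonstandard labels (e.g. `c("EEG F3-Cz" = "F3")`) before the required
#' frontoparietal set is checked.
#'
#' @param path Path to the recording file.
#' @param format `"edf"`, `"csv"`, or `"auto"` (by file extension).
#' @param config For csv input: a list or path to a YAML file with `channels`,
#'   `fs`, and optional `unit_scale` and `sep`. For EDF input, optional.
#' @param channel_map Named character vector mapping file labels to canonical
#'   labels.
#' @param subject_id Subject identifier; defaults to the file stem (EDF files
#'   use their embedded patient field).
#' @param min_duration_min See [new_recording()].
#' @return An `fp_recording`.
#' @export
load_recording <- function(path, format = c("auto", "edf", "csv"),
                           config = NULL, channel_map = NULL,
                           subject_id = NULL, min_duration_min = 30) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  }
  if (is.character(config)) config <- yaml::read_yaml(config)

  if (format == "edf") {
    raw <- read_edf(path)
    channels <- raw$channels
    data <- raw$data
    fs <- raw$fs
    units <- trimws(raw$units)
    bad <- !(tolower(units) %in% c("uv", "µv", ""))
    if (any(bad)) {
      scale <- config$unit_scale
      if (is.null(scale)) {
        stop("EDF declares non-uV unit (", paste(unique(units[bad]), collapse = ", "),
             ") and no unit_scale conversion factor was supplied")
      }
      data[, bad] <- data[, bad] * scale
    }
    if (is.null(subject_id)) {
      subject_id <- if (nzchar(raw$subject_id)) raw$subject_id else sub("\\.[^.]+$", "", basename(path))
    }
  } else {
    if (is.null(config) || is.null(config$channels) || is.null(config$fs)) {
      stop("csv input needs a sidecar config with 'channels' and 'fs'")
    }
    sep <- config$sep %||% ","
    data <- as.matrix(utils::read.table(path, sep = sep, header = isTRUE(config$header)))
    storage.mode(data) <- "double"
    channels <- as.character(config$channels)
    if (length(channels) != ncol(data)) {
      stop("config lists ", length(channels), " channels but file has ",
           ncol(data), " columns")
    }
    fs <- config$fs
    unit <- config$unit %||% "uV"
    scale <- config$unit_scale
    if (!tolower(unit) %in% c("uv", "µv") && is.null(scale)) {
      stop("config declares non-uV unit '", unit,
           "' without a unit_scale conversion factor")
    }
    if (!is.null(scale)) data <- data * scale
    if (is.null(subject_id)) subject_id <- sub("\\.[^.]+$", "", basename(path))
  }

  if (!is.null(channel_map)) {
    hit <- channels %in% names(channel_map)
    channels[hit] <- unname(channel_map[channels[hit]])
  }
  rec <- new_recording(data, channels, fs, subject_id,
                       min_duration_min = min_duration_min)
  message(sprintf("loaded %s: fs = %g Hz, duration = %.2f min",
                  rec$subject_id, rec$fs, nrow(rec$data) / rec$fs / 60))
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Partition a recording into fixed-length epochs
#'
#' Cuts the recording into contiguous non-overlapping windows of `epoch_s`
#' seconds starting at the first sample; any trailing remainder shorter than
#' one epoch is discarded.
#'
#' @param rec An `fp_recording`.
#' @param epoch_s Epoch length in seconds (default 120, i.e. 2 minutes).
#' @return A tibble with one row per epoch: `subject_id`, `epoch` (0-based
#'   index), `fs`, `data` (list column of samples-by-channels matrices),
#'   `qc_status`, `qc_reason`.
#' @export
partition_epochs <- function(rec, epoch_s = 120) {
  stopifnot(inherits(rec, "fp_recording"))
  len <- round(rec$fs * epoch_s)
  n_total <- nrow(rec$data)
  if (n_total < len) {
    stop(sprintf("recording duration (%.1f s) is shorter than one epoch (%g s)",
                 n_total / rec$fs, epoch_s))
  }
  n_epochs <- floor(n_total / len)
  mats <- lapply(seq_len(n_epochs) - 1L, function(i) {
    rec$data[(i * len + 1):((i + 1) * len), , drop = FALSE]
  })
  tibble::tibble(
    subject_id = rec$subject_id,
    epoch = seq_len(n_epochs) - 1L,
    fs = rec$fs,
    data = mats,
    qc_status = "retained",
    qc_reason = ""
  )
}

#' Baseline-calibrate epochs
#'
#' Removes the per-channel mean of each epoch, giving every channel exactly
#' zero mean over the window. Idempotent.
#'
#' @param epochs Epoch tibble from [partition_epochs()], or a bare numeric
#'   matrix (samples x channels).
#' @return The same structure with demeaned samples.
#' @export
baseline_calibrate <- function(epochs) {
  demean <- function(m) sweep(m, 2, colMeans(m))
  if (is.matrix(epochs)) return(demean(epochs))
  epochs$data <- lapply(epochs$data, demean)
  epochs
}

#' Zero-phase Butterworth bandpass for one channel
#'
#' Applies a Butterworth bandpass forward and backward (zero phase; effective
#' attenuation twice the single-pass order). Edge transients are suppressed by
#' odd-reflection padding of one filter-settling length at both ends.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz (defaults 0.1 and 40).
#' @param order Single-pass filter order (default 4).
#' @return Filtered vector, same length as `x`.
#' @export
zero_phase_bandpass <- function(x, fs, lo = 0.1, hi = 40, order = 4) {
  if (!(lo > 0 && lo < hi)) stop("need 0 < lo < hi")
  if (hi >= fs / 2) stop("upper edge ", hi, " Hz is at or above Nyquist (", fs / 2, " Hz)")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  n <- length(x)
  # settling length ~ 3 periods of the slowest passband component
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / lo)))
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(bf, xp)
  y <- rev(signal::filter(bf, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Bandpass-filter epochs
#'
#' Per-channel zero-phase Butterworth bandpass (see [zero_phase_bandpass()]),
#' default 0.1-40 Hz, order 4.
#'
#' @inheritParams zero_phase_bandpass
#' @param epochs Epoch tibble (or a bare matrix plus `fs`).
#' @param fs Sampling rate; taken from the epoch table when absent.
#' @return Filtered epochs in the same structure.
#' @export
bandpass_filter <- function(epochs, lo = 0.1, hi = 40, order = 4, fs = NULL) {
  flt <- function(m, fs) apply(m, 2, zero_phase_bandpass, fs = fs,
                               lo = lo, hi = hi, order = order)
  if (is.matrix(epochs)) {
    if (is.null(fs)) stop("fs required when filtering a bare matrix")
    return(flt(epochs, fs))
  }
  epochs$data <- purrr::map2(epochs$data, epochs$fs, flt)
  epochs
}

#' Reject artifacted epochs by amplitude threshold
#'
#' An epoch is rejected iff any channel contains any sample whose absolute
#' value exceeds `amp_thresh` uV (movement/electrode artifacts). The QC log
#' records every epoch's decision and, for rejections, the first offending
#' channel and sample.
#'
#' @param epochs Epoch tibble (calibrated and filtered).
#' @param amp_thresh Rejection threshold in uV (default 200).
#' @return A list with `retained` (epoch tibble of surviving epochs) and
#'   `qc` (tibble: `subject_id`, `epoch`, `status`, `reason`). Errors if no
#'   epoch survives.
#' @export
reject_artifacts <- function(epochs, amp_thresh = 200) {
  decide <- function(m) {
    absmax <- apply(abs(m), 2, max)
    bad <- which(absmax > amp_thresh)
    if (!length(bad)) return("")
    ch <- colnames(m)[bad[1]] %||% as.character(bad[1])
    smp <- which.max(abs(m[, bad[1]]))
    sprintf("|amplitude| %.1f uV > %g uV on %s at sample %d",
            absmax[bad[1]], amp_thresh, ch, smp)
  }
  reasons <- vapply(epochs$data, decide, "")
  epochs$qc_status <- ifelse(reasons == "", "retained", "rejected")
  epochs$qc_reason <- reasons
  qc <- tibble::tibble(
    subject_id = epochs$subject_id,
    epoch = epochs$epoch,
    status = epochs$qc_status,
    reason = epochs$qc_reason
  )
  retained <- epochs[epochs$qc_status == "retained", , drop = FALSE]
  if (nrow(retained) == 0) {
    stop(sprintf("all %d epochs rejected for subject %s; no features computable",
                 nrow(epochs), epochs$subject_id[1]))
  }
  list(retained = retained, qc = qc)
}

#' Full preprocessing chain for one recording
#'
#' Partition into 2-minute epochs, baseline-calibrate, zero-phase bandpass
#' (0.1-40 Hz, order 4), then amplitude-based rejection, in that order.
#'
#' @param rec An `fp_recording`.
#' @param epoch_s Epoch length in seconds.
#' @param lo,hi,order Filter settings, see [zero_phase_bandpass()].
#' @param amp_thresh Rejection threshold in uV.
#' @return A list with `epochs` (retained epoch tibble) and `qc` (QC log).
#' @export
preprocess_recording <- function(rec, epoch_s = 120, lo = 0.1, hi = 40,
                                 order = 4, amp_thresh = 200) {
  epochs <- partition_epochs(rec, epoch_s)
  epochs <- baseline_calibrate(epochs)
  epochs <- bandpass_filter(epochs, lo = lo, hi = hi, order = order)
  out <- reject_artifacts(epochs, amp_thresh)
  list(epochs = out$retained, qc = out$qc)
}
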