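# Minimal EDF (European Data Format) I/O: 16-bit integer samples, standard
# 256-byte header plus 256 bytes per signal, 1-second data records. Enough to
# round-trip the four-channel recordings this package works with.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled to the signal's physical range and quantised to 16-bit
#' integers, so values round-trip to within one quantisation step. The
#' recording is truncated to a whole number of 1-second data records.
#'
#' @param rec A recording object from [new_recording()] or [load_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "fp_recording"))
  fs <- rec$fs
  stopifnot(fs == round(fs))
  ns <- length(rec$channels)
  n_rec <- floor(nrow(rec$data) / fs)
  stopifnot(n_rec >= 1)
  x <- rec$data[seq_len(n_rec * fs), , drop = FALSE]

  phys_max <- max(1, ceiling(max(abs(x))))
  dig_max <- 32767L
  dig_min <- -32768L
  scale <- (dig_max - dig_min) / (2 * phys_max)
  digital <- round((x + phys_max) * scale) + dig_min
  digital[digital > dig_max] <- dig_max
  digital[digital < dig_min] <- dig_min

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr("fpqeeg", 80)
  wr("01.01.20", 8)
  wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1, 8)
  wr(ns, 4)
  for (ch in rec$channels) wr(ch, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(-phys_max, 8)
  for (i in seq_len(ns)) wr(phys_max, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  # data records: per record, all samples of signal 1, then signal 2, ...
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- as.integer(digital[idx, ])
    writeBin(block, con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Parses the standard EDF header and 16-bit data records, rescaling to
#' physical units. All signals must share one sampling rate.
#'
#' @param path EDF file path.
#' @return A list with `channels`, `data` (samples x channels matrix in the
#'   file's physical units), `fs`, and `subject_id`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("EDF file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    out <- readChar(con, w, useBytes = TRUE)
    if (length(out) == 0 || nchar(out, type = "bytes") < w) stop("unreadable EDF header")
    trimws(out)
  }
  rd(8)                      # version
  subject_id <- rd(80)
  rd(80); rd(8); rd(8)
  header_bytes <- as.numeric(rd(8))
  rd(44)
  n_rec <- as.numeric(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.numeric(rd(4))
  if (!is.finite(ns) || ns < 1 || !is.finite(n_rec) || n_rec < 1 ||
      !is.finite(rec_dur) || rec_dur <= 0) {
    stop("unreadable EDF header")
  }
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)            # transducer
  units <- vapply(seq_len(ns), function(i) rd(8), "")
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)            # prefilter
  spr <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr))) stop("unreadable EDF header")
  if (length(unique(spr / rec_dur)) != 1) {
    stop("EDF signals have differing sampling rates; not supported")
  }
  seek(con, header_bytes)
  fs <- spr[1] / rec_dur
  data <- matrix(NA_real_, nrow = n_rec * spr[1], ncol = ns)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2,
                     endian = "little", signed = TRUE)
      if (length(raw) < spr[s]) stop("truncated EDF data record")
      rows <- ((r - 1) * spr[s] + 1):(r * spr[s])
      data[rows, s] <- phys_min[s] + (raw - dig_min[s]) * gain[s]
    }
  }
  colnames(data) <- labels
  list(channels = labels, data = data, fs = fs,
       subject_id = subject_id, units = units)
}
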