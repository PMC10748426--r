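# Recording I/O, epoching, calibration, zero-phase filtering, QC rejection.

test_that("csv loading reads back the written signal and honours the sidecar config", {
  dir <- withr::local_tempdir()
  fs <- 50
  mat <- matrix(round(rnorm(4 * fs * 130), 4), ncol = 4)
  path <- file.path(dir, "rec.csv")
  utils::write.table(mat, path, sep = ",", row.names = FALSE, col.names = FALSE)
  cfg <- list(channels = c("F3", "F4", "P3", "P4"), fs = fs)
  rec <- suppressWarnings(suppressMessages(
    load_recording(path, format = "csv", config = cfg, min_duration_min = 0)
  ))
  expect_s3_class(rec, "fp_recording")
  expect_equal(rec$fs, fs)
  expect_equal(rec$channels, c("F3", "F4", "P3", "P4"))
  expect_equal(unname(rec$data), unname(mat), tolerance = 1e-12)

  # channel aliasing resolves nonstandard labels
  cfg2 <- list(channels = c("EEG F3-Cz", "F4", "P3", "P4"), fs = fs)
  rec2 <- suppressWarnings(suppressMessages(
    load_recording(path, format = "csv", config = cfg2,
                   channel_map = c("EEG F3-Cz" = "F3"), min_duration_min = 0)
  ))
  expect_equal(rec2$data[, "F3"], rec$data[, "F3"])

  # a missing required channel is named in the error
  cfg3 <- list(channels = c("F3", "F4", "P3", "O1"), fs = fs)
  expect_error(
    suppressWarnings(suppressMessages(
      load_recording(path, format = "csv", config = cfg3, min_duration_min = 0)
    )),
    "P4"
  )

  # non-uV unit without a conversion factor is fatal; with one, it scales
  cfg4 <- list(channels = c("F3", "F4", "P3", "P4"), fs = fs, unit = "mV")
  expect_error(
    suppressMessages(load_recording(path, format = "csv", config = cfg4,
                                    min_duration_min = 0)),
    "unit_scale"
  )
  cfg5 <- c(cfg4, list(unit_scale = 1000))
  rec5 <- suppressWarnings(suppressMessages(
    load_recording(path, format = "csv", config = cfg5, min_duration_min = 0)
  ))
  expect_equal(rec5$data[, 1], rec$data[, 1] * 1000)
})

test_that("short recordings warn under the minimum-duration rule", {
  mat <- matrix(rnorm(4 * 100), ncol = 4,
                dimnames = list(NULL, c("F3", "F4", "P3", "P4")))
  expect_warning(new_recording(mat, colnames(mat), fs = 10), "min")
  expect_silent(new_recording(mat, colnames(mat), fs = 10, min_duration_min = 0))
})

test_that("epoch partitioning is contiguous, non-overlapping, remainder-dropping", {
  fs <- 20
  mk <- function(minutes) {
    make_recording(matrix(seq_len(4 * fs * 60 * minutes), ncol = 4,
                          dimnames = list(NULL, c("F3", "F4", "P3", "P4"))), fs)
  }
  ep30 <- partition_epochs(mk(30))
  expect_equal(nrow(ep30), 15)
  ep31 <- partition_epochs(mk(31))
  expect_equal(nrow(ep31), 15)  # 60 s remainder dropped
  expect_true(all(vapply(ep30$data, nrow, integer(1)) == fs * 120))
  # contiguity: epoch k starts right after epoch k-1
  expect_equal(unname(ep30$data[[2]][1, 1]), unname(ep30$data[[1]][fs * 120, 1]) + 1)
  expect_equal(unname(ep30$data[[1]][1, 1]), 1)  # starts at sample 0

  short <- make_recording(matrix(rnorm(4 * fs * 119), ncol = 4,
                                 dimnames = list(NULL, c("F3", "F4", "P3", "P4"))), fs)
  expect_error(partition_epochs(short), "shorter")
})

test_that("baseline calibration removes the mean exactly and is idempotent", {
  m <- cbind(F3 = rep(7, 100), F4 = sin(1:100) + 3,
             P3 = rnorm(100), P4 = rnorm(100) - 5)
  cal <- baseline_calibrate(m)
  expect_equal(unname(colMeans(cal)), rep(0, 4), tolerance = 1e-12)
  expect_equal(cal[, "F3"], setNames(rep(0, 100), NULL) , ignore_attr = TRUE)
  expect_equal(cal[, "F4"], m[, "F4"] - mean(m[, "F4"]))
  expect_equal(baseline_calibrate(cal), cal, tolerance = 1e-12)
})

test_that("zero-phase bandpass passes the band, rejects outside, adds no delay", {
  # epoch-length fixtures: the 0.1 Hz edge needs seconds to settle, so gains
  # are measured away from the window ends
  fs <- 250
  t10 <- sine_epoch(10, fs, 120)
  y10 <- zero_phase_bandpass(t10, fs)
  mid <- (20 * fs):(100 * fs)
  gain10 <- max(abs(y10[mid])) / max(abs(t10[mid]))
  expect_gt(gain10, 0.99)
  expect_lt(gain10, 1.01)

  t60 <- sine_epoch(60, fs, 120)
  y60 <- zero_phase_bandpass(t60, fs)
  expect_lt(max(abs(y60[mid])), 0.05)

  # zero phase: input/output cross-correlation peaks at lag 0
  set.seed(42)
  x <- rnorm(4 * fs)
  y <- zero_phase_bandpass(x, fs, lo = 1, hi = 30)
  cc <- stats::ccf(y, x, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  # linearity
  ya <- zero_phase_bandpass(3.7 * x, fs, lo = 1, hi = 30)
  expect_equal(ya, 3.7 * y, tolerance = 1e-8)

  expect_error(zero_phase_bandpass(x, fs, hi = 125), "Nyquist")
})

test_that("artifact rejection applies the amplitude rule and conserves epochs", {
  fs <- 50
  chn <- c("F3", "F4", "P3", "P4")
  clean <- matrix(rnorm(4 * fs * 120 * 10, sd = 20), ncol = 4,
                  dimnames = list(NULL, chn))
  rec <- make_recording(clean, fs)
  ep <- partition_epochs(rec)
  # corrupt epoch 3 on F3 with one 250 uV sample
  ep$data[[3]][17, "F3"] <- 250
  out <- reject_artifacts(ep)
  expect_equal(nrow(out$retained) + sum(out$qc$status == "rejected"), nrow(ep))
  expect_equal(out$qc$status[3], "rejected")
  expect_match(out$qc$reason[3], "F3")
  expect_false(2L %in% out$retained$epoch)

  # boundary: 199 uV is retained
  ep$data[[3]][17, "F3"] <- 199
  out2 <- reject_artifacts(ep)
  expect_equal(nrow(out2$retained), nrow(ep))
  expect_true(all(out2$qc$reason == ""))

  # all epochs rejected is fatal
  ep_bad <- ep
  ep_bad$data <- lapply(ep_bad$data, function(m) m + 500)
  expect_error(reject_artifacts(ep_bad), "all .* rejected|no features")
})

test_that("the preprocessing chain runs calibrate-filter-reject end to end", {
  fs <- 100
  chn <- c("F3", "F4", "P3", "P4")
  mat <- matrix(rnorm(4 * fs * 60 * 6, sd = 15) + 10, ncol = 4,
                dimnames = list(NULL, chn))
  rec <- make_recording(mat, fs)
  pp <- preprocess_recording(rec)
  expect_equal(nrow(pp$epochs), 3)
  for (m in pp$epochs$data) {
    expect_lt(max(abs(colMeans(m))), 0.5)  # offsets removed (up to filter edge effects)
    expect_true(all(abs(m) <= 200))
  }
  expect_equal(nrow(pp$qc), 3)
})
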