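test_that("raw_f32 container round-trips bit-exactly", {
  rec <- recording(matrix(round(rnorm(2000), 4), ncol = 2), fs = 1000,
                   channel_ids = c("a", "b"), t0 = 1.5)
  # float32 representable values so the round-trip is bit-exact
  rec$data <- matrix(as.numeric(readBin(writeBin(as.vector(rec$data), raw(),
                                                 size = 4), "double",
                                        n = 2000, size = 4)), ncol = 2,
                     dimnames = list(NULL, c("a", "b")))
  path <- withr::local_tempfile()
  write_recording(rec, path)
  back <- read_recording(path)
  expect_identical(back$data, rec$data)
  expect_equal(back$fs, 1000)
  expect_equal(back$channel_ids, c("a", "b"))
  expect_equal(back$t0, 1.5)
})

test_that("malformed raw_f32 inputs raise distinct error kinds", {
  rec <- recording(matrix(rnorm(300), ncol = 3), fs = 100)
  path <- withr::local_tempfile()
  write_recording(rec, path)
  # sidecar declares 2 channels but the file holds 3
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$n_channels <- 2
  meta$channel_ids <- meta$channel_ids[1:2]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_recording(path), class = "neurowire_error_channel_mismatch")
  file.remove(paste0(path, ".json"))
  expect_error(read_recording(path), class = "neurowire_error_missing_sidecar")
})

test_that("EDF round-trip preserves fs and data to 16-bit quantization", {
  tt <- (0:999) / 250
  rec <- recording(cbind(50 * sin(2 * pi * 7 * tt), 20 * cos(2 * pi * 3 * tt)),
                   fs = 250)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_recording(path, format = "edf")
  expect_equal(back$fs, 250)
  rng <- diff(range(rec$data))
  expect_lt(max(abs(back$data[1:1000, ] - rec$data)), rng / 2^15)
})

test_that("notch and band filters attenuate per design", {
  fs <- 1000
  tt <- (0:9999) / fs
  line <- sin(2 * pi * 60 * tt)
  out <- apply_filter(recording(line, fs), filter_spec("notch", 60))
  expect_lt(sd(out$data), 0.05 * sd(line))
  # DC removal by 1-Hz high-pass
  dc <- apply_filter(recording(rnorm(4000) + 5, fs = 386),
                     filter_spec("highpass", 1, order = 8))
  expect_lt(abs(mean(dc$data)), 0.05)
  # out-of-band sine through a spike-band bandpass
  low <- sin(2 * pi * 10 * tt)
  bp <- apply_filter(recording(low, fs), filter_spec("bandpass", c(300, 450),
                                                     order = 8))
  expect_lt(sd(bp$data), 0.01 * sd(low))
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- sine_recording()
  expect_error(apply_filter(rec, filter_spec("highpass", 600)),
               class = "neurowire_error_bad_filter")
  expect_error(filter_spec("bandpass", c(100, 50)),
               class = "neurowire_error_bad_filter")
})

test_that("filtering is linear", {
  fs <- 500
  x <- rnorm(2000)
  y <- rnorm(2000)
  spec <- filter_spec("bandpass", c(5, 40), order = 4)
  fx <- apply_filter(recording(x, fs), spec)$data[, 1]
  fy <- apply_filter(recording(y, fs), spec)$data[, 1]
  fxy <- apply_filter(recording(2 * x - 3 * y, fs), spec)$data[, 1]
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-9)
})

test_that("resampling follows the length contract and preserves tones", {
  n <- 38600
  tt <- (seq_len(n) - 1) / 38600
  rec <- recording(sin(2 * pi * 5 * tt), fs = 38600)
  down <- resample_recording(rec, 386)
  expect_equal(nrow(down$data), 386)
  ref <- sin(2 * pi * 5 * (seq_len(386) - 1) / 386)
  expect_gt(cor(down$data[, 1], ref), 0.999)
  expect_identical(resample_recording(rec, 38600), rec)
  expect_error(resample_recording(rec, -1), class = "neurowire_error_bad_fs")
})

test_that("z-scoring normalizes per channel and is idempotent", {
  rec <- recording(cbind(rnorm(500, 10, 3), rnorm(500, -2, 0.1)), fs = 100)
  z <- zscore_recording(rec)
  expect_equal(colMeans(z$data), c(0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(apply(z$data, 2, var), c(1, 1), tolerance = 1e-6,
               ignore_attr = TRUE)
  z2 <- zscore_recording(z)
  expect_equal(z2$data, z$data, tolerance = 1e-9)
  const <- recording(cbind(rnorm(100), rep(1, 100)), fs = 10,
                     channel_ids = c("ok", "flat"))
  err <- tryCatch(zscore_recording(const), error = identity)
  expect_s3_class(err, "neurowire_error_constant_channel")
  expect_match(conditionMessage(err), "flat")
})

test_that("event streams validate kinds and ordering and survive CSV", {
  ev <- event_stream(c(1, 2, 3), c("word_onset", "crossing_start", "trigger"),
                     label = c(TRUE, NA, NA))
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(back$time_s, ev$time_s)
  expect_equal(back$kind, ev$kind)
  expect_error(event_stream(c(2, 1), c("trigger", "trigger")),
               class = "neurowire_error_bad_events")
  expect_error(event_stream(1, "unknown_kind"),
               class = "neurowire_error_bad_events")
})
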