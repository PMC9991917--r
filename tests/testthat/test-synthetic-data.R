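test_that("generators are seed-deterministic", {
  a <- gen_microwire(n_channels = 2, fs = 4000, duration_s = 2,
                     units = list(list(rate_hz = 5)), seed = 9)
  b <- gen_microwire(n_channels = 2, fs = 4000, duration_s = 2,
                     units = list(list(rate_hz = 5)), seed = 9)
  expect_identical(a$rec$data, b$rec$data)
  expect_identical(a$truth$unit_spike_times, b$truth$unit_spike_times)
  w1 <- gen_walk_session(n_crossings = 3, n_channels = 2, seed = 4)
  w2 <- gen_walk_session(n_crossings = 3, n_channels = 2, seed = 4)
  expect_identical(w1$rec$data, w2$rec$data)
  s1 <- gen_stim_session(stim_protocol(amplitudes = 0.5, frequencies_hz = 100,
                                       repeats = 1, interburst_s = 0.5),
                         channel_gains = 1, seed = 2)
  s2 <- gen_stim_session(stim_protocol(amplitudes = 0.5, frequencies_hz = 100,
                                       repeats = 1, interburst_s = 0.5),
                         channel_gains = 1, seed = 2)
  expect_identical(s1$rec$data, s2$rec$data)
})

test_that("spike counts follow the Poisson rate", {
  mw <- gen_microwire(n_channels = 1, fs = 8000, duration_s = 10,
                      units = list(list(rate_hz = 10, amplitude = 60)),
                      seed = 11)
  n <- length(mw$truth$unit_spike_times[[1]])
  expect_gt(n, 100 - 3 * sqrt(100))
  expect_lt(n, 100 + 3 * sqrt(100))
  expect_error(gen_microwire(units = list(list(rate_hz = 0)), duration_s = 1,
                             n_channels = 1, fs = 4000),
               class = "neurowire_error_bad_config")
})

test_that("line_amp controls the 55-65-Hz band", {
  base <- gen_microwire(n_channels = 1, fs = 2000, duration_s = 10,
                        line_amp = 0, units = list(), seed = 3)
  lined <- gen_microwire(n_channels = 1, fs = 2000, duration_s = 10,
                         line_amp = 20, units = list(), seed = 3)
  p0 <- power_60hz(base$rec$data[, 1], 2000, fs_target = 2000)
  p1 <- power_60hz(lined$rec$data[, 1], 2000, fs_target = 2000)
  expect_gt(p1, 10 * p0)
})

test_that("motion-artifact injection books its ground truth", {
  base <- gen_microwire(n_channels = 3, fs = 4000, duration_s = 60,
                        units = list(), seed = 6)
  art <- inject_motion_artifacts(base$rec, n_sharp = 20, slow_amp = 0,
                                 seed = 7)
  sharp <- art$truth$artifact_intervals[
    art$truth$artifact_intervals$kind == "sharp", ]
  expect_equal(nrow(sharp), 20)
  # identity when nothing is injected
  none <- inject_motion_artifacts(base$rec, n_sharp = 0, slow_amp = 0)
  expect_identical(none$rec$data, base$rec$data)
})

test_that("injected slow drift is confined below its band limit", {
  base <- gen_microwire(n_channels = 1, fs = 1000, duration_s = 30,
                        units = list(), seed = 8)
  art <- inject_motion_artifacts(base$rec, n_sharp = 0, slow_amp = 50,
                                 slow_band_hz = 1, seed = 9)
  drift <- art$rec$data[, 1] - base$rec$data[, 1]
  ps <- fft_power(drift, 1000)
  below <- sum(ps$power[ps$freq_hz < 1])
  expect_gt(below / sum(ps$power), 0.99)
})

test_that("walk sessions emit paired crossing events with a boundary effect", {
  ws <- gen_walk_session(n_crossings = 10, n_channels = 2,
                         boundary_gain = 2, seed = 5)
  expect_equal(sum(ws$events$kind == "crossing_start"), 10)
  expect_equal(sum(ws$events$kind == "crossing_end"), 10)
  # theta bandpower higher in the boundary third by construction
  bp <- recording_bandpower(ws$rec, c(3, 12))
  split <- split_crossings(ws$events)
  n <- nrow(bp)
  ii <- neurowire:::interval_samples(split$t_a, split$t_b, ws$rec$fs, n)
  bi <- neurowire:::interval_samples(split$t_b, split$t_end, ws$rec$fs, n)
  expect_gt(mean(bp[bi, ]), mean(bp[ii, ]))
})

test_that("memory sessions carry labeled onsets with the stated counts", {
  ms <- gen_memory_session(n_blocks = 9, words_per_block = 10, seed = 3)
  on <- ms$events[ms$events$kind == "word_onset", ]
  expect_equal(nrow(on), 90)
  expect_true(all(!is.na(on$label)))
  expect_equal(length(ms$truth$block), 90)
  expect_equal(unname(table(ms$truth$block)[1]), 10)
})

test_that("stim sessions render the full default grid", {
  p <- stim_protocol()
  sched <- schedule_bursts(p)
  expect_equal(nrow(sched), 100)
  expect_true(all(vapply(sched$pulse_times_s, length, 0L) == 10))
  # all-zero gains leave pure noise
  sml <- stim_protocol(amplitudes = 1, frequencies_hz = 100, repeats = 1,
                       interburst_s = 0.2)
  sess <- gen_stim_session(sml, channel_gains = 0, noise_sd = 1, seed = 4)
  expect_lt(max(abs(sess$rec$data)), 6)   # gaussian range, no pulses
})
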