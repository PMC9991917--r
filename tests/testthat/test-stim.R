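test_that("burst scheduling obeys the count law and pulse spacing", {
  p <- stim_protocol()
  sched <- schedule_bursts(p)
  expect_equal(nrow(sched), length(p$amplitudes) * length(p$frequencies_hz) *
                 p$repeats)
  expect_equal(nrow(sched), 100)
  i100 <- which(sched$frequency_hz == 100)[1]
  expect_equal(diff(sched$pulse_times_s[[i100]])[1], 1 / 100)
  # ten pulses at 60 Hz span (n-1)/f = 150 ms
  i60 <- which(sched$frequency_hz == 60)[1]
  expect_equal(diff(range(sched$pulse_times_s[[i60]])), 9 / 60)
  expect_equal(diff(sched$start_s)[1], p$interburst_s)
  # arbitrary grids follow the same law
  p2 <- stim_protocol(amplitudes = c(1, 2, 3), frequencies_hz = c(50, 80),
                      repeats = 7)
  expect_equal(nrow(schedule_bursts(p2)), 42)
})

test_that("off-grid protocol parameters are rejected by name", {
  err <- tryCatch(stim_protocol(pulse_width_ms = 1.285), error = identity)
  expect_s3_class(err, "neurowire_error_off_grid")
  expect_match(conditionMessage(err), "pulse_width")
  err2 <- tryCatch(stim_protocol(interphase_us = 155), error = identity)
  expect_s3_class(err2, "neurowire_error_off_grid")
  expect_match(conditionMessage(err2), "interphase")
  expect_error(stim_protocol(pulse_width_ms = 2), class =
                 "neurowire_error_off_grid")
})

test_that("rendered pulses are charge balanced and linear in amplitude", {
  w <- render_pulse(amplitude = 2, pulse_width_ms = 1.28,
                    interphase_us = 150, fs = 6250)
  expect_equal(sum(w), 0, tolerance = 1e-9 * max(abs(w)))
  expect_equal(render_pulse(amplitude = 4, fs = 6250), 2 * w / 2 * 2)
  # custom 16-step shape with equal steps degenerates to the rectangle
  cs <- render_pulse(shape = "custom_16_step", amplitude = 1,
                     custom_steps = rep(1, 16), fs = 6250)
  rect <- render_pulse(amplitude = 1, fs = 6250)
  expect_equal(cs, rect)
  expect_equal(sum(cs), 0, tolerance = 1e-12)
})

test_that("template detection recovers every scheduled pulse", {
  p <- stim_protocol(amplitudes = c(0.5, 1), frequencies_hz = c(60, 100),
                     repeats = 2, interburst_s = 0.5)
  sess <- gen_stim_session(p, channel_gains = c(1, 0.4), noise_sd = 2,
                           seed = 2)
  tmpl <- render_pulse(amplitude = 1, fs = 6250)
  det <- detect_pulses(sess$rec, tmpl)
  expect_equal(nrow(det), 2 * 8 * 10)     # channels x bursts x pulses
  sched_times <- sort(unlist(sess$schedule$pulse_times_s))
  ch1 <- sort(det$time_s[det$channel == "ch1"])
  expect_equal(length(ch1), length(sched_times))
  expect_lt(max(abs(ch1 - sched_times)), 1.5 / 6250)  # <= 1 sample off
  # zero-gain channel yields no detections
  sess0 <- gen_stim_session(p, channel_gains = c(1, 0), noise_sd = 2,
                            seed = 3)
  det0 <- detect_pulses(sess0$rec, tmpl)
  expect_equal(sum(det0$channel == "ch2"), 0)
})

test_that("propagation statistics normalize by the largest pulse", {
  p <- stim_protocol(amplitudes = c(0.25, 0.5, 1), frequencies_hz = 100,
                     repeats = 2, interburst_s = 0.5)
  sess <- gen_stim_session(p, channel_gains = c(1, 0.5), noise_sd = 0,
                           seed = 4)
  det <- detect_pulses(sess$rec, render_pulse(amplitude = 1, fs = 6250))
  expect_equal(max(det$norm_power), 1)
  st <- propagation_stats(det, sess$schedule)
  # noiseless identical pulses: zero within-condition SD
  expect_lt(max(st$sd_norm_power, na.rm = TRUE), 1e-9)
  top <- st[st$channel == "ch1" & st$amplitude == 1, ]
  expect_equal(top$mean_norm_power, 1, tolerance = 1e-9)
})

test_that("noise makes normalized-power SD fall as amplitude rises", {
  p <- stim_protocol(amplitudes = c(0.25, 1.25), frequencies_hz = 100,
                     repeats = 4, interburst_s = 0.5)
  sess <- gen_stim_session(p, channel_gains = 1, noise_sd = 15, seed = 5)
  det <- detect_pulses(sess$rec, render_pulse(amplitude = 1, fs = 6250),
                       threshold = 0.6)
  st <- propagation_stats(det, sess$schedule)
  lo <- st[st$amplitude == 0.25, ]
  hi <- st[st$amplitude == 1.25, ]
  expect_gt(nrow(lo), 0)
  expect_gt(nrow(hi), 0)
  expect_gt(mean(lo$sd_norm_power / lo$mean_norm_power),
            mean(hi$sd_norm_power / hi$mean_norm_power))
})
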