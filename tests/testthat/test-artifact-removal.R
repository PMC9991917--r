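test_that("slow-transient removal keeps in-band content and kills drift", {
  fs <- 1000
  tt <- (0:29999) / fs
  drift <- 10 * sin(2 * pi * 0.5 * tt)
  tone <- sin(2 * pi * 40 * tt)
  out <- remove_slow_transients(recording(drift + tone, fs), cutoff_hz = 1)
  resid_drift <- out$data[, 1] - tone
  expect_lt(sd(resid_drift), sd(drift) / 10)
  keep <- 5000:25000   # away from filter edge transients
  expect_lt(max(abs(out$data[keep, 1] - tone[keep])), 0.05)
  # pure 10-Hz sine passes nearly unchanged
  tone10 <- sin(2 * pi * 10 * tt)
  out10 <- remove_slow_transients(recording(tone10, fs), cutoff_hz = 1)
  expect_equal(sd(out10$data[keep, 1]), sd(tone10[keep]), tolerance = 0.02)
  # zero in, zero out
  z <- remove_slow_transients(recording(numeric(5000), fs))
  expect_equal(max(abs(z$data)), 0)
})

test_that("ICA finds shared sharp transients against ground truth", {
  art <- artifact_session(seed = 5)
  iv <- detect_sharp_transients(art$rec)
  sc <- score_intervals(iv, art$truth$artifact_intervals)
  expect_gte(sc$recall, 0.95)
  expect_gte(sc$precision, 0.9)
  # an absurd threshold yields no intervals
  none <- detect_sharp_transients(art$rec, threshold_sd = 1e6)
  expect_equal(nrow(none), 0)
  expect_error(detect_sharp_transients(art$rec, n_components = 99),
               class = "neurowire_error_bad_config")
})

test_that("interpolation touches only padded intervals and reports ASTR", {
  rec <- recording(cbind(as.numeric(1:100), sin(1:100)), fs = 100)
  iv <- tibble::tibble(start_sample = 50L, end_sample = 59L)
  out <- interpolate_intervals(rec, iv)
  outside <- setdiff(1:100, 50:59)
  expect_identical(out$rec$data[outside, ], rec$data[outside, ])
  # linear ramp: interpolation reproduces the line exactly
  expect_equal(unname(out$rec$data[50:59, 1]), as.numeric(50:59))
  expect_equal(out$report$astr_percent, 10)
  # single interior sample between boundary values 1 and 3 -> midpoint 2
  r3 <- recording(c(1, 5, 3), fs = 10)
  o3 <- interpolate_intervals(r3, tibble::tibble(start_sample = 2L,
                                                 end_sample = 2L))
  expect_equal(unname(o3$rec$data[2, 1]), 2)
  # empty interval list: identity, ASTR 0
  o0 <- interpolate_intervals(rec, tibble::tibble(start_sample = integer(),
                                                  end_sample = integer()))
  expect_identical(o0$rec$data, rec$data)
  expect_equal(o0$report$astr_percent, 0)
})

test_that("ASTR equals the removed fraction exactly", {
  rec <- recording(rnorm(10000), fs = 1000)
  iv <- tibble::tibble(start_sample = c(101L, 5001L),
                       end_sample = c(150L, 5050L))
  out <- interpolate_intervals(rec, iv)
  expect_equal(out$report$astr_percent, 1.0)
  expect_equal(out$report$n_removed, 100L)
})

test_that("shared artifacts give near-identical per-channel ASTR", {
  art <- artifact_session(seed = 12)
  iv <- detect_sharp_transients(art$rec)
  # intervals come from one shared component, so ASTR is common to all
  # channels by construction; verify the removal bookkeeping agrees with
  # the padded interval mass
  out <- interpolate_intervals(art$rec, iv)
  manual <- sum(iv$end_sample - iv$start_sample + 1L)
  expect_equal(out$report$n_removed, manual)
})
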