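test_that("detection recovers injected units and rejects pure noise", {
  mw <- spike_session(seed = 3)
  det <- detect_spikes(mw$rec, threshold_sd = 5)
  tt <- mw$truth$unit_spike_times[[1]]
  dt <- det$channels[[1]]$times_s
  recall <- mean(vapply(tt, function(t) any(abs(dt - t) < 5e-4), logical(1)))
  expect_gte(recall, 0.9)
  # pure noise at 5 SD: < 0.5 false detections per second
  noise <- gen_microwire(n_channels = 1, fs = 8000, duration_s = 20,
                         units = list(), seed = 4)
  dn <- detect_spikes(noise$rec, threshold_sd = 5)
  expect_lt(length(dn$channels[[1]]$times_s) / 20, 0.5)
  # zero signal: zero detections
  z <- detect_spikes(recording(numeric(8000), fs = 8000))
  expect_equal(length(z$channels[[1]]$times_s), 0)
})

test_that("clustering separates distinct templates deterministically", {
  mw <- gen_microwire(
    n_channels = 1, fs = 8000, duration_s = 40,
    units = list(list(template = 1, rate_hz = 8, amplitude = 80, channel = 1),
                 list(template = 3, rate_hz = 8, amplitude = 40, channel = 1)),
    seed = 21)
  det <- detect_spikes(mw$rec, threshold_sd = 4)
  cl <- cluster_spikes(det, seed = 1)
  cl2 <- cluster_spikes(det, seed = 1)
  expect_equal(length(cl), length(cl2))
  expect_identical(cl[[1]]$spike_times_s, cl2[[1]]$spike_times_s)
  big <- cl[order(-vapply(cl, function(u) length(u$spike_times_s), 0))][1:2]
  # reference waveforms: templates through the same 300-3,000-Hz filter,
  # windowed around the filtered peak like detected snippets
  filt_tmpl <- function(shape, amp, fs = 8000, L = 12) {
    tm <- neurowire:::spike_template(shape, fs) * amp
    xf <- neurowire:::filter_vector(
      c(numeric(400), tm, numeric(400)),
      neurowire:::design_filter(filter_spec("bandpass", c(300, 3000),
                                            order = 4), fs))
    pk <- which.max(abs(xf))
    xf[(pk - L %/% 2):(pk - L %/% 2 + L - 1)]
  }
  refs <- list(filt_tmpl(1, 80), filt_tmpl(3, 40))
  cors <- t(vapply(big, function(u)
    c(cor(u$mean_waveform, refs[[1]]), cor(u$mean_waveform, refs[[2]])),
    numeric(2)))
  # each major cluster matches its own template nearly perfectly, and the
  # two clusters match different templates
  expect_true(all(apply(cors, 1, max) > 0.95))
  expect_equal(sort(apply(cors, 1, which.max)), c(1, 2))
  # no detections -> empty list
  z <- detect_spikes(recording(numeric(8000), fs = 8000))
  expect_equal(length(cluster_spikes(z)), 0)
})

test_that("the acceptance rule reproduces hand-computed decisions", {
  mk <- function(n, viol) {
    # n spikes at 10-ms spacing, plus `viol` extra spikes placed 2 ms after
    # every third base spike (exactly `viol` sub-3-ms ISIs)
    base <- cumsum(rep(0.010, n - viol))
    times <- sort(c(base, base[seq_len(viol) * 3] + 0.002))
    neurowire:::new_unit_cluster("ch1", times,
                                 matrix(rnorm(n * 10), n), 8000)
  }
  expect_true(accept_cluster(mk(300, 2)))     # 0.67% violations
  expect_false(accept_cluster(mk(250, 0)))    # "more than 250" is strict
  expect_false(accept_cluster(mk(1000, 15)))  # 1.5% violations
  expect_true(accept_cluster(mk(251, 0)))
  # monotone: adding clean spikes never flips accept -> reject
  a <- mk(300, 2)
  more <- sort(c(a$spike_times_s, a$spike_times_s + 1000))
  b <- neurowire:::new_unit_cluster("ch1", more,
                                    matrix(rnorm(600 * 10), 600), 8000)
  expect_true(accept_cluster(b))
})

test_that("firing-rate smoothing conserves the spike count", {
  fr <- firing_rate(seq(0.05, 9.95, length.out = 100), duration_s = 10)
  expect_equal(sum(fr$count), 100, tolerance = 1e-6)
  expect_equal(mean(fr$rate_hz), 10, tolerance = 1e-6)
  one <- firing_rate(5.2, duration_s = 10)
  expect_equal(sum(one$count), 1, tolerance = 1e-6)
  empty <- firing_rate(numeric(0), duration_s = 10)
  expect_true(all(empty$count == 0))
})

test_that("SNR follows the three-SD definition", {
  cl <- neurowire:::new_unit_cluster("ch1", c(1, 2),
                                     rbind(c(0, -60, 10), c(0, -60, 10)),
                                     8000)
  expect_equal(unit_snr(cl, noise_sd = 4), 5.0)
  expect_equal(unit_snr(numeric(0), 4), 0)
  # recovered SNR on synthetic data within 10% of the analytic value
  mw <- gen_microwire(n_channels = 1, fs = 8000, duration_s = 60,
                      units = list(list(template = 1, rate_hz = 8,
                                        amplitude = 100, channel = 1)),
                      seed = 31)
  det <- detect_spikes(mw$rec, threshold_sd = 5)
  cl2 <- cluster_spikes(det, seed = 1)
  main <- cl2[[which.max(vapply(cl2, function(u) length(u$spike_times_s), 0))]]
  noise_sd <- estimate_noise_sd(mw$rec, 1, main$spike_times_s)
  analytic <- 100 / (3 * noise_sd)
  expect_equal(unit_snr(main, noise_sd), analytic, tolerance = 0.1)
})

test_that("yield and ARI follow their formulas", {
  mk <- function(n, shift = 0) {
    w <- matrix(rep(sin(seq(0, 2 * pi, length.out = 12)), n), n,
                byrow = TRUE) * 50
    neurowire:::new_unit_cluster("ch1", seq_len(n) + shift, w, 8000)
  }
  before <- list(mk(200))
  after <- list(mk(198))
  res <- yield_and_ari(before, after, n_channels = 16)
  expect_equal(res$ari_percent, -1.0)
  # identical sorts: ARI 0
  res0 <- yield_and_ari(before, before, n_channels = 16)
  expect_equal(res0$ari_percent, 0)
  # yield: accepted units per channel (9 of 16 channels -> 0.5625)
  accepted <- lapply(1:9, function(i) {
    cl <- mk(300)
    cl$channel_id <- paste0("ch", i)
    cl
  })
  resy <- yield_and_ari(accepted, accepted, n_channels = 16)
  expect_equal(resy$yield, 0.5625)
})
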