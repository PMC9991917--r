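# Shared small fixtures, built in code at test time.

# a short two-channel recording with known sinusoids
sine_recording <- function(fs = 1000, dur = 2, freqs = c(10, 40)) {
  tt <- (seq_len(fs * dur) - 1) / fs
  recording(vapply(freqs, function(f) sin(2 * pi * f * tt), numeric(length(tt))),
            fs = fs)
}

# micro-wire session with spikes for the spike pipeline tests
spike_session <- function(seed = 3, duration_s = 30, fs = 8000) {
  gen_microwire(
    n_channels = 2, fs = fs, duration_s = duration_s,
    units = list(list(template = 1, rate_hz = 10, amplitude = 120, channel = 1),
                 list(template = 2, rate_hz = 8, amplitude = 90, channel = 2)),
    seed = seed)
}

# artifact-laden session (4 channels, shared sharp transients)
artifact_session <- function(seed = 5, n_sharp = 20, mult = 10,
                             duration_s = 30, fs = 8000) {
  base <- gen_microwire(n_channels = 4, fs = fs, duration_s = duration_s,
                        units = list(), seed = seed)
  inject_motion_artifacts(base$rec, n_sharp = n_sharp,
                          sharp_amp_sd_multiple = mult, seed = seed + 1)
}

# tiny memory dataset for decoder mechanics (not performance)
tiny_memory_ds <- function(seed = 2, n_blocks = 4, theta_effect = 2) {
  ms <- gen_memory_session(n_blocks = n_blocks, theta_effect = theta_effect,
                           seed = seed)
  list(ds = extract_windows(ms$rec, ms$events), truth = ms$truth)
}

# fast decoder spec for mechanics tests (tiny network)
tiny_decoder_spec <- function(...) {
  decoder_spec(conv1_filters = 6, conv2_filters = 8, conv1_kernel = 15,
               conv1_stride = 8, conv2_kernel = 5, conv2_stride = 8,
               lstm_units = 8, dense_units = 6, batch_size = 32, ...)
}
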