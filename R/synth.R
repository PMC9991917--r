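#' @name synthetic-data
#' @title Seed-deterministic synthetic session generators
#'
#' @description
#' Every generator returns its inputs together with a `ground_truth` list so
#' downstream stages (artifact detection, spike sorting, bandpower
#' statistics, decoding, phase-locked stimulation) can be scored without any
#' recorded data. All randomness is driven by the `seed` argument; the same
#' seed always yields bit-identical output.
NULL

# evaluate `expr` under a local RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

ground_truth <- function(unit_spike_times = list(),
                         artifact_intervals = tibble::tibble(
                           start_s = numeric(), end_s = numeric(),
                           kind = character()),
                         theta_phase = NULL,
                         condition_labels = NULL,
                         propagation_gains = NULL, ...) {
  structure(list(unit_spike_times = unit_spike_times,
                 artifact_intervals = artifact_intervals,
                 theta_phase = theta_phase,
                 condition_labels = condition_labels,
                 propagation_gains = propagation_gains, ...),
            class = "ground_truth")
}

# 1/f^exponent background, unit SD, via spectral shaping of white noise
# (generated at a power-of-two length for FFT speed, then truncated)
one_over_f <- function(n, fs, exponent = 1) {
  n2 <- stats::nextn(n, 2)
  white <- stats::rnorm(n2)
  X <- stats::fft(white)
  f <- c(1e-12, seq_len(n2 - 1)) * fs / n2      # avoid the DC singularity
  f <- pmin(f, fs - f)                          # mirror for negative freqs
  shape <- 1 / pmax(f, fs / n2)^(exponent / 2)
  shape[1] <- 0
  x <- Re(stats::fft(X * shape, inverse = TRUE) / n2)[seq_len(n)]
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# canonical biphasic extracellular spike templates, 1.5 ms, abs peak = 1
spike_template <- function(shape = 1, fs, width_ms = 1.5) {
  n <- max(3L, round(width_ms * fs / 1000))
  t <- seq(-1, 1, length.out = n)
  w <- switch(as.character(shape),
    "1" = -exp(-(t / 0.25)^2) + 0.45 * exp(-((t - 0.45) / 0.45)^2),
    "2" = -exp(-(t / 0.18)^2) + 0.30 * exp(-((t - 0.55) / 0.35)^2),
    "3" = -0.9 * exp(-(t / 0.35)^2) + 0.6 * exp(-((t - 0.35) / 0.30)^2),
    stop_neurowire("template shape must be 1, 2 or 3", "bad_config"))
  w / max(abs(w))
}

add_at <- function(x, idx, w) {
  # overlap-add waveform w into x starting at sample idx (may clip at edges)
  n <- length(x); L <- length(w)
  lo <- max(1L, idx); hi <- min(n, idx + L - 1L)
  if (lo > hi) return(x)
  x[lo:hi] <- x[lo:hi] + w[(lo - idx + 1L):(hi - idx + 1L)]
  x
}

#' Generate a synthetic micro-wire recording with embedded spike trains
#'
#' Emulates a high-rate micro-wire recording: a `1/f^exponent` background,
#' a 60-Hz line component and Poisson spike trains of canonical biphasic
#' 1.5-ms waveforms.
#'
#' @param n_channels,fs,duration_s Geometry of the recording (defaults
#'   16 channels at 38,600 Hz).
#' @param noise_exponent Spectral exponent of the background (default 1).
#' @param noise_sd Background SD in microvolts (default 10).
#' @param line_amp Amplitude of the 60-Hz line component (microvolts).
#' @param units List of unit descriptors `list(template =, rate_hz =,
#'   amplitude =, channel =)`; `channel` defaults to round-robin assignment.
#' @param seed Integer seed.
#' @return `list(rec = recording, truth = ground_truth)`; ground truth holds
#'   per-unit spike times (seconds).
#' @export
gen_microwire <- function(n_channels = 16, fs = 38600, duration_s = 10,
                          noise_exponent = 1, noise_sd = 10, line_amp = 2,
                          units = list(), seed = 1) {
  with_seed(seed, {
    n <- round(duration_s * fs)
    tt <- (seq_len(n) - 1) / fs
    data <- matrix(0, n, n_channels)
    for (ch in seq_len(n_channels)) {
      data[, ch] <- noise_sd * one_over_f(n, fs, noise_exponent) +
        line_amp * sin(2 * pi * 60 * tt + stats::runif(1, 0, 2 * pi))
    }
    spike_times <- vector("list", length(units))
    for (i in seq_along(units)) {
      u <- units[[i]]
      if (is.null(u$rate_hz) || u$rate_hz <= 0) {
        stop_neurowire("unit rate_hz must be > 0", "bad_config")
      }
      ch <- u$channel %||% ((i - 1L) %% n_channels + 1L)
      tmpl <- spike_template(u$template %||% 1, fs) * (u$amplitude %||% 60)
      st <- cumsum(stats::rexp(ceiling(u$rate_hz * duration_s * 2) + 20,
                               rate = u$rate_hz))
      st <- st[st < duration_s - length(tmpl) / fs]
      for (t in st) data[, ch] <- add_at(data[, ch], round(t * fs) + 1L, tmpl)
      # ground-truth time at the waveform's absolute peak
      spike_times[[i]] <- st + (which.max(abs(tmpl)) - 1L) / fs
    }
    if (length(units)) {
      names(spike_times) <- paste0("unit", seq_along(units))
    }
    list(rec = recording(data, fs = fs, units = "uV"),
         truth = ground_truth(unit_spike_times = spike_times,
                              unit_channels = vapply(seq_along(units),
                                function(i) units[[i]]$channel %||%
                                  ((i - 1L) %% n_channels + 1L), numeric(1))))
  })
}

#' Inject motion artifacts into a recording
#'
#' Adds the two artifact forms seen during ambulatory recording: a slow
#' drift confined below `slow_band_hz` and large sharp transients (brief
#' high-frequency bursts) scaled to a multiple of each channel's SD and,
#' by default, shared across channels.
#'
#' @param rec A [recording()].
#' @param n_sharp Number of sharp transients.
#' @param sharp_amp_sd_multiple Peak amplitude of each sharp transient as a
#'   multiple of the channel SD (default 10).
#' @param slow_amp SD of the slow drift component in recording units
#'   (0 disables it).
#' @param slow_band_hz Upper frequency bound of the slow component.
#' @param shared_across_channels Identical artifact on every channel.
#' @param seed Integer seed.
#' @return `list(rec = recording, truth = ground_truth)` with artifact
#'   intervals `(start_s, end_s, kind)` recorded in the ground truth.
#' @export
inject_motion_artifacts <- function(rec, n_sharp = 20,
                                    sharp_amp_sd_multiple = 10,
                                    slow_amp = 0, slow_band_hz = 1,
                                    shared_across_channels = TRUE,
                                    seed = 1) {
  stopifnot(inherits(rec, "recording"))
  with_seed(seed, {
    n <- nrow(rec$data); fs <- rec$fs; nch <- ncol(rec$data)
    data <- rec$data
    ivals <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                            kind = character())
    if (slow_amp > 0) {
      drift <- filter_vector(stats::rnorm(n),
                             design_filter(filter_spec("lowpass",
                                                       slow_band_hz * 0.5,
                                                       order = 4), fs))
      drift <- slow_amp * drift / stats::sd(drift)
      for (ch in seq_len(nch)) {
        d <- if (shared_across_channels) drift else {
          d2 <- filter_vector(stats::rnorm(n),
                              design_filter(filter_spec("lowpass",
                                                        slow_band_hz * 0.5,
                                                        order = 4), fs))
          slow_amp * d2 / stats::sd(d2)
        }
        data[, ch] <- data[, ch] + d
      }
      ivals <- dplyr::bind_rows(ivals, tibble::tibble(
        start_s = 0, end_s = n / fs, kind = "slow"))
    }
    if (n_sharp > 0) {
      # sharp transient: 1-kHz burst under a 3-ms Gaussian envelope
      half_ms <- 4
      L <- round(2 * half_ms / 1000 * fs)
      te <- seq(-half_ms, half_ms, length.out = L) / 1000
      burst <- exp(-(te / 0.0015)^2) * sin(2 * pi * 1000 * te + pi / 4)
      burst <- burst / max(abs(burst))
      margin <- L / fs
      starts <- sort(stats::runif(n_sharp * 50, margin, n / fs - 2 * margin))
      keep <- c(TRUE, diff(starts) > 4 * margin)
      starts <- utils::head(starts[keep], n_sharp)
      if (length(starts) < n_sharp) {
        stop_neurowire("recording too short for requested n_sharp",
                       "bad_config")
      }
      sds <- apply(rec$data, 2, stats::sd)
      sds[sds == 0] <- 1
      for (t in starts) {
        idx <- round(t * fs) + 1L
        for (ch in seq_len(nch)) {
          g <- if (shared_across_channels) 1 else stats::runif(1, 0.7, 1.3)
          data[, ch] <- add_at(data[, ch], idx,
                               burst * sharp_amp_sd_multiple * sds[ch] * g)
        }
      }
      ivals <- dplyr::bind_rows(ivals, tibble::tibble(
        start_s = starts, end_s = starts + L / fs, kind = "sharp"))
    }
    out <- rec
    out$data <- data
    list(rec = out, truth = ground_truth(artifact_intervals = ivals))
  })
}

# intermittent theta process: amplitude-modulated sinusoid with exponential
# burst/gap durations and raised-cosine ramps; returns signal, envelope, phase
theta_process <- function(n, fs, theta_hz = 6, amp = 1, burst_mean_s = 1,
                          gap_mean_s = 1, freq_jitter_hz = 0.2,
                          ramp_s = 0.1) {
  env <- numeric(n)
  t <- 0
  on_phase <- stats::runif(1) < burst_mean_s / (burst_mean_s + gap_mean_s)
  while (t < n) {
    len <- round(stats::rexp(1, 1 / (if (on_phase) burst_mean_s else
      gap_mean_s)) * fs)
    len <- max(len, round(0.2 * fs))
    if (on_phase) env[t + seq_len(min(len, n - t))] <- 1
    t <- t + len
    on_phase <- !on_phase
  }
  # smooth the gate so bursts switch on/off over ~ramp_s
  k <- max(3L, round(ramp_s * fs)); k <- k + (k + 1L) %% 2L
  env <- as.numeric(stats::filter(c(rep(env[1], k), env, rep(env[n], k)),
                                  rep(1 / k, k), sides = 2))[k + seq_len(n)]
  inst_f <- theta_hz + freq_jitter_hz *
    filter_vector(stats::rnorm(n), design_filter(
      filter_spec("lowpass", min(0.5, fs / 8), order = 2), fs))
  phase <- (stats::runif(1, 0, 2 * pi) + cumsum(2 * pi * inst_f / fs)) %%
    (2 * pi)
  list(signal = amp * env * sin(phase), envelope = env, phase = phase)
}

#' Generate a back-and-forth walking session
#'
#' Emulates LFP recorded while a participant walks repeatedly between two
#' points: each channel carries an independent intermittent theta
#' oscillation on a `1/f` background, and the theta amplitude is multiplied
#' by `boundary_gain` during the final third of every crossing (the
#' boundary segment).
#'
#' @param n_crossings Number of crossings (default 10).
#' @param crossing_duration_s Duration of one crossing.
#' @param pause_s Pause between crossings.
#' @param theta_hz Theta frequency (default 6).
#' @param theta_amp Baseline theta amplitude relative to the unit-SD noise.
#' @param boundary_gain Theta amplitude multiplier inside the final third
#'   of each crossing; 1 is the null case.
#' @param n_channels,fs Recording geometry (default 16 channels at 386 Hz).
#' @param seed Integer seed.
#' @return `list(rec, events, truth)`; `events` holds `crossing_start` /
#'   `crossing_end` pairs.
#' @export
gen_walk_session <- function(n_crossings = 10, crossing_duration_s = 6,
                             pause_s = 1, theta_hz = 6, theta_amp = 1.5,
                             boundary_gain = 1, n_channels = 16, fs = 386,
                             seed = 1) {
  with_seed(seed, {
    starts <- pause_s + (seq_len(n_crossings) - 1) *
      (crossing_duration_s + pause_s)
    ends <- starts + crossing_duration_s
    dur <- ends[n_crossings] + pause_s
    n <- round(dur * fs)
    tt <- (seq_len(n) - 1) / fs
    gain <- rep(1, n)
    b_start <- starts + 2 * crossing_duration_s / 3
    for (i in seq_len(n_crossings)) {
      gain[tt >= b_start[i] & tt < ends[i]] <- boundary_gain
    }
    data <- matrix(0, n, n_channels)
    for (ch in seq_len(n_channels)) {
      th <- theta_process(n, fs, theta_hz, amp = theta_amp)
      data[, ch] <- one_over_f(n, fs, 1) + gain * th$signal
    }
    events <- event_stream(
      time_s = as.vector(rbind(starts, ends)),
      kind = rep(c("crossing_start", "crossing_end"), n_crossings))
    list(rec = recording(data, fs = fs, units = "uV"),
         events = events,
         truth = ground_truth(boundary_gain = boundary_gain,
                              crossing_start_s = starts,
                              crossing_end_s = ends))
  })
}

#' Generate a verbal memory session
#'
#' Word-onset events with remembered/forgotten labels; every channel
#' carries ongoing intermittent theta on a `1/f` background, and
#' remembered-class onsets additionally receive a Hann-windowed theta burst
#' over the 2 s after word onset whose amplitude is
#' `theta_effect * theta_amp`. `theta_effect = 0` is the null case (labels
#' independent of the signal).
#'
#' @param n_blocks,words_per_block Task structure (defaults 9 blocks of 10
#'   words).
#' @param word_s,isi_s Word presentation time and inter-stimulus interval
#'   (defaults 2 s and 0.8 s).
#' @param block_gap_s Gap between blocks (distractor/recall period).
#' @param p_remember Probability a word is later remembered.
#' @param theta_effect Strength of the onset-locked remembered-class theta
#'   burst (multiples of `theta_amp`).
#' @param theta_hz,theta_amp Theta frequency and baseline amplitude.
#' @param n_channels,fs Recording geometry (defaults 2 channels -- one per
#'   hippocampal region -- at 250 Hz).
#' @param seed Integer seed.
#' @return `list(rec, events, truth)`; `events$label` is the logical
#'   remembered flag.
#' @export
gen_memory_session <- function(n_blocks = 9, words_per_block = 10,
                               word_s = 2, isi_s = 0.8, block_gap_s = 12,
                               p_remember = 0.6, theta_effect = 0,
                               theta_hz = 6, theta_amp = 2,
                               n_channels = 2, fs = 250, seed = 1) {
  with_seed(seed, {
    onset_step <- word_s + isi_s
    block_len <- words_per_block * onset_step + block_gap_s
    onsets <- as.vector(vapply(seq_len(n_blocks), function(b) {
      6 + (b - 1) * block_len + (seq_len(words_per_block) - 1) * onset_step
    }, numeric(words_per_block)))
    dur <- max(onsets) + 6
    n <- round(dur * fs)
    labels <- stats::runif(length(onsets)) < p_remember
    data <- matrix(0, n, n_channels)
    for (ch in seq_len(n_channels)) {
      th <- theta_process(n, fs, theta_hz, amp = theta_amp)
      x <- one_over_f(n, fs, 1) + th$signal
      if (theta_effect > 0) {
        L <- round(2 * fs)
        hann <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = L))
        for (i in which(labels)) {
          idx <- round(onsets[i] * fs) + 1L
          ph <- stats::runif(1, 0, 2 * pi)
          burst <- theta_effect * theta_amp * hann *
            sin(2 * pi * theta_hz * (seq_len(L) - 1) / fs + ph)
          x <- add_at(x, idx, burst)
        }
      } else {
        stats::runif(sum(labels))   # keep the RNG stream aligned across effects
      }
      data[, ch] <- x
    }
    events <- event_stream(onsets, rep("word_onset", length(onsets)),
                           label = labels)
    blocks <- rep(seq_len(n_blocks), each = words_per_block)
    list(rec = recording(data, fs = fs, units = "uV"),
         events = events,
         truth = ground_truth(condition_labels = labels, onsets_s = onsets,
                              block = blocks))
  })
}

#' Generate a single-channel LFP with intermittent theta for closed-loop use
#'
#' The ground truth carries the full instantaneous oscillator phase series
#' and the burst envelope, so phase-locked triggers can be scored exactly.
#'
#' @param duration_s,fs Length and sampling rate (default 300 s at 250 Hz).
#' @param theta_hz Oscillator frequency (default 6).
#' @param snr Theta amplitude relative to the unit-SD `1/f` background.
#' @param burst_mean_s,gap_mean_s Mean burst/gap durations (s).
#' @param freq_jitter_hz SD of the slow frequency wander.
#' @param seed Integer seed.
#' @return `list(rec, truth)`; `truth$theta_phase` is the phase series in
#'   radians, `truth$theta_envelope` the burst gate.
#' @export
gen_theta_lfp <- function(duration_s = 300, fs = 250, theta_hz = 6,
                          snr = 2, burst_mean_s = 1, gap_mean_s = 1.5,
                          freq_jitter_hz = 0.2, seed = 1) {
  with_seed(seed, {
    n <- round(duration_s * fs)
    th <- theta_process(n, fs, theta_hz, amp = snr,
                        burst_mean_s = burst_mean_s,
                        gap_mean_s = gap_mean_s,
                        freq_jitter_hz = freq_jitter_hz)
    x <- one_over_f(n, fs, 1) + th$signal
    list(rec = recording(x, fs = fs, units = "uV"),
         truth = ground_truth(theta_phase = th$phase,
                              theta_envelope = th$envelope,
                              theta_hz = theta_hz))
  })
}

#' Generate a stimulation-burst session
#'
#' Renders the scheduled biphasic pulses of a [stim_protocol()] on every
#' channel, scaled by per-channel propagation gains, plus white sensor
#' noise. The default protocol is the full propagation-mapping grid
#' (5 amplitudes x 5 frequencies x 4 repeats = 100 bursts of 10 pulses).
#'
#' @param protocol A [stim_protocol()]; default `stim_protocol()`.
#' @param channel_gains Per-channel attenuation factors (default
#'   `exp(-(0:3))` for 4 channels).
#' @param gain_uv_per_ma Conversion from delivered current to recorded
#'   artifact amplitude at unit gain (microvolts per mA).
#' @param noise_sd Additive white noise SD (microvolts).
#' @param fs Sampling rate of the macro recording (default 6,250 Hz).
#' @param seed Integer seed.
#' @return `list(rec, schedule, truth)`; `schedule` is the burst table from
#'   [schedule_bursts()], `truth$propagation_gains` the channel gains.
#' @export
gen_stim_session <- function(protocol = stim_protocol(),
                             channel_gains = exp(-(0:3)),
                             gain_uv_per_ma = 1000, noise_sd = 5,
                             fs = 6250, seed = 1) {
  with_seed(seed, {
    sched <- schedule_bursts(protocol)
    pulse_times <- unlist(sched$pulse_times_s)
    dur <- max(pulse_times) + protocol$interburst_s
    n <- round(dur * fs)
    nch <- length(channel_gains)
    data <- matrix(stats::rnorm(n * nch, sd = noise_sd), n, nch)
    for (b in seq_len(nrow(sched))) {
      w <- render_pulse(shape = protocol$shape,
                        amplitude = sched$amplitude[b] * gain_uv_per_ma,
                        pulse_width_ms = protocol$pulse_width_ms,
                        interphase_us = protocol$interphase_us,
                        polarity = protocol$polarity, fs = fs)
      for (t in sched$pulse_times_s[[b]]) {
        idx <- round(t * fs) + 1L
        for (ch in seq_len(nch)) {
          data[, ch] <- add_at(data[, ch], idx, w * channel_gains[ch])
        }
      }
    }
    list(rec = recording(data, fs = fs, units = "uV"),
         schedule = sched,
         truth = ground_truth(propagation_gains = channel_gains))
  })
}
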