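#' Stimulation protocol
#'
#' A parameterized burst schedule on the device's stimulation grid: pulse
#' width 0.01-1.28 ms in 10-us steps, inter-phase gap 0-150 us in 10-us
#' steps. The default protocol is the propagation-mapping grid: amplitudes
#' 0.25-1.25 mA x frequencies 60-140 Hz, four repeats each (100 bursts of
#' ten biphasic rectangular pulses, 16.67-s inter-burst delay).
#'
#' @param amplitudes Stimulation amplitudes (interpretation set by
#'   `amplitude_unit`).
#' @param frequencies_hz Within-burst pulse rates in Hz.
#' @param repeats Repeats per (amplitude, frequency) combination.
#' @param pulses_per_burst Pulses per burst (default 10).
#' @param pulse_width_ms Single-phase width in ms (grid: 0.01-1.28 in 0.01
#'   steps).
#' @param interphase_us Gap between the two phases in us (grid: 0-150 in
#'   10-us steps).
#' @param interburst_s Burst-onset spacing in seconds.
#' @param polarity `"cathodic_first"` or `"anodic_first"`.
#' @param shape `"rectangular"` or `"custom_16_step"`.
#' @param custom_steps 16 per-step amplitudes for the custom shape.
#' @param amplitude_unit Label only (`"mA"` default).
#' @return A `stim_protocol` object.
#' @export
stim_protocol <- function(amplitudes = c(0.25, 0.5, 0.75, 1.0, 1.25),
                          frequencies_hz = c(60, 80, 100, 120, 140),
                          repeats = 4, pulses_per_burst = 10,
                          pulse_width_ms = 1.28, interphase_us = 150,
                          interburst_s = 16.67,
                          polarity = c("cathodic_first", "anodic_first"),
                          shape = c("rectangular", "custom_16_step"),
                          custom_steps = NULL, amplitude_unit = "mA") {
  polarity <- match.arg(polarity)
  shape <- match.arg(shape)
  on_grid <- function(x, step) abs(x / step - round(x / step)) < 1e-9
  if (pulse_width_ms < 0.01 - 1e-9 || pulse_width_ms > 1.28 + 1e-9 ||
      !on_grid(pulse_width_ms, 0.01)) {
    stop_neurowire(sprintf(
      "pulse_width_ms %g off the device grid (0.01-1.28 ms, 10-us steps)",
      pulse_width_ms), "off_grid")
  }
  if (interphase_us < 0 || interphase_us > 150 || !on_grid(interphase_us, 10)) {
    stop_neurowire(sprintf(
      "interphase_us %g off the device grid (0-150 us, 10-us steps)",
      interphase_us), "off_grid")
  }
  if (shape == "custom_16_step" &&
      (is.null(custom_steps) || length(custom_steps) != 16)) {
    stop_neurowire("custom_16_step shape needs 16 step amplitudes",
                   "bad_config")
  }
  if (any(frequencies_hz <= 0) || any(amplitudes < 0)) {
    stop_neurowire("amplitudes must be >= 0 and frequencies > 0",
                   "bad_config")
  }
  structure(list(amplitudes = amplitudes, frequencies_hz = frequencies_hz,
                 repeats = as.integer(repeats),
                 pulses_per_burst = as.integer(pulses_per_burst),
                 pulse_width_ms = pulse_width_ms,
                 interphase_us = interphase_us,
                 interburst_s = interburst_s, polarity = polarity,
                 shape = shape, custom_steps = custom_steps,
                 amplitude_unit = amplitude_unit),
            class = "stim_protocol")
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf(
    "<stim_protocol> %d amp x %d freq x %d repeats = %d bursts of %d pulses\n",
    length(x$amplitudes), length(x$frequencies_hz), x$repeats,
    length(x$amplitudes) * length(x$frequencies_hz) * x$repeats,
    x$pulses_per_burst))
  invisible(x)
}

#' Schedule the bursts of a protocol
#'
#' One burst per (amplitude, frequency, repeat) combination; bursts are
#' spaced `interburst_s` apart and pulse onsets within a burst are spaced
#' `1/frequency` apart (onset-to-onset).
#'
#' @param p A [stim_protocol()].
#' @return Tibble with one row per burst: `burst`, `amplitude`,
#'   `frequency_hz`, `rep`, `start_s` and the list-column `pulse_times_s`.
#' @export
schedule_bursts <- function(p) {
  stopifnot(inherits(p, "stim_protocol"))
  grid <- expand.grid(rep = seq_len(p$repeats),
                      frequency_hz = p$frequencies_hz,
                      amplitude = p$amplitudes)
  n_b <- nrow(grid)
  starts <- (seq_len(n_b) - 1) * p$interburst_s
  tibble::tibble(
    burst = seq_len(n_b),
    amplitude = grid$amplitude,
    frequency_hz = grid$frequency_hz,
    rep = grid$rep,
    start_s = starts,
    pulse_times_s = lapply(seq_len(n_b), function(i) {
      starts[i] + (seq_len(p$pulses_per_burst) - 1) / grid$frequency_hz[i]
    }))
}

#' Render one biphasic stimulation pulse
#'
#' Charge-balanced biphasic waveform: first phase, inter-phase gap, second
#' phase of opposite sign and equal area. The `custom_16_step` shape
#' renders 16 equal-duration amplitude steps within each phase (mirrored
#' in the second phase so the net charge stays zero).
#'
#' @param shape `"rectangular"` or `"custom_16_step"`.
#' @param amplitude Peak amplitude (output units).
#' @param pulse_width_ms Single-phase width in ms.
#' @param interphase_us Gap between phases in us.
#' @param polarity `"cathodic_first"` (first phase negative) or
#'   `"anodic_first"`.
#' @param fs Rendering sampling rate in Hz.
#' @param custom_steps 16 step amplitudes for the custom shape.
#' @return Numeric waveform.
#' @export
render_pulse <- function(shape = "rectangular", amplitude = 1,
                         pulse_width_ms = 1.28, interphase_us = 150,
                         polarity = "cathodic_first", fs = 6250,
                         custom_steps = NULL) {
  wph <- max(1L, round(pulse_width_ms / 1000 * fs))
  gap <- round(interphase_us / 1e6 * fs)
  sgn <- if (polarity == "cathodic_first") -1 else 1
  phase1 <- if (shape == "custom_16_step") {
    if (is.null(custom_steps) || length(custom_steps) != 16) {
      stop_neurowire("custom_16_step shape needs 16 step amplitudes",
                     "bad_config")
    }
    rep(custom_steps, each = max(1L, ceiling(wph / 16)))[seq_len(wph)] *
      amplitude
  } else {
    rep(amplitude, wph)
  }
  c(sgn * phase1, rep(0, gap), -sgn * phase1)
}

#' Detect propagated stimulation pulses by template cross-correlation
#'
#' Computes the normalized cross-correlation of each channel against the
#' delivered-pulse template and places detections at correlation peaks at
#' or above `threshold`, separated by at least one template length.
#' Aligned snippets (template span plus `margin_ms` on each side) are
#' extracted at the peak lag.
#'
#' @param rec A [recording()] of the stimulation session.
#' @param template Numeric template waveform at `rec$fs` (e.g. from
#'   [render_pulse()]).
#' @param threshold Correlation threshold (default 0.8).
#' @param margin_ms Snippet margin around the template span (default 2 ms).
#' @param min_snr Amplitude gate: a detection's window RMS must exceed
#'   `min_snr` times the channel's robust noise SD (default 3), so chance
#'   correlations of the short template with noise on silent channels do
#'   not fire.
#' @return A `pulse_detections` tibble: `channel`, `time_s` (template
#'   onset), `ncc`, `power` (sum of squared snippet samples) and
#'   `norm_power` (power / largest pulse power over all channels).
#' @export
detect_pulses <- function(rec, template, threshold = 0.8, margin_ms = 2,
                          min_snr = 3) {
  stopifnot(inherits(rec, "recording"))
  L <- length(template)
  tz <- template - mean(template)
  tnorm <- sqrt(sum(tz^2))
  n <- nrow(rec$data)
  margin <- round(margin_ms / 1000 * rec$fs)
  rows <- list()
  for (ch in seq_len(ncol(rec$data))) {
    x <- rec$data[, ch]
    # running cross-correlation and window energy via filtering
    num <- stats::filter(x, rev(tz), sides = 1)      # ends at window end
    csum <- cumsum(c(0, x))
    csum2 <- cumsum(c(0, x^2))
    idx_end <- L:n
    win_sum <- csum[idx_end + 1] - csum[idx_end + 1 - L]
    win_sq <- csum2[idx_end + 1] - csum2[idx_end + 1 - L]
    win_en <- pmax(win_sq - win_sum^2 / L, 1e-12)
    ncc <- as.numeric(num[idx_end]) / (sqrt(win_en) * tnorm)
    robust_sd <- stats::median(abs(x - stats::median(x))) / 0.6745
    loud <- sqrt(win_en / L) > min_snr * max(robust_sd, 1e-12)
    above <- which(ncc >= threshold & loud)
    peaks <- integer(0)
    if (length(above)) {
      pk <- above[ncc[pmax(1, above - 1)] <= ncc[above] &
                  ncc[above] >= ncc[pmin(length(ncc), above + 1)]]
      last <- -Inf
      for (i in pk) {
        if (i - last >= L) { peaks <- c(peaks, i); last <- i }
      }
    }
    if (length(peaks)) {
      onset <- peaks            # window start sample = peak index (1-based)
      pw <- vapply(onset, function(s) {
        lo <- max(1L, s - margin); hi <- min(n, s + L - 1L + margin)
        sum(x[lo:hi]^2)
      }, numeric(1))
      rows[[ch]] <- tibble::tibble(channel = rec$channel_ids[ch],
                                   time_s = (onset - 1) / rec$fs,
                                   ncc = ncc[peaks], power = pw)
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(channel = character(), time_s = numeric(),
                   ncc = numeric(), power = numeric())
  out$norm_power <- if (nrow(out)) out$power / max(out$power) else numeric(0)
  class(out) <- c("pulse_detections", class(out))
  out
}

#' Propagation statistics by stimulation condition
#'
#' Assigns every detected pulse to its scheduled burst (nearest scheduled
#' pulse onset within `tol_s`) and summarizes the normalized pulse power
#' per channel and (amplitude, frequency) condition. Normalization divides
#' every pulse power by the single largest pulse power across all channels
#' and pulses.
#'
#' @param det A `pulse_detections` tibble from [detect_pulses()].
#' @param schedule Burst table from [schedule_bursts()].
#' @param tol_s Assignment tolerance (default 2 ms).
#' @return Tibble grouped rows: `channel`, `amplitude`, `frequency_hz`,
#'   `n_pulses`, `mean_norm_power`, `sd_norm_power`.
#' @export
propagation_stats <- function(det, schedule, tol_s = 0.002) {
  sched_long <- tidyr::unnest(
    schedule[, c("burst", "amplitude", "frequency_hz", "pulse_times_s")],
    cols = "pulse_times_s")
  names(sched_long)[names(sched_long) == "pulse_times_s"] <- "sched_time_s"
  if (!nrow(det)) {
    return(tibble::tibble(channel = character(), amplitude = numeric(),
                          frequency_hz = numeric(), n_pulses = integer(),
                          mean_norm_power = numeric(),
                          sd_norm_power = numeric()))
  }
  idx <- findInterval(det$time_s, sched_long$sched_time_s)
  lo <- pmax(idx, 1L)
  hi <- pmin(idx + 1L, nrow(sched_long))
  pick <- ifelse(abs(det$time_s - sched_long$sched_time_s[lo]) <=
                   abs(det$time_s - sched_long$sched_time_s[hi]), lo, hi)
  ok <- abs(det$time_s - sched_long$sched_time_s[pick]) <= tol_s
  det$amplitude <- ifelse(ok, sched_long$amplitude[pick], NA)
  det$frequency_hz <- ifelse(ok, sched_long$frequency_hz[pick], NA)
  det <- det[ok, ]
  dplyr::summarise(
    dplyr::group_by(det, .data$channel, .data$amplitude, .data$frequency_hz),
    n_pulses = dplyr::n(),
    mean_norm_power = mean(.data$norm_power),
    sd_norm_power = stats::sd(.data$norm_power),
    .groups = "drop")
}

#' Plot propagation statistics against stimulation amplitude
#' @param object Tibble from [propagation_stats()].
#' @param ... Unused.
#' @export
plot_propagation <- function(object, ...) {
  df <- dplyr::summarise(
    dplyr::group_by(object, .data$amplitude, .data$frequency_hz),
    mean_norm_power = mean(.data$mean_norm_power),
    sd_norm_power = mean(.data$sd_norm_power, na.rm = TRUE),
    .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amplitude,
                                   y = .data$mean_norm_power,
                                   color = factor(.data$frequency_hz))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_norm_power - .data$sd_norm_power,
      ymax = .data$mean_norm_power + .data$sd_norm_power)) +
    ggplot2::labs(x = "stimulation amplitude", y = "normalized power",
                  color = "burst freq (Hz)")
}
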