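#' Configuration for the phase-locked stimulation loop
#'
#' @param band_hz Detection band, default theta `c(3, 8)`.
#' @param target_phase_rad Oscillator phase at which stimulation should
#'   land (0 = upward zero crossing of a sine).
#' @param power_threshold Trigger gate in z units on the band RMS
#'   (default 1.5).
#' @param latency_ms Simulated round-trip delay from detection to
#'   stimulation output (default 1.57 ms).
#' @param refractory_ms Minimum spacing between triggers (default 50 ms).
#' @param rms_window_s Causal RMS window (default 0.5 s).
#' @param baseline_s Running-baseline window for the z-score (default 10 s).
#' @return A `pls_config` object.
#' @export
pls_config <- function(band_hz = c(3, 8), target_phase_rad = 0,
                       power_threshold = 1.5, latency_ms = 1.57,
                       refractory_ms = 50, rms_window_s = 0.5,
                       baseline_s = 10) {
  if (latency_ms < 0) stop_neurowire("latency must be >= 0", "bad_config")
  if (band_hz[1] <= 0 || band_hz[1] >= band_hz[2]) {
    stop_neurowire("band must be increasing and positive", "bad_config")
  }
  structure(list(band_hz = band_hz, target_phase_rad = target_phase_rad,
                 power_threshold = power_threshold, latency_ms = latency_ms,
                 refractory_ms = refractory_ms, rms_window_s = rms_window_s,
                 baseline_s = baseline_s),
            class = "pls_config")
}

# phase delay (seconds, modulo one period) of a section cascade at f:
# the steady-state time shift a sinusoid at f suffers through the filter
cascade_phase_delay <- function(sections, f, fs) {
  w <- 2 * pi * f / fs
  z <- exp(-1i * w)
  H <- Reduce(`*`, lapply(sections, function(s) {
    sum(s$b * z^(0:(length(s$b) - 1))) / sum(s$a * z^(0:(length(s$a) - 1)))
  }))
  ((-Arg(H)) %% (2 * pi)) / w / fs
}

# causal running mean over the last `w` samples (expanding at the start)
running_mean <- function(x, w) {
  cs <- cumsum(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(i - w, 0L)
  (cs - c(0, cs)[lo + 1L]) / (i - lo)
}

#' Causal phase-locked stimulation simulation
#'
#' Processes a single-channel recording strictly causally: a causal
#' band-pass (4th order per edge) isolates the detection band, band power
#' is a sliding RMS z-scored against a running baseline, and phase is
#' tracked from upward zero crossings of the filtered trace (period =
#' previous inter-crossing interval, bounded to the band). Each valid
#' cycle yields at most one trigger at the predicted time of the target
#' phase, gated on supra-threshold power and the refractory period; the
#' stimulation lands `latency_ms` later. Triggers are scored against the
#' ground-truth oscillator phase at the stimulation time.
#'
#' @param rec A single-channel [recording()].
#' @param truth A `ground_truth` with `theta_phase` (radians per sample),
#'   e.g. from [gen_theta_lfp()]. May be `NULL`; then trigger phases are
#'   not scored.
#' @param cfg A [pls_config()].
#' @return A `trigger_log`: tibble with `trigger_time_s` (stimulation
#'   time), `detect_time_s`, `phase_rad` (ground-truth phase at
#'   stimulation, if truth given), `z_power`; attributes `circ_variance`
#'   and `config`.
#' @export
run_pls <- function(rec, truth = NULL, cfg = pls_config()) {
  stopifnot(inherits(rec, "recording"))
  if (ncol(rec$data) != 1) {
    stop_neurowire("run_pls expects a single detection channel", "bad_config")
  }
  fs <- rec$fs
  x <- rec$data[, 1]
  n <- length(x)
  sections <- design_filter(filter_spec("bandpass", cfg$band_hz, order = 4),
                            fs)
  xf <- filter_vector(x, sections, zero_phase = FALSE)
  # causal band power: sliding RMS z-scored against a running baseline
  w_rms <- max(2L, round(cfg$rms_window_s * fs))
  w_base <- max(w_rms + 1L, round(cfg$baseline_s * fs))
  ms <- running_mean(xf^2, w_rms)
  rms <- sqrt(ms)
  mu <- running_mean(rms, w_base)
  m2 <- running_mean(rms^2, w_base)
  sd_r <- sqrt(pmax(m2 - mu^2, 1e-12))
  z <- (rms - mu) / sd_r
  # upward zero crossings with sub-sample interpolation
  up <- which(xf[-n] < 0 & xf[-1] >= 0)
  t_zc <- (up - 1) / fs + (-xf[up]) / (xf[up + 1] - xf[up]) / fs
  frac <- (cfg$target_phase_rad %% (2 * pi)) / (2 * pi)
  t_min <- 1 / cfg$band_hz[2]
  t_max <- 1 / cfg$band_hz[1]
  # compensate the causal filter's phase delay (known at design time);
  # delays are interpolated over the band per detected cycle frequency
  gd_freqs <- seq(cfg$band_hz[1], cfg$band_hz[2], length.out = 11)
  gd_vals <- vapply(gd_freqs, function(f)
    cascade_phase_delay(sections, f, fs), numeric(1))
  det_t <- numeric(0); det_z <- numeric(0)
  last <- -Inf
  if (length(t_zc) > 1) {
    periods <- diff(t_zc)
    for (k in seq_along(periods)) {
      tp <- periods[k]
      if (tp < t_min || tp > t_max) next
      gd <- stats::approx(gd_freqs, gd_vals, xout = 1 / tp, rule = 2)$y
      # shift into the current cycle so the trigger stays causal
      cand <- t_zc[k + 1] + (frac * tp - gd) %% tp
      i_c <- min(n, floor(cand * fs) + 1L)
      if (i_c <= w_rms) next             # power estimate not yet formed
      if (z[i_c] < cfg$power_threshold) next
      if (cand - last < cfg$refractory_ms / 1000) next
      det_t <- c(det_t, cand); det_z <- c(det_z, z[i_c])
      last <- cand
    }
  }
  stim_t <- det_t + cfg$latency_ms / 1000
  phases <- rep(NA_real_, length(stim_t))
  if (!is.null(truth) && !is.null(truth$theta_phase)) {
    ph <- truth$theta_phase
    idx <- stim_t * fs                    # 0-based fractional sample
    i0 <- pmin(length(ph) - 1L, pmax(1L, floor(idx) + 1L))
    a <- idx - (i0 - 1L)
    # interpolate on the unit circle to survive 2*pi wraps
    phases <- Arg(exp(1i * ph[i0]) * (1 - a) + exp(1i * ph[i0 + 1L]) * a)
    phases <- phases %% (2 * pi)
  }
  out <- tibble::tibble(trigger_time_s = stim_t, detect_time_s = det_t,
                        phase_rad = phases, z_power = det_z)
  attr(out, "circ_variance") <- if (all(is.na(phases))) NA_real_ else
    circular_variance(phases[!is.na(phases)])
  attr(out, "config") <- cfg
  class(out) <- c("trigger_log", class(out))
  out
}

#' Circular variance of a set of phases
#'
#' `1 - |mean resultant vector|`: 0 for perfectly aligned phases, 1 for a
#' balanced (e.g. uniform) phase distribution.
#'
#' @param phases_rad Phases in radians.
#' @return Numeric in `[0, 1]`.
#' @export
circular_variance <- function(phases_rad) {
  if (!length(phases_rad)) return(NA_real_)
  1 - Mod(mean(exp(1i * phases_rad)))
}

#' @export
glance.trigger_log <- function(x, ...) {
  tibble::tibble(n_triggers = nrow(x),
                 circ_variance = attr(x, "circ_variance"),
                 mean_phase_rad = if (nrow(x) && !all(is.na(x$phase_rad)))
                   Arg(mean(exp(1i * x$phase_rad[!is.na(x$phase_rad)]))) %%
                     (2 * pi) else NA_real_)
}

#' Plot the trigger phase distribution
#' @param object A `trigger_log`.
#' @param bins Number of phase bins.
#' @param ... Unused.
#' @export
autoplot.trigger_log <- function(object, bins = 24, ...) {
  df <- object[!is.na(object$phase_rad), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase_rad)) +
    ggplot2::geom_histogram(breaks = seq(0, 2 * pi, length.out = bins + 1)) +
    ggplot2::coord_polar() +
    ggplot2::labs(x = "ground-truth phase at stimulation (rad)", y = NULL)
}
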