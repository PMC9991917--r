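#' Hjorth parameters
#'
#' Activity is the signal variance; mobility is
#' `sqrt(var(dy/dt) / var(y))`; complexity is the ratio of the mobility of
#' the derivative to the mobility of the signal. The derivative is the
#' forward difference scaled by the sampling rate.
#'
#' @param y Numeric series (length >= 3, non-constant).
#' @param fs Sampling rate in Hz.
#' @return A one-row tibble with `activity`, `mobility`, `complexity`.
#' @export
hjorth_params <- function(y, fs) {
  if (length(y) < 3) stop_neurowire("need at least 3 samples", "bad_config")
  if (stats::var(y) == 0) {
    stop_neurowire("constant signal has undefined Hjorth parameters",
                   "constant_channel")
  }
  dy <- diff(y) * fs
  ddy <- diff(dy) * fs
  mob <- function(sig, dsig) sqrt(stats::var(dsig) / stats::var(sig))
  m_y <- mob(y, dy)
  m_dy <- mob(dy, ddy)
  tibble::tibble(activity = stats::var(y), mobility = m_y,
                 complexity = m_dy / m_y)
}

#' Pearson (non-excess) kurtosis
#'
#' `E[(y - mu)^4] / sigma^4` with population moments and no small-sample
#' correction; a Gaussian gives 3.
#'
#' @param y Numeric vector.
#' @return Numeric kurtosis.
#' @export
kurtosis_pearson <- function(y) {
  m <- mean(y)
  s2 <- mean((y - m)^2)
  mean((y - m)^4) / s2^2
}

#' Artifact spike count
#'
#' Number of samples of the z-scored trace falling outside `±z_bound`
#' (default 6) after resampling to `fs_target` (default 250 Hz).
#'
#' @param y Numeric series.
#' @param fs Sampling rate of `y`.
#' @param z_bound Bound in z units (default 6).
#' @param fs_target Evaluation sampling rate (default 250 Hz).
#' @return Integer count.
#' @export
artifact_spike_count <- function(y, fs, z_bound = 6, fs_target = 250) {
  if (fs != fs_target) {
    y <- resample_recording(recording(y, fs), fs_target)$data[, 1]
  }
  z <- (y - mean(y)) / stats::sd(y)
  sum(abs(z) > z_bound)
}

#' Average band power in the 55-65 Hz line band
#'
#' Integrates the one-sided periodogram (Hamming-windowed) over the band
#' after resampling to `fs_target` (250 Hz). A unit-amplitude 60-Hz sine
#' gives ~0.5 (its total power).
#'
#' @param y Numeric series.
#' @param fs Sampling rate of `y`.
#' @param band Band in Hz (default `c(55, 65)`).
#' @param fs_target Evaluation sampling rate (default 250 Hz).
#' @return Numeric band power (units^2).
#' @export
power_60hz <- function(y, fs, band = c(55, 65), fs_target = 250) {
  if (fs != fs_target) {
    y <- resample_recording(recording(y, fs), fs_target)$data[, 1]
  }
  n <- length(y)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  yw <- (y - mean(y)) * w
  half <- floor(n / 2)
  psd <- Mod(stats::fft(yw)[1:(half + 1)])^2 / (fs_target * sum(w^2))
  psd[2:half] <- 2 * psd[2:half]
  freqs <- (0:half) * fs_target / n
  df <- fs_target / n
  sum(psd[freqs >= band[1] & freqs <= band[2]]) * df
}

#' Device-concordance report for two simultaneously recorded traces
#'
#' Both traces are resampled to `fs_target` (250 Hz), trimmed to a common
#' length, and compared via Pearson correlation plus per-trace Hjorth
#' parameters, kurtosis, artifact spike count and 55-65-Hz power.
#'
#' @param a,b [recording()] objects (first channel used) or numeric
#'   vectors with `fs_a` / `fs_b` supplied.
#' @param fs_a,fs_b Sampling rates when `a` / `b` are plain vectors.
#' @param fs_target Comparison sampling rate (default 250 Hz).
#' @return A `concordance_report`: list with `pearson_r` and a two-row
#'   `metrics` tibble.
#' @export
concordance_report <- function(a, b, fs_a = NULL, fs_b = NULL,
                               fs_target = 250) {
  as_chan <- function(x, fs) {
    if (inherits(x, "recording")) {
      list(y = x$data[, 1], fs = x$fs)
    } else list(y = as.numeric(x), fs = fs)
  }
  ca <- as_chan(a, fs_a); cb <- as_chan(b, fs_b)
  if (is.null(ca$fs) || is.null(cb$fs)) {
    stop_neurowire("sampling rates required for plain vectors", "bad_config")
  }
  ya <- if (ca$fs == fs_target) ca$y else
    resample_recording(recording(ca$y, ca$fs), fs_target)$data[, 1]
  yb <- if (cb$fs == fs_target) cb$y else
    resample_recording(recording(cb$y, cb$fs), fs_target)$data[, 1]
  L <- min(length(ya), length(yb))
  ya <- ya[seq_len(L)]; yb <- yb[seq_len(L)]
  metric_row <- function(y, label) {
    hj <- hjorth_params(y, fs_target)
    tibble::tibble(trace = label, activity = hj$activity,
                   mobility = hj$mobility, complexity = hj$complexity,
                   kurtosis = kurtosis_pearson(y),
                   artifact_spike_count = artifact_spike_count(y, fs_target),
                   power_60hz = power_60hz(y, fs_target))
  }
  structure(list(
    pearson_r = stats::cor(ya, yb),
    metrics = dplyr::bind_rows(metric_row(ya, "a"), metric_row(yb, "b")),
    fs_target = fs_target, n = L
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat(sprintf("<concordance_report> r = %.4f over %d samples @ %g Hz\n",
              x$pearson_r, x$n, x$fs_target))
  print(x$metrics)
  invisible(x)
}

#' @export
tidy.concordance_report <- function(x, ...) x$metrics

#' @export
glance.concordance_report <- function(x, ...) {
  tibble::tibble(pearson_r = x$pearson_r, n = x$n, fs_target = x$fs_target)
}
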