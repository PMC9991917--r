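#' Continuous wavelet scalogram (analytic Morse wavelet)
#'
#' Computes a time-frequency power scalogram with a generalized Morse
#' wavelet (symmetry parameter `gamma`, time-bandwidth product
#' `time_bandwidth`; the defaults gamma = 3, time-bandwidth = 60 give a
#' smooth, nearly symmetric analytic wavelet). Frequencies are laid out on
#' a logarithmic axis, 70 points from 1 to 125 Hz by default. Power is the
#' squared magnitude of the coefficients, so it scales quadratically with
#' input amplitude. Input is expected to be z-scored.
#'
#' @param x Numeric series (one channel).
#' @param fs Sampling rate in Hz.
#' @param n_freqs Number of log-spaced frequency points (default 70).
#' @param f_range_hz Frequency range, default `c(1, 125)` (clipped to the
#'   Nyquist range).
#' @param gamma,time_bandwidth Morse wavelet parameters.
#' @return A `scalogram`: list with `power` (time x frequency), `freqs_hz`,
#'   `fs`, `coi` (cone-of-influence flags, TRUE where edge effects reach)
#'   and `normalization`.
#' @export
cwt_scalogram <- function(x, fs, n_freqs = 70, f_range_hz = c(1, 125),
                          gamma = 3, time_bandwidth = 60) {
  n <- length(x)
  f_hi <- min(f_range_hz[2], 0.5 * fs * 0.999)
  freqs <- exp(seq(log(f_range_hz[1]), log(f_hi), length.out = n_freqs))
  beta <- time_bandwidth / gamma
  wp <- (beta / gamma)^(1 / gamma)       # peak of w^beta exp(-w^gamma)
  n2 <- stats::nextn(n, 2)               # zero-pad for FFT speed
  X <- stats::fft(c(x, numeric(n2 - n)))
  w <- 2 * pi * (seq_len(n2) - 1) / n2   # rad/sample, one-sided use
  power <- matrix(0, n, n_freqs)
  coi <- matrix(FALSE, n, n_freqs)
  half <- floor(n2 / 2)
  pos <- 2:(half + 1)                    # strictly positive frequencies
  t_idx <- seq_len(n)
  for (k in seq_len(n_freqs)) {
    w0 <- 2 * pi * freqs[k] / fs
    a <- wp / w0
    psi <- numeric(n2)
    lw <- log(w[pos] * a)
    psi[pos] <- 2 * exp(beta * lw - (w[pos] * a)^gamma -
                          (beta * log(wp) - wp^gamma))
    coef <- stats::fft(X * psi, inverse = TRUE)[seq_len(n)] / n2
    power[, k] <- Mod(coef)^2
    # temporal footprint ~ sqrt(beta*gamma)/w0 samples on each edge
    fp <- ceiling(sqrt(beta * gamma) / w0)
    coi[, k] <- t_idx <= fp | t_idx > n - fp
  }
  structure(list(power = power, freqs_hz = freqs, fs = fs, coi = coi,
                 normalization = "morse_peak2"),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d samples x %d freqs (%.3g-%.3g Hz) @ %g Hz\n",
              nrow(x$power), length(x$freqs_hz), min(x$freqs_hz),
              max(x$freqs_hz), x$fs))
  invisible(x)
}

#' Tidy a scalogram into long format
#' @param x A `scalogram`.
#' @param ... Unused.
#' @return Tibble with `time_s`, `freq_hz`, `power`, `in_coi`.
#' @export
tidy.scalogram <- function(x, ...) {
  tibble::tibble(
    time_s = rep((seq_len(nrow(x$power)) - 1) / x$fs, length(x$freqs_hz)),
    freq_hz = rep(x$freqs_hz, each = nrow(x$power)),
    power = as.vector(x$power),
    in_coi = as.vector(x$coi))
}

#' @export
autoplot.scalogram <- function(object, ...) {
  df <- tidy.scalogram(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = log10(.data$power + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::scale_fill_viridis_c(name = "log10 power") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)")
}

#' One-sided FFT power spectrum
#'
#' The transform length is the largest power of 2 strictly less than the
#' series length; coefficients are normalized by the transform length and
#' the one-sided power is twice the squared magnitude (DC and Nyquist bins
#' are not doubled).
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @return Tibble with `freq_hz` and `power`.
#' @export
fft_power <- function(x, fs) {
  n <- length(x)
  nfft <- 2^floor(log2(n - 1e-9))
  if (nfft < 2) stop_neurowire("series too short for fft_power", "bad_config")
  c0 <- stats::fft(x[seq_len(nfft)]) / nfft
  half <- nfft / 2
  pw <- 2 * Mod(c0[1:(half + 1)])^2
  pw[1] <- pw[1] / 2
  pw[half + 1] <- pw[half + 1] / 2
  tibble::tibble(freq_hz = (0:half) * fs / nfft, power = pw)
}

#' Welch power spectral density
#'
#' Hamming-windowed averaged periodograms; defaults to 8 segments with 50%
#' overlap. Density scaling: the integral of the PSD over frequency
#' approximates the series variance.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param n_segments Number of segments (default 8).
#' @param overlap Fractional overlap (default 0.5).
#' @return Tibble with `freq_hz` and `psd` (power / Hz).
#' @export
welch_psd <- function(x, fs, n_segments = 8, overlap = 0.5) {
  n <- length(x)
  L <- floor(n / (1 + (n_segments - 1) * (1 - overlap)))
  if (L < 8) stop_neurowire("series too short for welch_psd", "bad_config")
  step <- max(1L, floor(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  U <- fs * sum(w^2)
  half <- floor(L / 2)
  acc <- numeric(half + 1)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- Mod(stats::fft(seg)[1:(half + 1)])^2 / U
    P[2:half] <- 2 * P[2:half]
    if (L %% 2 == 1) P[half + 1] <- 2 * P[half + 1]
    acc <- acc + P
  }
  tibble::tibble(freq_hz = (0:half) * fs / L, psd = acc / length(starts))
}

#' BOSC-style frequency grid
#'
#' 0.25-Hz increments below 30 Hz (starting at 3 Hz) and 1-Hz increments
#' from 30 to 90 Hz: 169 points in total.
#'
#' @return Numeric vector of grid frequencies in Hz.
#' @export
bosc_grid <- function() c(seq(3, 29.75, by = 0.25), seq(30, 90, by = 1))

#' Fixed-cycle Morlet bandpower series
#'
#' Wavelet power (Morlet with `n_cycles` cycles, default 6) is computed at
#' every grid frequency inside `band_hz` and summed across frequencies,
#' giving a bandpower time series. Band membership is half-open
#' `[low, high)` except that the top of the grid (90 Hz) is included when
#' `high >= 90`, so adjacent bands add exactly. With `normalize = TRUE`
#' (default) the series is z-scored over its full extent.
#'
#' @param x Numeric series (one channel).
#' @param fs Sampling rate in Hz.
#' @param band_hz Band `(low, high)`, e.g. `c(3, 12)` for theta.
#' @param n_cycles Wavelet cycles (default 6).
#' @param grid_freqs Frequency grid (default [bosc_grid()]), clipped to
#'   the Nyquist range.
#' @param normalize Z-score the series (default TRUE).
#' @return A `bandpower_series`: tibble with `time_s` and `value`, plus
#'   attributes `band_hz`, `fs`, `raw` (unnormalized sum).
#' @export
bosc_bandpower <- function(x, fs, band_hz = c(3, 12), n_cycles = 6,
                           grid_freqs = bosc_grid(), normalize = TRUE) {
  grid_max <- max(grid_freqs)
  sel <- grid_freqs >= band_hz[1] &
    (grid_freqs < band_hz[2] | (band_hz[2] >= grid_max &
                                  grid_freqs == grid_max))
  freqs <- grid_freqs[sel & grid_freqs < 0.5 * fs * 0.999]
  if (!length(freqs)) {
    stop_neurowire("no grid frequencies inside band", "bad_config")
  }
  n <- length(x)
  n2 <- stats::nextn(n, 2)             # zero-pad for FFT speed
  X <- stats::fft(c(x, numeric(n2 - n)))
  w <- 2 * pi * (seq_len(n2) - 1) / n2
  half <- floor(n2 / 2)
  pos <- 2:(half + 1)
  total <- numeric(n)
  for (f in freqs) {
    w0 <- 2 * pi * f / fs
    sf <- w0 / n_cycles                # spectral width for n-cycle wavelet
    psi <- numeric(n2)
    psi[pos] <- 2 * exp(-(w[pos] - w0)^2 / (2 * sf^2))
    coef <- stats::fft(X * psi, inverse = TRUE)[seq_len(n)] / n2
    total <- total + Mod(coef)^2
  }
  vals <- if (normalize) (total - mean(total)) / stats::sd(total) else total
  out <- tibble::tibble(time_s = (seq_len(n) - 1) / fs, value = vals)
  attr(out, "band_hz") <- band_hz
  attr(out, "fs") <- fs
  attr(out, "raw") <- total
  attr(out, "grid_freqs") <- freqs
  class(out) <- c("bandpower_series", class(out))
  out
}

#' Per-channel z-scored bandpower of a recording
#'
#' @param rec A [recording()].
#' @param band_hz Band `(low, high)` in Hz.
#' @param n_cycles Wavelet cycles (default 6).
#' @return Matrix time x channel of z-scored bandpower.
#' @export
recording_bandpower <- function(rec, band_hz = c(3, 12), n_cycles = 6) {
  stopifnot(inherits(rec, "recording"))
  out <- apply(rec$data, 2, function(x)
    bosc_bandpower(x, rec$fs, band_hz, n_cycles)$value)
  colnames(out) <- rec$channel_ids
  out
}

#' @export
autoplot.bandpower_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = sprintf("z-scored %g-%g Hz bandpower",
                              attr(object, "band_hz")[1],
                              attr(object, "band_hz")[2]))
}
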