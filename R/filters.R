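#' Filter specification
#'
#' Describes an IIR filter to apply to a [recording()]. High-, low- and
#' band-pass filters use a Butterworth design (maximally flat passband);
#' the notch is a second-order IIR with quality factor `q` (default 30,
#' i.e. ~2 Hz wide at 60 Hz). Filters are realized as cascaded
#' second-order sections so that high orders stay numerically stable at
#' cutoffs far below the sampling rate (a 1-Hz high-pass on a 38.6-kHz
#' recording, for instance). A band-pass is realized as a high-pass /
#' low-pass cascade of the stated order per edge.
#'
#' @param kind `"highpass"`, `"lowpass"`, `"bandpass"` or `"notch"`.
#' @param cutoffs Cutoff frequency in Hz; two values for `bandpass`, the
#'   center frequency for `notch`.
#' @param order Filter order (>= 1); ignored for `notch`.
#' @param q Notch quality factor.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("highpass", "lowpass", "bandpass", "notch"),
                        cutoffs, order = 8, q = 30) {
  kind <- match.arg(kind)
  if (order < 1) stop_neurowire("filter order must be >= 1", "bad_filter")
  n_cut <- if (kind == "bandpass") 2L else 1L
  if (length(cutoffs) != n_cut) {
    stop_neurowire(sprintf("%s needs %d cutoff(s)", kind, n_cut), "bad_filter")
  }
  if (any(cutoffs <= 0)) stop_neurowire("cutoffs must be > 0", "bad_filter")
  if (kind == "bandpass" && cutoffs[1] >= cutoffs[2]) {
    stop_neurowire("bandpass cutoffs must be increasing", "bad_filter")
  }
  structure(list(kind = kind, cutoffs = as.numeric(cutoffs),
                 order = as.integer(order), q = q, design = "butter"),
            class = "filter_spec")
}

# bilinear transform s = (z-1)/(z+1) of an analog section given ascending
# polynomial coefficients (constant, s, s^2); returns digital b, a
bilinear_section <- function(B, A) {
  if (length(B) == 3) {
    num <- c(B[1] + B[2] + B[3], 2 * B[1] - 2 * B[3], B[1] - B[2] + B[3])
    den <- c(A[1] + A[2] + A[3], 2 * A[1] - 2 * A[3], A[1] - A[2] + A[3])
  } else {
    num <- c(B[1] + B[2], B[1] - B[2])
    den <- c(A[1] + A[2], A[1] - A[2])
  }
  list(b = num / den[1], a = den / den[1])
}

# Butterworth high/low-pass as a list of second-order (plus one first-order
# when `order` is odd) digital sections; w = cutoff as fraction of Nyquist
butter_sections <- function(order, w, type = c("low", "high")) {
  type <- match.arg(type)
  wc <- tan(pi * w / 2)              # prewarped analog cutoff
  n_pairs <- order %/% 2
  sections <- list()
  for (k in seq_len(n_pairs)) {
    re_p <- cos(pi * (2 * k + order - 1) / (2 * order))   # Re of pole pair
    A <- c(wc^2, -2 * re_p * wc, 1)
    B <- if (type == "low") c(wc^2, 0, 0) else c(0, 0, 1)
    sections[[k]] <- bilinear_section(B, A)
  }
  if (order %% 2 == 1) {
    A <- c(wc, 1)
    B <- if (type == "low") c(wc, 0) else c(0, 1)
    sections[[n_pairs + 1]] <- bilinear_section(B, A)
  }
  sections
}

design_filter <- function(spec, fs) {
  nyq <- fs / 2
  if (any(spec$cutoffs >= nyq)) {
    stop_neurowire(sprintf("cutoff %g Hz at or above Nyquist (%g Hz)",
                           max(spec$cutoffs), nyq), "bad_filter")
  }
  switch(spec$kind,
    notch = {
      # RBJ biquad notch
      w0 <- 2 * pi * spec$cutoffs / fs
      alpha <- sin(w0) / (2 * spec$q)
      b <- c(1, -2 * cos(w0), 1)
      a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
      list(list(b = b / a[1], a = a / a[1]))
    },
    lowpass = butter_sections(spec$order, spec$cutoffs / nyq, "low"),
    highpass = butter_sections(spec$order, spec$cutoffs / nyq, "high"),
    bandpass = c(
      butter_sections(spec$order, spec$cutoffs[1] / nyq, "high"),
      butter_sections(spec$order, spec$cutoffs[2] / nyq, "low"))
  )
}

filter_vector <- function(x, sections, zero_phase = TRUE) {
  for (s in sections) {
    arma <- signal::Arma(b = s$b, a = s$a)
    x <- if (zero_phase) {
      as.numeric(signal::filtfilt(arma, x))
    } else {
      as.numeric(signal::filter(arma, x))
    }
  }
  x
}

#' Apply an IIR filter to every channel of a recording
#'
#' Zero-phase (forward-backward) filtering is the default for offline
#' analysis; set `zero_phase = FALSE` for causal stages such as the
#' phase-locked stimulation simulator.
#'
#' @param rec A [recording()].
#' @param spec A [filter_spec()].
#' @param zero_phase Forward-backward filtering if `TRUE`.
#' @return A filtered `recording` of identical shape and sampling rate.
#' @examples
#' rec <- recording(sin(2 * pi * 60 * (0:999) / 1000), fs = 1000)
#' out <- apply_filter(rec, filter_spec("notch", 60))
#' @export
apply_filter <- function(rec, spec, zero_phase = TRUE) {
  stopifnot(inherits(rec, "recording"), inherits(spec, "filter_spec"))
  sections <- design_filter(spec, rec$fs)
  out <- rec
  out$data <- apply(rec$data, 2, filter_vector, sections = sections,
                    zero_phase = zero_phase)
  if (is.vector(out$data)) out$data <- matrix(out$data, ncol = 1)
  colnames(out$data) <- rec$channel_ids
  out
}

#' Resample a recording
#'
#' Polyphase FIR resampling (anti-alias filtered on downsampling). The
#' output length is `round(n * target_fs / fs)`.
#'
#' @param rec A [recording()].
#' @param target_fs Target sampling rate in Hz.
#' @return A `recording` at `target_fs`.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "recording"))
  if (!is.numeric(target_fs) || length(target_fs) != 1 || target_fs <= 0) {
    stop_neurowire("target_fs must be positive", "bad_fs")
  }
  if (target_fs == rec$fs) return(rec)
  frac <- ratio_approx(target_fs / rec$fs)
  n_out <- round(nrow(rec$data) * target_fs / rec$fs)
  out_cols <- apply(rec$data, 2, function(x) {
    y <- as.numeric(signal::resample(x, frac[1], frac[2]))
    length(y) <- n_out            # pad/trim to the contracted length
    y[is.na(y)] <- 0
    y
  })
  if (is.vector(out_cols)) out_cols <- matrix(out_cols, ncol = 1)
  recording(out_cols, fs = target_fs, channel_ids = rec$channel_ids,
            t0 = rec$t0, units = rec$units)
}

# rational approximation p/q of a positive ratio
ratio_approx <- function(r, max_den = 10000) {
  best <- c(1, 1); err <- Inf
  for (q in 1:max_den) {
    p <- round(r * q)
    if (p < 1) next
    e <- abs(p / q - r)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  best
}

#' Z-score a recording
#'
#' @param rec A [recording()].
#' @param per_channel Normalize each channel separately (default) or use
#'   the grand mean/SD of all channels.
#' @return A `recording` with (per-channel) mean 0 and variance 1.
#' @export
zscore_recording <- function(rec, per_channel = TRUE) {
  stopifnot(inherits(rec, "recording"))
  out <- rec
  if (per_channel) {
    sds <- apply(rec$data, 2, stats::sd)
    bad <- which(sds == 0 | !is.finite(sds))
    if (length(bad)) {
      stop_neurowire(sprintf("constant channel(s): %s",
                             paste(rec$channel_ids[bad], collapse = ", ")),
                     "constant_channel")
    }
    out$data <- scale(rec$data)
    attr(out$data, "scaled:center") <- NULL
    attr(out$data, "scaled:scale") <- NULL
  } else {
    s <- stats::sd(as.vector(rec$data))
    if (s == 0) stop_neurowire("constant recording", "constant_channel")
    out$data <- (rec$data - mean(rec$data)) / s
  }
  out$units <- "z"
  out
}

# analytic signal via FFT; magnitude gives the envelope
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

envelope <- function(x) Mod(analytic_signal(x))
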