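#' Remove slow motion transients by high-pass filtering
#'
#' Slow transients from cable and body movement occupy the band below a few
#' hertz; they are removed with a zero-phase Butterworth high-pass. The
#' default 1-Hz cutoff follows the offline LFP pipeline; a 4-Hz cutoff is a
#' documented option covering the full slow-transient band.
#'
#' @param rec A [recording()].
#' @param cutoff_hz High-pass cutoff (default 1 Hz).
#' @param order Filter order (default 8).
#' @return The filtered `recording`.
#' @export
remove_slow_transients <- function(rec, cutoff_hz = 1, order = 8) {
  apply_filter(rec, filter_spec("highpass", cutoff_hz, order = order))
}

# fastICA-style symmetric-decorrelation ICA with a logcosh contrast.
# Deterministic: whitening via eigendecomposition and a seeded start.
ica_decompose <- function(X, n_components, seed = 1, tol = 1e-6,
                          max_iter = 500) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  C <- crossprod(Xc) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  if (eig$values[n_components] < 1e-12 * eig$values[1]) {
    stop_neurowire("channels too collinear for requested n_components",
                   "ica_failure")
  }
  K <- eig$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(1 / sqrt(eig$values[seq_len(n_components)]), n_components)
  Z <- Xc %*% K                       # whitened, n x m
  m <- n_components
  W <- with_seed(seed, matrix(stats::rnorm(m * m), m, m))
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  best_delta <- Inf
  best_W <- W
  for (it in seq_len(max_iter)) {
    WX <- Z %*% t(W)                  # n x m source estimates
    G <- tanh(WX)
    W1 <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), m) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < best_delta) { best_delta <- delta; best_W <- W }
    if (delta < tol) {
      return(list(S = Z %*% t(W), W = W, K = K, converged = TRUE,
                  iter = it, delta = delta))
    }
  }
  list(S = Z %*% t(best_W), W = best_W, K = K, converged = FALSE,
       iter = max_iter, delta = best_delta)
}

#' Detect sharp motion transients with ICA
#'
#' Decomposes the recording into `n_components` independent components,
#' selects the artifact component and thresholds the z-scored envelope of
#' its band-filtered trace. Detected intervals are maximal supra-threshold
#' runs padded by `pad_ms` on each side, merged when they overlap.
#'
#' The artifact component is auto-selected as the component whose
#' band-filtered trace has maximal kurtosis (sharp transients are far more
#' heavy-tailed than spiking backgrounds); pass `component` to override.
#' The detection statistic is the z-scored log-envelope: the analytic
#' (Hilbert) envelope is smoothed over `smooth_ms` and log-compressed
#' before z-scoring, which gives the statistic a light upper tail --
#' a 4-SD cut then fires rarely on artifact-free noise while large
#' transients exceed it by a wide margin.
#'
#' @param rec A [recording()].
#' @param n_components Number of ICA components (default 3).
#' @param band_hz Band used for the envelope (default 300-3,000 Hz, clipped
#'   to the recording's Nyquist range).
#' @param threshold_sd Threshold on the z-scored log-envelope (default 4).
#' @param pad_ms Padding added to each side of a supra-threshold run.
#' @param smooth_ms Envelope smoothing window (default 5 ms).
#' @param component Optional manual component index.
#' @param seed Seed for the ICA start.
#' @return A tibble of intervals `(start_s, end_s, start_sample,
#'   end_sample)` with the selected component index and the ICA fit in
#'   attributes `component` and `ica`.
#' @export
detect_sharp_transients <- function(rec, n_components = 3,
                                    band_hz = c(300, 3000),
                                    threshold_sd = 4, pad_ms = 1,
                                    smooth_ms = 5, component = NULL,
                                    seed = 1) {
  stopifnot(inherits(rec, "recording"))
  if (n_components > ncol(rec$data)) {
    stop_neurowire("n_components exceeds channel count", "bad_config")
  }
  fs <- rec$fs
  band <- c(max(band_hz[1], 1), min(band_hz[2], 0.45 * fs))
  fit <- ica_decompose(rec$data, n_components, seed = seed)
  restart <- 0
  while (!fit$converged && restart < 3) {
    # deterministic restarts from fresh seeded rotations
    restart <- restart + 1
    fit <- ica_decompose(rec$data, n_components,
                         seed = seed + 7919 * restart)
  }
  if (!fit$converged) {
    # a residual rotation in a near-Gaussian subspace is unidentifiable
    # and harmless for component selection; only an unstable fit is fatal
    if (fit$delta > 0.05) {
      stop_neurowire(sprintf(
        "ICA did not stabilize in %d iterations (%d restarts, delta %.3g)",
        fit$iter, restart, fit$delta), "ica_failure")
    }
    warning(sprintf(
      "ICA rotation not fully converged (delta %.2g); using best iterate",
      fit$delta))
  }
  sections <- design_filter(filter_spec("bandpass", band, order = 4), fs)
  filt <- apply(fit$S, 2, filter_vector, sections = sections)
  if (is.null(component)) {
    component <- which.max(apply(filt, 2, kurtosis_pearson))
  }
  env <- envelope(filt[, component])
  k <- max(1L, round(smooth_ms / 1000 * fs))
  if (k > 1) {
    sm <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
    sm[is.na(sm)] <- mean(env)
    env <- sm
  }
  env <- log(env + 1e-12)
  z <- (env - mean(env)) / stats::sd(env)
  above <- z > threshold_sd
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  pad <- round(pad_ms / 1000 * fs)
  iv <- tibble::tibble(start_sample = pmax(1L, starts[keep] - pad),
                       end_sample = pmin(nrow(rec$data), ends[keep] + pad))
  iv <- merge_intervals(iv)
  iv$start_s <- (iv$start_sample - 1) / fs
  iv$end_s <- iv$end_sample / fs      # half-open [start, end)
  attr(iv, "component") <- component
  attr(iv, "ica") <- fit
  iv
}

merge_intervals <- function(iv) {
  if (nrow(iv) < 2) return(iv)
  iv <- iv[order(iv$start_sample), ]
  out_s <- iv$start_sample[1]; out_e <- iv$end_sample[1]
  ss <- integer(); ee <- integer()
  for (i in 2:nrow(iv)) {
    if (iv$start_sample[i] <= out_e + 1L) {
      out_e <- max(out_e, iv$end_sample[i])
    } else {
      ss <- c(ss, out_s); ee <- c(ee, out_e)
      out_s <- iv$start_sample[i]; out_e <- iv$end_sample[i]
    }
  }
  tibble::tibble(start_sample = c(ss, out_s), end_sample = c(ee, out_e))
}

#' Interpolate artifact intervals and report the artifact-to-signal ratio
#'
#' Samples inside each interval are replaced, on every channel, by the
#' straight line between the samples just outside the interval; samples
#' outside the intervals are untouched. The artifact-to-signal time ratio
#' (ASTR) is the fraction of samples removed, in percent.
#'
#' @param rec A [recording()].
#' @param intervals Tibble with `start_sample` / `end_sample` columns
#'   (inclusive sample indices, as returned by
#'   [detect_sharp_transients()]), or `start_s` / `end_s` in seconds.
#' @return `list(rec, report)` where `report` is an `artifact_report` with
#'   `removed_intervals`, `astr_percent` and (if present on the intervals)
#'   the ICA `component_index`.
#' @export
interpolate_intervals <- function(rec, intervals) {
  stopifnot(inherits(rec, "recording"))
  n <- nrow(rec$data)
  if (is.null(intervals$start_sample)) {
    intervals$start_sample <- pmax(1L, round(intervals$start_s * rec$fs) + 1L)
    intervals$end_sample <- pmin(n, round(intervals$end_s * rec$fs))
  }
  iv <- merge_intervals(tibble::tibble(
    start_sample = as.integer(intervals$start_sample),
    end_sample = as.integer(intervals$end_sample)))
  data <- rec$data
  removed <- 0L
  for (i in seq_len(nrow(iv))) {
    s <- iv$start_sample[i]; e <- iv$end_sample[i]
    if (e < s) next
    lo <- max(1L, s - 1L); hi <- min(n, e + 1L)
    for (ch in seq_len(ncol(data))) {
      y0 <- data[lo, ch]; y1 <- data[hi, ch]
      # line between the boundary samples; interval endpoints excluded
      data[s:e, ch] <- y0 + (y1 - y0) * ((s:e) - lo) / (hi - lo)
    }
    removed <- removed + (e - s + 1L)
  }
  out <- rec
  out$data <- data
  report <- structure(list(
    removed_intervals = iv,
    astr_percent = 100 * removed / n,
    n_removed = removed,
    n_total = n,
    component_index = attr(intervals, "component")
  ), class = "artifact_report")
  list(rec = out, report = report)
}

#' @export
print.artifact_report <- function(x, ...) {
  cat(sprintf("<artifact_report> %d interval(s), ASTR %.3f%%\n",
              nrow(x$removed_intervals), x$astr_percent))
  invisible(x)
}

#' @export
glance.artifact_report <- function(x, ...) {
  tibble::tibble(n_intervals = nrow(x$removed_intervals),
                 n_removed = x$n_removed, n_total = x$n_total,
                 astr_percent = x$astr_percent,
                 component_index = x$component_index %||% NA_integer_)
}

#' Score detected intervals against ground-truth artifact intervals
#'
#' An injected interval counts as recalled when at least one detected
#' interval overlaps it; a detected interval counts as a true positive when
#' it overlaps any injected interval.
#'
#' @param detected Tibble with `start_s` / `end_s`.
#' @param truth_intervals Tibble with `start_s` / `end_s` (ground truth).
#' @param tol_s Temporal slack applied to the truth intervals.
#' @return A one-row tibble with `recall`, `precision`, counts.
#' @export
score_intervals <- function(detected, truth_intervals, tol_s = 0.002) {
  overlaps <- function(a0, a1, b0, b1) a0 <= b1 & a1 >= b0
  hit_truth <- vapply(seq_len(nrow(truth_intervals)), function(i) {
    any(overlaps(detected$start_s, detected$end_s,
                 truth_intervals$start_s[i] - tol_s,
                 truth_intervals$end_s[i] + tol_s))
  }, logical(1))
  tp_det <- vapply(seq_len(nrow(detected)), function(i) {
    any(overlaps(detected$start_s[i], detected$end_s[i],
                 truth_intervals$start_s - tol_s,
                 truth_intervals$end_s + tol_s))
  }, logical(1))
  tibble::tibble(
    n_truth = nrow(truth_intervals), n_detected = nrow(detected),
    recall = if (nrow(truth_intervals)) mean(hit_truth) else NA_real_,
    precision = if (nrow(detected)) mean(tp_det) else NA_real_)
}
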