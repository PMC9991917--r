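#' Detect spikes by amplitude thresholding of the band-passed trace
#'
#' Each channel is band-pass filtered (default 300-3,000 Hz, zero phase),
#' the noise level is estimated robustly as `median(|x|) / 0.6745`, and
#' detections are placed at local extrema of `|x|` exceeding
#' `threshold_sd` times that level. Fixed-length snippets are cut around
#' each extremum.
#'
#' @param rec A [recording()].
#' @param band_hz Spike band (clipped to the Nyquist range).
#' @param threshold_sd Detection threshold in robust noise SDs (default 5).
#' @param snippet_ms Snippet length (default 1.5 ms, centered on the peak).
#' @return A `spike_detections` object: per-channel list with `times_s`,
#'   `snippets` (spikes x samples, recording units), `noise_sd`, `fs`.
#' @export
detect_spikes <- function(rec, band_hz = c(300, 3000), threshold_sd = 5,
                          snippet_ms = 1.5) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  band <- c(max(band_hz[1], 1), min(band_hz[2], 0.45 * fs))
  sections <- design_filter(filter_spec("bandpass", band, order = 4), fs)
  L <- max(3L, round(snippet_ms / 1000 * fs))
  pre <- L %/% 2
  chans <- lapply(seq_len(ncol(rec$data)), function(ch) {
    x <- filter_vector(rec$data[, ch], sections)
    noise_sd <- stats::median(abs(x)) / 0.6745
    thr <- threshold_sd * noise_sd
    a <- abs(x)
    n <- length(x)
    # local maxima of |x| above threshold, separated by >= half a snippet
    cand <- which(a > thr)
    cand <- cand[cand > pre & cand <= n - (L - pre)]
    is_peak <- cand[a[cand] >= a[pmax(1, cand - 1)] &
                    a[cand] >= a[pmin(n, cand + 1)]]
    times <- integer(0)
    if (length(is_peak)) {
      keep <- integer(length(is_peak)); k <- 0L; last <- -Inf
      for (i in is_peak) {
        if (i - last >= pre) { k <- k + 1L; keep[k] <- i; last <- i }
      }
      times <- keep[seq_len(k)]
    }
    snips <- if (length(times)) {
      t(vapply(times, function(i) x[(i - pre):(i - pre + L - 1L)],
               numeric(L)))
    } else matrix(numeric(0), 0, L)
    list(times_s = (times - 1) / fs, snippets = snips,
         noise_sd = noise_sd, channel_id = rec$channel_ids[ch])
  })
  structure(list(channels = chans, fs = fs, snippet_len = L, pre = pre),
            class = "spike_detections")
}

#' @export
print.spike_detections <- function(x, ...) {
  n <- vapply(x$channels, function(ch) length(ch$times_s), 0)
  cat(sprintf("<spike_detections> %d channel(s), %d spikes total\n",
              length(n), sum(n)))
  invisible(x)
}

new_unit_cluster <- function(channel_id, times_s, waveforms, fs,
                             isi_floor_ms = 3) {
  mw <- if (nrow(waveforms)) colMeans(waveforms) else numeric(ncol(waveforms))
  viol <- if (length(times_s) > 1) {
    sum(diff(times_s) < isi_floor_ms / 1000)
  } else 0L
  structure(list(channel_id = channel_id, spike_times_s = times_s,
                 waveforms = waveforms, mean_waveform = mw,
                 n_isi_violations = viol, fs = fs, accepted = NA),
            class = "unit_cluster")
}

#' @export
print.unit_cluster <- function(x, ...) {
  cat(sprintf(
    "<unit_cluster> %s: %d spikes, %d ISI violation(s), accepted: %s\n",
    x$channel_id, length(x$spike_times_s), x$n_isi_violations,
    as.character(x$accepted)))
  invisible(x)
}

#' Cluster detected spikes into putative units
#'
#' Snippets are projected onto their first two principal components and
#' clustered with k-means; the number of clusters (up to `k_max`) is picked
#' by mean silhouette width, falling back to a single cluster when no
#' multi-cluster split reaches a silhouette of 0.4. Deterministic for a
#' fixed seed.
#'
#' @param det A `spike_detections` object from [detect_spikes()].
#' @param k_max Maximum clusters per channel (default 5).
#' @param seed Integer seed for the k-means starts.
#' @param isi_floor_ms Refractory floor used to count ISI violations.
#' @return A list of `unit_cluster` objects (all channels pooled).
#' @export
cluster_spikes <- function(det, k_max = 5, seed = 1, isi_floor_ms = 3) {
  stopifnot(inherits(det, "spike_detections"))
  out <- list()
  for (ch in det$channels) {
    n <- length(ch$times_s)
    if (n == 0) next
    if (n < 10) {
      out <- c(out, list(new_unit_cluster(ch$channel_id, ch$times_s,
                                          ch$snippets, det$fs,
                                          isi_floor_ms)))
      next
    }
    pc <- stats::prcomp(ch$snippets, center = TRUE, scale. = FALSE)
    Y <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
    best_k <- 1L; best_sil <- -Inf; best_fit <- NULL
    d <- stats::dist(Y)
    for (k in 2:max(2, min(k_max, n - 1))) {
      if (k > k_max) break
      fit <- with_seed(seed + k, stats::kmeans(Y, centers = k,
                                               nstart = 5, iter.max = 50))
      sil <- mean(cluster::silhouette(fit$cluster, d)[, 3])
      if (sil > best_sil) { best_sil <- sil; best_k <- k; best_fit <- fit }
    }
    assign_k <- if (best_sil >= 0.4) best_fit$cluster else rep(1L, n)
    for (k in sort(unique(assign_k))) {
      idx <- which(assign_k == k)
      out <- c(out, list(new_unit_cluster(
        ch$channel_id, ch$times_s[idx],
        ch$snippets[idx, , drop = FALSE], det$fs, isi_floor_ms)))
    }
  }
  out
}

#' Cluster-acceptance rule
#'
#' A cluster is accepted as a single unit when it holds strictly more than
#' `min_spikes` spikes and at most `max_violation_frac` of them violate the
#' `isi_floor_ms` refractory floor.
#'
#' @param cl A `unit_cluster`.
#' @param min_spikes Strict lower bound on the spike count (default 250).
#' @param isi_floor_ms Refractory floor in ms (default 3).
#' @param max_violation_frac Maximum tolerated ISI-violation fraction
#'   (default 0.01).
#' @return Logical.
#' @export
accept_cluster <- function(cl, min_spikes = 250, isi_floor_ms = 3,
                           max_violation_frac = 0.01) {
  stopifnot(inherits(cl, "unit_cluster"))
  n <- length(cl$spike_times_s)
  if (n <= min_spikes) return(FALSE)
  viol <- if (n > 1) sum(diff(sort(cl$spike_times_s)) < isi_floor_ms / 1000)
          else 0L
  viol / n <= max_violation_frac
}

#' Smoothed firing-rate series
#'
#' Spikes are counted in non-overlapping `bin_ms` windows and the count
#' histogram is convolved with a unit-area Gaussian window of
#' `gauss_points` points (SD = `gauss_points`/6, so the window spans about
#' +/-3 SD). Mass cropped at the series edges is folded back onto the edge
#' bins, so the total spike count is conserved exactly.
#'
#' @param cl A `unit_cluster` (or numeric vector of spike times).
#' @param bin_ms Bin width (default 50 ms).
#' @param gauss_points Gaussian window length in bins (default 50).
#' @param duration_s Series duration; defaults to the last spike time.
#' @return A tibble with `time_s` (bin centers), `count` (smoothed counts
#'   per bin) and `rate_hz`.
#' @export
firing_rate <- function(cl, bin_ms = 50, gauss_points = 50,
                        duration_s = NULL) {
  times <- if (inherits(cl, "unit_cluster")) cl$spike_times_s else cl
  if (is.null(duration_s)) {
    duration_s <- if (length(times)) max(times) + bin_ms / 1000 else 1
  }
  bin_s <- bin_ms / 1000
  n_bins <- max(1L, ceiling(duration_s / bin_s))
  counts <- tabulate(pmin(n_bins, floor(times / bin_s) + 1L), n_bins)
  g <- stats::dnorm(seq_len(gauss_points) - (gauss_points + 1) / 2,
                    sd = gauss_points / 6)
  g <- g / sum(g)
  full <- stats::convolve(counts, rev(g), type = "open")
  # crop to length n_bins, folding edge mass back in
  off <- (gauss_points - 1) %/% 2
  sm <- full[off + seq_len(n_bins)]
  sm[1] <- sm[1] + sum(full[seq_len(off)])
  tail_idx <- (off + n_bins + 1):length(full)
  if (off + n_bins < length(full)) sm[n_bins] <- sm[n_bins] +
    sum(full[tail_idx])
  tibble::tibble(time_s = (seq_len(n_bins) - 0.5) * bin_s,
                 count = sm, rate_hz = sm / bin_s)
}

#' Unit signal-to-noise ratio
#'
#' SNR is the maximum absolute amplitude of the unit's average waveform
#' divided by three times the background-noise SD.
#'
#' @param cl A `unit_cluster` (or a numeric mean waveform).
#' @param noise_sd Background noise SD in the same units (300-3,000-Hz
#'   band, spikes excised; see [estimate_noise_sd()]).
#' @return Numeric SNR.
#' @export
unit_snr <- function(cl, noise_sd) {
  mw <- if (inherits(cl, "unit_cluster")) cl$mean_waveform else cl
  if (!length(mw)) return(0)
  max(abs(mw)) / (3 * noise_sd)
}

#' Background-noise SD with spikes excised
#'
#' @param rec A [recording()].
#' @param channel Channel index.
#' @param spike_times_s Spike times whose +/- `excise_ms` neighborhoods are
#'   dropped before taking the SD.
#' @param band_hz Band of the noise estimate (default 300-3,000 Hz).
#' @param excise_ms Half-width of the excision window per spike.
#' @return Numeric SD in recording units.
#' @export
estimate_noise_sd <- function(rec, channel = 1, spike_times_s = numeric(),
                              band_hz = c(300, 3000), excise_ms = 1.5) {
  fs <- rec$fs
  band <- c(max(band_hz[1], 1), min(band_hz[2], 0.45 * fs))
  x <- filter_vector(rec$data[, channel],
                     design_filter(filter_spec("bandpass", band, order = 4),
                                   fs))
  keep <- rep(TRUE, length(x))
  half <- round(excise_ms / 1000 * fs)
  for (t in spike_times_s) {
    i <- round(t * fs) + 1L
    keep[max(1, i - half):min(length(x), i + half)] <- FALSE
  }
  stats::sd(x[keep])
}

#' Yield and artifact-removal impact
#'
#' Yield is the number of accepted units per channel after artifact
#' removal. ARI is the mean percent change in per-unit spike counts across
#' units matched between the before/after sorts; units are matched greedily
#' by mean-waveform correlation (> 0.9), ties broken by spike-time overlap.
#'
#' @param before,after Lists of `unit_cluster` objects sorted before and
#'   after artifact removal.
#' @param n_channels Number of recording channels.
#' @param min_spikes,max_violation_frac Acceptance-rule parameters passed
#'   to [accept_cluster()].
#' @return A one-row tibble with `yield`, `ari_percent`, `n_accepted`,
#'   `n_matched`.
#' @export
yield_and_ari <- function(before, after, n_channels, min_spikes = 250,
                          max_violation_frac = 0.01) {
  acc <- vapply(after, accept_cluster, logical(1), min_spikes = min_spikes,
                max_violation_frac = max_violation_frac)
  matches <- match_units(before, after)
  ari <- if (nrow(matches)) {
    nb <- vapply(matches$before, function(i)
      length(before[[i]]$spike_times_s), 0)
    na <- vapply(matches$after, function(i)
      length(after[[i]]$spike_times_s), 0)
    mean(100 * (na - nb) / nb)
  } else NA_real_
  tibble::tibble(yield = sum(acc) / n_channels, ari_percent = ari,
                 n_accepted = sum(acc), n_matched = nrow(matches))
}

match_units <- function(before, after, min_cor = 0.9) {
  if (!length(before) || !length(after)) {
    return(tibble::tibble(before = integer(), after = integer()))
  }
  cors <- outer(seq_along(before), seq_along(after),
                Vectorize(function(i, j) {
    a <- before[[i]]$mean_waveform; b <- after[[j]]$mean_waveform
    if (before[[i]]$channel_id != after[[j]]$channel_id) return(-Inf)
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(-Inf)
    stats::cor(a, b)
  }))
  out_b <- integer(); out_a <- integer()
  while (TRUE) {
    best <- which(cors == max(cors), arr.ind = TRUE)
    if (!nrow(best) || max(cors) < min_cor) break
    if (nrow(best) > 1) {
      # tie-break on spike-time overlap (fraction of shared +/-1 ms spikes)
      ov <- apply(best, 1, function(ij) {
        tb <- before[[ij[1]]]$spike_times_s
        ta <- after[[ij[2]]]$spike_times_s
        if (!length(tb) || !length(ta)) return(0)
        mean(vapply(tb, function(t) any(abs(ta - t) < 1e-3), logical(1)))
      })
      best <- best[which.max(ov), , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    out_b <- c(out_b, i); out_a <- c(out_a, j)
    cors[i, ] <- -Inf; cors[, j] <- -Inf
  }
  tibble::tibble(before = out_b, after = out_a)
}

#' Summarize a list of unit clusters as a tibble
#'
#' @param x List of `unit_cluster` objects.
#' @param ... Unused.
#' @return One row per unit: channel, spike count, ISI violations,
#'   violation fraction, peak amplitude.
#' @export
tidy_units <- function(x, ...) {
  tibble::tibble(
    unit = seq_along(x),
    channel_id = vapply(x, function(u) u$channel_id, ""),
    n_spikes = vapply(x, function(u) length(u$spike_times_s), 0),
    n_isi_violations = vapply(x, function(u) u$n_isi_violations, 0),
    violation_frac = n_isi_violations / pmax(1, n_spikes),
    peak_uv = vapply(x, function(u)
      if (length(u$mean_waveform)) max(abs(u$mean_waveform)) else 0, 0))
}
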