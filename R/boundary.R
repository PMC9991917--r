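#' Split crossings into inner and boundary segments
#'
#' For each crossing `[t0, t1]`, the split points are `A = t0 + (t1-t0)/3`
#' and `B = t0 + 2(t1-t0)/3`; the inner condition is `[A, B)` and the
#' boundary condition is the final third `[B, t1)`.
#'
#' @param events An [event_stream()] with paired `crossing_start` /
#'   `crossing_end` events.
#' @return A `condition_split`: tibble with one row per crossing
#'   (`crossing`, `t_start`, `t_a`, `t_b`, `t_end`).
#' @export
split_crossings <- function(events) {
  starts <- events$time_s[events$kind == "crossing_start"]
  ends <- events$time_s[events$kind == "crossing_end"]
  if (length(starts) != length(ends)) {
    stop_neurowire("unpaired crossing events", "bad_events")
  }
  if (any(ends <= starts)) {
    stop_neurowire("crossing_end at or before crossing_start", "bad_events")
  }
  out <- tibble::tibble(
    crossing = seq_along(starts),
    t_start = starts,
    t_a = starts + (ends - starts) / 3,
    t_b = starts + 2 * (ends - starts) / 3,
    t_end = ends)
  class(out) <- c("condition_split", class(out))
  out
}

# sample indices (1-based) covered by half-open [start_s, end_s) intervals
interval_samples <- function(start_s, end_s, fs, n) {
  idx <- unlist(lapply(seq_along(start_s), function(i) {
    lo <- floor(start_s[i] * fs) + 1L
    hi <- ceiling(end_s[i] * fs)
    lo:min(hi, n)
  }))
  idx[idx >= 1 & idx <= n]
}

#' Condition means with subsample equalization
#'
#' The two conditions usually hold unequal numbers of samples; per
#' iteration the larger condition is randomly subsampled to the size of
#' the smaller one, and the reported mean is the average over `n_iter`
#' iterations (default 500). Seed-deterministic.
#'
#' @param bp Time x channel matrix of (z-scored) bandpower, as returned by
#'   [recording_bandpower()].
#' @param fs Sampling rate of `bp` rows.
#' @param split A `condition_split` from [split_crossings()].
#' @param n_iter Number of subsample iterations (default 500).
#' @param seed Integer seed.
#' @return Tibble with one row per channel: `channel`, `inner_mean`,
#'   `boundary_mean`.
#' @export
equalized_condition_means <- function(bp, fs, split, n_iter = 500,
                                      seed = 1) {
  bp <- as.matrix(bp)
  n <- nrow(bp)
  inner_idx <- interval_samples(split$t_a, split$t_b, fs, n)
  bound_idx <- interval_samples(split$t_b, split$t_end, fs, n)
  m <- min(length(inner_idx), length(bound_idx))
  if (m < 1) stop_neurowire("empty condition segments", "bad_events")
  with_seed(seed, {
    if (length(inner_idx) == length(bound_idx)) {
      inner_mean <- colMeans(bp[inner_idx, , drop = FALSE])
      bound_mean <- colMeans(bp[bound_idx, , drop = FALSE])
    } else if (length(inner_idx) > length(bound_idx)) {
      bound_mean <- colMeans(bp[bound_idx, , drop = FALSE])
      acc <- 0
      for (i in seq_len(n_iter)) {
        acc <- acc + colMeans(bp[sample(inner_idx, m), , drop = FALSE])
      }
      inner_mean <- acc / n_iter
    } else {
      inner_mean <- colMeans(bp[inner_idx, , drop = FALSE])
      acc <- 0
      for (i in seq_len(n_iter)) {
        acc <- acc + colMeans(bp[sample(bound_idx, m), , drop = FALSE])
      }
      bound_mean <- acc / n_iter
    }
    tibble::tibble(channel = colnames(bp) %||% paste0("ch", seq_len(ncol(bp))),
                   inner_mean = as.numeric(inner_mean),
                   boundary_mean = as.numeric(bound_mean))
  })
}

#' Paired sign-flip permutation test
#'
#' Tests whether the paired difference `a - b` has zero mean by randomly
#' flipping the sign of each pair's difference. Two-sided by default: the
#' p-value is the fraction of permuted |mean differences| at least as large
#' as the observed |mean difference| (ties count as exceedances). When all
#' `2^n` sign patterns fit within `n_perm` the null is enumerated
#' exhaustively; otherwise `n_perm` random patterns are drawn
#' (seed-deterministic).
#'
#' @param a,b Paired per-channel values (equal length >= 2).
#' @param n_perm Number of permutations (default 10,000).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @param smoothed Use the `(k+1)/(n+1)` estimator instead of `k/n`.
#' @param exact `"auto"` (default: exhaustive when feasible), `TRUE` or
#'   `FALSE`.
#' @return A `perm_test` object with `p_value`, `observed_diff`, `method`,
#'   `n_perm_used`.
#' @export
paired_permutation_test <- function(a, b, n_perm = 10000, seed = 1,
                                    alternative = c("two.sided", "greater",
                                                    "less"),
                                    smoothed = FALSE, exact = "auto") {
  alternative <- match.arg(alternative)
  if (length(a) != length(b) || length(a) < 2) {
    stop_neurowire("a and b must be paired with length >= 2", "bad_config")
  }
  d <- as.numeric(a) - as.numeric(b)
  n <- length(d)
  obs <- mean(d)
  use_exact <- isTRUE(exact) || (identical(exact, "auto") && 2^n <= n_perm)
  perm_means <- if (use_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    as.numeric(signs %*% d) / n
  } else {
    with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        mean(d * sample(c(-1, 1), n, replace = TRUE))
      }, numeric(1))
    })
  }
  k <- switch(alternative,
    two.sided = sum(abs(perm_means) >= abs(obs)),
    greater = sum(perm_means >= obs),
    less = sum(perm_means <= obs))
  m <- length(perm_means)
  p <- if (smoothed) (k + 1) / (m + 1) else k / m
  structure(list(p_value = p, observed_diff = obs, n = n,
                 n_perm_used = m, alternative = alternative,
                 exact = use_exact, smoothed = smoothed,
                 perm_means = perm_means),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> observed mean diff %.4g, p = %.4g (%s, %d %s permutations)\n",
    x$observed_diff, x$p_value, x$alternative, x$n_perm_used,
    if (x$exact) "exhaustive" else "random"))
  invisible(x)
}

#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(observed_diff = x$observed_diff, p_value = x$p_value,
                 n_pairs = x$n, n_perm = x$n_perm_used,
                 alternative = x$alternative, exact = x$exact)
}

#' @export
glance.perm_test <- function(x, ...) tidy.perm_test(x)

#' Boundary-versus-inner theta bandpower test for a walking session
#'
#' End-to-end wrapper: z-scored per-channel bandpower on the wavelet grid,
#' crossing split into inner/boundary conditions, subsample equalization of
#' condition sizes, and the paired sign-flip permutation test across
#' channels (boundary minus inner).
#'
#' @param rec A [recording()] of the walking session.
#' @param events The session's [event_stream()].
#' @param band_hz Bandpower band (default theta, 3-12 Hz).
#' @param n_iter Equalization iterations (default 500).
#' @param n_perm Permutations (default 10,000).
#' @param seed Integer seed.
#' @return A list with `test` (a `perm_test`), `means` (per-channel
#'   condition means) and `split`.
#' @export
boundary_theta_test <- function(rec, events, band_hz = c(3, 12),
                                n_iter = 500, n_perm = 10000, seed = 1) {
  bp <- recording_bandpower(rec, band_hz)
  split <- split_crossings(events)
  means <- equalized_condition_means(bp, rec$fs, split, n_iter = n_iter,
                                     seed = seed)
  test <- paired_permutation_test(means$boundary_mean, means$inner_mean,
                                  n_perm = n_perm, seed = seed + 1)
  list(test = test, means = means, split = split)
}
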