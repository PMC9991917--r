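#' Extract Gaussian-weighted event windows for decoding
#'
#' Cuts a 10-s chunk (default span -5 to +5 s) around every labeled word
#' onset at 250 Hz, multiplies it by a Gaussian window (SD 2.5 s, peak 1
#' at the onset) and packs the channels separately per brain region.
#' Recordings at other sampling rates are 0.1-Hz high-passed and
#' anti-alias resampled first. Events whose window would leave the
#' recording are dropped with a warning.
#'
#' @param rec A [recording()].
#' @param events An [event_stream()] with labeled `word_onset` events.
#' @param fs_target Decoding sampling rate (default 250 Hz).
#' @param span_s Window span around the onset (default `c(-5, 5)`).
#' @param sigma_s Gaussian SD (default 2.5 s).
#' @param regions Named list mapping region name to channel ids; default
#'   splits the channels into two halves `L` / `R`.
#' @return A `windowed_dataset`: list with `x` (per-region arrays
#'   events x time x channel), `labels`, `weights`, `onsets_s`, `fs`,
#'   `regions`.
#' @export
extract_windows <- function(rec, events, fs_target = 250,
                            span_s = c(-5, 5), sigma_s = 2.5,
                            regions = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (rec$fs != fs_target) {
    rec <- apply_filter(rec, filter_spec("highpass", 0.1, order = 2))
    rec <- resample_recording(rec, fs_target)
  }
  if (is.null(regions)) {
    nch <- ncol(rec$data)
    half <- max(1L, nch %/% 2L)
    regions <- list(L = rec$channel_ids[seq_len(half)],
                    R = rec$channel_ids[(half + 1):nch])
    if (nch == 1) regions <- list(L = rec$channel_ids)
  }
  on <- events[events$kind == "word_onset" & !is.na(events$label), ]
  L <- round((span_s[2] - span_s[1]) * fs_target)
  tt <- span_s[1] + (seq_len(L) - 1) / fs_target
  weights <- exp(-tt^2 / (2 * sigma_s^2))
  n_rec <- nrow(rec$data)
  starts <- round((on$time_s + span_s[1] - rec$t0) * fs_target) + 1L
  ok <- starts >= 1 & starts + L - 1L <= n_rec
  if (any(!ok)) {
    warning(sprintf("%d event(s) too close to the recording edge, dropped",
                    sum(!ok)))
  }
  on <- on[ok, ]; starts <- starts[ok]
  n <- nrow(on)
  xs <- lapply(regions, function(chans) {
    ci <- match(chans, rec$channel_ids)
    a <- array(0, c(n, L, length(ci)))
    for (i in seq_len(n)) {
      a[i, , ] <- rec$data[starts[i]:(starts[i] + L - 1L), ci,
                           drop = FALSE] * weights
    }
    a
  })
  structure(list(x = xs, labels = as.logical(on$label), weights = weights,
                 onsets_s = on$time_s, fs = fs_target, span_s = span_s,
                 regions = regions),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf(
    "<windowed_dataset> %d events x %d samples; regions: %s; %d remembered\n",
    length(x$labels), dim(x$x[[1]])[2],
    paste(names(x$x), collapse = ", "), sum(x$labels)))
  invisible(x)
}

#' Subset / combine windowed datasets
#'
#' @param ds,a,b `windowed_dataset` objects.
#' @param idx Event indices to keep.
#' @return A `windowed_dataset`.
#' @export
subset_windows <- function(ds, idx) {
  ds$x <- lapply(ds$x, function(a) a[idx, , , drop = FALSE])
  ds$labels <- ds$labels[idx]
  ds$onsets_s <- ds$onsets_s[idx]
  ds
}

#' @rdname subset_windows
#' @export
bind_windows <- function(a, b) {
  stopifnot(identical(names(a$x), names(b$x)))
  a$x <- lapply(seq_along(a$x), function(i) {
    d1 <- dim(a$x[[i]]); d2 <- dim(b$x[[i]])
    out <- array(0, c(d1[1] + d2[1], d1[2], d1[3]))
    out[seq_len(d1[1]), , ] <- a$x[[i]]
    out[d1[1] + seq_len(d2[1]), , ] <- b$x[[i]]
    out
  })
  names(a$x) <- names(b$x)
  a$labels <- c(a$labels, b$labels)
  a$onsets_s <- c(a$onsets_s, b$onsets_s)
  a
}

#' Balance classes by subsampling the majority class
#'
#' @param ds A `windowed_dataset`.
#' @param seed Integer seed.
#' @return A `windowed_dataset` with exactly equal class counts.
#' @export
balance_classes <- function(ds, seed = 1) {
  pos <- which(ds$labels); neg <- which(!ds$labels)
  m <- min(length(pos), length(neg))
  with_seed(seed, {
    keep <- sort(c(if (length(pos) > m) sample(pos, m) else pos,
                   if (length(neg) > m) sample(neg, m) else neg))
    subset_windows(ds, keep)
  })
}

#' Classification metrics for decoder predictions
#'
#' Precision, recall, F1 (`2PR/(P+R)`), accuracy at the given threshold,
#' plus an ROC curve by threshold sweep and its trapezoid AUC.
#'
#' @param predictions Predicted probabilities.
#' @param labels Logical (or 0/1) true labels.
#' @param threshold Decision threshold (default 0.5).
#' @return A `decode_report`: list with `f1`, `accuracy`, `precision`,
#'   `recall`, `auc`, `roc` (tibble) and per-event `predictions`.
#' @export
decode_metrics <- function(predictions, labels, threshold = 0.5) {
  labels <- as.logical(labels)
  pred_pos <- predictions >= threshold
  tp <- sum(pred_pos & labels); fp <- sum(pred_pos & !labels)
  fn <- sum(!pred_pos & labels)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  accuracy <- mean(pred_pos == labels)
  ord <- order(predictions, decreasing = TRUE)
  tpr <- c(0, cumsum(labels[ord]) / max(1, sum(labels)))
  fpr <- c(0, cumsum(!labels[ord]) / max(1, sum(!labels)))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(
    f1 = f1, accuracy = accuracy, precision = precision, recall = recall,
    auc = auc, threshold = threshold,
    roc = tibble::tibble(fpr = fpr, tpr = tpr),
    predictions = tibble::tibble(prob = predictions, label = labels)),
    class = "decode_report")
}

#' @export
print.decode_report <- function(x, ...) {
  cat(sprintf(
    "<decode_report> F1 %.3f, accuracy %.3f, AUC %.3f (P %.3f / R %.3f)\n",
    x$f1, x$accuracy, x$auc, x$precision, x$recall))
  invisible(x)
}

#' @export
glance.decode_report <- function(x, ...) {
  tibble::tibble(f1 = x$f1, accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, auc = x$auc, threshold = x$threshold,
                 n = nrow(x$predictions))
}

#' @export
tidy.decode_report <- function(x, ...) x$roc

#' @export
autoplot.decode_report <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_path() +
    ggplot2::labs(x = "false-positive rate", y = "true-positive rate",
                  subtitle = sprintf("AUC = %.3f", object$auc))
}

#' Train the base decoder with cross-validation
#'
#' Stratified k-fold cross-validation (default 5): for each fold the
#' remaining data are class-balanced and a fresh model is trained, then
#' scored on the held-out fold. A final model is fit on the full balanced
#' dataset. Deterministic for a fixed seed (single-threaded BLAS assumed).
#'
#' @param ds A `windowed_dataset`.
#' @param spec A [decoder_spec()].
#' @param folds Number of CV folds (default 5).
#' @param epochs Training epochs per fit (default from `spec`).
#' @param seed Integer seed.
#' @param verbose Print per-epoch loss.
#' @return List with `model` (final fit), `report` (a `decode_report` on
#'   the pooled out-of-fold predictions) and `fold_metrics` (tibble).
#' @export
train_base <- function(ds, spec = decoder_spec(), folds = 5, epochs = NULL,
                       seed = 1, verbose = FALSE) {
  stopifnot(inherits(ds, "windowed_dataset"))
  n <- length(ds$labels)
  branch_channels <- vapply(ds$x, function(a) dim(a)[3], 0L)
  fold_id <- with_seed(seed, {
    f <- integer(n)
    for (cl in c(TRUE, FALSE)) {
      idx <- sample(which(ds$labels == cl))
      f[idx] <- rep_len(seq_len(folds), length(idx))
    }
    f
  })
  pooled_p <- numeric(n)
  rows <- list()
  for (k in seq_len(folds)) {
    tr <- balance_classes(subset_windows(ds, which(fold_id != k)),
                          seed = seed + 100 + k)
    model_k <- init_decoder(spec, branch_channels, seed = seed + k)
    model_k <- fit_decoder(model_k, tr$x, as.numeric(tr$labels),
                           epochs = epochs, seed = seed + 200 + k,
                           verbose = verbose)
    te_idx <- which(fold_id == k)
    p <- predict_decoder(model_k, subset_windows(ds, te_idx))
    pooled_p[te_idx] <- p
    m <- decode_metrics(p, ds$labels[te_idx], spec$threshold)
    rows[[k]] <- tibble::tibble(fold = k, f1 = m$f1, accuracy = m$accuracy,
                                auc = m$auc, n_test = length(te_idx))
  }
  full <- balance_classes(ds, seed = seed + 99)
  model <- init_decoder(spec, branch_channels, seed = seed)
  model <- fit_decoder(model, full$x, as.numeric(full$labels),
                       epochs = epochs, seed = seed + 300,
                       verbose = verbose)
  list(model = model,
       report = decode_metrics(pooled_p, ds$labels, spec$threshold),
       fold_metrics = dplyr::bind_rows(rows))
}

#' Transfer learning with frozen feature layers and online prediction
#'
#' Mirrors the online protocol: the convolutional and LSTM coefficients of
#' a pretrained model are frozen; after each training block the incoming
#' chunks are pooled with all previous chunks, shuffled, and the dense
#' head is retrained for `epochs_per_block` epochs starting from its
#' previous coefficients. The remaining blocks are then predicted and
#' scored at the 0.5 threshold.
#'
#' @param model A pretrained `decoder_model`.
#' @param blocks List of per-block `windowed_dataset`s (task blocks in
#'   presentation order).
#' @param n_train_blocks Number of leading blocks used for retraining.
#' @param epochs_per_block Head-retraining epochs per block (default 20,
#'   emulating the fixed 30-s distractor budget).
#' @param seed Integer seed.
#' @return List with `model`, `report` (prediction-phase metrics),
#'   `frozen_identical` (logical) and `checksums`.
#' @export
transfer_and_predict <- function(model, blocks, n_train_blocks,
                                 epochs_per_block = 20, seed = 1) {
  if (n_train_blocks < 1 || n_train_blocks >= length(blocks)) {
    stop_neurowire("need 1 <= n_train_blocks < number of blocks",
                   "bad_config")
  }
  ck0 <- frozen_checksum(model)
  pool <- NULL
  for (b in seq_len(n_train_blocks)) {
    pool <- if (is.null(pool)) blocks[[b]] else
      bind_windows(pool, blocks[[b]])
    model <- fit_decoder(model, pool$x, as.numeric(pool$labels),
                         epochs = epochs_per_block, trainable = "head",
                         seed = seed + b)
  }
  ck1 <- frozen_checksum(model)
  pred_blocks <- blocks[(n_train_blocks + 1):length(blocks)]
  probs <- unlist(lapply(pred_blocks, function(bl)
    predict_decoder(model, bl)))
  labs <- unlist(lapply(pred_blocks, function(bl) bl$labels))
  list(model = model,
       report = decode_metrics(probs, labs, model$spec$threshold),
       frozen_identical = identical(ck0, ck1),
       checksums = c(before = ck0, after = ck1))
}

#' Split a windowed dataset into task blocks
#'
#' @param ds A `windowed_dataset`.
#' @param block Integer block id per event (e.g. `truth$block` from
#'   [gen_memory_session()]).
#' @return List of per-block `windowed_dataset`s.
#' @export
split_blocks <- function(ds, block) {
  lapply(sort(unique(block)), function(b) subset_windows(ds, which(block == b)))
}

#' Visualize conv2 filters by gradient ascent on the input
#'
#' Starting from an all-zero 10-s chunk, the input is adjusted by
#' L2-normalized gradient ascent to maximize the mean activation of one
#' second-layer convolutional filter; the optimized chunk is then
#' transformed to the time-frequency domain with the analytic-Morse CWT.
#' Filters whose activation gradient is identically zero (dead filters)
#' are flagged and yield an all-zero map.
#'
#' @param model A `decoder_model`.
#' @param branch Branch index (default 1).
#' @param filters Filter indices (default all conv2 filters).
#' @param steps Ascent steps (default 40).
#' @param step_size Step size after gradient normalization (default 1).
#' @param input_span_s Chunk length in seconds (default 10).
#' @param fs Sampling rate of the chunk (default 250).
#' @return Tibble with one row per filter: `filter`, `activation`, `dead`,
#'   and list-columns `chunk` (optimized input) and `map` (`scalogram`).
#' @export
visualize_filters <- function(model, branch = 1, filters = NULL,
                              steps = 40, step_size = 1,
                              input_span_s = 10, fs = 250) {
  spec <- model$spec
  br <- model$branches[[branch]]
  n_ch <- br$n_ch
  t_len <- round(input_span_s * fs)
  filters <- filters %||% seq_len(spec$conv2_filters)
  t1 <- conv_t_out(t_len, spec$conv1_kernel, spec$conv1_stride)
  rows <- lapply(filters, function(j) {
    x <- matrix(0, t_len, n_ch)          # flat (1*T) x C
    act <- 0; dead <- FALSE
    for (s in seq_len(steps)) {
      c1 <- flat_im2col(x, 1L, t_len, spec$conv1_kernel, spec$conv1_stride)
      z1 <- sweep(c1 %*% br$W1, 2, br$b1, `+`)
      a1 <- pmax(z1, 0)
      c2 <- flat_im2col(a1, 1L, t1, spec$conv2_kernel, spec$conv2_stride)
      z2 <- sweep(c2 %*% br$W2, 2, br$b2, `+`)
      a2 <- pmax(z2, 0)
      act <- mean(a2[, j])
      # d(mean act_j)/d(z2): uniform over time where the relu is active
      da2 <- matrix(0, nrow(z2), ncol(z2))
      da2[, j] <- (z2[, j] > 0) / nrow(z2)
      dc2 <- da2 %*% t(br$W2)
      da1 <- flat_col2im(dc2, 1L, t1, spec$conv1_filters,
                         spec$conv2_kernel, spec$conv2_stride)
      da1 <- da1 * (z1 > 0)
      dxcol <- da1 %*% t(br$W1)
      dx <- flat_col2im(dxcol, 1L, t_len, n_ch, spec$conv1_kernel,
                        spec$conv1_stride)
      g_norm <- sqrt(sum(dx^2))
      if (g_norm < 1e-12) { dead <- TRUE; break }
      x <- x + step_size * dx / g_norm
    }
    chunk <- x
    map <- if (dead) {
      structure(list(power = matrix(0, t_len, 1), freqs_hz = NA,
                     fs = fs, coi = matrix(FALSE, t_len, 1),
                     normalization = "dead"), class = "scalogram")
    } else {
      sums <- 0
      for (ch in seq_len(n_ch)) {
        sc <- cwt_scalogram(chunk[, ch], fs, n_freqs = 40,
                            f_range_hz = c(1, 40))
        sums <- sums + sc$power
      }
      sc$power <- sums
      sc
    }
    tibble::tibble(filter = j, activation = act, dead = dead,
                   chunk = list(chunk), map = list(map))
  })
  dplyr::bind_rows(rows)
}

#' Shallow baseline classifiers on the same windows
#'
#' Trains a baseline on a stratified half/half split of the dataset:
#' `svm_raw` (RBF SVM on the time-decimated chunks), `pca_svm` (SVM on the
#' leading principal components) or `alt_nn` (single-hidden-layer network
#' on the same components). Splits are identical across methods for a
#' given seed.
#'
#' @param ds A `windowed_dataset`.
#' @param method `"svm_raw"`, `"pca_svm"` or `"alt_nn"`.
#' @param seed Integer seed.
#' @param decimate Temporal decimation factor for the feature matrix
#'   (default 10).
#' @param n_pc Number of principal components for `pca_svm` / `alt_nn`.
#' @return A `decode_report` on the held-out half.
#' @export
baseline_classifiers <- function(ds, method = c("svm_raw", "pca_svm",
                                                "alt_nn"),
                                 seed = 1, decimate = 10, n_pc = 20) {
  method <- match.arg(method)
  n <- length(ds$labels)
  keep_t <- seq(1, dim(ds$x[[1]])[2], by = decimate)
  feats <- do.call(cbind, lapply(ds$x, function(a) {
    m <- a[, keep_t, , drop = FALSE]
    dim(m) <- c(dim(m)[1], length(keep_t) * dim(a)[3])
    m
  }))
  tr_idx <- with_seed(seed, {
    sort(c(sample(which(ds$labels), sum(ds$labels) %/% 2),
           sample(which(!ds$labels), sum(!ds$labels) %/% 2)))
  })
  te_idx <- setdiff(seq_len(n), tr_idx)
  y <- factor(ds$labels, levels = c(FALSE, TRUE))
  if (method != "svm_raw") {
    pc <- stats::prcomp(feats[tr_idx, , drop = FALSE], center = TRUE)
    k <- min(n_pc, ncol(pc$rotation))
    tr_x <- pc$x[, seq_len(k), drop = FALSE]
    te_x <- scale(feats[te_idx, , drop = FALSE], center = pc$center,
                  scale = FALSE) %*% pc$rotation[, seq_len(k), drop = FALSE]
  } else {
    tr_x <- feats[tr_idx, , drop = FALSE]
    te_x <- feats[te_idx, , drop = FALSE]
  }
  prob <- if (method == "alt_nn") {
    fit <- with_seed(seed + 1, nnet::nnet(tr_x, as.numeric(ds$labels[tr_idx]),
                                          size = 8, decay = 1e-3,
                                          maxit = 200, trace = FALSE))
    as.numeric(stats::predict(fit, te_x))
  } else {
    fit <- with_seed(seed + 1, e1071::svm(tr_x, y[tr_idx],
                                          kernel = "radial",
                                          probability = TRUE))
    pr <- stats::predict(fit, te_x, probability = TRUE)
    attr(pr, "probabilities")[, "TRUE"]
  }
  decode_metrics(prob, ds$labels[te_idx])
}
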