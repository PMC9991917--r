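# Minimal batched neural-network engine for the memory decoder.
#
# Implements exactly the architecture the decoder needs -- per-region
# branches of two 1-D convolutions feeding an LSTM, concatenated into a
# dense head with a sigmoid output -- with full backpropagation (BPTT for
# the LSTM, in compiled code), inverted dropout, L2 weight decay and an
# RMSprop optimizer. Sequences are held as flat (n*T) x D matrices in
# block-time layout so convolutions are single BLAS GEMMs; all randomness
# (initialization, shuffling, dropout masks) is seed-deterministic.

#' Decoder hyperparameters
#'
#' Architecture of one branch: conv1 (32 filters), conv2 (64 filters), an
#' LSTM with 64 units (dropout 0.1, recurrent dropout 0.25); branch
#' outputs are concatenated into a 32-unit dense layer and a 1-unit
#' sigmoid classifier. Dropout after the other layers is 0.2,
#' optimization is RMSprop with learning rate 0.001, loss is binary
#' cross-entropy and the decision threshold is 0.5. The conv geometry
#' (kernel 50 / stride 25, then kernel 9 / stride 2) makes conv1 a bank
#' of learned 200-ms frame features hopping every 100 ms -- a
#' spectrogram-like frontend -- and gives conv2 a one-second receptive
#' field spanning several theta cycles; the recurrent-dropout default is
#' set for session-scale training sets (see the methods vignette) and
#' can be raised for large pooled corpora.
#'
#' @param conv1_filters,conv2_filters Filter counts (defaults 32, 64).
#' @param conv1_kernel,conv1_stride,conv2_kernel,conv2_stride Conv
#'   geometry in samples.
#' @param lstm_units LSTM width (default 64).
#' @param dense_units Dense head width (default 32).
#' @param dropout,lstm_dropout,lstm_recurrent_dropout Dropout rates.
#' @param l2 L2 penalty on conv/dense weights (default 1e-4).
#' @param learning_rate RMSprop learning rate (default 0.001).
#' @param batch_size Minibatch size (default 32).
#' @param epochs Default training epochs (default 120).
#' @param threshold Classification threshold (default 0.5).
#' @return A `decoder_spec` object.
#' @export
decoder_spec <- function(conv1_filters = 32, conv2_filters = 64,
                         conv1_kernel = 50, conv1_stride = 25,
                         conv2_kernel = 9, conv2_stride = 2,
                         lstm_units = 64, dense_units = 32,
                         dropout = 0.2, lstm_dropout = 0.1,
                         lstm_recurrent_dropout = 0.25, l2 = 1e-4,
                         learning_rate = 0.001, batch_size = 32,
                         epochs = 80, threshold = 0.5) {
  structure(as.list(environment()), class = "decoder_spec")
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_branch <- function(spec, n_ch) {
  H <- spec$lstm_units
  list(
    W1 = glorot(spec$conv1_kernel * n_ch, spec$conv1_filters),
    b1 = numeric(spec$conv1_filters),
    W2 = glorot(spec$conv2_kernel * spec$conv1_filters, spec$conv2_filters),
    b2 = numeric(spec$conv2_filters),
    Wl = glorot(spec$conv2_filters + H, 4 * H),
    bl = c(numeric(H), rep(1, H), numeric(2 * H)),   # forget-gate bias 1
    n_ch = n_ch)
}

#' Initialize a decoder model
#'
#' @param spec A [decoder_spec()].
#' @param branch_channels Named integer vector: channels per region branch.
#' @param seed Integer seed for the weight initialization.
#' @return A `decoder_model` object.
#' @export
init_decoder <- function(spec, branch_channels, seed = 1) {
  with_seed(seed, {
    branches <- lapply(branch_channels, function(nc) init_branch(spec, nc))
    H <- spec$lstm_units
    head <- list(
      Wd1 = glorot(H * length(branches), spec$dense_units),
      bd1 = numeric(spec$dense_units),
      Wd2 = glorot(spec$dense_units, 1),
      bd2 = numeric(1))
    structure(list(spec = spec, branches = branches, head = head,
                   regions = names(branch_channels), opt = NULL),
              class = "decoder_model")
  })
}

#' @export
print.decoder_model <- function(x, ...) {
  cat(sprintf("<decoder_model> %d branch(es): %s; LSTM %d, dense %d\n",
              length(x$branches), paste(x$regions, collapse = ", "),
              x$spec$lstm_units, x$spec$dense_units))
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# [n, T, C] array -> flat (n*T) x C matrix in block-time layout (free:
# the array's memory order already matches)
as_flat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

conv_t_out <- function(t_in, k, stride) (t_in - k) %/% stride + 1L

# im2col on a flat block-time matrix
flat_im2col <- function(xflat, n, t_in, k, stride) {
  c_in <- ncol(xflat)
  t_out <- conv_t_out(t_in, k, stride)
  out <- matrix(0, n * t_out, k * c_in)
  base <- (0:(t_out - 1L)) * stride * n
  for (o in seq_len(k)) {
    rows <- as.vector(outer(seq_len(n) + (o - 1L) * n, base, `+`))
    out[, ((o - 1L) * c_in + 1L):(o * c_in)] <- xflat[rows, , drop = FALSE]
  }
  out
}

# scatter-add transpose of flat_im2col
flat_col2im <- function(dmat, n, t_in, c_in, k, stride) {
  t_out <- nrow(dmat) / n
  dx <- matrix(0, n * t_in, c_in)
  base <- (0:(t_out - 1L)) * stride * n
  for (o in seq_len(k)) {
    rows <- as.vector(outer(seq_len(n) + (o - 1L) * n, base, `+`))
    dx[rows, ] <- dx[rows, , drop = FALSE] +
      dmat[, ((o - 1L) * c_in + 1L):(o * c_in), drop = FALSE]
  }
  dx
}

# rows of a full-dataset block-time matrix belonging to batch items `idx`
flat_rows <- function(idx, n_all, t_out) {
  as.vector(outer(idx, (0:(t_out - 1L)) * n_all, `+`))
}

drop_mask <- function(n_row, n_col, rate, training) {
  if (!training || rate <= 0) return(matrix(0, 0, 0))
  matrix((stats::runif(n_row * n_col) >= rate) / (1 - rate), n_row, n_col)
}

# forward through one branch (compiled); c1 is the precomputed conv1
# im2col matrix for this batch, t1 the conv1 output length
branch_forward <- function(br, spec, c1, n, t1, training, cache) {
  t2 <- conv_t_out(t1, spec$conv2_kernel, spec$conv2_stride)
  m1 <- drop_mask(n * t1, spec$conv1_filters, spec$dropout, training)
  m2 <- drop_mask(n * t2, spec$conv2_filters, spec$dropout, training)
  mask_in <- drop_mask(n, spec$conv2_filters, spec$lstm_dropout, training)
  mask_rec <- drop_mask(n, spec$lstm_units, spec$lstm_recurrent_dropout,
                        training)
  lf <- branch_forward_cpp(c1, br$W1, br$b1, br$W2, br$b2, br$Wl, br$bl,
                           m1, m2, mask_in, mask_rec, n, t1,
                           spec$conv2_kernel, spec$conv2_stride, cache)
  out <- list(h = lf$h, t1 = t1, t2 = t2)
  if (cache) {
    out$cpp <- lf$cache
    out$c1 <- c1
    out$m1 <- m1; out$m2 <- m2
    out$mask_in <- mask_in; out$mask_rec <- mask_rec
  }
  out
}

branch_backward <- function(br, spec, bc, dh, n, want_dx = FALSE,
                            t_in = 0, c_in = 0) {
  g <- branch_backward_cpp(bc$cpp, bc$c1, br$W1, br$W2, br$Wl, dh,
                           bc$m1, bc$m2, bc$mask_in, bc$mask_rec, n, bc$t1,
                           spec$conv2_kernel, spec$conv2_stride, spec$l2,
                           want_dx, spec$conv1_kernel, spec$conv1_stride,
                           t_in, c_in)
  g$bl <- as.numeric(g$bl)
  g$b1 <- as.numeric(g$b1)
  g$b2 <- as.numeric(g$b2)
  list(grads = g[c("W1", "b1", "W2", "b2", "Wl", "bl")],
       dx = g$dx)
}

# prepare per-branch conv1 im2col for a full dataset
prep_conv1 <- function(model, xs) {
  spec <- model$spec
  lapply(seq_along(model$branches), function(b) {
    x <- xs[[b]]
    d <- dim(x)
    flat_im2col(as_flat(x), d[1], d[2], spec$conv1_kernel, spec$conv1_stride)
  })
}

# full forward pass; xs: list of [n, T, C] arrays, one per branch, or a
# `pre` list from prep_conv1 with `idx` selecting batch items
decoder_forward <- function(model, xs = NULL, training = FALSE,
                            cache = FALSE, pre = NULL, idx = NULL,
                            n_all = NULL, t_in = NULL) {
  spec <- model$spec
  if (is.null(pre)) {
    n <- dim(xs[[1]])[1]
    t_in <- dim(xs[[1]])[2]
    pre <- prep_conv1(model, xs)
    idx <- seq_len(n)
    n_all <- n
  } else {
    n <- length(idx)
  }
  t1 <- conv_t_out(t_in, spec$conv1_kernel, spec$conv1_stride)
  rows <- if (n == n_all && all(idx == seq_len(n_all))) NULL else
    flat_rows(idx, n_all, t1)
  hs <- list(); br_caches <- list()
  for (b in seq_along(model$branches)) {
    c1 <- if (is.null(rows)) pre[[b]] else pre[[b]][rows, , drop = FALSE]
    bf <- branch_forward(model$branches[[b]], spec, c1, n, t1, training,
                         cache)
    hs[[b]] <- bf$h
    if (cache) br_caches[[b]] <- bf
  }
  hcat <- do.call(cbind, hs)
  z1 <- sweep(hcat %*% model$head$Wd1, 2, model$head$bd1, `+`)
  a1 <- pmax(z1, 0)
  md <- drop_mask(nrow(a1), ncol(a1), spec$dropout, training)
  a1d <- if (length(md)) a1 * md else a1
  logit <- sweep(a1d %*% model$head$Wd2, 2, model$head$bd2, `+`)
  p <- sigmoid(logit)
  out <- list(p = as.numeric(p))
  if (cache) {
    out$cache <- list(branches = br_caches, hcat = hcat, z1pos = z1 > 0,
                      a1d = a1d, md = md, n = n)
  }
  out
}

# gradients of mean binary cross-entropy over the batch
decoder_backward <- function(model, fw, y) {
  spec <- model$spec
  cache <- fw$cache
  n <- cache$n
  dlogit <- matrix((fw$p - y) / n, n, 1)
  g_head <- list(
    Wd2 = crossprod(cache$a1d, dlogit) + spec$l2 * model$head$Wd2,
    bd2 = sum(dlogit))
  da1 <- (dlogit %*% t(model$head$Wd2)) * cache$z1pos
  if (length(cache$md)) da1 <- da1 * cache$md
  g_head$Wd1 <- crossprod(cache$hcat, da1) + spec$l2 * model$head$Wd1
  g_head$bd1 <- colSums(da1)
  dhcat <- da1 %*% t(model$head$Wd1)
  H <- spec$lstm_units
  g_branches <- vector("list", length(model$branches))
  for (b in seq_along(model$branches)) {
    dh <- dhcat[, ((b - 1) * H + 1):(b * H), drop = FALSE]
    bb <- branch_backward(model$branches[[b]], spec,
                          cache$branches[[b]], dh, n)
    g_branches[[b]] <- bb$grads
  }
  list(branches = g_branches, head = g_head)
}

# RMSprop step over the parameter tree; `which` limits the update
rmsprop_step <- function(model, grads, lr, which = "all", rho = 0.9,
                         eps = 1e-8) {
  if (is.null(model$opt)) {
    zero_like <- function(p) lapply(p, function(w) w * 0)
    model$opt <- list(branches = lapply(model$branches, function(b)
      zero_like(b[c("W1", "b1", "W2", "b2", "Wl", "bl")])),
      head = zero_like(model$head))
  }
  upd <- function(p, g, v) {
    v <- rho * v + (1 - rho) * g^2
    list(p = p - lr * g / (sqrt(v) + eps), v = v)
  }
  if (which == "all") {
    for (b in seq_along(model$branches)) {
      for (nm in c("W1", "b1", "W2", "b2", "Wl", "bl")) {
        u <- upd(model$branches[[b]][[nm]], grads$branches[[b]][[nm]],
                 model$opt$branches[[b]][[nm]])
        model$branches[[b]][[nm]] <- u$p
        model$opt$branches[[b]][[nm]] <- u$v
      }
    }
  }
  for (nm in c("Wd1", "bd1", "Wd2", "bd2")) {
    u <- upd(model$head[[nm]], grads$head[[nm]], model$opt$head[[nm]])
    model$head[[nm]] <- u$p
    model$opt$head[[nm]] <- u$v
  }
  model
}

# train in place for `epochs`; `trainable` = "all" or "head"
fit_decoder <- function(model, xs, y, epochs = NULL, trainable = "all",
                        seed = 1, verbose = FALSE) {
  spec <- model$spec
  epochs <- epochs %||% spec$epochs
  n <- length(y)
  t_in <- dim(xs[[1]])[2]
  pre <- prep_conv1(model, xs)
  history <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / spec$batch_size))
      loss <- 0
      for (bt in batches) {
        fw <- decoder_forward(model, training = TRUE, cache = TRUE,
                              pre = pre, idx = bt, n_all = n, t_in = t_in)
        p <- pmin(pmax(fw$p, 1e-12), 1 - 1e-12)
        loss <- loss - sum(y[bt] * log(p) + (1 - y[bt]) * log(1 - p))
        grads <- decoder_backward(model, fw, y[bt])
        model <- rmsprop_step(model, grads, spec$learning_rate, trainable)
      }
      history[ep] <- loss / n
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, history[ep]))
    }
  })
  model$history <- c(model$history, history)
  model
}

#' Predict remembered-class probabilities
#'
#' @param model A trained `decoder_model`.
#' @param ds A `windowed_dataset` (or list of branch arrays).
#' @return Numeric probabilities in `[0, 1]`.
#' @export
predict_decoder <- function(model, ds) {
  xs <- if (inherits(ds, "windowed_dataset")) ds$x else ds
  decoder_forward(model, xs, training = FALSE)$p
}

subset_branch_arrays <- function(xs, idx) {
  lapply(xs, function(a) a[idx, , , drop = FALSE])
}

# deterministic checksum of the frozen (conv + LSTM) parameters
frozen_checksum <- function(model) {
  vals <- unlist(lapply(model$branches, function(b)
    b[c("W1", "b1", "W2", "b2", "Wl", "bl")]), use.names = FALSE)
  sum(vals * rep_len(c(1, -0.5, 0.25), length(vals)))
}

#' Serialize a decoder to a portable JSON manifest
#'
#' Weights are stored as base64-encoded little-endian doubles, so a
#' save/load round-trip reproduces predictions bit-exactly.
#'
#' @param model A `decoder_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_decoder <- function(model, path) {
  enc <- function(w) list(dim = dim(w) %||% length(w),
                          data = jsonlite::base64_enc(writeBin(
                            as.numeric(w), raw(), size = 8,
                            endian = "little")))
  manifest <- list(
    spec = unclass(model$spec),
    regions = model$regions,
    branches = lapply(model$branches, function(b) {
      c(lapply(b[c("W1", "b1", "W2", "b2", "Wl", "bl")], enc),
        list(n_ch = b$n_ch))
    }),
    head = lapply(model$head, enc))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_decoder
#' @export
load_decoder <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  dec <- function(e) {
    w <- readBin(jsonlite::base64_dec(e$data), "double",
                 n = prod(unlist(e$dim)), size = 8, endian = "little")
    if (length(e$dim) == 2) dim(w) <- unlist(e$dim)
    w
  }
  spec <- do.call(decoder_spec, man$spec)
  branches <- lapply(man$branches, function(b) {
    out <- lapply(b[c("W1", "b1", "W2", "b2", "Wl", "bl")], dec)
    out$n_ch <- b$n_ch
    out
  })
  head <- lapply(man$head, dec)
  structure(list(spec = spec, branches = branches, head = head,
                 regions = man$regions, opt = NULL),
            class = "decoder_model")
}
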