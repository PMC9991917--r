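test_that("window extraction follows the Gaussian-weighting contract", {
  tm <- tiny_memory_ds(seed = 2, n_blocks = 4)
  ds <- tm$ds
  expect_equal(length(ds$labels), 40)
  expect_equal(dim(ds$x$L)[2], 2500)        # 10 s at 250 Hz
  # weight 1 at the onset, exp(-1/2) at +/- one SD (2.5 s)
  expect_equal(max(ds$weights), 1)
  expect_equal(which.max(ds$weights), 1251)
  expect_equal(ds$weights[1251 + 2.5 * 250], exp(-0.5), tolerance = 1e-3)
  expect_equal(ds$weights[1251 - 2.5 * 250], exp(-0.5), tolerance = 1e-3)
})

test_that("events too close to the recording edges are dropped", {
  rec <- recording(matrix(rnorm(250 * 30 * 2), ncol = 2), fs = 250)
  ev <- event_stream(c(2, 15, 28), rep("word_onset", 3),
                     label = c(TRUE, FALSE, TRUE))
  expect_warning(ds <- extract_windows(rec, ev), "dropped")
  expect_equal(length(ds$labels), 1)        # only the interior event
  expect_equal(ds$onsets_s, 15)
})

test_that("class balancing equalizes counts deterministically", {
  tm <- tiny_memory_ds(seed = 5, n_blocks = 6)
  ds <- tm$ds
  bal <- balance_classes(ds, seed = 3)
  expect_equal(sum(bal$labels), sum(!bal$labels))
  expect_equal(sum(bal$labels), min(sum(ds$labels), sum(!ds$labels)))
  bal2 <- balance_classes(ds, seed = 3)
  expect_identical(bal$onsets_s, bal2$onsets_s)
  # already balanced data keep their membership counts
  idx <- c(which(ds$labels)[1:5], which(!ds$labels)[1:5])
  even <- subset_windows(ds, idx)
  expect_equal(length(balance_classes(even, 1)$labels), 10)
})

test_that("decode metrics match hand-computed confusion matrices", {
  m <- decode_metrics(c(0.9, 0.8, 0.2, 0.6, 0.4), c(TRUE, TRUE, FALSE,
                                                    FALSE, TRUE))
  # tp=2 fp=1 fn=1: P=2/3 R=2/3 F1=2/3; acc=3/5
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 2 / 3)
  expect_equal(m$accuracy, 0.6)
  # F1 equals P (= R) when precision and recall coincide
  expect_equal(m$f1, m$precision)
  perfect <- decode_metrics(c(0.9, 0.9, 0.1), c(TRUE, TRUE, FALSE))
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  set.seed(4)
  rnd <- decode_metrics(runif(10000), rep(c(TRUE, FALSE), 5000))
  expect_equal(rnd$auc, 0.5, tolerance = 0.02)
})

test_that("the network gradient matches numerical differentiation", {
  set.seed(1)
  spec <- decoder_spec(conv1_filters = 4, conv2_filters = 5,
                       conv1_kernel = 5, conv1_stride = 2,
                       conv2_kernel = 3, conv2_stride = 2,
                       lstm_units = 6, dense_units = 4, l2 = 0,
                       dropout = 0, lstm_dropout = 0,
                       lstm_recurrent_dropout = 0)
  model <- init_decoder(spec, c(L = 2), seed = 2)
  n <- 3; t_len <- 30
  xs <- list(L = array(rnorm(n * t_len * 2), c(n, t_len, 2)))
  y <- c(1, 0, 1)
  loss_fn <- function(m) {
    p <- pmin(pmax(neurowire:::decoder_forward(m, xs)$p, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  }
  fw <- neurowire:::decoder_forward(model, xs, training = TRUE, cache = TRUE)
  gr <- neurowire:::decoder_backward(model, fw, y)
  for (probe in list(list(get = function(m) m$branches[[1]]$Wl,
                          g = gr$branches[[1]]$Wl, path = "Wl"),
                     list(get = function(m) m$branches[[1]]$W1,
                          g = gr$branches[[1]]$W1, path = "W1"))) {
    w <- probe$get(model)
    idx <- sample(length(w), 12)
    for (i in idx) {
      eps <- 1e-6
      m1 <- model; m1$branches[[1]][[probe$path]][i] <- w[i] + eps
      m2 <- model; m2$branches[[1]][[probe$path]][i] <- w[i] - eps
      num <- (loss_fn(m1) - loss_fn(m2)) / (2 * eps)
      expect_equal(probe$g[i], num, tolerance = 1e-5)
    }
  }
})

test_that("training learns a separable tiny problem; serialization is exact", {
  # two classes differing in a 6-Hz amplitude burst
  set.seed(7)
  n <- 60; t_len <- 500
  tt <- (seq_len(t_len) - 1) / 250
  y <- rep(c(1, 0), n / 2)
  x <- array(0, c(n, t_len, 1))
  for (i in seq_len(n)) {
    x[i, , 1] <- rnorm(t_len, sd = 0.5) +
      (if (y[i] == 1) 2 else 0.3) * sin(2 * pi * 6 * tt + runif(1, 0, 6))
  }
  spec <- decoder_spec(conv1_filters = 8, conv2_filters = 8,
                       conv1_kernel = 25, conv1_stride = 10,
                       conv2_kernel = 5, conv2_stride = 2,
                       lstm_units = 12, dense_units = 8,
                       lstm_recurrent_dropout = 0, batch_size = 16)
  model <- init_decoder(spec, c(L = 1), seed = 3)
  model <- neurowire:::fit_decoder(model, list(L = x), y, epochs = 40,
                                   seed = 4)
  p <- predict_decoder(model, list(L = x))
  expect_gt(decode_metrics(p, y == 1)$f1, 0.9)
  # JSON manifest round-trip reproduces predictions bit-exactly
  path <- withr::local_tempfile(fileext = ".json")
  save_decoder(model, path)
  back <- load_decoder(path)
  expect_identical(predict_decoder(back, list(L = x)), p)
})

test_that("transfer learning freezes feature layers exactly", {
  tm <- tiny_memory_ds(seed = 9, n_blocks = 6, theta_effect = 1)
  blocks <- split_blocks(tm$ds, tm$truth$block)
  spec <- tiny_decoder_spec()
  model <- init_decoder(spec, c(L = 1, R = 1), seed = 1)
  model <- neurowire:::fit_decoder(model, blocks[[1]]$x,
                                   as.numeric(blocks[[1]]$labels),
                                   epochs = 3, seed = 2)
  before <- model$branches
  res <- transfer_and_predict(model, blocks, n_train_blocks = 3,
                              epochs_per_block = 3, seed = 5)
  expect_true(res$frozen_identical)
  expect_identical(res$model$branches[[1]]$W1, before[[1]]$W1)
  expect_identical(res$model$branches[[2]]$Wl, before[[2]]$Wl)
  expect_false(identical(res$model$head$Wd1, model$head$Wd1))
  expect_s3_class(res$report, "decode_report")
  expect_equal(nrow(res$report$predictions),
               sum(vapply(blocks[4:6], function(b) length(b$labels), 0)))
})

test_that("gradient ascent maximizes a constructed theta filter", {
  spec <- decoder_spec(conv1_filters = 2, conv2_filters = 2,
                       conv1_kernel = 42, conv1_stride = 42,
                       conv2_kernel = 5, conv2_stride = 2,
                       lstm_units = 4, dense_units = 4)
  model <- init_decoder(spec, c(L = 1), seed = 6)
  # first-layer filter 1: one 6-Hz cycle-and-a-bit sinusoidal kernel
  kt <- (seq_len(42) - 1) / 250
  model$branches[[1]]$W1[, 1] <- sin(2 * pi * 6 * kt)
  model$branches[[1]]$b1[] <- 0.05          # small positive bias seeds ascent
  # second-layer filter 1 reads only conv1 filter 1 (uniform over its kernel)
  W2 <- matrix(0, 5 * 2, 2)
  W2[seq(1, 10, by = 2), 1] <- 1
  model$branches[[1]]$W2 <- W2
  vis <- visualize_filters(model, branch = 1, filters = 1, steps = 30,
                           fs = 250)
  expect_false(vis$dead[1])
  map <- vis$map[[1]]
  prof <- colMeans(map$power)
  peak_f <- map$freqs_hz[which.max(prof)]
  grid_step <- exp(diff(log(map$freqs_hz))[1])
  expect_lt(abs(log(peak_f / 6)), 1.5 * log(grid_step))
  # activations increase over the ascent
  expect_gt(vis$activation[1], 0)
  # a filter with zero incoming weights is flagged dead
  model$branches[[1]]$W2[, 2] <- 0
  model$branches[[1]]$b2[2] <- 0
  vis2 <- visualize_filters(model, branch = 1, filters = 2, steps = 5,
                            fs = 250)
  expect_true(vis2$dead[1])
  expect_equal(max(vis2$map[[1]]$power), 0)
})

test_that("baseline classifiers run on identical splits", {
  tm <- tiny_memory_ds(seed = 12, n_blocks = 6, theta_effect = 2)
  r1 <- baseline_classifiers(tm$ds, "pca_svm", seed = 3)
  r2 <- baseline_classifiers(tm$ds, "alt_nn", seed = 3)
  expect_equal(nrow(r1$predictions), nrow(r2$predictions))
  expect_identical(r1$predictions$label, r2$predictions$label)
  expect_true(all(c(r1$f1, r2$f1) >= 0 & c(r1$f1, r2$f1) <= 1))
})
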