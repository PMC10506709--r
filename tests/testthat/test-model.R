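test_that("depth resolution follows the copy-layer-2 rule", {
  expect_equal(cnn_config(3)$filters, c(64L, 16L, 4L))
  expect_equal(cnn_config(3)$kernel_sizes, c(7L, 5L, 3L))
  expect_equal(cnn_config(5)$filters, c(64L, 16L, 16L, 16L, 4L))
  expect_equal(cnn_config(5)$kernel_sizes, c(7L, 5L, 5L, 5L, 3L))
  expect_equal(cnn_config(2)$filters, c(64L, 4L))
  expect_equal(cnn_config(2)$kernel_sizes, c(7L, 3L))
  expect_error(cnn_config(6), "2, 3, 4, 5")
  expect_error(cnn_config(3, filters = c(8, 4), kernel_sizes = c(3, 3, 3)),
               "length 3")
  expect_error(cnn_config(3, filters = c(8, 4, 2)), "both")
})

test_that("the pooling cascade shapes and guards are correct", {
  m <- build_cnn(cnn_config(seed = 1), width = 33, dim = 21)
  expect_equal(m$pooled_lengths, c(16L, 8L, 4L))
  expect_error(build_cnn(cnn_config(), width = 4, dim = 21), "width >= 8")
})

test_that("the default architecture has a stable parameter fingerprint", {
  m1 <- build_cnn(cnn_config(seed = 1), width = 33, dim = 21)
  m2 <- build_cnn(cnn_config(seed = 99), width = 33, dim = 21)
  # conv: (7*21)*64+64, (5*64)*16+16, (3*16)*4+4; dense: 16*8+8, 8*1+1
  expect_equal(m1$n_params, 9472 + 5136 + 196 + 136 + 9)
  expect_equal(m1$n_params, m2$n_params)
  # same seed, same initialization
  m3 <- build_cnn(cnn_config(seed = 1), width = 33, dim = 21)
  expect_identical(m1$weights, m3$weights)
})

test_that("analytic gradients match finite differences everywhere", {
  cfg <- cnn_config(n_conv_layers = 2, filters = c(3, 2),
                    kernel_sizes = c(3, 3), dropout_rate = 0,
                    dense_units = 4, seed = 7)
  m <- build_cnn(cfg, width = 9, dim = 5)
  set.seed(1)
  X <- array(rnorm(4 * 9 * 5), c(4, 9, 5))
  y <- c(1, 0, 1, 0)
  sw <- c(1, 2, 1, 0.5)  # non-uniform sample weights exercised too
  fwd <- hotspotcnn:::cnn_forward(m$weights, cfg, X, keep_cache = TRUE)
  gr <- hotspotcnn:::cnn_backward(m$weights, cfg, fwd, y, sw)
  loss_at <- function(w) {
    hotspotcnn:::bce_loss(hotspotcnn:::cnn_forward(w, cfg, X)$prob, y, sw)
  }
  eps <- 1e-6
  for (path in hotspotcnn:::param_paths(m$weights)) {
    W <- hotspotcnn:::get_param(m$weights, path)
    G <- hotspotcnn:::get_param(gr, path)
    probe <- seq_len(min(length(W), 4L))
    for (i in probe) {
      Wp <- W; Wp[i] <- W[i] + eps
      Wm <- W; Wm[i] <- W[i] - eps
      num <- (loss_at(hotspotcnn:::set_param(m$weights, path, Wp)) -
                loss_at(hotspotcnn:::set_param(m$weights, path, Wm))) /
        (2 * eps)
      expect_equal(G[i], num, tolerance = 1e-5)
    }
  }
})

test_that("training separates separable data and reaches validation F1 1", {
  wd <- separable_windows(n_per_class = 40L, width = 9L, dim = 4L)
  sp <- split_dataset(wd, seed = 3)
  cfg <- cnn_config(n_conv_layers = 2, filters = c(8, 4),
                    kernel_sizes = c(5, 3), dropout_rate = 0,
                    max_epochs = 80, patience = 80, batch_size = 16,
                    seed = 2)
  m <- build_cnn(cfg, wd$width, wd$dim)
  fit <- train_cnn(m, sp$train, sp$validation)
  expect_equal(fit$best_val_f1, 1)
  expect_true(fit$best_epoch >= 1L)
})

test_that("training histories are identical under a fixed seed", {
  wd <- separable_windows(n_per_class = 20L, width = 9L, dim = 4L)
  sp <- split_dataset(wd, seed = 3)
  cfg <- cnn_config(n_conv_layers = 2, filters = c(4, 2),
                    kernel_sizes = c(3, 3), max_epochs = 6, patience = 6,
                    seed = 5)
  m <- build_cnn(cfg, wd$width, wd$dim)
  f1 <- train_cnn(m, sp$train, sp$validation)
  f2 <- train_cnn(m, sp$train, sp$validation)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$best_epoch, f2$best_epoch)
  expect_identical(f1$model$weights, f2$model$weights)
})

test_that("patience 0 stops at the first non-improving epoch", {
  wd <- separable_windows(n_per_class = 20L, width = 9L, dim = 4L)
  sp <- split_dataset(wd, seed = 3)
  cfg <- cnn_config(n_conv_layers = 2, filters = c(4, 2),
                    kernel_sizes = c(3, 3), max_epochs = 50, patience = 0,
                    seed = 5)
  m <- build_cnn(cfg, wd$width, wd$dim)
  fit <- train_cnn(m, sp$train, sp$validation)
  f1s <- fit$history$val_f1
  n <- length(f1s)
  if (n < 50L) {
    # every epoch but the last improved strictly; the last did not
    if (n > 1L) {
      expect_true(all(diff(f1s[seq_len(n - 1L)]) > 0 | n == 2L))
      expect_lte(f1s[n], max(f1s[seq_len(n - 1L)]))
    }
    expect_equal(fit$best_epoch, which.max(f1s))
  }
})

test_that("training rejects degenerate inputs", {
  wd <- separable_windows(n_per_class = 10L, width = 9L, dim = 4L)
  sp <- split_dataset(wd, seed = 3)
  cfg <- cnn_config(n_conv_layers = 2, filters = c(4, 2),
                    kernel_sizes = c(3, 3), max_epochs = 2, seed = 5)
  m <- build_cnn(cfg, wd$width, wd$dim)
  empty <- window_subset(wd, integer(0))
  expect_error(train_cnn(m, sp$train, empty), "validation")
  wrong <- build_cnn(cfg, 11, wd$dim)
  expect_error(train_cnn(wrong, sp$train, sp$validation), "expects")
})

test_that("prediction respects thresholds, ordering and shape checks", {
  wd <- separable_windows(n_per_class = 25L, width = 9L, dim = 4L)
  sp <- split_dataset(wd, seed = 3)
  cfg <- cnn_config(n_conv_layers = 2, filters = c(8, 4),
                    kernel_sizes = c(5, 3), max_epochs = 15, patience = 15,
                    seed = 2)
  fit <- train_cnn(build_cnn(cfg, wd$width, wd$dim), sp$train, sp$validation)

  preds <- predict(fit, sp$test)
  expect_true(all(preds$score >= 0 & preds$score <= 1))
  expect_equal(preds$label, as.integer(preds$score >= 0.5))

  # raising the threshold never increases the positive count
  counts <- vapply(c(0, 0.25, 0.5, 0.75, 1, 1.000001), function(th) {
    sum(predict(fit, sp$test, threshold = th)$label)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[length(counts)], 0)  # threshold above 1: no positives

  # scores are invariant to example order
  set.seed(9)
  perm <- sample.int(n_windows(sp$test))
  shuffled <- window_subset(sp$test, perm)
  expect_equal(predict(fit, shuffled)$score, preds$score[perm])

  expect_error(predict(fit, array(0, c(2, 5, 4))), "expects|array")
})
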