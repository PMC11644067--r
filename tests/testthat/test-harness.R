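# Training harness: loss bookkeeping, gradient descent sanity, reproducible
# fits, and evaluation-mode behavior.

make_toy_mlp <- function(alpha_max = 0.5, seed = 1, ...) {
  cfg <- if (alpha_max > 0) {
    bsda_config(feature_dim = 8, alpha_max = alpha_max,
                alpha_warmup_epochs = 0, hidden_dim = 8, seed = seed, ...)
  } else NULL
  bsda_model("mlp", n_classes = 2, input_dim = 4, k = 8, hidden = 8,
             config = cfg, seed = seed)
}

toy_xy <- function(n = 40, seed = 31) {
  set.seed(seed)
  y <- rep(0:1, length.out = n)
  x <- matrix(rnorm(n * 4), n, 4) + 2 * y  # linearly separable shift
  list(x = x, y = y)
}

test_that("forward_train decomposes the loss exactly and respects alpha = 0", {
  d <- toy_xy()
  m0 <- make_toy_mlp(alpha_max = 0)
  set.seed(32)
  r0 <- forward_train(m0, d$x, d$y, epoch = 0)
  # alpha_max = 0: plain cross-entropy of the unaugmented pass
  a <- bsda:::nn_forward(m0$f1, d$x, training = TRUE)
  ce <- bsda:::softmax_ce(bsda:::nn_forward(m0$f2, a, training = TRUE), d$y)
  expect_equal(r0$total, ce$loss, tolerance = 1e-12)
  expect_identical(r0$parts$task_aug, 0)

  m1 <- make_toy_mlp(alpha_max = 0.5)
  set.seed(33)
  r1 <- forward_train(m1, d$x, d$y, epoch = 3)
  expect_equal(r1$total,
               r1$parts$task_orig + r1$alpha *
                 (r1$parts$kl + r1$parts$recon + r1$parts$task_aug),
               tolerance = 1e-6)
  set_training(m1, FALSE)
  expect_error(forward_train(m1, d$x, d$y, 0), "training mode")
})

test_that("a single gradient step decreases the loss on a separable toy set", {
  d <- toy_xy()
  m <- make_toy_mlp(alpha_max = 0.5, seed = 4)
  st <- bsda:::rng_stream(77)
  for (net in bsda:::model_nets(m)) bsda:::nn_zero_grads(net)
  r_before <- bsda:::with_stream(st, bsda:::step_forward_backward(
    m, d$x, d$y, epoch = 3, compute_grads = TRUE))
  opt <- bsda:::adamw_new(bsda:::model_nets(m))
  bsda:::adamw_step(opt, 1e-2)
  st2 <- bsda:::rng_stream(77)  # same draws, post-update parameters
  r_after <- bsda:::with_stream(st2, bsda:::step_forward_backward(
    m, d$x, d$y, epoch = 3, compute_grads = FALSE))
  expect_lt(r_after$total, r_before$total)
})

test_that("fit is a reproducible smoke-tested loop with a sane log", {
  ds <- get_blobs(200, seed = 1)
  cfg <- bsda_config(feature_dim = 16, alpha_max = 0.5, seed = 5)
  tc <- train_config(epochs = 2, batch_size = 32, seed = 5)
  m <- bsda_model("cnn", 3, input_shape = c(32, 32, 1), k = 16, config = cfg, seed = 5)
  r1 <- fit(m, ds, tc)
  expect_s3_class(r1, "bsda_fit")
  lg <- r1$log
  expect_setequal(unique(lg$split), c("train", "val", "test"))
  expect_true(all(c("loss_total", "loss_task_orig", "loss_task_aug",
                    "loss_kl", "loss_recon", "acc", "auc") %in% names(lg)))
  # zero-initialized estimator head and alpha warm-up: KL starts at zero
  expect_lt(abs(lg$loss_kl[lg$split == "train" & lg$epoch == 0]), 1e-8)
  m2 <- bsda_model("cnn", 3, input_shape = c(32, 32, 1), k = 16, config = cfg, seed = 5)
  r2 <- fit(m2, ds, tc)
  expect_identical(r1$test_acc, r2$test_acc)
  expect_identical(r1$test_auc, r2$test_auc)
  expect_identical(r1$log$loss_total, r2$log$loss_total)
  expect_error(fit(m, list(train = list(x = NULL, y = NULL), val = NULL, test = NULL), tc))
})

test_that("predict returns softmax rows and no augmentation at evaluation", {
  d <- toy_xy(20)
  m <- make_toy_mlp(alpha_max = 0.5, seed = 6)
  set_training(m, FALSE)
  p <- predict(m, d$x)
  expect_equal(rowSums(p), rep(1, 20), tolerance = 1e-6)
  expect_true(all(p > 0 & p < 1))
  # duplicate inputs give duplicate rows; repeated calls identical (no sampling)
  p2 <- predict(m, d$x[c(1, 1, 2), ])
  expect_identical(p2[1, ], p2[2, ])
  expect_identical(p, predict(m, d$x))
})

test_that("checkpoints round-trip the model exactly", {
  ds <- get_blobs(200, seed = 1)
  cfg <- bsda_config(feature_dim = 16, alpha_max = 0.5, seed = 8)
  m <- bsda_model("cnn", 3, input_shape = c(32, 32, 1), k = 16, config = cfg, seed = 8)
  r <- fit(m, ds, train_config(epochs = 1, batch_size = 32, seed = 8))
  path <- tempfile(fileext = ".rds")
  save_checkpoint(r$model, path)
  m2 <- load_checkpoint(path)
  sp <- dataset_splits(ds)
  expect_equal(predict(m2, sp$test$x), predict(r$model, sp$test$x), tolerance = 1e-12)
})

test_that("gradients partition across parameter groups as the loss dictates", {
  d <- toy_xy()
  m <- make_toy_mlp(alpha_max = 0.5, seed = 9)
  for (net in bsda:::model_nets(m)) bsda:::nn_zero_grads(net)
  st <- bsda:::rng_stream(55)
  bsda:::with_stream(st, bsda:::step_forward_backward(m, d$x, d$y, epoch = 3,
                                                      compute_grads = TRUE))
  grad_norm <- function(net) {
    sum(vapply(net$layers, function(l) {
      sum(vapply(l$grads, function(g) sum(g^2), numeric(1)))
    }, numeric(1)))
  }
  # all four parameter groups receive gradient under the full loss
  expect_gt(grad_norm(m$f1), 0)
  expect_gt(grad_norm(m$f2), 0)
  expect_gt(grad_norm(m$bsda$estimator), 0)
  expect_gt(grad_norm(m$bsda$reconstructor), 0)
})
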