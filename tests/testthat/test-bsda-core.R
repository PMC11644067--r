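# The augmentation core: direction sampling, sigma estimation, reparameterized
# magnitudes, masked augmentation, and the variational loss.

test_that("direction masks are Bernoulli(lambda) with exact degenerate cases", {
  set.seed(21)
  expect_identical(sample_direction(2, 3, 0), matrix(0, 2, 3))
  expect_identical(sample_direction(2, 3, 1), matrix(1, 2, 3))
  d <- sample_direction(1, 1e5, 0.5)
  expect_true(all(d %in% c(0, 1)))
  expect_lt(abs(mean(d) - 0.5), 3 * sqrt(0.25 / 1e5))  # binomial 3-sigma band
  expect_error(sample_direction(2, 3, 1.5), "lambda")
})

test_that("estimate_sigma is positive, starts at 1, and validates widths", {
  set.seed(22)
  cfg <- bsda_config(feature_dim = 6, hidden_dim = 8, seed = 3)
  mod <- bsda_module(cfg)
  fb <- feature_batch(matrix(rnorm(30), 5, 6), rep(0:1, length.out = 5))
  s <- estimate_sigma(fb, mod$estimator)
  expect_equal(dim(s), c(5L, 6L))
  expect_equal(unclass(s), matrix(1, 5, 6))  # zero-initialized head: exp(0/2)
  expect_error(feature_batch(matrix(c(1, NA), 1, 2), 0), "finite")
  wrong <- feature_batch(matrix(rnorm(10), 2, 5), c(0L, 1L))
  expect_error(estimate_sigma(wrong, mod$estimator), "width")
  # after a parameter nudge, still strictly positive everywhere
  mod$estimator$layers[[4]]$params$W[] <- rnorm(48, sd = 2)
  s2 <- estimate_sigma(fb, mod$estimator)
  expect_true(all(s2 > 0) && all(is.finite(s2)))
})

test_that("magnitude draws are reparameterized, deterministic, and scale with sigma", {
  expect_identical(sample_magnitude(matrix(0, 3, 4))$m, matrix(0, 3, 4))
  set.seed(23)
  mg <- sample_magnitude(matrix(1, 1e5, 1))
  expect_identical(mg$m, mg$eps)                       # m = sigma * eps at sigma = 1
  v <- stats::var(as.numeric(mg$m))
  expect_lt(abs(v - 1), 3 * sqrt(2 / 1e5))             # chi-square SE band
  set.seed(99); m1 <- sample_magnitude(matrix(2, 4, 4))$m
  set.seed(99); m2 <- sample_magnitude(matrix(2, 4, 4))$m
  expect_identical(m1, m2)
  expect_error(sample_magnitude(matrix(-1, 1, 1)), "non-negative")
})

test_that("augment applies the masked translation and preserves its inputs", {
  a <- matrix(c(1, 0, 2), 1, 3)
  d <- matrix(1, 1, 3)
  m <- matrix(0.5, 1, 3)
  expect_equal(augment(a, d, m, mask_zero = TRUE), matrix(c(1.5, 0, 2.5), 1, 3))
  expect_equal(augment(a, d, m, mask_zero = FALSE), matrix(c(1.5, 0.5, 2.5), 1, 3))
  expect_identical(augment(a, matrix(0, 1, 3), m), a)   # lambda = 0 identity
  expect_error(augment(a, matrix(1, 2, 3), m), "shape")
  set.seed(24)
  # property loop: zero coordinates never move under mask_zero, any lambda/sigma
  for (i in 1:25) {
    B <- sample(1:6, 1); k <- sample(2:12, 1)
    a <- matrix(rexp(B * k) * rbinom(B * k, 1, 0.6), B, k)
    d <- sample_direction(B, k, runif(1))
    m <- sample_magnitude(matrix(runif(B * k, 0, 3), B, k))$m
    at <- augment(a, d, m, mask_zero = TRUE)
    expect_identical(at[a == 0], a[a == 0])
    expect_identical(augment(a, matrix(0, B, k), m, mask_zero = FALSE), a)
  }
})

test_that("kl_term matches numerical integration of KL(N(0,s^2) || N(0,1))", {
  for (s in c(0.25, 0.5, 1, 2, 4)) {
    expect_equal(kl_term(matrix(s, 1, 1)), kl_numeric(s^2), tolerance = 1e-6)
  }
  expect_identical(kl_term(matrix(1, 3, 4)), 0)
  expect_equal(kl_term(matrix(sqrt(exp(1)), 1, 1)), 0.5 * (exp(1) - 2),
               tolerance = 1e-9)
  expect_gt(kl_term(matrix(c(1, 1.2), 1, 2)), 0)
  expect_error(kl_term(matrix(0, 1, 1)), "positive")
  # batch-size invariance of the reduction
  expect_equal(kl_term(matrix(2, 7, 3)), kl_term(matrix(2, 1, 3)))
})

test_that("recon_term and bsda_loss arithmetic", {
  a <- matrix(rnorm(12), 3, 4)
  expect_identical(recon_term(a, a), 0)
  expect_equal(recon_term(a + 2, a), 2.0)
  expect_equal(recon_term(matrix(c(1, 3), 1, 2), matrix(0, 1, 2)), 2.5)
  expect_error(recon_term(a, a[1:2, ]), "shape")
  sig1 <- matrix(1, 3, 4)
  expect_identical(bsda_loss(sig1, a, a), 0)
  expect_identical(bsda_loss(sig1, a + 100, a, use_recon = FALSE), 0)
  expect_equal(bsda_loss(matrix(sqrt(exp(1)), 1, 1), matrix(1), matrix(1)),
               0.5 * (exp(1) - 2), tolerance = 1e-9)
})

test_that("total_loss and alpha_schedule follow the declared contracts", {
  expect_identical(total_loss(1.7, 99, 99, 0), 1.7)
  expect_equal(total_loss(1.0, 2.0, 0.5, 0.5), 2.25)
  cfg <- bsda_config(feature_dim = 4, alpha_max = 0.5, alpha_warmup_epochs = 5)
  expect_identical(alpha_schedule(0, cfg), 0)
  expect_equal(alpha_schedule(2, cfg), 0.2)
  expect_identical(alpha_schedule(5, cfg), 0.5)
  expect_identical(alpha_schedule(50, cfg), 0.5)
  sched <- vapply(0:10, alpha_schedule, numeric(1), config = cfg)
  expect_true(all(diff(sched) >= 0))
  expect_identical(bsda_config(4)$alpha_max, 0.5)  # recommended default
})

test_that("augmented features match the stated first and second moments", {
  set.seed(25)
  n <- 1e5
  a_row <- c(1.5, 0, -0.7)
  a <- matrix(rep(a_row, each = n), n, 3)
  lambda <- 0.5; sigma <- 1
  d <- sample_direction(n, 3, lambda)
  m <- sample_magnitude(matrix(sigma, n, 3))$m
  at <- augment(a, d, m, mask_zero = TRUE)
  diff <- at - a
  se_mean <- sqrt(lambda * sigma^2 / n)
  expect_true(all(abs(colMeans(diff)) < 3 * se_mean))
  # Var = lambda sigma^2 on non-zero coordinates; fourth moment gives the SE
  se_var <- sqrt((3 * lambda - (lambda * sigma^2)^2) / n)
  for (j in c(1, 3)) expect_lt(abs(stats::var(diff[, j]) - lambda * sigma^2), 3 * se_var)
  expect_true(all(diff[, 2] == 0))  # a = 0 coordinate frozen by the indicator
})

test_that("random-noise ablation is distributionally a + d * eps (KS test)", {
  set.seed(26)
  n <- 1e4
  a <- matrix(1.3, n, 1)
  d <- sample_direction(n, 1, 0.5)
  m <- sample_magnitude(matrix(1, n, 1))$m   # fixed_sigma = 1 path
  at <- as.numeric(augment(a, d, m, mask_zero = FALSE))
  ref <- 1.3 + sample_direction(n, 1, 0.5) * rnorm(n)
  ks <- suppressWarnings(stats::ks.test(at, as.numeric(ref)))
  expect_gt(ks$p.value, 0.01)
})

test_that("gradients flow through sigma: pathwise MC matches 2*sigma and the loss responds", {
  set.seed(27)
  sigma <- 1.7
  eps <- rnorm(1e5)
  # d E[m^2] / d sigma via the reparameterized path m = sigma * eps
  expect_lt(abs(mean(2 * sigma * eps^2) - 2 * sigma) / (2 * sigma), 0.05)
  # finite-difference perturbation of an estimator parameter moves bsda_loss
  cfg <- bsda_config(feature_dim = 5, hidden_dim = 6, seed = 9)
  mod <- bsda_module(cfg)
  fb <- feature_batch(matrix(abs(rnorm(20)), 4, 5), rep(0:1, 2))
  eps_fix <- matrix(rnorm(20), 4, 5)
  loss_of <- function() {
    s <- unclass(estimate_sigma(fb, mod$estimator))
    ahat <- reconstruct(s * eps_fix, mod$reconstructor)
    bsda_loss(s, ahat, fb)
  }
  l0 <- loss_of()
  mod$estimator$layers[[4]]$params$b[1] <- 0.1
  expect_gt(abs(loss_of() - l0), 0)
})
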