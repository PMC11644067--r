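#' BSDA configuration
#'
#' Collects every hyperparameter of the Bayesian random semantic data
#' augmentation module. Augmentation adds `indicator * d * m` to a feature
#' vector, where `d` is an elementwise Bernoulli(lambda) direction mask and
#' `m = sigma * epsilon` is a reparameterized Gaussian magnitude whose
#' per-sample, per-dimension scale `sigma` is produced by a small estimator
#' network trained variationally.
#'
#' @param feature_dim width k of the feature vectors the module operates on.
#' @param lambda probability in `[0, 1]` that a given feature dimension is
#'   selected as a semantic direction. Default 0.5.
#' @param num_samples U, the number of augmented copies drawn per original
#'   feature per training step. Default 1.
#' @param alpha_max plateau value of the weight on the augmentation branch of
#'   the total loss. Default 0.5 (the recommended setting); `0` disables the
#'   module entirely.
#' @param alpha_warmup_epochs epochs over which alpha ramps linearly from 0 to
#'   `alpha_max`. Default 5, mirroring the learning-rate warm-up.
#' @param hidden_dim hidden width of the estimator/reconstructor networks;
#'   defaults to `feature_dim`.
#' @param mask_zero if `TRUE` (default) feature coordinates that are exactly
#'   zero are never perturbed, preserving the sparsity structure of
#'   post-activation features.
#' @param use_recon if `TRUE` (default) the reconstruction half of the
#'   variational loss is used; `FALSE` gives the "-Recon" ablation.
#' @param fixed_sigma optional non-negative scalar; when set, the estimator is
#'   bypassed and magnitudes are drawn with this constant scale (the
#'   "Random Noise" ablation uses 1).
#' @param seed integer seed for the module's random draws.
#' @return an object of class `bsda_config`.
#' @export
bsda_config <- function(feature_dim,
                        lambda = 0.5,
                        num_samples = 1L,
                        alpha_max = 0.5,
                        alpha_warmup_epochs = 5L,
                        hidden_dim = feature_dim,
                        mask_zero = TRUE,
                        use_recon = TRUE,
                        fixed_sigma = NULL,
                        seed = 0L) {
  stopifnot(
    is.numeric(feature_dim), length(feature_dim) == 1, feature_dim >= 1,
    is.numeric(lambda), length(lambda) == 1,
    is.numeric(num_samples), num_samples >= 1,
    is.numeric(alpha_max), alpha_max >= 0,
    is.numeric(alpha_warmup_epochs), alpha_warmup_epochs >= 0,
    is.numeric(hidden_dim), hidden_dim >= 1
  )
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (!is.null(fixed_sigma)) {
    stopifnot(is.numeric(fixed_sigma), length(fixed_sigma) == 1, fixed_sigma >= 0)
  }
  structure(list(
    feature_dim = as.integer(feature_dim),
    lambda = lambda,
    num_samples = as.integer(num_samples),
    alpha_max = alpha_max,
    alpha_warmup_epochs = as.integer(alpha_warmup_epochs),
    hidden_dim = as.integer(hidden_dim),
    mask_zero = isTRUE(mask_zero),
    use_recon = isTRUE(use_recon),
    fixed_sigma = fixed_sigma,
    seed = as.integer(seed)
  ), class = "bsda_config")
}

#' A batch of feature vectors with class labels
#'
#' @param features numeric matrix, B x k; all entries finite.
#' @param labels integer vector of length B with values in `[0, n_classes)`.
#' @param n_classes declared number of classes (default `max(labels) + 1`).
#' @return an object of class `feature_batch`.
#' @export
feature_batch <- function(features, labels, n_classes = NULL) {
  features <- as.matrix(features)
  if (nrow(features) < 1 || ncol(features) < 1) stop("features must be non-empty")
  if (any(!is.finite(features))) stop("features contain non-finite entries")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) stop("labels length must equal nrow(features)")
  if (is.null(n_classes)) n_classes <- max(labels) + 1L
  if (any(labels < 0L | labels >= n_classes)) {
    stop("labels must lie in [0, n_classes)")
  }
  structure(list(features = features, labels = labels,
                 n_classes = as.integer(n_classes)),
            class = "feature_batch")
}

#' Build the estimator + reconstructor pair
#'
#' Both are two fully connected layers with BatchNorm and GeLU after the first.
#' The estimator maps a feature vector to log sigma^2 (exponentiation
#' guarantees positivity); its head is zero-initialized so training starts at
#' sigma = 1, where the KL term vanishes. The reconstructor maps a magnitude
#' draw m back to a feature-space prediction a-hat.
#'
#' @param config a [bsda_config()].
#' @return a list with elements `estimator`, `reconstructor` (may be `NULL`
#'   when `fixed_sigma` is set), and `config`.
#' @export
bsda_module <- function(config) {
  stopifnot(inherits(config, "bsda_config"))
  mod <- list(config = config, estimator = NULL, reconstructor = NULL)
  if (is.null(config$fixed_sigma)) {
    k <- config$feature_dim
    h <- config$hidden_dim
    mod$estimator <- nn_sequential(
      nn_linear(k, h), nn_batchnorm(h), nn_gelu(),
      nn_linear(h, k, zero_init = TRUE)
    )
    mod$reconstructor <- nn_sequential(
      nn_linear(k, h), nn_batchnorm(h), nn_gelu(),
      nn_linear(h, k)
    )
  }
  class(mod) <- "bsda_module"
  mod
}

#' Sample a Bernoulli direction mask
#'
#' Each entry of the B x k mask is an independent Bernoulli(lambda) draw:
#' a 1 selects that feature dimension as a semantic direction to perturb.
#'
#' @param batch_size number of rows B.
#' @param k number of feature dimensions.
#' @param lambda selection probability in `[0, 1]`.
#' @return binary matrix B x k.
#' @export
sample_direction <- function(batch_size, k, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda > 1) {
    stop("lambda must be a single number in [0, 1]")
  }
  matrix(as.numeric(stats::runif(batch_size * k) < lambda), batch_size, k)
}

#' Estimate the magnitude-distribution scale sigma
#'
#' Runs the estimator network on the batch features. The network predicts
#' log sigma^2; the return value is sigma = exp(log sigma^2 / 2), strictly
#' positive by construction.
#'
#' @param batch a [feature_batch()].
#' @param estimator an estimator network (from [bsda_module()]).
#' @param training use batch statistics in BatchNorm (`TRUE`) or running
#'   statistics (`FALSE`).
#' @return positive matrix B x k of class `magnitude_distribution`.
#' @export
estimate_sigma <- function(batch, estimator, training = TRUE) {
  stopifnot(inherits(batch, "feature_batch"))
  k_in <- nrow(estimator$layers[[1]]$params$W)
  if (ncol(batch$features) != k_in) {
    stop("estimator width (", k_in, ") does not match feature dimension (",
         ncol(batch$features), ")")
  }
  logvar <- nn_forward(estimator, batch$features, training = training)
  sigma <- exp(0.5 * logvar)
  structure(sigma, class = c("magnitude_distribution", class(sigma)))
}

#' Draw reparameterized magnitudes m = sigma * epsilon
#'
#' epsilon ~ N(0, I) is drawn independently of sigma, so the pathwise gradient
#' of m with respect to sigma is exactly epsilon.
#'
#' @param sigma non-negative B x k matrix of scales.
#' @return list with `m` (B x k magnitudes) and `eps` (the noise draw, kept
#'   for backpropagation).
#' @export
sample_magnitude <- function(sigma) {
  sigma <- unclass(sigma)
  if (any(sigma < 0)) stop("sigma must be non-negative")
  eps <- matrix(stats::rnorm(length(sigma)), nrow(sigma), ncol(sigma))
  list(m = sigma * eps, eps = eps)
}

#' Apply the masked feature-space translation
#'
#' Returns `a + d * m`, optionally multiplied by the indicator `I[a != 0]`
#' that forbids perturbing exactly-zero coordinates (preserving the sparsity
#' of post-activation features). The indicator is an exact comparison to 0.
#'
#' @param batch a [feature_batch()] (or bare matrix of features).
#' @param directions binary B x k direction mask.
#' @param magnitudes B x k magnitude draws.
#' @param mask_zero apply the zero-feature indicator.
#' @return augmented feature matrix B x k; the input is not modified.
#' @export
augment <- function(batch, directions, magnitudes, mask_zero = TRUE) {
  a <- if (inherits(batch, "feature_batch")) batch$features else as.matrix(batch)
  directions <- as.matrix(directions)
  magnitudes <- as.matrix(magnitudes)
  if (!all(dim(a) == dim(directions)) || !all(dim(a) == dim(magnitudes))) {
    stop("features, directions and magnitudes must share the same B x k shape")
  }
  delta <- directions * magnitudes
  if (mask_zero) delta <- delta * (a != 0)
  a + delta
}

#' Reconstruct features from magnitudes
#'
#' @param magnitudes B x k magnitude matrix.
#' @param reconstructor reconstructor network (from [bsda_module()]).
#' @param training BatchNorm mode.
#' @return predicted feature matrix B x k.
#' @export
reconstruct <- function(magnitudes, reconstructor, training = TRUE) {
  magnitudes <- as.matrix(magnitudes)
  k_in <- nrow(reconstructor$layers[[1]]$params$W)
  if (ncol(magnitudes) != k_in) {
    stop("reconstructor width (", k_in, ") does not match magnitude dimension (",
         ncol(magnitudes), ")")
  }
  nn_forward(reconstructor, magnitudes, training = training)
}

#' Closed-form KL divergence of the magnitude distribution from the prior
#'
#' For each dimension, KL(N(0, sigma^2) || N(0, 1)) = (sigma^2 - 1 -
#' log sigma^2) / 2. The result is summed over dimensions and averaged over
#' the batch, so its magnitude does not depend on batch size.
#'
#' @param sigma positive B x k matrix.
#' @return non-negative scalar.
#' @export
kl_term <- function(sigma) {
  sigma <- unclass(as.matrix(sigma))
  if (any(sigma <= 0)) stop("sigma must be strictly positive")
  s2 <- sigma^2
  mean(rowSums(0.5 * (s2 - 1 - log(s2))))
}

#' Reconstruction half of the variational loss
#'
#' Half the mean squared error between the reconstructed and original
#' features, over all entries.
#'
#' @param a_hat reconstructed matrix.
#' @param a original matrix.
#' @return non-negative scalar.
#' @export
recon_term <- function(a_hat, a) {
  a_hat <- as.matrix(a_hat); a <- as.matrix(a)
  if (!all(dim(a_hat) == dim(a))) stop("a_hat and a must have identical shapes")
  0.5 * mean((a_hat - a)^2)
}

#' The BSDA loss: KL term plus (optionally) the reconstruction term
#'
#' @param sigma positive B x k matrix.
#' @param a_hat reconstructed features (ignored when `use_recon = FALSE`).
#' @param batch the originating [feature_batch()] (or feature matrix).
#' @param use_recon include the reconstruction term.
#' @return non-negative scalar, minimized during training.
#' @export
bsda_loss <- function(sigma, a_hat, batch, use_recon = TRUE) {
  kl <- kl_term(sigma)
  if (!use_recon) return(kl)
  a <- if (inherits(batch, "feature_batch")) batch$features else as.matrix(batch)
  kl + recon_term(a_hat, a)
}

#' Combine task and augmentation losses
#'
#' `total = task_orig + alpha * (bsda + task_aug)`, where `task_aug` has
#' already been averaged over the U augmented copies.
#'
#' @param task_loss_orig cross-entropy on the original features.
#' @param task_loss_aug cross-entropy on the augmented features.
#' @param bsda the [bsda_loss()] value.
#' @param alpha non-negative branch weight.
#' @return scalar total loss.
#' @export
total_loss <- function(task_loss_orig, task_loss_aug, bsda, alpha) {
  stopifnot(alpha >= 0)
  task_loss_orig + alpha * (bsda + task_loss_aug)
}

#' Linear warm-up schedule for the augmentation-branch weight
#'
#' alpha ramps linearly from 0 at epoch 0 to `alpha_max` at
#' `alpha_warmup_epochs`, then stays constant. This softens the influence of
#' the augmentation branch while the backbone has not yet learned useful
#' features.
#'
#' @param epoch 0-based epoch index.
#' @param config a [bsda_config()].
#' @return alpha value in `[0, alpha_max]`, non-decreasing in `epoch`.
#' @export
alpha_schedule <- function(epoch, config) {
  stopifnot(epoch >= 0)
  w <- config$alpha_warmup_epochs
  if (w <= 0 || epoch >= w) return(config$alpha_max)
  config$alpha_max * epoch / w
}
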