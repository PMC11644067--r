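# Training harness: plugs the augmentation module between a feature extractor
# f1 and a linear classifier head f2, and runs the full training loop
# (feature -> sigma -> magnitude draws -> masked augmentation -> reconstruction
# -> combined loss -> joint update of backbone, head, estimator, reconstructor).

#' Training configuration
#'
#' @param epochs number of epochs (>= 1).
#' @param batch_size mini-batch size (>= 1); trailing batches of size 1 are
#'   dropped because BatchNorm batch statistics are undefined there.
#' @param learning_rate AdamW learning rate (default 1e-3).
#' @param warmup_epochs linear learning-rate warm-up length (default 5).
#' @param optimizer only `"adamw"` is implemented.
#' @param weight_decay decoupled weight decay on weight matrices.
#' @param seed seed controlling data order (the model carries its own
#'   initialization and sampling seeds).
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs, batch_size = 64L, learning_rate = 1e-3,
                         warmup_epochs = 5L, optimizer = "adamw",
                         weight_decay = 0, seed = 0L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0)
  optimizer <- match.arg(optimizer, "adamw")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 warmup_epochs = as.integer(warmup_epochs),
                 optimizer = optimizer, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a classifier with an optional plug-in augmentation module
#'
#' Two reference backbones are provided. `"cnn"`: two 3x3 convolution blocks
#' (GeLU, 2x2 max pooling) followed by global average pooling to a k-vector.
#' `"mlp"`: two dense layers with GeLU, for pre-extracted feature datasets.
#' The classifier head f2 is a single linear layer; augmentation acts on the
#' k-dimensional vector between the two.
#'
#' Backbone/head initialization and the augmentation module use separate
#' derived random streams, so a model with the module disabled is initialized
#' identically to one without it.
#'
#' @param backbone `"cnn"` or `"mlp"`.
#' @param n_classes number of classes c.
#' @param input_shape for `"cnn"`, integer `c(H, W, C)` of the input images.
#' @param input_dim for `"mlp"`, width of the input feature vectors.
#' @param k penultimate feature width (default 64).
#' @param hidden hidden width of the MLP backbone.
#' @param config a [bsda_config()] with `feature_dim = k`, or `NULL` for a
#'   plain model with no augmentation module attached.
#' @param seed integer seed for weight initialization.
#' @return object of class `bsda_model`.
#' @export
bsda_model <- function(backbone = c("cnn", "mlp"), n_classes,
                       input_shape = NULL, input_dim = NULL,
                       k = 64L, hidden = 128L, config = NULL, seed = 0L) {
  backbone <- match.arg(backbone)
  k <- as.integer(k)
  if (!is.null(config)) {
    stopifnot(inherits(config, "bsda_config"))
    if (config$feature_dim != k) stop("config$feature_dim must equal k")
  }
  init_stream <- rng_stream(derive_seed(seed, "backbone_init"))
  f1 <- with_stream(init_stream, {
    if (backbone == "cnn") {
      stopifnot(length(input_shape) == 3)
      nn_sequential(
        nn_conv3x3(input_shape[3], 16L), nn_gelu(), nn_maxpool2(),
        nn_conv3x3(16L, k), nn_gelu(), nn_maxpool2(),
        nn_gap()
      )
    } else {
      stopifnot(!is.null(input_dim))
      nn_sequential(
        nn_linear(as.integer(input_dim), as.integer(hidden)), nn_gelu(),
        nn_linear(as.integer(hidden), k), nn_gelu()
      )
    }
  })
  f2 <- with_stream(init_stream, nn_sequential(nn_linear(k, as.integer(n_classes))))
  mod <- NULL
  if (!is.null(config) && config$alpha_max > 0) {
    bsda_init <- rng_stream(derive_seed(seed, "bsda_init"))
    mod <- with_stream(bsda_init, bsda_module(config))
  }
  state <- new.env(parent = emptyenv())
  state$training <- TRUE
  structure(list(
    backbone = backbone, f1 = f1, f2 = f2, bsda = mod, config = config,
    k = k, n_classes = as.integer(n_classes), input_shape = input_shape,
    input_dim = input_dim, hidden = as.integer(hidden), seed = as.integer(seed),
    state = state
  ), class = "bsda_model")
}

#' Switch a model between training and evaluation mode
#' @param model a [bsda_model()].
#' @param training logical.
#' @export
set_training <- function(model, training = TRUE) {
  model$state$training <- isTRUE(training)
  invisible(model)
}

bsda_enabled <- function(model) {
  !is.null(model$bsda) && model$config$alpha_max > 0
}

# The core forward (and optionally backward) pass of one training step.
# When the module is enabled, the original and augmented rows go through the
# head as one enlarged batch (f1 runs once per image) and a single backward
# pass distributes both task gradients. Returns loss parts; with
# compute_grads = TRUE, parameter gradients are left accumulated in the nets.
step_forward_backward <- function(model, x, y, epoch, sample_stream = NULL,
                                  compute_grads = TRUE) {
  f1 <- model$f1; f2 <- model$f2
  a <- nn_forward(f1, x, training = TRUE)
  B <- nrow(a); k <- ncol(a)
  enabled <- bsda_enabled(model)
  if (!enabled) {
    ce <- softmax_ce(nn_forward(f2, a, training = TRUE), y)
    if (compute_grads) {
      da <- nn_backward(f2, ce$dlogits)
      nn_backward(f1, da)
    }
    return(list(total = ce$loss,
                parts = list(task_orig = ce$loss, task_aug = 0, kl = 0, recon = 0),
                alpha = 0))
  }

  cfg <- model$config
  U <- cfg$num_samples
  alpha <- alpha_schedule(epoch, cfg)

  # --- sampling branch (all draws from the module's own stream) ---
  draw <- function() {
    if (is.null(cfg$fixed_sigma)) {
      sigma <- exp(0.5 * nn_forward(model$bsda$estimator, a, training = TRUE))
    } else {
      sigma <- matrix(cfg$fixed_sigma, B, k)
    }
    d_all <- matrix(as.numeric(stats::runif(U * B * k) < cfg$lambda), U * B, k)
    eps_all <- matrix(stats::rnorm(U * B * k), U * B, k)
    list(sigma = sigma, d_all = d_all, eps_all = eps_all)
  }
  dr <- if (is.null(sample_stream)) draw() else with_stream(sample_stream, draw())
  sigma <- dr$sigma; d_all <- dr$d_all; eps_all <- dr$eps_all

  rep_idx <- rep(seq_len(B), times = U)
  sigma_rep <- sigma[rep_idx, , drop = FALSE]
  a_rep <- a[rep_idx, , drop = FALSE]
  m_all <- sigma_rep * eps_all
  ind <- if (cfg$mask_zero) (a != 0) * 1 else matrix(1, B, k)
  ind_rep <- ind[rep_idx, , drop = FALSE]
  a_tilde <- a_rep + ind_rep * d_all * m_all

  # --- head on [a; a_tilde] as one batch ---
  logits_all <- nn_forward(f2, rbind(a, a_tilde), training = TRUE)
  ce_o <- softmax_ce(logits_all[seq_len(B), , drop = FALSE], y)
  ce_a <- softmax_ce(logits_all[-seq_len(B), , drop = FALSE], y[rep_idx])

  # --- variational loss parts ---
  use_recon <- cfg$use_recon && !is.null(model$bsda$reconstructor)
  kl <- if (is.null(cfg$fixed_sigma)) kl_term(sigma) else 0
  recon <- 0
  a_hat <- NULL
  if (use_recon) {
    a_hat <- nn_forward(model$bsda$reconstructor, m_all, training = TRUE)
    recon <- recon_term(a_hat, a_rep)
  }
  total <- total_loss(ce_o$loss, ce_a$loss, kl + recon, alpha)

  if (compute_grads) {
    dlogits <- rbind(ce_o$dlogits, alpha * ce_a$dlogits)
    da_all <- nn_backward(f2, dlogits)
    da <- da_all[seq_len(B), , drop = FALSE]
    d_atilde <- da_all[-seq_len(B), , drop = FALSE]

    dm_all <- d_atilde * ind_rep * d_all
    # identity path a -> a_tilde
    for (u in seq_len(U)) {
      rows <- ((u - 1L) * B + 1L):(u * B)
      da <- da + d_atilde[rows, , drop = FALSE]
    }
    if (use_recon) {
      dahat <- alpha * (a_hat - a_rep) / length(a_hat)
      dm_all <- dm_all + nn_backward(model$bsda$reconstructor, dahat)
      for (u in seq_len(U)) {
        rows <- ((u - 1L) * B + 1L):(u * B)
        da <- da - dahat[rows, , drop = FALSE]  # target side of the MSE
      }
    }
    if (is.null(cfg$fixed_sigma)) {
      dsig_all <- dm_all * eps_all
      dsigma <- matrix(0, B, k)
      for (u in seq_len(U)) {
        rows <- ((u - 1L) * B + 1L):(u * B)
        dsigma <- dsigma + dsig_all[rows, , drop = FALSE]
      }
      dsigma <- dsigma + alpha * (sigma - 1 / sigma) / B  # KL path
      dlogvar <- dsigma * 0.5 * sigma                     # sigma = exp(logvar/2)
      da <- da + nn_backward(model$bsda$estimator, dlogvar)
    }
    nn_backward(f1, da)
  }

  list(total = total,
       parts = list(task_orig = ce_o$loss, task_aug = ce_a$loss,
                    kl = kl, recon = recon),
       alpha = alpha)
}

#' One training-mode forward pass with loss decomposition
#'
#' Executes the full augmented forward pass at the given epoch's alpha and
#' returns the total loss and its parts, without updating any parameters.
#'
#' @param model a [bsda_model()] in training mode.
#' @param x input batch (image array for the CNN backbone, matrix for the MLP).
#' @param labels 0-based integer labels.
#' @param epoch 0-based epoch index (sets alpha via [alpha_schedule()]).
#' @return list with `total`, `parts` (task_orig, task_aug, kl, recon), and
#'   `alpha`.
#' @export
forward_train <- function(model, x, labels, epoch = 0L) {
  stopifnot(inherits(model, "bsda_model"))
  if (!isTRUE(model$state$training)) {
    stop("forward_train requires training mode; augmentation is disabled at evaluation time")
  }
  step_forward_backward(model, x, as.integer(labels), epoch, compute_grads = FALSE)
}

model_nets <- function(model) {
  nets <- list(model$f1, model$f2)
  if (!is.null(model$bsda)) {
    if (!is.null(model$bsda$estimator)) nets <- c(nets, list(model$bsda$estimator))
    if (!is.null(model$bsda$reconstructor)) nets <- c(nets, list(model$bsda$reconstructor))
  }
  nets
}

model_state <- function(model) lapply(model_nets(model), nn_state)

model_load_state <- function(model, state) {
  nets <- model_nets(model)
  stopifnot(length(nets) == length(state))
  for (i in seq_along(nets)) nn_load_state(nets[[i]], state[[i]])
  invisible(model)
}

subset_x <- function(x, idx) {
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx, , , , drop = FALSE]
}

#' Class-probability predictions
#'
#' Evaluation-mode forward pass: no augmentation, BatchNorm running
#' statistics. Rows are softmax probabilities summing to 1.
#'
#' @param object a [bsda_model()].
#' @param x input images/features.
#' @param chunk_size evaluate in chunks of this many rows to bound memory.
#' @param ... unused.
#' @return N x c probability matrix.
#' @export
predict.bsda_model <- function(object, x, chunk_size = 256L, ...) {
  n <- if (is.matrix(x)) nrow(x) else dim(x)[1]
  out <- NULL
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    a <- nn_forward(object$f1, subset_x(x, idx), training = FALSE)
    p <- softmax_rows(nn_forward(object$f2, a, training = FALSE))
    out <- rbind(out, p)
  }
  out
}

split_metrics <- function(model, x, y) {
  p <- predict(model, x)
  list(acc = compute_acc(p, y), auc = compute_auc(p, y))
}

#' Train a model with the full augmented objective
#'
#' Runs the training loop: AdamW with a linear learning-rate warm-up, the
#' alpha warm-up schedule on the augmentation branch, per-epoch validation
#' metrics, and checkpoint selection by best validation AUC (ties broken by
#' ACC, then by the later epoch). Returns test-set metrics of the selected
#' checkpoint plus the per-epoch metrics log.
#'
#' Reproducibility: data order is driven by `tc$seed`, module sampling by the
#' module config's seed, weight init by the model's seed — identical seeds
#' give identical results.
#'
#' @param model a [bsda_model()].
#' @param dataset a dataset with `train`/`val`/`test` splits, e.g. from
#'   [make_blob_images()] or [make_sparse_features()] via [dataset_splits()],
#'   or a list of `list(x =, y =)` splits directly.
#' @param tc a [train_config()].
#' @param verbose print per-epoch progress lines.
#' @return object of class `bsda_fit`: list with `test_acc`, `test_auc`,
#'   `best_epoch`, `log` (metrics data frame), and the trained `model`.
#' @export
fit <- function(model, dataset, tc, verbose = FALSE) {
  stopifnot(inherits(model, "bsda_model"), inherits(tc, "train_config"))
  sp <- dataset_splits(dataset)
  for (s in c("train", "val", "test")) {
    n_s <- if (is.matrix(sp[[s]]$x)) nrow(sp[[s]]$x) else dim(sp[[s]]$x)[1]
    if (is.null(n_s) || n_s < 1) stop("empty ", s, " split")
  }
  n <- length(sp$train$y)
  shuffle_stream <- rng_stream(derive_seed(tc$seed, "shuffle"))
  sample_stream <- if (bsda_enabled(model)) {
    rng_stream(derive_seed(model$config$seed, "bsda_sample"))
  } else NULL
  opt <- adamw_new(model_nets(model), weight_decay = tc$weight_decay)
  set_training(model, TRUE)

  log_rows <- list()
  best <- list(auc = -Inf, acc = -Inf, epoch = -1L, state = NULL)
  for (epoch in 0:(tc$epochs - 1L)) {
    lr <- tc$learning_rate *
      if (tc$warmup_epochs > 0) min(1, (epoch + 1) / tc$warmup_epochs) else 1
    ord <- with_stream(shuffle_stream, sample.int(n))
    sums <- c(total = 0, task_orig = 0, task_aug = 0, kl = 0, recon = 0)
    nb <- 0L
    for (start in seq(1L, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1L, n)]
      if (length(idx) < 2L) next  # BatchNorm needs >= 2 rows
      for (net in model_nets(model)) nn_zero_grads(net)
      res <- step_forward_backward(model, subset_x(sp$train$x, idx),
                                   sp$train$y[idx], epoch,
                                   sample_stream = sample_stream,
                                   compute_grads = TRUE)
      adamw_step(opt, lr)
      sums <- sums + c(res$total, res$parts$task_orig, res$parts$task_aug,
                       res$parts$kl, res$parts$recon)
      nb <- nb + 1L
    }
    avg <- sums / max(nb, 1L)
    vm <- split_metrics(model, sp$val$x, sp$val$y)
    set_training(model, TRUE)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      epoch = epoch, split = "train", loss_total = avg[["total"]],
      loss_task_orig = avg[["task_orig"]], loss_task_aug = avg[["task_aug"]],
      loss_kl = avg[["kl"]], loss_recon = avg[["recon"]],
      acc = NA_real_, auc = NA_real_)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      epoch = epoch, split = "val", loss_total = NA_real_,
      loss_task_orig = NA_real_, loss_task_aug = NA_real_,
      loss_kl = NA_real_, loss_recon = NA_real_,
      acc = vm$acc, auc = vm$auc)
    better <- vm$auc > best$auc ||
      (vm$auc == best$auc && (vm$acc > best$acc ||
                              (vm$acc == best$acc && epoch > best$epoch)))
    if (better) {
      best <- list(auc = vm$auc, acc = vm$acc, epoch = epoch,
                   state = model_state(model))
    }
    if (verbose) {
      message(sprintf(
        "[%s] seed %d epoch %d total %.4f task_orig %.4f task_aug %.4f kl %.4f recon %.4f val_acc %.2f val_auc %.2f",
        format(Sys.time(), "%Y-%m-%d %H:%M:%S"), tc$seed, epoch,
        avg[["total"]], avg[["task_orig"]], avg[["task_aug"]],
        avg[["kl"]], avg[["recon"]], vm$acc, vm$auc))
    }
  }
  model_load_state(model, best$state)
  set_training(model, FALSE)
  tm <- split_metrics(model, sp$test$x, sp$test$y)
  log_rows[[length(log_rows) + 1L]] <- data.frame(
    epoch = best$epoch, split = "test", loss_total = NA_real_,
    loss_task_orig = NA_real_, loss_task_aug = NA_real_,
    loss_kl = NA_real_, loss_recon = NA_real_, acc = tm$acc, auc = tm$auc)
  structure(list(test_acc = tm$acc, test_auc = tm$auc, best_epoch = best$epoch,
                 val_auc = best$auc, log = do.call(rbind, log_rows),
                 model = model),
            class = "bsda_fit")
}

#' Save a trained model to a single checkpoint file
#'
#' The archive embeds all network parameters, the module configuration and
#' the model constructor arguments, so [load_checkpoint()] can rebuild the
#' model exactly.
#' @param model a [bsda_model()].
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(
    backbone = model$backbone, n_classes = model$n_classes,
    input_shape = model$input_shape, input_dim = model$input_dim,
    k = model$k, hidden = model$hidden, seed = model$seed,
    config = model$config, state = model_state(model)
  ), path)
  invisible(path)
}

#' Rebuild a model from a checkpoint file
#' @param path file written by [save_checkpoint()].
#' @return a [bsda_model()] in evaluation mode.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- bsda_model(backbone = ck$backbone, n_classes = ck$n_classes,
                      input_shape = ck$input_shape, input_dim = ck$input_dim,
                      k = ck$k, hidden = ck$hidden, config = ck$config,
                      seed = ck$seed)
  model_load_state(model, ck$state)
  set_training(model, FALSE)
  model
}
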