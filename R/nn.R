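# Minimal neural-network substrate with hand-written backpropagation.
#
# No deep-learning framework ships with this R installation, so the layers the
# method needs (dense, BatchNorm, GeLU, 3x3 convolution, max pooling, global
# average pooling) are implemented directly on base matrices/arrays. Each layer
# is an environment carrying parameters, parameter gradients, and the forward
# cache needed by its backward pass. Gradient correctness is established by
# finite-difference checks in the test suite.

new_layer <- function(type) {
  l <- new.env(parent = emptyenv())
  l$type <- type
  l$params <- list()
  l$grads <- list()
  l$cache <- NULL
  l
}

#' Dense (fully connected) layer
#' @param fan_in,fan_out input/output widths.
#' @param zero_init initialize all parameters at zero (used for the estimator
#'   head so that training starts at sigma = 1).
#' @keywords internal
nn_linear <- function(fan_in, fan_out, zero_init = FALSE) {
  l <- new_layer("linear")
  if (zero_init) {
    W <- matrix(0, fan_in, fan_out)
  } else {
    W <- matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(2 / fan_in)), fan_in, fan_out)
  }
  l$params <- list(W = W, b = numeric(fan_out))
  l
}

#' BatchNorm over features (input N x k)
#' @keywords internal
nn_batchnorm <- function(k, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("batchnorm")
  l$params <- list(gamma = rep(1, k), beta = rep(0, k))
  l$running_mean <- rep(0, k)
  l$running_var <- rep(1, k)
  l$momentum <- momentum
  l$eps <- eps
  l
}

#' GeLU activation (exact, via the normal CDF)
#' @keywords internal
nn_gelu <- function() new_layer("gelu")

#' 3x3 same-padding convolution on N x H x W x C arrays
#' @keywords internal
nn_conv3x3 <- function(c_in, c_out) {
  l <- new_layer("conv")
  fan_in <- 9 * c_in
  l$params <- list(
    W = matrix(stats::rnorm(fan_in * c_out, sd = sqrt(2 / fan_in)), fan_in, c_out),
    b = numeric(c_out)
  )
  l$c_in <- c_in
  l$c_out <- c_out
  l
}

#' 2x2 stride-2 max pooling
#' @keywords internal
nn_maxpool2 <- function() new_layer("maxpool")

#' Global average pooling N x H x W x C -> N x C
#' @keywords internal
nn_gap <- function() new_layer("gap")

#' Sequential container
#' @keywords internal
nn_sequential <- function(...) {
  net <- new.env(parent = emptyenv())
  net$layers <- list(...)
  net
}

# ---- forward -----------------------------------------------------------------

layer_forward <- function(l, x, training) {
  switch(l$type,
    linear = {
      l$cache <- list(x = x)
      x %*% l$params$W + matrix(l$params$b, nrow(x), length(l$params$b), byrow = TRUE)
    },
    batchnorm = {
      k <- length(l$params$gamma)
      if (training) {
        n <- nrow(x)
        mu <- colMeans(x)
        vr <- colMeans(x^2) - mu^2
        vr <- pmax(vr, 0)
        if (n > 1) {
          l$running_mean <- (1 - l$momentum) * l$running_mean + l$momentum * mu
          l$running_var <- (1 - l$momentum) * l$running_var + l$momentum * vr * n / (n - 1)
        }
      } else {
        mu <- l$running_mean
        vr <- l$running_var
      }
      ivar <- 1 / sqrt(vr + l$eps)
      xc <- x - matrix(mu, nrow(x), k, byrow = TRUE)
      xhat <- xc * matrix(ivar, nrow(x), k, byrow = TRUE)
      l$cache <- list(xc = xc, ivar = ivar, xhat = xhat, training = training)
      xhat * matrix(l$params$gamma, nrow(x), k, byrow = TRUE) +
        matrix(l$params$beta, nrow(x), k, byrow = TRUE)
    },
    gelu = {
      l$cache <- list(x = x)
      x * stats::pnorm(x)
    },
    conv = {
      dims <- dim(x)
      n <- dims[1]; h <- dims[2]; w <- dims[3]; ci <- dims[4]
      stopifnot(ci == l$c_in)
      xp <- array(0, c(n, h + 2, w + 2, ci))
      xp[, 2:(h + 1), 2:(w + 1), ] <- x
      cols <- matrix(0, n * h * w, 9 * ci)
      p <- 0L
      for (j in 1:3) for (i in 1:3) {
        p <- p + 1L
        blk <- xp[, i:(i + h - 1), j:(j + w - 1), , drop = FALSE]
        dim(blk) <- c(n * h * w, ci)
        cols[, ((p - 1L) * ci + 1L):(p * ci)] <- blk
      }
      out <- cols %*% l$params$W +
        matrix(l$params$b, n * h * w, l$c_out, byrow = TRUE)
      l$cache <- list(cols = cols, in_dim = dims)
      dim(out) <- c(n, h, w, l$c_out)
      out
    },
    maxpool = {
      d <- dim(x)
      n <- d[1]; h <- d[2]; w <- d[3]; ci <- d[4]
      oi <- seq(1, h, 2); oj <- seq(1, w, 2)
      s <- list(
        x[, oi, oj, , drop = FALSE], x[, oi + 1, oj, , drop = FALSE],
        x[, oi, oj + 1, , drop = FALSE], x[, oi + 1, oj + 1, , drop = FALSE]
      )
      m <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
      taken <- array(FALSE, dim(m))
      masks <- vector("list", 4)
      for (q in 1:4) {
        mk <- (s[[q]] == m) & !taken
        taken <- taken | mk
        masks[[q]] <- mk
      }
      l$cache <- list(masks = masks, in_dim = d)
      m
    },
    gap = {
      d <- dim(x)
      n <- d[1]; hw <- d[2] * d[3]; ci <- d[4]
      xm <- x
      dim(xm) <- c(n, hw, ci)
      out <- matrix(0, n, ci)
      for (cc in seq_len(ci)) out[, cc] <- rowMeans(xm[, , cc, drop = FALSE])
      l$cache <- list(in_dim = d)
      out
    },
    stop("unknown layer type: ", l$type)
  )
}

# ---- backward ----------------------------------------------------------------

layer_backward <- function(l, dout) {
  switch(l$type,
    linear = {
      x <- l$cache$x
      l$grads$W <- acc(l$grads$W, crossprod(x, dout))
      l$grads$b <- acc(l$grads$b, colSums(dout))
      dout %*% t(l$params$W)
    },
    batchnorm = {
      if (!isTRUE(l$cache$training)) {
        k <- length(l$params$gamma)
        gi <- l$params$gamma * l$cache$ivar
        l$grads$gamma <- acc(l$grads$gamma, colSums(dout * l$cache$xhat))
        l$grads$beta <- acc(l$grads$beta, colSums(dout))
        return(dout * matrix(gi, nrow(dout), k, byrow = TRUE))
      }
      n <- nrow(dout); k <- ncol(dout)
      xhat <- l$cache$xhat; ivar <- l$cache$ivar; xc <- l$cache$xc
      l$grads$gamma <- acc(l$grads$gamma, colSums(dout * xhat))
      l$grads$beta <- acc(l$grads$beta, colSums(dout))
      dxhat <- dout * matrix(l$params$gamma, n, k, byrow = TRUE)
      ivm <- matrix(ivar, n, k, byrow = TRUE)
      dvar <- colSums(dxhat * xc) * (-0.5) * ivar^3
      dmu <- colSums(-dxhat * ivm) + dvar * colMeans(-2 * xc)
      dxhat * ivm +
        xc * matrix(2 * dvar / n, n, k, byrow = TRUE) +
        matrix(dmu / n, n, k, byrow = TRUE)
    },
    gelu = {
      x <- l$cache$x
      dout * (stats::pnorm(x) + x * stats::dnorm(x))
    },
    conv = {
      d <- l$cache$in_dim
      n <- d[1]; h <- d[2]; w <- d[3]; ci <- d[4]
      dom <- dout
      dim(dom) <- c(n * h * w, l$c_out)
      l$grads$W <- acc(l$grads$W, crossprod(l$cache$cols, dom))
      l$grads$b <- acc(l$grads$b, colSums(dom))
      dcols <- dom %*% t(l$params$W)
      dxp <- array(0, c(n, h + 2, w + 2, ci))
      p <- 0L
      for (j in 1:3) for (i in 1:3) {
        p <- p + 1L
        blk <- dcols[, ((p - 1L) * ci + 1L):(p * ci)]
        dim(blk) <- c(n, h, w, ci)
        dxp[, i:(i + h - 1), j:(j + w - 1), ] <-
          dxp[, i:(i + h - 1), j:(j + w - 1), , drop = FALSE] + blk
      }
      dxp[, 2:(h + 1), 2:(w + 1), , drop = FALSE]
    },
    maxpool = {
      d <- l$cache$in_dim
      n <- d[1]; h <- d[2]; w <- d[3]; ci <- d[4]
      oi <- seq(1, h, 2); oj <- seq(1, w, 2)
      dx <- array(0, d)
      off <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
      for (q in 1:4) {
        dx[, oi + off[[q]][1], oj + off[[q]][2], ] <-
          dx[, oi + off[[q]][1], oj + off[[q]][2], , drop = FALSE] +
          dout * l$cache$masks[[q]]
      }
      dx
    },
    gap = {
      d <- l$cache$in_dim
      n <- d[1]; h <- d[2]; w <- d[3]; ci <- d[4]
      dx <- array(0, d)
      sc <- dout / (h * w)
      for (cc in seq_len(ci)) dx[, , , cc] <- array(rep(sc[, cc], h * w), c(n, h, w))
      dx
    },
    stop("unknown layer type: ", l$type)
  )
}

acc <- function(g, delta) if (is.null(g)) delta else g + delta

#' Forward pass through a sequential net
#' @keywords internal
nn_forward <- function(net, x, training = TRUE) {
  for (l in net$layers) x <- layer_forward(l, x, training)
  x
}

#' Backward pass; accumulates parameter gradients, returns input gradient
#' @keywords internal
nn_backward <- function(net, dout) {
  for (l in rev(net$layers)) dout <- layer_backward(l, dout)
  dout
}

#' Zero all accumulated gradients
#' @keywords internal
nn_zero_grads <- function(net) {
  for (l in net$layers) l$grads <- list()
  invisible(net)
}

# ---- parameter state (checkpointing, cloning) --------------------------------

#' Extract all parameters (and BatchNorm running stats) as a plain list
#' @keywords internal
nn_state <- function(net) {
  lapply(net$layers, function(l) {
    s <- list(params = l$params)
    if (l$type == "batchnorm") {
      s$running_mean <- l$running_mean
      s$running_var <- l$running_var
    }
    s
  })
}

#' Restore parameters from [nn_state()]
#' @keywords internal
nn_load_state <- function(net, state) {
  stopifnot(length(state) == length(net$layers))
  for (i in seq_along(net$layers)) {
    net$layers[[i]]$params <- state[[i]]$params
    if (net$layers[[i]]$type == "batchnorm") {
      net$layers[[i]]$running_mean <- state[[i]]$running_mean
      net$layers[[i]]$running_var <- state[[i]]$running_var
    }
  }
  invisible(net)
}

# ---- AdamW -------------------------------------------------------------------

#' AdamW optimizer over a list of nets
#'
#' Adaptive-moment estimation with decoupled weight decay. Decay is applied to
#' weight matrices only, never to biases or BatchNorm scale/shift.
#' @keywords internal
adamw_new <- function(nets, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0) {
  o <- new.env(parent = emptyenv())
  o$nets <- nets
  o$beta1 <- beta1; o$beta2 <- beta2; o$eps <- eps
  o$weight_decay <- weight_decay
  o$t <- 0L
  o$m <- list(); o$v <- list()
  o
}

#' One AdamW update from accumulated gradients
#' @keywords internal
adamw_step <- function(opt, lr) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (ni in seq_along(opt$nets)) {
    net <- opt$nets[[ni]]
    for (li in seq_along(net$layers)) {
      l <- net$layers[[li]]
      for (pn in names(l$params)) {
        g <- l$grads[[pn]]
        if (is.null(g)) next
        key <- paste(ni, li, pn, sep = ".")
        if (is.null(opt$m[[key]])) {
          opt$m[[key]] <- g * 0
          opt$v[[key]] <- g * 0
        }
        opt$m[[key]] <- opt$beta1 * opt$m[[key]] + (1 - opt$beta1) * g
        opt$v[[key]] <- opt$beta2 * opt$v[[key]] + (1 - opt$beta2) * g^2
        mhat <- opt$m[[key]] / bc1
        vhat <- opt$v[[key]] / bc2
        p <- l$params[[pn]]
        if (opt$weight_decay > 0 && pn == "W") p <- p - lr * opt$weight_decay * p
        l$params[[pn]] <- p - lr * mhat / (sqrt(vhat) + opt$eps)
      }
    }
  }
  invisible(opt)
}

# ---- losses ------------------------------------------------------------------

#' Softmax cross-entropy with gradient
#'
#' @param logits N x c matrix.
#' @param labels 0-based integer vector of length N.
#' @return list with `loss` (mean over rows), `probs`, and `dlogits`
#'   (gradient of the mean loss).
#' @keywords internal
softmax_ce <- function(logits, labels) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  idx <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(probs[idx], 1e-12)))
  dl <- probs
  dl[idx] <- dl[idx] - 1
  list(loss = loss, probs = probs, dlogits = dl / n)
}

#' Row-wise softmax
#' @keywords internal
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  ez / rowSums(ez)
}
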