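# Exact t-SNE (quadratic in the number of points). Desk-scale visualization
# only needs a few hundred points, so the Barnes-Hut approximation is not
# worth its complexity here. Standard recipe: per-point bandwidths found by
# binary search on the perplexity, symmetrized affinities, early exaggeration,
# momentum gradient descent with per-coordinate gains.

tsne_perplexity_p <- function(X, perplexity) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betamin <- -Inf; betamax <- Inf
    Di <- D[i, -i]
    for (it in 1:50) {
      Pi <- exp(-Di * beta)
      sumP <- sum(Pi)
      if (sumP < 1e-300) sumP <- 1e-300
      H <- log(sumP) + beta * sum(Di * Pi) / sumP
      if (abs(H - logU) < 1e-5) break
      if (H > logU) {
        betamin <- beta
        beta <- if (is.finite(betamax)) (beta + betamax) / 2 else beta * 2
      } else {
        betamax <- beta
        beta <- if (is.finite(betamin)) (beta + betamin) / 2 else beta / 2
      }
    }
    P[i, -i] <- Pi / sumP
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' 2D embedding by exact t-SNE
#'
#' @param X N x k matrix.
#' @param perplexity effective neighborhood size.
#' @param max_iter iterations of gradient descent.
#' @param seed controls the random initialization; the embedding is a
#'   deterministic function of `(X, perplexity, max_iter, seed)`.
#' @return N x 2 coordinate matrix.
#' @keywords internal
tsne_embed <- function(X, perplexity = 10, max_iter = 400L, seed = 0L) {
  n <- nrow(X)
  P <- tsne_perplexity_p(as.matrix(X), perplexity)
  stream <- rng_stream(derive_seed(seed, "tsne"))
  Y <- with_stream(stream, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  dY <- matrix(0, n, 2); iY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
  exag <- 12; stop_exag <- 100L
  eta <- 200
  Pex <- P * exag
  for (iter in seq_len(max_iter)) {
    if (iter == stop_exag + 1L) Pex <- P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pex - Q) * num
    dY <- 4 * (diag(rowSums(L)) - L) %*% Y
    momentum <- if (iter <= 20) 0.5 else 0.8
    gains <- ifelse(sign(dY) != sign(iY), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    iY <- momentum * iY - eta * (gains * dY)
    Y <- Y + iY
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}
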