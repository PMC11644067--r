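# Independent oracles used across the suite.

# KL(N(0, s2) || N(0, 1)) by numerical integration, independent of the
# closed form used in the package.
kl_numeric <- function(s2) {
  f <- function(x) {
    q <- stats::dnorm(x, 0, sqrt(s2))
    lr <- stats::dnorm(x, 0, sqrt(s2), log = TRUE) - stats::dnorm(x, log = TRUE)
    ifelse(q > 0, q * lr, 0)
  }
  lim <- 20 * sqrt(max(s2, 1))
  stats::integrate(f, -lim, lim, rel.tol = 1e-12, abs.tol = 1e-12)$value
}

# Brute-force pairwise AUC: fraction of correctly ordered positive-negative
# pairs, ties counted one half.
auc_bruteforce <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# Central finite-difference gradient of f at x[idx].
fd_grad <- function(f, x, idx, h = 1e-5) {
  xp <- x; xp[idx] <- xp[idx] + h
  xm <- x; xm[idx] <- xm[idx] - h
  (f(xp) - f(xm)) / (2 * h)
}

# Shared small blob dataset, built once per test run.
blob_cache <- new.env(parent = emptyenv())
get_blobs <- function(n = 300, classes = 3, size = 32, noise = 0.05, seed = 0) {
  key <- paste(n, classes, size, noise, seed, sep = "_")
  if (is.null(blob_cache[[key]])) {
    blob_cache[[key]] <- make_blob_images(n, classes, size, noise, seed = seed)
  }
  blob_cache[[key]]
}
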