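# Evaluation: ACC/AUC metrics, the repeated-seed mean +/- standard-error
# protocol, and feature-space visualization.

#' Classification accuracy (percent)
#'
#' Argmax of each probability row against the label; ties are broken toward
#' the lowest class index.
#'
#' @param probabilities N x c matrix of class probabilities (or scores).
#' @param labels 0-based integer labels.
#' @return accuracy in percent.
#' @export
compute_acc <- function(probabilities, labels) {
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) == 0) stop("empty input")
  if (nrow(probabilities) != length(labels)) stop("probabilities/labels length mismatch")
  pred <- max.col(probabilities, ties.method = "first") - 1L
  100 * mean(pred == as.integer(labels))
}

auc_binary <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(score)  # average ranks: ties count 1/2
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the ROC curve (percent)
#'
#' Binary problems use the positive-class (class 1) probability; ties in the
#' score count one half, equivalent to the Mann-Whitney statistic.
#' Multi-class problems are scored one-vs-rest per class and macro-averaged
#' without weights over the classes present in `labels`.
#'
#' @param probabilities N x c probability matrix, or a score vector for a
#'   binary problem.
#' @param labels 0-based integer labels; at least two classes must be
#'   present.
#' @return AUC in percent.
#' @export
compute_auc <- function(probabilities, labels) {
  labels <- as.integer(labels)
  present <- sort(unique(labels))
  if (length(present) < 2) stop("AUC requires at least two classes present in labels")
  if (is.null(dim(probabilities))) {
    return(100 * auc_binary(as.numeric(probabilities), labels == max(present)))
  }
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) != length(labels)) stop("probabilities/labels length mismatch")
  if (ncol(probabilities) == 2 && identical(present, c(0L, 1L))) {
    return(100 * auc_binary(probabilities[, 2], labels == 1L))
  }
  100 * mean(vapply(present, function(cl) {
    auc_binary(probabilities[, cl + 1L], labels == cl)
  }, numeric(1)))
}

#' Repeated-seed evaluation protocol
#'
#' Runs `runner(seed)` for every seed and aggregates the returned ACC/AUC
#' values as mean and standard error (sample standard deviation divided by
#' the square root of the number of seeds). Three seeds is the conventional
#' default.
#'
#' @param runner function taking a seed and returning `list(acc =, auc =)`
#'   in percent.
#' @param seeds integer vector of length >= 2 (default `c(0, 1, 2)`).
#' @return object of class `run_result`: `per_seed` data frame plus
#'   `mean_acc`, `mean_auc`, `stderr_acc`, `stderr_auc`.
#' @export
multi_seed_protocol <- function(runner, seeds = c(0L, 1L, 2L)) {
  if (length(seeds) < 2) stop("need at least 2 seeds")
  rows <- lapply(seeds, function(s) {
    r <- tryCatch(runner(s), error = function(e) {
      stop("runner failed for seed ", s, ": ", conditionMessage(e))
    })
    data.frame(seed = s, acc = r$acc, auc = r$auc)
  })
  per_seed <- do.call(rbind, rows)
  ns <- length(seeds)
  structure(list(
    per_seed = per_seed,
    mean_acc = mean(per_seed$acc), mean_auc = mean(per_seed$auc),
    stderr_acc = stats::sd(per_seed$acc) / sqrt(ns),
    stderr_auc = stats::sd(per_seed$auc) / sqrt(ns)
  ), class = "run_result")
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("ACC %.2f%% +/- %.2f | AUC %.2f%% +/- %.2f (n = %d seeds)\n",
              x$mean_acc, x$stderr_acc, x$mean_auc, x$stderr_auc,
              nrow(x$per_seed)))
  invisible(x)
}

#' Embed original and augmented features with t-SNE and export the result
#'
#' Concatenates original and augmented feature vectors, embeds them into 2D
#' with exact t-SNE, writes the coordinates to a CSV (`x`, `y`, `label`,
#' `is_augmented`) and draws a figure with circles for original features and
#' crosses for augmented ones, colored by class.
#'
#' @param original a [feature_batch()] or bare N x k matrix.
#' @param augmented matrix of augmented features sharing dimension k.
#' @param labels 0-based labels for the original rows; augmented rows reuse
#'   their source labels (recycled if `nrow(augmented)` is a multiple of N).
#' @param path output CSV path; the figure is written next to it as `.pdf`.
#' @param seed embedding seed.
#' @param perplexity t-SNE perplexity (default 10; needs at least
#'   `3 * perplexity + 1` points).
#' @param max_iter gradient-descent iterations.
#' @return invisibly, a list with the coordinates data frame and file paths.
#' @export
tsne_export <- function(original, augmented, labels = NULL, path,
                        seed = 0L, perplexity = 10, max_iter = 400L) {
  a <- if (inherits(original, "feature_batch")) original$features else as.matrix(original)
  if (is.null(labels) && inherits(original, "feature_batch")) labels <- original$labels
  augmented <- as.matrix(augmented)
  if (ncol(a) != ncol(augmented)) stop("original and augmented must share dimension k")
  n_o <- nrow(a); n_a <- nrow(augmented)
  if (n_a %% n_o != 0) stop("nrow(augmented) must be a multiple of nrow(original)")
  labels <- as.integer(labels)
  all_lab <- c(labels, rep(labels, times = n_a / n_o))
  X <- rbind(a, augmented)
  if (nrow(X) < 3 * perplexity + 1) {
    stop("too few points for perplexity ", perplexity,
         ": need at least ", 3 * perplexity + 1,
         " rows; lower perplexity or add points")
  }
  Y <- tsne_embed(X, perplexity = perplexity, max_iter = max_iter, seed = seed)
  df <- data.frame(x = Y[, 1], y = Y[, 2], label = all_lab,
                   is_augmented = rep(c(FALSE, TRUE), c(n_o, n_a)))
  utils::write.csv(df, path, row.names = FALSE)
  fig <- paste0(sub("\\.[^.]*$", "", path), ".pdf")
  grDevices::pdf(fig, width = 5, height = 5)
  cols <- df$label + 1L
  graphics::plot(df$x, df$y, type = "n", xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = "original (o) vs augmented (x) features")
  graphics::points(df$x[!df$is_augmented], df$y[!df$is_augmented],
                   pch = 1, col = cols[!df$is_augmented])
  graphics::points(df$x[df$is_augmented], df$y[df$is_augmented],
                   pch = 4, col = cols[df$is_augmented])
  grDevices::dev.off()
  invisible(list(coordinates = df, csv = path, figure = fig))
}
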