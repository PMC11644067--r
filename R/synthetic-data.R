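# Desk-scale synthetic fixtures with the statistical structure the
# augmentation module assumes: small multi-class images whose classes differ
# in shape family while a size attribute varies continuously within class,
# and sparse non-negative feature vectors with known class means and a known
# label-preserving perturbation radius.

#' Generate a synthetic ellipse ("blob") image dataset
#'
#' Each image contains one or two bright ellipses on a dark background. The
#' class determines the shape family (eccentricity, and ellipse count beyond
#' three classes); the latent attribute — the ellipse radius — varies
#' continuously and uniformly within class, so a within-class semantic
#' magnitude exists by construction. Splits follow the 7:1:2
#' train/validation/test convention.
#'
#' @param n number of images (>= 10 per class).
#' @param classes number of classes.
#' @param size image side length in pixels (>= 16).
#' @param noise standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return object of class `blob_image_dataset`: `images` (n x size x size x
#'   1 array in `[0,1]`), `labels` (0-based), `attribute` (radius in pixels),
#'   `split` (index vectors `train`/`val`/`test`), `n_classes`.
#' @export
make_blob_images <- function(n, classes = 3L, size = 32L, noise = 0.05,
                             seed = 0L) {
  n <- as.integer(n); classes <- as.integer(classes); size <- as.integer(size)
  if (n < classes * 10L) stop("n must be at least 10 images per class")
  if (size < 16L) stop("size must be >= 16")
  stream <- rng_stream(derive_seed(seed, "blobs"))
  labels <- rep(0:(classes - 1L), length.out = n)
  ratios <- c(1.0, 0.45, 0.22)
  with_stream(stream, {
    radius <- stats::runif(n, 0.25, 0.45) * (size / 2)
    images <- array(0, c(n, size, size, 1))
    gx <- matrix(seq_len(size), size, size)                 # row coordinate
    gy <- matrix(seq_len(size), size, size, byrow = TRUE)   # column coordinate
    cx <- (size + 1) / 2
    for (i in seq_len(n)) {
      cls <- labels[i]
      ratio <- ratios[(cls %% 3L) + 1L]
      count <- 1L + cls %/% 3L
      img <- matrix(0, size, size)
      offs <- if (count == 1L) 0 else seq(-size / 5, size / 5, length.out = count)
      for (o in offs) {
        d <- sqrt(((gx - cx - o) / radius[i])^2 + ((gy - cx) / (radius[i] * ratio))^2)
        img <- pmax(img, pmin(1, pmax(0, (1 - d) * 4)) * 0.8)
      }
      if (noise > 0) img <- img + matrix(stats::rnorm(size * size, sd = noise), size, size)
      images[i, , , 1] <- pmin(1, pmax(0, img))
    }
    ord <- sample.int(n)
    n_tr <- round(0.7 * n); n_va <- round(0.1 * n)
    structure(list(
      images = images, labels = labels, attribute = radius,
      split = list(train = sort(ord[seq_len(n_tr)]),
                   val = sort(ord[(n_tr + 1L):(n_tr + n_va)]),
                   test = sort(ord[(n_tr + n_va + 1L):n])),
      n_classes = classes
    ), class = "blob_image_dataset")
  })
}

#' Generate sparse non-negative feature vectors with known geometry
#'
#' Emulates post-activation deep features: each class has a mean vector that
#' is exactly zero outside a class-specific support (hit the target zero
#' fraction) and positive on it; class means are rescaled so their minimal
#' pairwise distance equals `sep`. Samples add small norm-capped Gaussian
#' noise on the support only, so every sample keeps the exact zero pattern
#' and is closer to its own class mean than to any other — nearest-class-mean
#' classification of clean features is correct by construction.
#' `label_radius` (per class) is half the distance from that class mean to
#' the nearest other mean: any perturbation of smaller norm cannot change the
#' nearest-mean label of the mean point.
#'
#' @param n number of samples.
#' @param k feature dimension.
#' @param classes number of classes (>= 2).
#' @param zero_frac target fraction of exact zeros in `[0, 1)`.
#' @param sep minimal pairwise distance between class means (> 0).
#' @param seed integer seed.
#' @return object of class `sparse_feature_dataset`: `features` (n x k,
#'   non-negative), `labels` (0-based), `class_means` (classes x k),
#'   `label_radius` (length-classes vector), `split`, `n_classes`.
#' @export
make_sparse_features <- function(n, k, classes = 3L, zero_frac = 0.5,
                                 sep = 6, seed = 0L) {
  n <- as.integer(n); k <- as.integer(k); classes <- as.integer(classes)
  if (zero_frac < 0 || zero_frac >= 1) stop("zero_frac must be in [0, 1)")
  if (sep <= 0) stop("sep must be > 0")
  if (classes < 2L) stop("need at least 2 classes")
  n_zero <- round(zero_frac * k)
  n_sup <- k - n_zero
  if (n_sup < 1L) stop("infeasible zero_frac: no non-zero coordinates left")
  stream <- rng_stream(derive_seed(seed, "sparse"))
  with_stream(stream, {
    means <- matrix(0, classes, k)
    for (cl in seq_len(classes)) {
      sup <- sample.int(k, n_sup)
      means[cl, sup] <- abs(stats::rnorm(n_sup, 1, 0.5)) + 0.5
    }
    dm <- as.matrix(stats::dist(means))
    min_d <- min(dm[upper.tri(dm)])
    if (min_d <= 0) stop("infeasible zero_frac/sep combination: coincident class means")
    means <- means * (sep / min_d)
    dm <- dm * (sep / min_d)
    labels <- rep(0:(classes - 1L), length.out = n)
    feats <- means[labels + 1L, , drop = FALSE]
    noise_sd <- 0.02 * sep
    cap <- 0.2 * sep
    for (i in seq_len(n)) {
      sup <- which(feats[i, ] > 0)
      nz <- stats::rnorm(length(sup), 0, noise_sd)
      nrm <- sqrt(sum(nz^2))
      if (nrm > cap) nz <- nz * cap / nrm
      feats[i, sup] <- pmax(feats[i, sup] + nz, 1e-6)
    }
    if (any(nearest_mean_label(feats, means) != labels)) {
      stop("infeasible zero_frac/sep combination: construction lost separability")
    }
    label_radius <- vapply(seq_len(classes), function(cl) {
      min(dm[cl, -cl]) / 2
    }, numeric(1))
    ord <- sample.int(n)
    n_tr <- round(0.7 * n); n_va <- round(0.1 * n)
    structure(list(
      features = feats, labels = labels, class_means = means,
      label_radius = label_radius,
      split = list(train = sort(ord[seq_len(n_tr)]),
                   val = sort(ord[(n_tr + 1L):(n_tr + n_va)]),
                   test = sort(ord[(n_tr + n_va + 1L):n])),
      n_classes = classes
    ), class = "sparse_feature_dataset")
  })
}

#' Nearest-class-mean labels
#' @param features N x k matrix.
#' @param class_means c x k matrix (row order = class 0, 1, ...).
#' @return 0-based integer labels.
#' @export
nearest_mean_label <- function(features, class_means) {
  features <- as.matrix(features)
  d2 <- outer(rowSums(features^2), rep(1, nrow(class_means))) -
    2 * features %*% t(class_means) +
    outer(rep(1, nrow(features)), rowSums(class_means^2))
  max.col(-d2, ties.method = "first") - 1L
}

#' Extract train/val/test splits in harness form
#'
#' @param dataset a `blob_image_dataset`, `sparse_feature_dataset`, the list
#'   returned by [read_npz_layout()], or already a list of splits.
#' @return list with `train`, `val`, `test`, each `list(x =, y =)`.
#' @export
dataset_splits <- function(dataset) {
  if (inherits(dataset, "blob_image_dataset")) {
    lapply(dataset$split, function(idx) {
      list(x = dataset$images[idx, , , , drop = FALSE], y = dataset$labels[idx])
    })
  } else if (inherits(dataset, "sparse_feature_dataset")) {
    lapply(dataset$split, function(idx) {
      list(x = dataset$features[idx, , drop = FALSE], y = dataset$labels[idx])
    })
  } else if (inherits(dataset, "npz_dataset") ||
             (is.list(dataset) && all(c("train", "val", "test") %in% names(dataset)))) {
    dataset[c("train", "val", "test")]
  } else {
    stop("unsupported dataset object")
  }
}

#' Write a dataset in the six-array packed layout
#'
#' Writes `train_images`, `train_labels`, `val_images`, `val_labels`,
#' `test_images`, `test_labels` into one `.npz`-layout archive (a ZIP of
#' `.npy` members), the packed-array convention of the MedMNIST family.
#' Images are stored as float64 with their full N x H x W x C shape; labels
#' as N x 1 integer column vectors.
#'
#' @param dataset a `blob_image_dataset`.
#' @param path output file path (conventionally `.npz`).
#' @return `path`, invisibly.
#' @export
write_npz_layout <- function(dataset, path) {
  stopifnot(inherits(dataset, "blob_image_dataset"))
  arrays <- list()
  for (s in c("train", "val", "test")) {
    idx <- dataset$split[[s]]
    arrays[[paste0(s, "_images")]] <- dataset$images[idx, , , , drop = FALSE]
    arrays[[paste0(s, "_labels")]] <- matrix(as.integer(dataset$labels[idx]), ncol = 1)
  }
  npz_write(arrays, path)
  invisible(path)
}

#' Read a packed six-array dataset
#'
#' Accepts archives written by [write_npz_layout()] or by numpy's
#' `savez`/`savez_compressed` (stored or deflated members). Grayscale images
#' stored as N x H x W are expanded to N x H x W x 1.
#'
#' @param path archive path.
#' @return object of class `npz_dataset`: list of `train`/`val`/`test`
#'   splits, each `list(x = images, y = labels)`.
#' @export
read_npz_layout <- function(path) {
  arrays <- npz_read(path)
  need <- c("train_images", "train_labels", "val_images", "val_labels",
            "test_images", "test_labels")
  missing <- setdiff(need, names(arrays))
  if (length(missing)) {
    stop("packed dataset is missing array(s): ", paste(missing, collapse = ", "))
  }
  out <- lapply(c(train = "train", val = "val", test = "test"), function(s) {
    x <- arrays[[paste0(s, "_images")]]
    if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
    y <- as.integer(arrays[[paste0(s, "_labels")]])
    list(x = x, y = y)
  })
  structure(out, class = "npz_dataset")
}
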