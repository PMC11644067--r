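# Synthetic fixtures: blob images, sparse features, and the packed-array
# container.

test_that("blob images honor the 7:1:2 split, determinism, and the attribute axis", {
  ds <- make_blob_images(300, 3, 32, 0.05, seed = 0)
  expect_equal(lengths(ds$split[c("train", "val", "test")]),
               c(train = 210L, val = 30L, test = 60L))
  expect_equal(dim(ds$images), c(300, 32, 32, 1))
  expect_true(all(ds$images >= 0 & ds$images <= 1))
  ds2 <- make_blob_images(300, 3, 32, 0.05, seed = 0)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$split, ds2$split)
  expect_false(identical(ds$images, make_blob_images(300, 3, 32, 0.05, seed = 1)$images))
  # noiseless: within a class the image is driven by the attribute alone —
  # blob area (mean pixel) increases monotonically with the radius attribute
  dn <- make_blob_images(60, 3, 32, 0, seed = 3)
  cls0 <- which(dn$labels == 0)
  pm0 <- apply(dn$images[cls0, , , , drop = FALSE], 1, mean)
  expect_gt(stats::cor(pm0, dn$attribute[cls0], method = "spearman"), 0.99)
  # a pixel-mean threshold classifier beats chance
  pm <- apply(dn$images, 1, mean)
  fit_lm <- stats::aov(pm ~ factor(dn$labels))
  expect_lt(summary(fit_lm)[[1]][["Pr(>F)"]][1], 0.01)
  expect_error(make_blob_images(20, 3), "at least 10")
  expect_error(make_blob_images(300, 3, size = 8), "size")
})

test_that("sparse features hit the zero fraction and are separable by construction", {
  ds <- make_sparse_features(1e4, 50, classes = 3, zero_frac = 0.5, sep = 6, seed = 0)
  zf <- mean(ds$features == 0)
  expect_gte(zf, 0.48); expect_lte(zf, 0.52)
  expect_true(all(ds$features >= 0))
  expect_identical(nearest_mean_label(ds$features, ds$class_means), ds$labels)
  # minimal pairwise mean distance equals sep; label_radius is half of it
  dm <- as.matrix(stats::dist(ds$class_means))
  expect_equal(min(dm[upper.tri(dm)]), 6, tolerance = 1e-9)
  expect_equal(min(ds$label_radius), 3, tolerance = 1e-9)
  # mean perturbations below label_radius never flip the nearest-mean label
  set.seed(41)
  for (i in 1:20) {
    cl <- sample(0:2, 1)
    u <- rnorm(50); u <- u / sqrt(sum(u^2)) * runif(1, 0, 0.999) * ds$label_radius[cl + 1]
    x <- ds$class_means[cl + 1, ] + u
    expect_identical(nearest_mean_label(matrix(x, 1), ds$class_means), cl)
  }
  ds2 <- make_sparse_features(1e4, 50, 3, 0.5, 6, seed = 0)
  expect_identical(ds$features, ds2$features)
  expect_error(make_sparse_features(100, 10, 3, zero_frac = 1), "zero_frac")
  expect_error(make_sparse_features(100, 10, 3, zero_frac = 0.99), "infeasible")
  expect_error(make_sparse_features(100, 10, 3, sep = -1), "sep")
})

test_that("npz layout round-trips exactly and validates keys", {
  ds <- make_blob_images(60, 3, 16, 0.05, seed = 2)
  path <- tempfile(fileext = ".npz")
  write_npz_layout(ds, path)
  rt <- read_npz_layout(path)
  for (s in c("train", "val", "test")) {
    idx <- ds$split[[s]]
    expect_equal(unname(rt[[s]]$x), unname(ds$images[idx, , , , drop = FALSE]))
    expect_identical(rt[[s]]$y, as.integer(ds$labels[idx]))
  }
  # labels are stored as N x 1 integer column vectors
  arrays <- bsda:::npz_read(path)
  expect_equal(dim(arrays$train_labels), c(42L, 1L))
  expect_true(is.integer(arrays$train_labels))
  # a missing array is reported by name
  bsda:::npz_write(arrays[c("train_images", "train_labels")], path)
  expect_error(read_npz_layout(path), "val_images")
})

test_that("the container interoperates with numpy in both directions", {
  ds <- make_blob_images(60, 3, 16, 0.05, seed = 2)
  path <- tempfile(fileext = ".npz")
  write_npz_layout(ds, path)
  # numpy reads ours and reports the checksum of one array
  out <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; d=np.load('", path, "'); ",
    "print(repr(sorted(d.files))); print(float(d['train_images'].sum()))"
  ))), stdout = TRUE)
  expect_match(out[1], "train_images")
  expect_equal(as.numeric(out[2]), sum(ds$images[ds$split$train, , , ]),
               tolerance = 1e-9)
  # we read numpy's compressed output (deflated, zip64 extras)
  np_path <- tempfile(fileext = ".npz")
  system2("python", c("-c", shQuote(paste0(
    "import numpy as np; rng=np.random.default_rng(7); ",
    "arrs={f'{s}_images': rng.random((5,4,4)) for s in ['train','val','test']}; ",
    "arrs.update({f'{s}_labels': rng.integers(0,3,(5,1)) for s in ['train','val','test']}); ",
    "np.savez_compressed('", np_path, "', **arrs); ",
    "print(float(arrs['train_images'][0,0,0])); print(int(arrs['val_labels'][0,0]))"
  ))), stdout = "/dev/null")
  d <- read_npz_layout(np_path)
  ref <- system2("python", c("-c", shQuote(paste0(
    "import numpy as np; d=np.load('", np_path, "'); ",
    "print(float(d['train_images'].sum()))"
  ))), stdout = TRUE)
  expect_equal(sum(d$train$x), as.numeric(ref), tolerance = 1e-9)
  expect_equal(dim(d$train$x), c(5L, 4L, 4L, 1L))
})
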