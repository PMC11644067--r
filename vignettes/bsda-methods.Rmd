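---
title: "Bayesian random semantic data augmentation: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian random semantic data augmentation: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsda)
```

## The model

Semantic data augmentation perturbs a classifier's penultimate feature
vector $a = f_1(x) \in \mathbb{R}^k$ instead of the input image. A
perturbation along a direction that encodes a semantic attribute (lesion
size, staining intensity, ...) yields a new, plausible training example for
free — provided its magnitude stays inside the range that does not change
the true label. This package implements the Bayesian-random variant of that
idea:

$$\tilde a = a + \mathbb{1}[a \neq 0] \odot d_\lambda \odot m,$$

where

* $d_\lambda \in \{0,1\}^k$ selects the perturbed dimensions, elementwise
  Bernoulli($\lambda$);
* $m = \sigma \odot \varepsilon$, $\varepsilon \sim N(0, I)$, is the
  semantic magnitude, with a per-sample, per-dimension scale $\sigma(a)$
  predicted by a small estimator network;
* $\mathbb{1}[a \neq 0]$ is an indicator that forbids perturbing
  coordinates that are exactly zero, preserving the sparsity structure of
  post-activation features.

The label-preserving magnitude distribution $p(m \mid a)$ is unknown, so it
is approximated variationally by $q_{\phi_m}(m \mid a) = N(0,
\sigma^2(a))$: the mean is pinned at zero because $m$ is an offset relative
to $a$, and the fit is driven by the loss

$$L_B = \underbrace{\tfrac{1}{B}\sum_b \sum_i \tfrac12\left(\sigma_{bi}^2 -
1 - \log \sigma_{bi}^2\right)}_{\mathrm{KL}\left(N(0,\sigma^2)\,\|\,N(0,I)\right)}
\;+\; \underbrace{\tfrac12\,\overline{(\hat a - a)^2}}_{\text{reconstruction}},$$

where $\hat a$ is produced by a reconstructor network that sees only $m$
(the literal reading of $p_{\phi_a}(a \mid m)$; an autoencoder-style
reconstructor conditioned on $a$ as well would be the other defensible
reading). Sampling uses the reparameterization $m = \sigma \odot
\varepsilon$ so that $\partial m / \partial \sigma = \varepsilon$ and
gradients flow into the estimator. The total objective is

$$L = L_\mathrm{task}^{a} + \alpha\left(L_B + L_\mathrm{task}^{\tilde a}\right),$$

minimized jointly over the backbone, head, estimator, and reconstructor.
The augmented-task term is averaged over $U$ independent $(d, \varepsilon)$
draws per feature. Augmentation is a training-time regularizer only:
evaluation-mode forward passes are exactly $f_2(f_1(x))$.

A sign note: the variational derivation is stated as an ELBO to be
maximized, but the printed loss equals KL $+$ half-MSE; the only reading
consistent with adding $L_B$ to a minimized total is to treat it as a loss,
which is what this package does.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `lambda` | 0.5 | probability each feature dimension is perturbed; 0 is the identity |
| `num_samples` (U) | 1 | augmented copies per feature per step; copies share sigma but draw independent masks and noise |
| `alpha_max` | 0.5 | plateau weight of the augmentation branch (the recommended default; 0 disables the module) |
| `alpha_warmup_epochs` | 5 | linear ramp of alpha from 0, mirroring the 5-epoch learning-rate warm-up; the exact ramp shape is a package choice, the source only asks for a "dynamic" early-training attenuation |
| `hidden_dim` | k | hidden width of estimator/reconstructor (layer count and activations are specified upstream, width is not) |
| `mask_zero` | TRUE | the $\mathbb{1}[a \neq 0]$ indicator; exact comparison to 0.0, no epsilon band, because the point is preserving structural (hard) zeros |
| `fixed_sigma` | NULL | bypasses the estimator with a constant scale; 1 gives the "random noise" ablation |

The estimator and reconstructor are each two fully connected layers with
BatchNorm and GeLU after the first. The estimator predicts $\log \sigma^2$
and exponentiates, which guarantees positivity without clipping; its final
layer is zero-initialized so training starts at $\sigma = 1$, where the KL
term and its gradient vanish — a gentle start that also makes the
first-epoch KL exactly zero (a property the tests assert).

Training uses AdamW at learning rate $10^{-3}$ with a 5-epoch linear
warm-up; the estimator and reconstructor share the backbone's optimizer and
learning rate (the source is silent; separate optimizers add knobs without
evident benefit). Checkpoints are selected by best validation AUC, ties
broken by ACC and then by the later epoch; the selection metric is another
quantity the source never states.

## What the synthetic data emulates — and what it does not

`make_blob_images()` renders one or two ellipses per image: class sets the
shape family (eccentricity, then count), while the radius — the within-class
semantic attribute — varies continuously and uniformly. Gaussian pixel noise
(sd 0.05 by default) keeps the task non-trivial; splits follow the 7:1:2
convention of the benchmark family the harness targets. This captures the
two properties the method needs from data (a continuous label-preserving
semantic axis, and class structure a small CNN can learn) but none of the
appearance statistics of medical images; a green end-to-end test says the
machinery works, not that the method improves any particular clinical task.

`make_sparse_features()` produces non-negative vectors that are exactly
zero outside a class-specific support (hitting the target zero fraction by
construction), with class means rescaled so their minimal pairwise distance
is exactly `sep` and sample noise norm-capped at $0.2\,\mathrm{sep}$ —
which makes nearest-class-mean classification of clean samples correct by
construction and gives a known per-class `label_radius` of half the
distance to the nearest other mean. This is the ground-truth testbed for
the label-preservation property: draws with $3\sigma\sqrt{\lambda k}$ below
the radius keep their labels, quantifying the "augmentable range" the
method is built around.

Two honest findings from this stated world, measured by the acceptance
script: the blob task is nearly saturated (baseline AUC above 99.5), so the
end-to-end criterion is a non-inferiority check rather than an improvement
demonstration; and the zero-indicator is a no-op on the reference CNN,
whose GeLU + global-average-pool features contain no exact zeros — the
indicator's effect is exercised on the sparse-feature fixture, where hard
zeros exist by construction.

## Numerical choices

* **Loss reduction.** The KL term is summed over feature dimensions and
  averaged over the batch, so loss magnitudes are batch-size invariant; the
  upstream summation index is ambiguous between batch and dimension.
* **Determinism.** Weight initialization, data shuffling, and the module's
  sampling draws run on three separate derived RNG streams. Consequences:
  identical seeds reproduce runs exactly, and a model with `alpha_max = 0`
  consumes the same random numbers as one with no module attached, making
  the baseline-neutrality property bit-exact rather than approximate.
* **BatchNorm.** Batch statistics in training, running statistics in
  evaluation; batches of one row are dropped from training (their batch
  variance is undefined) but evaluate fine.
* **Backpropagation.** All layers are hand-written R matrix code (no deep
  learning framework exists in the target environment); every backward pass
  is validated against central finite differences in the test suite, and
  the full composite step (backbone, enlarged-batch head, estimator through
  the reparameterized path, reconstructor, KL) agrees with finite
  differences to relative error below $10^{-6}$.
* **t-SNE.** The feature-visualization export uses an exact $O(n^2)$
  implementation (perplexity binary search, early exaggeration, momentum)
  because no t-SNE package is available in the environment; it is intended
  for hundreds of points, which is all the visualization contract needs.
* **Packed arrays.** The `.npz`-layout reader/writer is likewise built in:
  npy v1.0 members inside a stored-method ZIP on write; stored or deflated
  members (including zip64 size extensions) on read. Interoperability is
  tested against numpy in both directions.

## Known limitations

* No covariance across feature dimensions: $\sigma$ is diagonal by design
  (class-conditional covariance modeling is a different method family).
* The reconstructor never sees $a$, and the reconstruction target is the
  full (unmasked) feature vector; both are the literal readings of the
  source formulation, and the alternatives were consciously not taken.
* Whether the augmented-task loss should reach the backbone through the
  original features is unstated upstream; this implementation lets it (no
  detaching), matching a pseudocode that updates all parameter groups from
  one total loss.
* Desk-scale only: the reference CNN and MLP are deliberately small, and
  nothing here attempts the full 224-pixel benchmark training the method
  was originally evaluated on.
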