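---
title: "Learning stochastic object models from noisy measurements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning stochastic object models from noisy measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ambientsom)
```

## The problem

Objective, task-based assessment of imaging systems requires accounting for
the variability of the objects being imaged.  A *stochastic object model*
(SOM) is a generative model of that variability: a machine that produces
random object realizations `f` with the right ensemble statistics,
independent of any particular scanner, noise level, or reconstruction
algorithm.  The difficulty is that real training data never shows us `f`:
an imaging system delivers noisy, possibly incomplete measurements
`g = H f + n`, and reconstructed images inherit both the measurement noise
and the reconstruction operator's fingerprints.  A generative model trained
naively on reconstructed images learns the noise along with the anatomy.

`ambientsom` implements the ambient adversarial approach to this problem
for a stylized Fourier-space (single-coil MRI-like) imaging model.  The
generator `G(z)` proposes objects; a simulated measurement operator `H_n`
(masked 2D DFT plus fresh complex Gaussian noise) and a reconstruction
operator `O` map each proposal into the same space as the reconstructed
real data; and the discriminator compares the two *reconstructed* ensembles.
At the optimum the generator must explain the data ensemble *before* noise
was added, because the noise is supplied — fresh each step — by `H_n` on the
generator branch too.  The trained generator is the SOM.

Two training styles are provided, mirroring the two multiresolution GAN
families in common use:

* **progressive**: the networks are grown from 4x4 to the final resolution,
  each new scale faded in smoothly; reconstructed images (real and fake
  alike) are average-pooled down to the active resolution before the
  discriminator.
* **skip-sum**: the generator always sums per-resolution detail images
  (bilinearly upsampled) into the final image and is trained in a single
  stage; the discriminator uses a residual trunk.

The default loss is a Wasserstein critic with gradient penalty for the
progressive style, and the non-saturating logistic loss with R1
regularization for the skip-sum style.

## The imaging model and its conventions

The measurement model is `g = F(f) + n` where `F` is the unscaled 2D DFT
(the inverse carries `1/(H*W)`), `n` is i.i.d. zero-mean complex Gaussian
noise with per-component standard deviation `sigma` applied only to sampled
k-space entries, and Cartesian undersampling removes whole phase-encode
lines.  Under this convention, on an `N x N` grid:

* the real-part zero-filled reconstruction of pure noise has pixel standard
  deviation `sigma / N` — so `sigma = 4` and `16` on `[0,1]`-normalized
  256x256 images correspond to 1.56% and 6.25% image-domain noise;
* background pixels of magnitude reconstructions follow a Rayleigh
  distribution with scale `sigma / N`, which is what
  `estimate_kspace_noise()` exploits to calibrate an unknown noise model
  from magnitude images (maximum-likelihood Rayleigh fit on pooled
  background patches, rescaled by `N`).

Sampling masks are Hermitian-symmetric: lines are kept in `+k/-k` pairs
(DC always, the Nyquist line self-paired).  For real-valued objects a line
and its mirror carry identical information, and the symmetric choice makes
the zero-filled real-part reconstruction `H^+ H` an exact orthogonal
projector — `(H^+H)^2 = H^+H` holds to machine precision, which keeps the
"measurement component" `f_meas = H^+ H f` a well-defined projection of the
object.  Random line selection is uniform over the `+k/-k` pairs
(`uniform_random`), or a guaranteed central band plus random pairs
(`center_band_random`); the choice and seed are recorded in the mask.

When the discriminator must be fed *magnitude* images, the generator branch
uses the ReLU-corrected reconstruction
`f_hat + [ |F^-1(F(ReLU(f_hat)) + n)| - ReLU(f_hat) ]`: for nonnegative
proposals this is exactly the magnitude reconstruction of their simulated
measurement, while negative-valued proposals leak through unchanged and
remain visible (and punishable) to the discriminator, which drives the
trained generator toward nonnegative objects.  Its derivative is diagonal
and is propagated exactly during training.  The correction is defined for
fully sampled magnitude data; combining it with undersampled masks is
refused rather than guessed.

## Synthetic objects: the lumpy background

The in-package object model is the classic lumpy background: a Poisson
number of isotropic Gaussian lumps (continuous sub-pixel centers, periodic
wrapping) plus a constant offset.  Defaults — 32x32 grid, mean 25 lumps,
lump width 4 px, amplitude 1 — follow the proportions of the lumpy-background
literature scaled to a 32-px grid, and per-image `[0,1]` min-max
normalization is used for GAN studies to mirror the normalization used with
clinical slices.  With periodic boundaries and no normalization the process
is strictly stationary, and both its mean and autocovariance have closed
forms (`lumpy_mean()`, `lumpy_autocovariance()`), which the test-suite uses
as Monte Carlo oracles and the Hotelling-observer code uses as an exact
covariance reference.

What the generator does *not* emulate: anatomical structure, spatially
varying noise, phase errors, coil sensitivities, or inter-subject
covariates.  Tests passing on lumpy ensembles therefore validate the
operator insertion, the training machinery and the metrics — not the claim
that any particular clinical ensemble is learnable at a given size.

## Networks and training recipe

The networks are deliberately small, dense multiresolution
re-implementations of the two architectural ideas above — the contribution
this package exists for is the operator insertion and the multiresolution
schedule, both of which are architecture-agnostic.  A dense trunk maps the
latent vector (standard normal, default dimension 64 at desk scale; 512 is
the full-scale convention) to a feature vector; per-resolution dense
"to-image" heads emit detail images that are combined through fixed
bilinear-upsampling matrices.  The discriminator mirrors this with
per-resolution "from-image" heads, and additionally receives per-scale
*band energies* — the mean squared pixel value of the input at each dyadic
resolution, differenced across scales.  These features make the spectral
allocation of energy, in particular the white-noise floor, directly visible
to the critic: without them a small dense critic is statistically too weak
to distinguish a clean generator passed through fresh measurement noise
from a generator that has itself memorized noise, and the ambient/plain
distinction that motivates the method dissolves at desk scale.

All backward passes are hand-derived, including the second-order pass that
gradient penalties require (the parameter gradient of `||dD/dx||`), with
activation masks held at their forward values — exact almost everywhere for
piecewise-linear activations.  Every gradient path, including the operator
adjoints (`H^+H` projector, corrected-magnitude diagonal), is verified
against finite differences in the test suite.

Training details that matter, with defaults and reasons:

* **Adam** with `beta1 = 0, beta2 = 0.99`, learning rate `1e-3` — the
  progressive-GAN convention for small batches.
* **Schedule**: non-final stages get 4,800 images (half fade-in, half
  stabilize); the final stage gets 36,000 images with a 2,400-image fade
  and the rest as a stabilize phase at batch 32 with 2 critic steps per
  generator step and the learning rate scaled by 0.2.  The long, calmer
  final phase is where the noise statistics equilibrate: the critic needs
  the extra updates and the larger batch to resolve band-energy differences
  between the branches.
* **Head learning-rate multiplier 0.25**: Adam normalizes per-parameter
  step sizes, so the finest "to-image" head performs a random walk whose
  accumulated white parameter noise appears as high-frequency image noise.
  Keeping head steps small caps that floor without slowing the trunk.
* **Fresh measurement noise per generated sample per step**: the
  measurement process is stochastic; reusing realizations would let the
  critic key on fixed noise patterns.
* **Stopping** is by images-seen budget; the loss trajectory (and the
  Wasserstein gap) is recorded in the manifest for post-hoc inspection,
  since visual stopping rules are subjective by nature.

Determinism: every random draw flows from the master seed through named
streams (parameter init, latents, measurement noise, data order, penalty
mixing), so runs are bit-reproducible and an interrupted run can be resumed
to the identical trajectory.

## Evaluation stack

* `estimate_image_noise_std()` — a blind estimate of the white-noise level
  of an image ensemble: median absolute deviation of the finest diagonal
  Haar wavelet details divided by 0.6745, averaged per image.  Smooth
  content contributes almost nothing to that band, so on smooth objects the
  estimator reads the noise floor; it is exactly scale-equivariant.  This
  is the package's stand-in for external noise-level estimators used in the
  literature, and the method tag records it.
* `compute_fid()` — the Fréchet distance between Gaussian fits to feature
  embeddings of two ensembles.  The default embedding is a deterministic
  8x8 average-pool of each image ("pixel_pool"): download-free,
  reproducible, and adequate for small grayscale ensembles; pretrained
  network embeddings can be plugged in as a custom extractor function.  The
  matrix square root uses a symmetrized eigendecomposition with negative
  eigenvalues clipped at `-1e-8`.
* `compute_snr_ho()` — the Hotelling-observer SNR for a
  signal-known-exactly, background-known-statistically task on an ROI
  centered at the signal, with the covariance decomposed as empirical
  background covariance plus the exactly known task-noise diagonal
  (`K = K_bg + sigma_t^2 I`, positive definite by construction).  The SNR
  is computed via a Cholesky solve, never an explicit inverse.  The
  reported figure of merit is `sqrt(s' K^-1 s)` — the standard Hotelling
  SNR — and the raw quadratic form is returned alongside, with the
  convention flagged, since the quadratic form (without the square root)
  also circulates as a figure of merit.

## Problem sizes and what the shipped studies show

The package's own studies (test suite and `scripts/acceptance.R`) run at
desk scale, chosen so the full pipeline — simulation, two to three GAN
trainings, and all metrics — completes on a single CPU: 32x32 lumpy
objects, 512 training measurements, 200-sample evaluation ensembles,
latent dimension 64, and the schedule above with halved stage budgets
(roughly 1,400 optimizer steps per model).  At these sizes the fully sampled noisy study (k-space
`sigma = 0.1 * N`, i.e. 10% image-domain reconstruction noise) shows the
method's signature behavior: the plain GAN's generated images carry a
noise level close to the reconstruction noise of its training images,
while the ambient model's images are several-fold cleaner; and in the
4x-undersampled study the FID between generated and true *measurement
components* stays below the FID between generated and true objects,
reflecting that only the measurement component of the object ensemble is
learnable through an operator with a null space.  The corresponding
full-scale numbers in the literature come from 256x256 clinical ensembles
and GPU-scale training and are out of reach of a CPU-sized run; nothing in
the desk-scale configuration is specific to that scale, and
`final_resolution`, ensemble sizes and budgets are plain configuration
fields.

## Numerical choices and degenerate inputs

* Bilinear upsampling uses half-pixel centers with edge clamping; average
  pooling is the exact 2x2 block mean; both preserve the image mean and are
  applied as precomputed matrices so their adjoints are exact transposes.
* `corrected_fake_reconstruct` groups its arithmetic so that the
  nonnegative branch is bitwise equal to the plain magnitude
  reconstruction.
* Magnitude gradients at exact zeros use derivative 1 (measure-zero case).
* Constant (degenerate) images yield a zero noise estimate with a flag
  rather than an error; zero-amplitude lumpy configurations are valid and
  produce constant images; zero training budgets return the initialized
  model with a warning.
* `mean_lump_count` enters `rpois()` directly; configurations with
  `mean_lump_count <= 0` or non-power-of-two grids are rejected with the
  offending field named.

## Known limitations

* Dense (not convolutional) networks: parameter count grows with the
  fourth power of resolution in the heads, so the implementation is meant
  for small grids; the architecture is a vehicle for the operator-insertion
  method, not a state-of-the-art image synthesizer.
* Single-coil, Cartesian, noise-stationary imaging model only; no coil
  maps, non-Cartesian trajectories, or field inhomogeneity.
* The Hotelling observer is the only observer implemented; channelized,
  ideal, and anthropomorphic observers are out of scope.
* The pixel-pool FID embedding is insensitive to fine texture beyond its
  pooling scale by design; conclusions about fine-scale realism need a
  richer plug-in extractor.

## A minimal run

```{r demo, eval = FALSE}
cfg <- run_config(list(
  study = "fully_sampled",
  object = list(grid_size = 32, n_train = 512),
  imaging = list(kspace_std = 3.2),
  evaluation = list(n_samples = 200, roi_size = 8),
  seed = 1))
dataset <- run_simulate(cfg)
ambient <- run_train(cfg, dataset, ambient = TRUE)
plain <- run_train(cfg, dataset, ambient = FALSE)
run_evaluate(cfg, ambient, dataset$objects)
```
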