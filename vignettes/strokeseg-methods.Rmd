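---
title: "Methods: synthetic low-dose brain CT, denoising, segmentation and perfusion mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic low-dose brain CT, denoising, segmentation and perfusion mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

strokeseg is an end-to-end pipeline for low-dose brain CT analysis of acute
cerebral infarction that runs entirely on generated data. This vignette is
the package's account of the science inside it: the models each stage
implements, the tunable parameters and their defaults, what the synthetic
phantoms do and do not emulate, and the numerical decisions that were
genuinely open.

## The head phantom and what it emulates

No suitable public dataset pairs low-dose brain CT with lesion ground truth
on the same grid, so every stage here is exercised on synthetic phantoms
with known truth. `make_head_phantom()` builds a head-like attenuation map
from concentric ellipses: an outer skull shell at +1000 HU, brain parenchyma
at ~35 HU, paired CSF ventricles at 8 HU, air at -1000 HU, and ellipsoidal
ischemic lesions as *hypodense* offsets of -10 to -20 HU relative to
parenchyma (the appearance of an early infarct on non-contrast CT). A smooth,
seeded random field (default SD 2 HU, `texture_sd`) adds mild parenchymal
heterogeneity. The default grid is 256 x 256 (2D; 3D grids are supported);
desk-scale tests use 48-128 px grids to keep runtimes in seconds.

What the phantom does **not** emulate: real anatomy (gyri, ventricles'
shape, posterior fossa artifacts), beam hardening, sinogram-domain noise
correlations, or fine-grained stochastic texture. Consequences worth
knowing:

* Low-dose noise is inserted in the *image domain* as additive Gaussian
  noise of known `sigma` (a `poisson_gaussian` option adds
  signal-dependent variance). Real low-dose CT noise is correlated and
  streaky.
* The phantom is nearly piecewise constant. Denoisers that exploit
  self-similarity (BM3D) look better here than on textured anatomy, and the
  Wiener refinement stage of BM3D has little detail to recover at small
  grids — a behaviour visible in the test suite, where the classic
  two-stage gain is demonstrated on a textured fixture and on the full-size
  phantom, but inverts on small, ultra-smooth ones.
* Passing tests show the algorithms are implemented correctly and behave as
  designed under controlled conditions; they do not certify clinical
  performance.

## Low-dose model and the denoisers

The low-dose image is modelled as a mapping of the clean image,
\(\chi = \varphi(y)\), realized as \(\chi = y + n\) with seeded noise
\(n\). Denoising seeks an approximate inverse \(F \approx \varphi^{-1}\) by
minimizing \(\lVert F(\chi) - y \rVert_2^2\).

**BM3D** is implemented from scratch in C++ in its classic two-stage form.
Stage 1 groups, for each reference block on a step-3 grid, up to 16 similar
8 x 8 blocks from a 39 x 39 search window (mean-squared-difference
matching, ties broken in raster order for reproducibility), applies an
orthonormal 2D DCT per block and a 1D Haar transform along the group axis,
zeroes 3D coefficients below \(\lambda_{3D}\,\sigma\)
(\(\lambda_{3D} = 2.7\)), inverts, and aggregates overlapping blocks with
weights \(1/(\sigma^2 N_{\text{retained}})\). Stage 2 re-matches on the
stage-1 estimate and applies empirical Wiener shrinkage
\(w = p^2/(p^2 + \sigma^2)\) built from the pilot's coefficient energies to
the noisy image's coefficients, with aggregation weights
\(1/(\sigma^2 \sum w^2)\). The matching cutoff defaults to
\(4\sigma^2 + 300\) per pixel: two noisy copies of the same patch differ by
\(2\sigma^2\) in expectation, so this accepts same-structure patches with
margin. Border handling clips reference and candidate blocks to fully
in-image positions; this makes the filter exactly shift covariant outside
an influence zone of (window + block) pixels per stage, which the test
suite verifies literally.

**DnCNN** is a plain convolutional stack (default depth 5, width 16, 3 x 3
kernels, ReLU, no normalization layers and no spatial resampling) that
predicts the noise map and subtracts it from the input. The **cascade**
stacks such blocks; each block after the first receives the 2-channel
concatenation of the previous estimate and the original image, so later
blocks can repair artifacts without losing the raw evidence. Depth and
width are deliberately small: all training runs on one CPU in minutes, on
32 px patches, with Adam (learning rate 3e-3) and seeded batch order.

Two numerical choices matter here and were made after measurement:

* **Output-layer zero initialization.** Each block's last convolution
  starts at zero, so a residual block is initially an exact identity and
  gradient descent learns the noise map directly. With random final layers
  the first training phase just re-learns the identity; at desk scale it
  never escapes it.
* **Noise-adaptive standardization.** Training data are affinely mapped so
  the pairs' empirical noise SD becomes 0.1, the contrast regime
  residual denoisers are tuned for. Mapping the full HU range to [0, 1]
  puts sigma-25 noise at 0.0125 relative amplitude, and desk-scale training
  measurably stalls at the identity. The affine map is stored on the model
  and inverted at inference, so inputs and outputs remain in HU.

## Segmentation: preprocessing and RISEU-Net

`preprocess_ct()` mirrors the clinical flow: bone is removed by
thresholding at +300 HU plus morphological closing, the largest interior
region is kept as the brain, intensities are z-scored inside the brain mask
(non-brain set to 0), and an optional Gaussian smoothing pass follows.
Standardization here is plain z-scoring; atlas-space registration and
tissue-class priors are out of scope.

The segmenter is a U-shaped encoder-decoder. Each level holds a
two-convolution block wrapped in a residual shortcut \(X + F(X)\) (1 x 1
projection when channel counts change) and gated by a squeeze-excitation
module: global average pool to a channel descriptor, bottleneck of ratio
`r` (default 4) with ReLU, expansion, and a logistic gate multiplying each
channel. Max pooling (2 x 2) halves the spatial dimensions per level;
nearest-neighbour upsampling plus convolution mirrors it in the decoder;
skip connections concatenate encoder features; a 1 x 1 convolution with a
logistic output yields a probability map. With `use_se = FALSE` and
`use_residual = FALSE` the graph reduces to a plain U-Net, which serves as
the ablation comparator. Defaults (depth 2, base 8 channels) are sized for
CPU training on 64 px phantoms.

The whole network — convolutions by shift-and-GEMM, pooling, SE, residual
adds, upsampling — and its backward passes are hand-written in base R.
Every backward pass is checked against central finite differences in the
test suite, including one end-to-end gradient check through the full
residual + SE + skip architecture.

**Losses.** Training minimizes a soft Dice-family distance. For prediction
set \(E\) and truth \(F\),

\[\mathrm{Dice} = \frac{2|E \cap F|}{|E| + |F|}, \qquad
\mathrm{NewDice} = \frac{2(|E \cap F| - |\neg E \cap F| - |E \cap \neg F|)}{|E| + |F|},\]

so NewDice subtracts false negatives and false positives in the numerator,
ranges over \([-2, 1]\) (disjoint masks score \(-2\)), never exceeds Dice,
and equals it exactly when there are no errors. The soft relaxations
replace the indicator by the probability map. The denominator of both
relaxations is the *linear* sum \(\sum e_i + \sum f_i\): with a
sum-of-squares denominator and a negative numerator, a network can improve
the loss by inflating \(\sum e_i^2\) with confident false positives —
training then collapses to all-lesion predictions, the precise failure the
score exists to penalize. The linear form is identical on hard masks and
stable in training; the over-segmentation penalty (false-positive mass
hurts soft NewDice strictly more than soft Dice) is verified analytically
in the tests.

## Perfusion mapping

The contrast dynamics follow the indicator-dilution model: tissue
enhancement \(C(t) = f \,(\mathrm{AIF} \ast R)(t)\) with flow
\(f = \mathrm{CBF}/6000\) (1/s for CBF in mL/100 g/min), a gamma-variate
arterial input function
\(c(t) = A\,(t-t_0)^\alpha e^{-(t-t_0)/\beta}\) (defaults \(t_0 = 5\) s,
\(\alpha = 3\), \(\beta = 1.5\), peak 200), and an exponential residue
\(R(t) = e^{-t/\mathrm{MTT}}\). The acquisition grid defaults to 20
uniform frames over 45 s.

The generator discretizes this model *on the acquisition grid*: the
discrete residue carries the exact per-frame average of \(R\), and the
convolution operator is the same lower-triangular Toeplitz matrix
(rectangle rule) that the deconvolution stage inverts. Two consequences:
the tissue/AIF area ratio equals \(f\cdot\mathrm{MTT}\) up to the
truncated tail (the central-volume identity
\(\mathrm{MTT} = 60\,\mathrm{CBV}/\mathrm{CBF}\) is exact in the truth
maps), and recovery errors measure the inverse problem, not a quadrature
mismatch.

`svd_deconvolve()` inverts \(C = A k\) per voxel by truncated SVD, zeroing
singular values below `truncation_fraction` of the largest (default 0.2
under noise; use ~0.05 for noiseless data). `perfusion_maps()` then reads
CBF from the peak of \(k(t)\), CBV from the area ratio, MTT from the
central-volume identity, and TTP from the enhancement peak. Because the
discrete residue is frame-averaged, the raw peak understates the flow by
\((\mathrm{MTT}/\Delta t)(1 - e^{-\Delta t/\mathrm{MTT}})\); the estimator
removes this bias with a few fixed-point iterations using
\(\mathrm{MTT} \approx \mathrm{CBV}/\mathrm{CBF}\). The correction assumes
an exponential residue — exact for the generator, approximate for real
tissue. With it, noiseless recovery errors across CBF 10–80 mL/100 g/min
and MTT 2–12 s at 1 s sampling stay within a few percent; without it the
familiar clinical CBF underestimation at short MTT (~20% at MTT = 2 s)
reappears. Voxels with peak enhancement below `enhancement_floor`
(0.5 HU) are masked out of the maps.

## Evaluation layer

* `image_quality()`: RMSE, \(\mathrm{PSNR} = 20\log_{10}(\mathrm{MAX}/\mathrm{RMSE})\)
  with MAX taken from the volume's `value_range` (2000 for the default HU
  window, never hard-coded 255), and SSIM with the standard constants
  \(K_1 = 0.01, K_2 = 0.03\) over 7 x 7 windows.
* `texture_features()`: mean, skewness \(m_3/m_2^{3/2}\) and excess
  kurtosis \(m_4/m_2^2 - 3\) with population moments; zero-variance samples
  are flagged degenerate and report 0.
* `detection_report()`: a true lesion (connected component) counts as
  detected when at least one predicted voxel overlaps it; sensitivity is
  lesion-level, specificity and accuracy voxel-level, and
  `lesions_detected` is the per-case mean ± SD. The one-voxel-overlap rule
  is the weakest sensible criterion; stricter IoU-based matching would
  lower sensitivities.
* `compare_groups()`: Welch t-test on per-case detected counts and a 2 x 2
  chi-squared test (no continuity correction) on pooled detection
  proportions.
* `bias_variance()`: per-voxel decomposition
  \(\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{variance}\) over replicate
  predictions (population variance), exact per voxel.

## Orchestration and reproducibility

`run_pipeline()` validates a nested config against a fixed schema (unknown
keys are rejected before any stage runs), derives one deterministic seed
substream per stage from the root seed, executes phantom → noise → denoise
→ segment → perfuse → evaluate, and writes every artifact plus a JSON
manifest with MD5 sums. Re-running the same config reproduces every
artifact bit-identically; the test suite asserts this. A thin command-line
wrapper (`inst/cli/strokeseg.R`) exposes the same stages as subcommands.

## Problem sizes in the tests

The suite trains a depth-5/width-16 DnCNN on 64 px phantoms with a
three-phase stepped learning-rate schedule, compares 1- vs 2-block
cascades of depth-4/width-8 blocks on 48 px phantoms over five seeds, and
trains a depth-2/base-8 RISEU-Net on 64 px phantoms — the Dice capability
check on easy high-contrast lesions (radius 8 px, -20 HU) and the
false-positive comparison on standard-contrast lesions (radius 7 px,
-15 HU), where over-segmentation actually occurs. BM3D properties run at
the 256 x 256 default, the perfusion grid at 1 s sampling. These sizes are
the package's chosen desk-scale study conditions; they complete in minutes
on one CPU while leaving each claim (PSNR gain, cascade ordering, Dice
level, false-positive suppression, recovery bands) measurable.

## Known limitations

* Image-domain noise only; no projection-space physics.
* The CNN engine is CPU-bound base R: suitable for the desk-scale networks
  it ships with, not for training at clinical resolution.
* The perfusion CBF bias correction presumes the exponential residue of
  the forward model.
* Delay-insensitive (block-circulant) SVD, AIF auto-detection and
  Tmax-based mismatch classification are out of scope.
* Table-level clinical figures from patient cohorts cannot be reproduced
  here: the pipeline's evaluation layer computes the same *kinds* of
  quantities on synthetic cases instead.
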