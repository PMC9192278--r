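# strokeseg

Low-dose brain CT processing for acute cerebral infarction, as a fully
seeded, self-contained pipeline: synthetic head phantoms with known ground
truth, BM3D and residual-CNN denoising, residual squeeze-excitation U-Net
lesion segmentation, truncated-SVD perfusion mapping, and a clinical-style
evaluation layer. Everything runs on generated data — no downloads, no
GPU — so every stage is testable end to end.

## Who this is for

Researchers prototyping low-dose CT denoising or stroke-lesion
segmentation methods who need a controlled, reproducible sandbox with
ground truth; and anyone who wants reference implementations of the
building blocks below in plain, inspectable code.

## What is inside

* **Phantoms** — elliptical head sections (skull +1000 HU, parenchyma
  ~35 HU, CSF ventricles, air background) with ellipsoidal hypodense
  lesions, seeded low-dose noise χ = y + n of known σ, and 4D
  contrast-enhanced series driven by a gamma-variate arterial input
  function convolved with exponential residues (20 frames / 45 s by
  default), with CBF/CBV/MTT/TTP truth maps.
* **BM3D** (from scratch, C++ core) — two-stage collaborative filtering:
  block matching → 2D DCT + 1D Haar 3D-transform → hard thresholding at
  λ·σ (λ = 2.7) → weighted aggregation; then Wiener refinement using the
  stage-1 estimate as pilot.
* **Residual CNN denoisers** — DnCNN (predicts the noise map, subtracts
  it; no resampling) and a cascaded variant where each block consumes the
  previous estimate concatenated with the original image. The CNN engine
  (convolution, pooling, SE gates, backprop, Adam) is hand-written base R,
  with finite-difference gradient tests.
* **RISEU-Net** — a U-Net whose blocks carry residual shortcuts
  (X + F(X)) and squeeze-excitation channel gates; trained with soft Dice
  or the false-positive-penalizing New-Dice loss
  `2(|E∩F| − |¬E∩F| − |E∩¬F|) / (|E| + |F|)`; ablations (`use_se`,
  `use_residual`) reduce it to residual-U-Net or plain U-Net.
* **Perfusion** — Østergaard-style truncated-SVD deconvolution of the
  tissue curves against the AIF; CBF from the residue peak (with a
  documented discretization-bias correction), CBV from area ratios,
  MTT = 60·CBV/CBF, TTP from the enhancement peak.
* **Evaluation** — Dice family, PSNR/RMSE/SSIM, first-order texture
  statistics (mean, skewness, excess kurtosis), lesion-level detection
  reports (sensitivity/specificity/accuracy, lesions detected mean ± SD),
  Welch t and χ² group tests, and a bias²+variance = MSE decomposition.
* **Pipeline** — `run_pipeline()` with a validated YAML-able config, one
  seed substream per stage, artifact manifest with MD5 sums, and a thin
  CLI (`inst/cli/strokeseg.R`) with `phantom`, `denoise`,
  `train-denoiser`, `train-seg`, `segment`, `perfuse` and `run`
  subcommands.

## Worked example

```r
library(strokeseg)

# a 128 x 128 head section with one hypodense lesion, and its low-dose copy
spec <- phantom_spec(shape = c(128, 128),
                     lesions = list(list(center = c(55, 55),
                                         radii = c(8, 8), delta = -15)))
ph   <- make_head_phantom(spec)
pair <- add_lowdose_noise(ph$image, noise_model(sigma = 25, seed = 11))

image_quality(ph$image, pair$noisy)
#> PSNR 38.10 dB | RMSE 24.9 | SSIM 0.9041 (MAX 2000)

den <- bm3d_denoise(pair$noisy, bm3d_params(sigma = 25))
image_quality(ph$image, den)
#> PSNR 48.91 dB | RMSE 7.173 | SSIM 0.9972 (MAX 2000)
```

The noisy image sits 38 dB above the 2000-HU dynamic range (σ = 25 HU);
BM3D removes most of the noise (+10.8 dB, SSIM 0.90 → 0.997). Scoring a
perfect segmentation of the lesion mask against itself, and a deliberately
wrong one, shows the two overlap scores:

```r
dice_scores(ph$mask, ph$mask)
#> Dice 1.0000 (distance 0.0000), New Dice 1.0000  [TP 197 FP 0 FN 0]

shifted <- segmentation_mask(ph$mask$data[c(17:128, 1:16), ])
dice_scores(shifted, ph$mask)
#> Dice 0.0051 (distance 0.9949), New Dice -1.9848  [TP 1 FP 196 FN 196]
```

New Dice punishes the almost-disjoint prediction with a score near its
floor of −2, while plain Dice only falls to ~0 — that asymmetry is what the New-Dice training
loss exploits to suppress false positives. Perfusion mapping on the same
phantom recovers the flow deficit in the lesion:

```r
ser  <- make_perfusion_series(ph$image, ph$mask,
                              normal_cbf = 60, lesion_cbf = 20)
maps <- perfusion_maps(ser, deconvolution_params(0.05))
mean(maps$cbf[ph$mask$data == 1])   # lesion
#> [1] 20.01
mean(maps$cbf[ser$truth_maps$cbf > 0 & ph$mask$data == 0])  # normal tissue
#> [1] 59.78
```

against assigned truths of 20 and 60 mL/100 g/min. The full demo path —
phantoms → noise → BM3D → segmenter training → perfusion → reports — is one
call:

```r
manifest <- run_pipeline(default_run_config(seed = 1))
```

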