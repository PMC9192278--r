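Package: strokeseg
Title: Low-Dose Brain CT Denoising, Lesion Segmentation and Perfusion Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully seeded pipeline for low-dose brain CT analysis
    of acute cerebral infarction, running entirely on generated data. Provides
    synthetic head phantoms with ellipsoidal hypodense lesions and gamma-variate
    contrast dynamics; a from-scratch two-stage BM3D collaborative filter;
    residual CNN denoisers (DnCNN and a cascaded multi-block variant) trained on
    matched clean/low-dose pairs; a residual squeeze-excitation U-Net lesion
    segmenter trained with Dice-family losses including a false-positive
    penalizing variant; truncated-SVD deconvolution perfusion mapping
    (CBF/CBV/MTT/TTP); and a clinical-style evaluation layer (Dice scores,
    texture statistics, PSNR/RMSE/SSIM, lesion detection reports, group tests).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    RNifti,
    EBImage,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
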