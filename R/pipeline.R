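# Reproducible orchestration: validated run configs, per-stage seed
# substreams derived from one root seed, and the end-to-end demo path
# phantom -> noise -> denoise -> segment -> perfuse -> report.

pipeline_schema <- function() {
  list(
    version = c("version"),
    seed = c("seed"),
    output_dir = c("output_dir"),
    log_level = c("log_level"),
    phantom = c("n_cases", "shape", "n_lesions", "lesion_radius",
                "lesion_delta", "texture_sd"),
    noise = c("kind", "sigma", "alpha"),
    denoise = c("method", "sigma", "lambda3d", "block_size", "search_window",
                "max_group_size", "step"),
    segment = c("enabled", "depth", "base_channels", "se_reduction",
                "use_se", "use_residual", "loss", "epochs", "steps_per_epoch",
                "batch_size", "lr", "threshold", "smooth_sigma"),
    perfusion = c("enabled", "truncation_fraction", "baseline_frames",
                  "discretization", "normal_cbf", "lesion_cbf", "normal_mtt",
                  "lesion_mtt")
  )
}

#' Default pipeline run configuration
#'
#' A desk-scale demo: two 96x96 phantoms with one hypodense lesion each,
#' sigma-25 Gaussian low-dose noise, BM3D denoising, a tiny RISEU-Net
#' segmenter, and truncated-SVD perfusion mapping.
#'
#' @param seed root seed; every stochastic stage derives its own substream
#'   from it.
#' @param output_dir artifact directory.
#' @return Nested configuration list.
#' @export
default_run_config <- function(seed = 1L, output_dir = tempfile("strokeseg_run_")) {
  list(
    version = 1L,
    seed = as.integer(seed),
    output_dir = output_dir,
    log_level = "info",
    phantom = list(n_cases = 2L, shape = c(96L, 96L), n_lesions = 1L,
                   lesion_radius = 8, lesion_delta = -15, texture_sd = 2),
    noise = list(kind = "gaussian", sigma = 25),
    denoise = list(method = "bm3d", sigma = 25),
    segment = list(enabled = TRUE, depth = 2L, base_channels = 8L,
                   se_reduction = 4L, use_se = TRUE, use_residual = TRUE,
                   loss = "new_dice", epochs = 6L, steps_per_epoch = 8L,
                   batch_size = 2L, lr = 3e-3, threshold = 0.5,
                   smooth_sigma = 0),
    perfusion = list(enabled = TRUE, truncation_fraction = 0.2,
                     baseline_frames = 2L, discretization = "simpson",
                     normal_cbf = 60, lesion_cbf = 20, normal_mtt = 4,
                     lesion_mtt = 8)
  )
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file with the sections of [default_run_config()].
#' @return The validated config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Fails fast: any unknown section or key is rejected before any stage runs.
#'
#' @param config nested list as from [default_run_config()] or
#'   [yaml::read_yaml()].
#' @return The config, invisibly, on success.
#' @export
validate_run_config <- function(config) {
  schema <- pipeline_schema()
  bad_sections <- setdiff(names(config), names(schema))
  if (length(bad_sections)) {
    stop("unknown config section(s): ", paste(bad_sections, collapse = ", "))
  }
  for (sec in intersect(names(config), names(schema))) {
    if (!is.list(config[[sec]])) next
    bad <- setdiff(names(config[[sec]]), schema[[sec]])
    if (length(bad)) {
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
    }
  }
  if (is.null(config$seed)) stop("config must set `seed`")
  invisible(config)
}

#' Derive a stage seed from the root seed
#'
#' Deterministic substream: each named stage gets its own reproducible seed
#' below 2^31.
#'
#' @param root_seed integer root seed.
#' @param stage stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(root_seed, stage) {
  stages <- c("phantom", "noise", "denoise", "train_denoiser", "segment",
              "perfusion", "evaluate")
  i <- match(stage, stages)
  if (is.na(i)) stop("unknown stage: ", stage)
  as.integer((as.numeric(root_seed) * 7919 + i * 104729) %% 2147483629 + 1)
}

#' Seeded phantom spec with randomly placed lesions
#'
#' Lesion centers are drawn uniformly inside the central brain region so the
#' inside-brain invariant always holds.
#'
#' @param shape phantom shape (2 axes).
#' @param n_lesions number of lesions.
#' @param radius lesion radius in voxels (isotropic).
#' @param delta lesion contrast in HU (negative).
#' @param texture_sd parenchymal texture SD in HU.
#' @param seed integer seed.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(shape = c(96L, 96L), n_lesions = 1L,
                                radius = 8, delta = -15, texture_sd = 2,
                                seed = 1L) {
  shape <- as.integer(shape)
  center <- (shape + 1) / 2
  brain_radii <- 0.38 * shape
  lesions <- with_seed(seed, {
    lapply(seq_len(n_lesions), function(i) {
      shrink <- 0.85
      repeat {
        repeat {
          u <- stats::runif(2, -1, 1)
          if (sum(u^2) <= 1) break
        }
        ctr <- center + u * pmax(brain_radii - radius, 0) * shrink
        # conservative inside-brain bound used by the phantom_spec validator
        if (sum(((abs(ctr - center) + radius) / brain_radii)^2) <= 1) break
        shrink <- shrink * 0.9
      }
      list(center = ctr, radii = rep(radius, 2), delta = delta)
    })
  })
  phantom_spec(shape = shape, lesions = lesions, texture_sd = texture_sd,
               seed = seed)
}

pipeline_log <- function(level, cfg_level, ...) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[level] >= levels[cfg_level %||% "info"]) {
    message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
  }
}

#' Run the full pipeline
#'
#' Executes phantom generation, low-dose noise insertion, denoising, lesion
#' segmentation (training a small network on the generated cases),
#' perfusion mapping and evaluation, writing every artifact plus a JSON
#' manifest. Re-running with the same config reproduces all artifacts:
#' every stochastic stage is seeded from the root seed.
#'
#' @param config nested config list (see [default_run_config()]); validated
#'   before any stage runs.
#' @return The run manifest (list), invisibly written to
#'   `output_dir/manifest.json`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  validate_run_config(config)
  out_dir <- config$output_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  lvl <- config$log_level %||% "info"
  root <- config$seed
  manifest <- list(package_version = as.character(utils::packageVersion("strokeseg")),
                   config = config,
                   seeds = list(),
                   artifacts = list(), metrics = list(),
                   completed_stages = character(0))

  ph_cfg <- config$phantom
  n_cases <- ph_cfg$n_cases %||% 2L
  pipeline_log("info", lvl, "generating ", n_cases, " phantom case(s)")
  cases <- lapply(seq_len(n_cases), function(i) {
    sd_i <- stage_seed(root, "phantom") + i
    spec <- random_phantom_spec(shape = unlist(ph_cfg$shape %||% c(96L, 96L)),
                                n_lesions = ph_cfg$n_lesions %||% 1L,
                                radius = ph_cfg$lesion_radius %||% 8,
                                delta = ph_cfg$lesion_delta %||% -15,
                                texture_sd = ph_cfg$texture_sd %||% 2,
                                seed = sd_i)
    make_head_phantom(spec)
  })
  manifest$seeds$phantom <- stage_seed(root, "phantom")
  for (i in seq_along(cases)) {
    write_nifti_volume(cases[[i]]$image,
                       file.path(out_dir, sprintf("case%02d_clean.nii.gz", i)))
    write_nifti_volume(cases[[i]]$mask,
                       file.path(out_dir, sprintf("case%02d_mask.nii.gz", i)))
  }
  manifest$completed_stages <- c(manifest$completed_stages, "phantom")

  sg <- config$noise$sigma %||% 25
  pipeline_log("info", lvl, "adding low-dose noise, sigma ", sg)
  pairs <- lapply(seq_along(cases), function(i) {
    add_lowdose_noise(cases[[i]]$image,
                      noise_model(kind = config$noise$kind %||% "gaussian",
                                  sigma = sg,
                                  seed = stage_seed(root, "noise") + i,
                                  alpha = config$noise$alpha %||% 0.05))
  })
  for (i in seq_along(pairs)) {
    write_nifti_volume(pairs[[i]]$noisy,
                       file.path(out_dir, sprintf("case%02d_lowdose.nii.gz", i)))
  }
  manifest$seeds$noise <- stage_seed(root, "noise")
  manifest$completed_stages <- c(manifest$completed_stages, "noise")

  method <- config$denoise$method %||% "bm3d"
  denoised <- if (method == "bm3d") {
    pipeline_log("info", lvl, "BM3D denoising")
    bp <- bm3d_params(sigma = config$denoise$sigma %||% sg,
                      lambda3d = config$denoise$lambda3d %||% 2.7,
                      block_size = config$denoise$block_size %||% 8L,
                      search_window = config$denoise$search_window %||% 39L,
                      max_group_size = config$denoise$max_group_size %||% 16L,
                      step = config$denoise$step %||% 3L)
    lapply(pairs, function(p) bm3d_denoise(p$noisy, bp))
  } else {
    lapply(pairs, function(p) p$noisy)
  }
  for (i in seq_along(denoised)) {
    write_nifti_volume(denoised[[i]],
                       file.path(out_dir, sprintf("case%02d_denoised.nii.gz", i)))
  }
  qual <- lapply(seq_along(denoised), function(i) {
    image_quality(cases[[i]]$image, denoised[[i]])
  })
  qual_noisy <- lapply(seq_along(pairs), function(i) {
    image_quality(cases[[i]]$image, pairs[[i]]$noisy)
  })
  manifest$metrics$quality <- list(
    psnr_noisy_mean = mean(vapply(qual_noisy, `[[`, 0, "psnr")),
    psnr_denoised_mean = mean(vapply(qual, `[[`, 0, "psnr")),
    ssim_denoised_mean = mean(vapply(qual, `[[`, 0, "ssim")))
  manifest$completed_stages <- c(manifest$completed_stages, "denoise")

  if (isTRUE(config$segment$enabled %||% TRUE)) {
    sc <- config$segment
    pipeline_log("info", lvl, "training segmenter (", sc$loss %||% "new_dice", " loss)")
    prep <- lapply(denoised, preprocess_ct,
                   smooth_sigma = sc$smooth_sigma %||% 0)
    cfg <- segnet_config(depth = sc$depth %||% 2L,
                         base_channels = sc$base_channels %||% 8L,
                         se_reduction = sc$se_reduction %||% 4L,
                         use_se = sc$use_se %||% TRUE,
                         use_residual = sc$use_residual %||% TRUE)
    net <- build_riseu_net(cfg, seed = stage_seed(root, "segment"))
    net <- train_segmenter(net, prep, lapply(cases, `[[`, "mask"),
                           loss = sc$loss %||% "new_dice",
                           epochs = sc$epochs %||% 6L,
                           steps_per_epoch = sc$steps_per_epoch %||% 8L,
                           batch_size = sc$batch_size %||% 2L,
                           lr = sc$lr %||% 3e-3,
                           seed = stage_seed(root, "segment") + 1L)
    save_checkpoint(net, file.path(out_dir, "segmenter.json"))
    preds <- lapply(prep, function(im) {
      predict_mask(net, im, threshold = sc$threshold %||% 0.5)
    })
    for (i in seq_along(preds)) {
      write_nifti_volume(preds[[i]],
                         file.path(out_dir, sprintf("case%02d_pred.nii.gz", i)))
    }
    rep <- detection_report(preds, lapply(cases, `[[`, "mask"))
    manifest$metrics$evaluation <- list(
      sensitivity = rep$sensitivity, specificity = rep$specificity,
      accuracy = rep$accuracy,
      lesions_detected_mean = rep$lesions_detected$mean,
      lesions_detected_sd = rep$lesions_detected$sd,
      final_training_loss = utils::tail(net$history, 1))
    manifest$seeds$segment <- stage_seed(root, "segment")
    manifest$completed_stages <- c(manifest$completed_stages, "segment")
  }

  if (isTRUE(config$perfusion$enabled %||% TRUE)) {
    pc <- config$perfusion
    pipeline_log("info", lvl, "perfusion mapping")
    ser <- make_perfusion_series(cases[[1]]$image, cases[[1]]$mask,
                                 normal_cbf = pc$normal_cbf %||% 60,
                                 lesion_cbf = pc$lesion_cbf %||% 20,
                                 normal_mtt = pc$normal_mtt %||% 4,
                                 lesion_mtt = pc$lesion_mtt %||% 8,
                                 seed = stage_seed(root, "perfusion"))
    write_perfusion_series(ser, file.path(out_dir, "perfusion_4d.nii.gz"),
                           file.path(out_dir, "aif.csv"))
    maps <- perfusion_maps(ser,
                           deconvolution_params(
                             truncation_fraction = pc$truncation_fraction %||% 0.2,
                             baseline_frames = pc$baseline_frames %||% 2L,
                             discretization = pc$discretization %||% "simpson"))
    write_perfusion_maps(maps, out_dir, spacing = cases[[1]]$image$spacing)
    lesion <- cases[[1]]$mask$data > 0
    normal <- ser$truth_maps$cbf > 0 & !lesion
    manifest$metrics$perfusion <- list(
      lesion_cbf_mean = mean(maps$cbf[lesion & maps$cbf > 0]),
      normal_cbf_mean = mean(maps$cbf[normal & maps$cbf > 0]))
    manifest$seeds$perfusion <- stage_seed(root, "perfusion")
    manifest$completed_stages <- c(manifest$completed_stages, "perfusion")
  }

  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest$artifacts <- as.list(tools::md5sum(file.path(out_dir, sort(files))))
  names(manifest$artifacts) <- sort(files)
  manifest$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
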