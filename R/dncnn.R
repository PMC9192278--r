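# Residual CNN denoisers: DnCNN (a plain conv-ReLU stack predicting the
# noise map, subtracted from the input; no spatial resampling anywhere) and
# the cascaded multi-block variant in which every block after the first
# consumes the previous block's estimate concatenated with the original
# noisy image.

#' DnCNN architecture configuration
#'
#' @param depth number of convolution layers (>= 3).
#' @param width feature channels in the hidden layers.
#' @param kernel spatial kernel size (odd).
#' @param residual predict the noise and subtract it from the input
#'   (recommended); `FALSE` predicts the clean image directly.
#' @return Object of class `dncnn_config`.
#' @export
dncnn_config <- function(depth = 5L, width = 16L, kernel = 3L,
                         residual = TRUE) {
  if (depth < 3) stop("`depth` must be >= 3")
  if (kernel %% 2 == 0) stop("`kernel` must be odd (same-size convolutions)")
  structure(list(depth = as.integer(depth), width = as.integer(width),
                 kernel = as.integer(kernel), residual = isTRUE(residual)),
            class = "dncnn_config")
}

#' Cascaded denoiser configuration
#'
#' @param n_blocks number of DnCNN-style blocks (>= 1).
#' @param block a [dncnn_config()] shared by all blocks.
#' @return Object of class `cascade_config`.
#' @export
cascade_config <- function(n_blocks = 2L, block = dncnn_config()) {
  if (n_blocks < 1) stop("`n_blocks` must be >= 1")
  stopifnot(inherits(block, "dncnn_config"))
  structure(list(n_blocks = as.integer(n_blocks), block = block),
            class = "cascade_config")
}

dncnn_block_params <- function(cfg, cin) {
  k <- cfg$kernel; w <- cfg$width
  chans <- c(cin, rep(w, cfg$depth - 1L), 1L)
  p <- lapply(seq_len(cfg$depth), function(i) conv_params(k, chans[i], chans[i + 1]))
  # zero-init the output layer: the block starts as an exact identity
  # (residual mode) and learns the noise map from there
  p[[cfg$depth]]$W[] <- 0
  p[[cfg$depth]]$b[] <- 0
  p
}

#' Build an untrained DnCNN denoiser
#'
#' @param cfg a [dncnn_config()].
#' @param seed seed for the weight initialization.
#' @return Object of class `denoiser_model` (subclass `dncnn_model`).
#' @export
build_dncnn <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "dncnn_config"))
  params <- with_seed(seed, list(dncnn_block_params(cfg, 1L)))
  structure(list(config = cascade_config(1L, cfg), params = params,
                 history = numeric(0), norm = NULL,
                 intensity_units = NULL),
            class = c("dncnn_model", "denoiser_model"))
}

#' Build an untrained cascaded denoiser
#'
#' Block 1 sees the noisy image; every later block sees the 2-channel
#' concatenation (previous estimate, original image).
#'
#' @param cfg a [cascade_config()].
#' @param seed seed for the weight initialization.
#' @return Object of class `denoiser_model` (subclass `cascade_model`).
#' @export
build_cascade <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "cascade_config"))
  params <- with_seed(seed, lapply(seq_len(cfg$n_blocks), function(i) {
    dncnn_block_params(cfg$block, if (i == 1L) 1L else 2L)
  }))
  structure(list(config = cfg, params = params, history = numeric(0),
                 norm = NULL, intensity_units = NULL),
            class = c("cascade_model", "denoiser_model"))
}

#' @export
print.denoiser_model <- function(x, ...) {
  cfg <- x$config
  cat("<", class(x)[1], "> ", cfg$n_blocks, " block(s), depth ",
      cfg$block$depth, ", width ", cfg$block$width, ", kernel ",
      cfg$block$kernel, if (cfg$block$residual) ", residual" else "",
      "; ", n_params(x$params), " parameters; ",
      if (length(x$history)) paste0(length(x$history), " epochs trained")
      else "untrained", "\n", sep = "")
  invisible(x)
}

#' Number of learnable parameters
#'
#' @param model a trained or untrained model object.
#' @return Total parameter count.
#' @export
n_parameters <- function(model) UseMethod("n_parameters")

#' @export
n_parameters.denoiser_model <- function(model) n_params(model$params)

# forward through one DnCNN block; returns residual/clean estimate and caches
dncnn_block_fwd <- function(params, x, cfg) {
  caches <- vector("list", cfg$depth)
  h <- x
  pad <- (cfg$kernel - 1L) %/% 2L
  for (i in seq_len(cfg$depth)) {
    cv <- conv_fwd(h, params[[i]], pad)
    if (i < cfg$depth) {
      rl <- relu_fwd(cv$y)
      caches[[i]] <- list(conv = cv, relu = rl)
      h <- rl$y
    } else {
      caches[[i]] <- list(conv = cv)
      h <- cv$y
    }
  }
  list(out = h, caches = caches)
}

dncnn_block_bwd <- function(params, caches, dout, cfg) {
  grads <- vector("list", cfg$depth)
  dh <- dout
  for (i in rev(seq_len(cfg$depth))) {
    if (i < cfg$depth) dh <- relu_bwd(dh, caches[[i]]$relu)
    bk <- conv_bwd(dh, params[[i]], caches[[i]]$conv)
    grads[[i]] <- list(W = bk$dW, b = bk$db)
    dh <- bk$dx
  }
  list(grads = grads, dx = dh)
}

# full forward over all blocks of a denoiser; x0 is (H, W, 1)
denoiser_fwd <- function(model, x0) {
  cfg <- model$config$block
  nb <- model$config$n_blocks
  prev <- x0
  blocks <- vector("list", nb)
  for (i in seq_len(nb)) {
    inp <- if (i == 1L) x0 else concat_fwd(prev, x0)$y
    bf <- dncnn_block_fwd(model$params[[i]], inp, cfg)
    out <- if (cfg$residual) prev - bf$out else bf$out
    blocks[[i]] <- list(fwd = bf, prev = prev)
    prev <- out
  }
  list(out = prev, blocks = blocks)
}

denoiser_bwd <- function(model, fw, dout) {
  cfg <- model$config$block
  nb <- model$config$n_blocks
  grads <- vector("list", nb)
  dprev <- dout
  for (i in rev(seq_len(nb))) {
    # out_i = prev - r_i (residual) or r_i
    dr <- if (cfg$residual) -dprev else dprev
    bk <- dncnn_block_bwd(model$params[[i]], fw$blocks[[i]]$fwd$caches, dr, cfg)
    grads[[i]] <- bk$grads
    dinp <- bk$dx
    dprev_new <- if (i == 1L) array(0, dim(dinp)[c(1, 2)] |> c(1L)) else {
      dinp[, , 1L, drop = FALSE]  # channel 1 of the concat is prev
    }
    if (cfg$residual) {
      # prev also feeds the subtraction directly
      dprev_new <- dprev_new + dprev
    }
    dprev <- dprev_new
  }
  grads
}

# affine training units: noise-adaptive standardization mapping the assumed
# noise SD to ~0.1, the contrast regime residual denoisers train well in;
# norm = c(center, scale), v_std = (v - center) / scale
normalize_to_unit <- function(dat, norm) (dat - norm[1]) / norm[2]
denormalize_from_unit <- function(dat, norm) dat * norm[2] + norm[1]

denoiser_norm <- function(pairs) {
  res <- unlist(lapply(pairs, function(p) {
    as.numeric(p$noisy$data - p$clean$data)
  }))
  sigma_hat <- stats::sd(res)
  clean_all <- unlist(lapply(pairs, function(p) as.numeric(p$clean$data)))
  center <- mean(clean_all)
  scale <- if (is.finite(sigma_hat) && sigma_hat > 0) 10 * sigma_hat
           else max(stats::sd(clean_all), 1)   # noiseless pairs: content units
  c(center = center, scale = scale)
}

#' Train a denoiser on matched clean/low-dose pairs
#'
#' Minimizes the mean-squared error between the model output and the clean
#' image over randomly sampled patches. Inputs are affinely standardized so
#' that the empirical noise SD of the pairs maps to 0.1 (the contrast regime
#' residual denoisers are tuned for); the mapping is stored on the model for
#' round-tripping at inference.
#'
#' @param model a `denoiser_model` from [build_dncnn()] or
#'   [build_cascade()].
#' @param pairs list of `noise_pair` objects sharing intensity units.
#' @param epochs training epochs; each epoch records one mean loss.
#' @param steps_per_epoch optimizer steps per epoch.
#' @param batch_size patches per step.
#' @param patch patch side in pixels (patches are sampled uniformly from the
#'   pair images); use NULL to train on full images.
#' @param lr Adam learning rate.
#' @param seed seed controlling batch sampling (weights were seeded at
#'   build time).
#' @return The trained model, with per-epoch losses appended to `history`.
#' @export
train_denoiser <- function(model, pairs, epochs = 10L, steps_per_epoch = 20L,
                           batch_size = 4L, patch = 32L, lr = 1e-3,
                           seed = 1L) {
  stopifnot(inherits(model, "denoiser_model"))
  if (length(pairs) < 1) stop("need at least one training pair")
  units <- unique(vapply(pairs, function(p) p$clean$intensity_units, ""))
  if (length(units) != 1) stop("all pairs must share intensity units")
  nrm <- denoiser_norm(pairs)
  model$norm <- nrm
  model$intensity_units <- units

  xs <- lapply(pairs, function(p) normalize_to_unit(p$noisy$data, nrm))
  ys <- lapply(pairs, function(p) normalize_to_unit(p$clean$data, nrm))

  opt <- adam_init(model$params, lr = lr)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ep_loss <- 0
      for (st in seq_len(steps_per_epoch)) {
        gacc <- tree_zeros(model$params)
        lacc <- 0
        for (bi in seq_len(batch_size)) {
          pi <- sample.int(length(xs), 1L)
          xim <- xs[[pi]]; yim <- ys[[pi]]
          if (!is.null(patch) && all(dim(xim) >= patch)) {
            oy <- sample.int(nrow(xim) - patch + 1L, 1L)
            ox <- sample.int(ncol(xim) - patch + 1L, 1L)
            xim <- xim[oy:(oy + patch - 1L), ox:(ox + patch - 1L)]
            yim <- yim[oy:(oy + patch - 1L), ox:(ox + patch - 1L)]
          }
          x0 <- array(xim, c(dim(xim), 1L))
          fw <- denoiser_fwd(model, x0)
          ls <- mse_loss(fw$out, array(yim, dim(fw$out)))
          lacc <- lacc + ls$loss
          g <- denoiser_bwd(model, fw, ls$grad)
          gacc <- tree_map2(`+`, gacc, g)
        }
        gacc <- tree_map(function(g) g / batch_size, gacc)
        stp <- adam_step(opt, model$params, gacc)
        opt <- stp$opt
        model$params <- stp$params
        ep_loss <- ep_loss + lacc / batch_size
      }
      model$history <- c(model$history, ep_loss / steps_per_epoch)
    }
  })
  model
}

#' Apply a denoiser to an image
#'
#' Deterministic inference; the output grid equals the input grid.
#'
#' @param model a `denoiser_model` (trained models check intensity units).
#' @param image an `image_volume` (2D).
#' @return Denoised `image_volume` on the same grid.
#' @export
apply_denoiser <- function(model, image) {
  stopifnot(inherits(model, "denoiser_model"),
            inherits(image, "image_volume"))
  if (!is.null(model$intensity_units) &&
      model$intensity_units != image$intensity_units) {
    stop("image units (", image$intensity_units,
         ") differ from training units (", model$intensity_units, ")")
  }
  nrm <- if (!is.null(model$norm)) model$norm else c(mean(image$data), stats::sd(image$data))
  x0 <- array(normalize_to_unit(image$data, nrm), c(dim(image$data), 1L))
  out <- denoiser_fwd(model, x0)$out
  res <- denormalize_from_unit(matrix(out, dim(image$data)[1]), nrm)
  image_volume(res, spacing = image$spacing,
               intensity_units = image$intensity_units,
               value_range = image$value_range)
}

#' @export
predict.denoiser_model <- function(object, newdata, ...) {
  apply_denoiser(object, newdata)
}

#' Save / load a denoiser or segmenter checkpoint
#'
#' Checkpoints are plain JSON archives holding the configuration, learned
#' parameters, and training history.
#'
#' @param model a model object.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  unclass_deep <- function(x) {
    if (is.list(x)) lapply(unclass(x), unclass_deep) else x
  }
  obj <- unclass(model)
  obj$.class <- class(model)
  obj$config <- unclass_deep(obj$config)
  obj$params <- tree_map(function(p) list(dim = dim(p) %||% length(p),
                                          data = as.numeric(p)), obj$params)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- unlist(obj$.class)
  obj$.class <- NULL
  restore <- function(tree) {
    if (is.list(tree) && !is.null(tree$dim) && !is.null(tree$data)) {
      dm <- as.numeric(unlist(tree$dim))
      dat <- as.numeric(unlist(tree$data))
      if (length(dm) == 1L) dat else array(dat, dm)
    } else if (is.list(tree)) lapply(tree, restore) else tree
  }
  obj$params <- restore(obj$params)
  flat <- function(x) lapply(x, function(v) unlist(v))
  if ("denoiser_model" %in% cls) {
    blk <- do.call(dncnn_config,
                   flat(obj$config$block)[c("depth", "width", "kernel",
                                            "residual")])
    obj$config <- cascade_config(unlist(obj$config$n_blocks), blk)
  } else if ("riseu_model" %in% cls) {
    obj$config <- do.call(segnet_config, flat(obj$config)[segnet_config_fields()])
  }
  obj$history <- as.numeric(unlist(obj$history))
  obj$norm <- if (length(obj$norm)) as.numeric(unlist(obj$norm)) else NULL
  if (!is.null(obj$intensity_units)) obj$intensity_units <- unlist(obj$intensity_units)
  if (!is.null(obj$loss)) obj$loss <- unlist(obj$loss)
  structure(obj, class = cls)
}
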