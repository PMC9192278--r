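# Lesion segmentation stack: CT preprocessing (skull stripping,
# standardization, smoothing), the residual squeeze-excitation U-Net
# (RISEU-Net), Dice-family training, and mask prediction. With both the SE
# gates and the residual shortcuts disabled the network reduces to a plain
# U-Net, which serves as the ablation comparator.

#' Skull-strip, standardize and smooth a head CT image
#'
#' Bone is located by thresholding, closed morphologically, and removed
#' together with everything outside the cranial interior; intensities inside
#' the brain mask are z-scored (mean 0, SD 1) and all non-brain voxels set to
#' 0; an optional Gaussian smoothing pass follows.
#'
#' @param image an `image_volume` in HU (2D).
#' @param skull_threshold HU above which a voxel counts as bone.
#' @param smooth_sigma Gaussian smoothing SD in voxels; 0 disables smoothing
#'   (the z-scoring then holds exactly on the brain region).
#' @return A `standardized` `image_volume` with the brain mask attached as
#'   attribute `"brain_mask"`.
#' @export
preprocess_ct <- function(image, skull_threshold = 300, smooth_sigma = 1) {
  stopifnot(inherits(image, "image_volume"))
  dat <- image$data
  if (length(dim(dat)) != 2L) stop("preprocessing expects a 2D slice")
  skull <- dat > skull_threshold
  if (!any(skull)) {
    warning("no skull found above ", skull_threshold,
            " HU; standardizing the whole image")
    brain <- array(TRUE, dim(dat))
  } else {
    sk <- EBImage::closing(skull, EBImage::makeBrush(5, "disc"))
    interior <- EBImage::fillHull(sk) & !sk
    # keep the largest interior region (the cranial cavity)
    lab <- EBImage::bwlabel(interior)
    if (max(lab) > 0) {
      sizes <- tabulate(lab[lab > 0])
      brain <- lab == which.max(sizes)
    } else brain <- interior
  }
  out <- array(0, dim(dat))
  mu <- mean(dat[brain])
  sdv <- stats::sd(as.numeric(dat[brain]))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  out[brain] <- (dat[brain] - mu) / sdv
  if (smooth_sigma > 0) out <- EBImage::gblur(out, sigma = smooth_sigma)
  res <- image_volume(out, spacing = image$spacing,
                      intensity_units = "standardized",
                      value_range = range(out) + c(-1e-9, 1e-9))
  attr(res, "brain_mask") <- brain
  res
}

total_variation <- function(m) {
  m <- as_image_data(m)
  sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
}

segnet_config_fields <- function() {
  c("depth", "base_channels", "se_reduction", "use_se", "use_residual",
    "kernel", "pool")
}

#' RISEU-Net architecture configuration
#'
#' @param depth number of encoder levels (each halves the spatial dims by
#'   the pool factors).
#' @param base_channels feature channels at the first level; doubled per
#'   level.
#' @param se_reduction squeeze-excitation bottleneck ratio r;
#'   `base_channels` must be divisible by it.
#' @param use_se enable the squeeze-excitation gates.
#' @param use_residual enable the residual shortcuts (with a 1x1 projection
#'   across channel changes). Both flags off gives a plain U-Net.
#' @param kernel conv kernel size (odd).
#' @param pool pooling factors `(h, w)`, both >= 1.
#' @return Object of class `segnet_config`.
#' @export
segnet_config <- function(depth = 2L, base_channels = 8L, se_reduction = 4L,
                          use_se = TRUE, use_residual = TRUE, kernel = 3L,
                          pool = c(2L, 2L)) {
  if (base_channels %% se_reduction != 0) {
    stop("`base_channels` must be divisible by `se_reduction`")
  }
  pool <- rep_len(as.integer(pool), 2L)
  if (any(pool < 1)) stop("pool factors must be >= 1")
  if (kernel %% 2 == 0) stop("`kernel` must be odd")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 se_reduction = as.integer(se_reduction),
                 use_se = isTRUE(use_se), use_residual = isTRUE(use_residual),
                 kernel = as.integer(kernel), pool = pool),
            class = "segnet_config")
}

seg_block_params <- function(cfg, cin, cout) {
  k <- cfg$kernel
  p <- list(conv1 = conv_params(k, cin, cout),
            conv2 = conv_params(k, cout, cout))
  if (cfg$use_se) p$se <- se_params(cout, cfg$se_reduction)
  if (cfg$use_residual && cin != cout) p$proj <- conv_params(1L, cin, cout)
  p
}

#' Build an untrained RISEU-Net segmenter
#'
#' U-shaped encoder-decoder with skip connections; each level holds a
#' two-convolution block, optionally gated by a squeeze-excitation module and
#' wrapped in a residual shortcut; max pooling between encoder levels,
#' nearest-neighbour upsampling plus convolution in the decoder; 1x1
#' convolution and logistic output map in \[0, 1\].
#'
#' @param cfg a [segnet_config()].
#' @param seed seed for the weight initialization.
#' @return Object of class `riseu_model` (subclass `segmenter_model`).
#' @export
build_riseu_net <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "segnet_config"))
  L <- cfg$depth
  ch <- cfg$base_channels * 2^(0:L)  # channels per level, bottleneck last
  params <- with_seed(seed, {
    p <- list(enc = vector("list", L), up = vector("list", L),
              dec = vector("list", L))
    for (l in seq_len(L)) {
      cin <- if (l == 1L) 1L else ch[l - 1]
      p$enc[[l]] <- seg_block_params(cfg, cin, ch[l])
    }
    p$bottleneck <- seg_block_params(cfg, ch[L], ch[L + 1])
    for (l in seq_len(L)) {
      p$up[[l]] <- conv_params(cfg$kernel, ch[l + 1], ch[l])
      p$dec[[l]] <- seg_block_params(cfg, 2L * ch[l], ch[l])
    }
    p$head <- conv_params(1L, ch[1], 1L)
    p
  })
  structure(list(config = cfg, params = params, history = numeric(0)),
            class = c("riseu_model", "segmenter_model"))
}

#' @export
print.riseu_model <- function(x, ...) {
  cfg <- x$config
  cat("<riseu_model> depth ", cfg$depth, ", base ", cfg$base_channels,
      if (cfg$use_residual) ", residual" else "",
      if (cfg$use_se) paste0(", SE r=", cfg$se_reduction) else "",
      "; ", n_params(x$params), " parameters; ",
      if (length(x$history)) paste0(length(x$history), " epochs trained")
      else "untrained", "\n", sep = "")
  invisible(x)
}

#' @export
n_parameters.segmenter_model <- function(model) n_params(model$params)

seg_block_fwd <- function(p, x, cfg) {
  pad <- (cfg$kernel - 1L) %/% 2L
  c1 <- conv_fwd(x, p$conv1, pad)
  r1 <- relu_fwd(c1$y)
  c2 <- conv_fwd(r1$y, p$conv2, pad)
  cache <- list(c1 = c1, r1 = r1, c2 = c2)
  branch <- c2$y
  if (cfg$use_se) {
    cache$se <- se_fwd(branch, p$se)
    branch <- cache$se$y
  }
  if (cfg$use_residual) {
    if (!is.null(p$proj)) {
      cache$proj <- conv_fwd(x, p$proj, 0L)
      short <- cache$proj$y
    } else short <- x
    y <- short + branch
  } else {
    cache$r2 <- relu_fwd(branch)
    y <- cache$r2$y
  }
  list(y = y, cache = cache)
}

seg_block_bwd <- function(p, cache, dy, cfg) {
  grads <- list()
  if (cfg$use_residual) {
    dbranch <- dy
    if (!is.null(p$proj)) {
      pj <- conv_bwd(dy, p$proj, cache$proj)
      grads$proj <- list(W = pj$dW, b = pj$db)
      dx_short <- pj$dx
    } else dx_short <- dy
  } else {
    dbranch <- relu_bwd(dy, cache$r2)
    dx_short <- NULL
  }
  if (cfg$use_se) {
    seb <- se_bwd(dbranch, p$se, cache$se)
    grads$se <- seb$grads
    dbranch <- seb$dx
  }
  b2 <- conv_bwd(dbranch, p$conv2, cache$c2)
  grads$conv2 <- list(W = b2$dW, b = b2$db)
  dr1 <- relu_bwd(b2$dx, cache$r1)
  b1 <- conv_bwd(dr1, p$conv1, cache$c1)
  grads$conv1 <- list(W = b1$dW, b = b1$db)
  dx <- b1$dx
  if (!is.null(dx_short)) dx <- dx + dx_short
  # align gradient tree layout with the parameter tree
  list(dx = dx, grads = grads[names(p)])
}

riseu_check_shape <- function(cfg, d) {
  div <- cfg$pool^cfg$depth
  if (d[1] %% div[1] != 0 || d[2] %% div[2] != 0) {
    need <- c(ceiling(d[1] / div[1]) * div[1], ceiling(d[2] / div[2]) * div[2])
    stop("input ", d[1], "x", d[2], " not divisible by pool^depth (",
         div[1], "x", div[2], "); pad to ", need[1], "x", need[2])
  }
}

riseu_fwd <- function(model, x) {
  cfg <- model$config
  riseu_check_shape(cfg, dim(x))
  L <- cfg$depth
  ph <- cfg$pool[1]; pw <- cfg$pool[2]
  enc <- vector("list", L); pools <- vector("list", L)
  h <- x
  for (l in seq_len(L)) {
    bf <- seg_block_fwd(model$params$enc[[l]], h, cfg)
    enc[[l]] <- bf
    pf <- maxpool_fwd(bf$y, ph, pw)
    pools[[l]] <- pf
    h <- pf$y
  }
  bn <- seg_block_fwd(model$params$bottleneck, h, cfg)
  h <- bn$y
  ups <- vector("list", L); upconv <- vector("list", L)
  uprelu <- vector("list", L); cats <- vector("list", L)
  dec <- vector("list", L)
  pad <- (cfg$kernel - 1L) %/% 2L
  for (l in rev(seq_len(L))) {
    uf <- upsample_fwd(h, ph, pw)
    ups[[l]] <- uf
    uc <- conv_fwd(uf$y, model$params$up[[l]], pad)
    upconv[[l]] <- uc
    ur <- relu_fwd(uc$y)
    uprelu[[l]] <- ur
    cc <- concat_fwd(enc[[l]]$y, ur$y)
    cats[[l]] <- cc
    db <- seg_block_fwd(model$params$dec[[l]], cc$y, cfg)
    dec[[l]] <- db
    h <- db$y
  }
  hd <- conv_fwd(h, model$params$head, 0L)
  prob <- sigmoid_(hd$y)
  list(prob = prob, head = hd, enc = enc, pools = pools, bn = bn,
       ups = ups, upconv = upconv, uprelu = uprelu, cats = cats, dec = dec)
}

riseu_bwd <- function(model, fw, dprob) {
  cfg <- model$config
  L <- cfg$depth
  dlogit <- dprob * fw$prob * (1 - fw$prob)
  hb <- conv_bwd(dlogit, model$params$head, fw$head)
  grads <- list(enc = vector("list", L), up = vector("list", L),
                dec = vector("list", L))
  grads$head <- list(W = hb$dW, b = hb$db)
  dh <- hb$dx
  dskip <- vector("list", L)
  for (l in seq_len(L)) {  # decoder levels from shallowest (last applied)
    db <- seg_block_bwd(model$params$dec[[l]], fw$dec[[l]]$cache, dh, cfg)
    grads$dec[[l]] <- db$grads
    sp <- concat_bwd(db$dx, fw$cats[[l]])
    dskip[[l]] <- sp$da
    dur <- relu_bwd(sp$db, fw$uprelu[[l]])
    ub <- conv_bwd(dur, model$params$up[[l]], fw$upconv[[l]])
    grads$up[[l]] <- list(W = ub$dW, b = ub$db)
    dh <- upsample_bwd(ub$dx, fw$ups[[l]])
  }
  bb <- seg_block_bwd(model$params$bottleneck, fw$bn$cache, dh, cfg)
  grads$bottleneck <- bb$grads
  dh <- bb$dx
  for (l in rev(seq_len(L))) {
    dpool <- maxpool_bwd(dh, fw$pools[[l]])
    denc <- dpool + dskip[[l]]
    eb <- seg_block_bwd(model$params$enc[[l]], fw$enc[[l]]$cache, denc, cfg)
    grads$enc[[l]] <- eb$grads
    dh <- eb$dx
  }
  grads <- grads[names(model$params)]
  grads
}

#' Train a lesion segmenter
#'
#' Minimizes a soft Dice-family loss (standard Dice, or the
#' false-positive-penalizing New-Dice variant) over labeled images.
#'
#' @param model a `riseu_model` from [build_riseu_net()].
#' @param images list of preprocessed `image_volume`s (2D, spatial dims
#'   divisible by `pool^depth`).
#' @param masks list of matching binary `segmentation_mask`s.
#' @param loss `"dice"` or `"new_dice"`.
#' @param epochs,steps_per_epoch,batch_size training schedule.
#' @param lr Adam learning rate.
#' @param seed seed controlling batch order.
#' @return The trained model with per-epoch losses in `history` and the
#'   loss name in `loss`.
#' @export
train_segmenter <- function(model, images, masks, loss = c("dice", "new_dice"),
                            epochs = 10L, steps_per_epoch = 10L,
                            batch_size = 2L, lr = 3e-3, seed = 1L) {
  stopifnot(inherits(model, "segmenter_model"))
  loss <- match.arg(loss)
  if (length(images) < 1 || length(images) != length(masks)) {
    stop("need >= 1 labeled (image, mask) pair")
  }
  xs <- lapply(images, function(im) {
    d <- as_image_data(im)
    riseu_check_shape(model$config, dim(d))
    array(d, c(dim(d), 1L))
  })
  ys <- lapply(masks, function(mk) {
    d <- as_image_data(mk)
    if (!all(d %in% c(0, 1))) stop("masks must be binary")
    d
  })
  opt <- adam_init(model$params, lr = lr)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ep_loss <- 0
      for (st in seq_len(steps_per_epoch)) {
        gacc <- tree_zeros(model$params)
        lacc <- 0
        for (bi in seq_len(batch_size)) {
          pi <- sample.int(length(xs), 1L)
          fw <- riseu_fwd(model, xs[[pi]])
          lg <- dice_loss_grad(as.numeric(fw$prob), as.numeric(ys[[pi]]),
                               variant = loss)
          lacc <- lacc + lg$loss
          g <- riseu_bwd(model, fw, array(lg$grad, dim(fw$prob)))
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
  model$loss <- loss
  model
}

#' Probability map of a segmenter on one image
#'
#' @param model a `riseu_model`.
#' @param image preprocessed `image_volume` (or matrix).
#' @return Matrix of lesion probabilities in \[0, 1\].
#' @export
predict_probabilities <- function(model, image) {
  d <- as_image_data(image)
  riseu_check_shape(model$config, dim(d))
  fw <- riseu_fwd(model, array(d, c(dim(d), 1L)))
  matrix(fw$prob, dim(d)[1])
}

#' Threshold a segmenter's output into a lesion mask
#'
#' @param model a `riseu_model`.
#' @param image preprocessed `image_volume`.
#' @param threshold probability cutoff; voxels with `p >= threshold` are
#'   lesion.
#' @return A `segmentation_mask`.
#' @export
predict_mask <- function(model, image, threshold = 0.5) {
  p <- predict_probabilities(model, image)
  sp <- if (inherits(image, "image_volume")) image$spacing else 1
  segmentation_mask(array(as.numeric(p >= threshold), dim(p)), spacing = sp)
}

#' @export
predict.riseu_model <- function(object, newdata, threshold = 0.5, ...) {
  predict_mask(object, newdata, threshold = threshold)
}
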