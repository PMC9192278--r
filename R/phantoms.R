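# Synthetic head-CT phantoms, low-dose noise insertion, and 4D contrast
# dynamics with known ground truth. Every generator is a pure function of
# (spec, seed).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic head phantom
#'
#' Describes a head-like attenuation map: an elliptical cranium with a
#' high-attenuation skull shell, brain parenchyma, CSF ventricles, and
#' ellipsoidal hypodense (ischemic) lesions. Works in 2D (y, x) or 3D
#' (z, y, x).
#'
#' @param shape integer voxel counts per axis, length 2 or 3.
#' @param lesions list of lesions, each `list(center=, radii=, delta=)` with
#'   `center`/`radii` in voxel units (same axis order as `shape`) and `delta`
#'   the contrast offset in HU relative to parenchyma. Ischemic lesions are
#'   hypodense, so `delta` must be negative.
#' @param hu named list of tissue attenuations in HU; defaults: background
#'   -1000 (air), skull +1000, parenchyma 35, CSF 8.
#' @param texture_sd standard deviation (HU) of the smooth parenchymal
#'   texture field; 0 disables it.
#' @param seed integer seed driving the texture field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(256L, 256L), lesions = list(),
                         hu = list(background = -1000, skull = 1000,
                                   parenchyma = 35, csf = 8),
                         texture_sd = 2, seed = 1L) {
  shape <- as.integer(shape)
  if (!length(shape) %in% c(2L, 3L) || any(shape < 8L)) {
    stop("`shape` must give 2 or 3 axes of at least 8 voxels")
  }
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    if (!all(c("center", "radii", "delta") %in% names(les))) {
      stop("lesion ", i, " must have fields center, radii, delta")
    }
    if (les$delta >= 0) {
      stop("lesion ", i, ": ischemic lesions are hypodense; delta must be < 0")
    }
  }
  spec <- structure(list(shape = shape, lesions = lesions, hu = hu,
                         texture_sd = texture_sd, seed = as.integer(seed)),
                    class = "phantom_spec")
  geom <- phantom_geometry(spec)
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    ctr <- rep_len(as.numeric(les$center), length(shape))
    rad <- rep_len(as.numeric(les$radii), length(shape))
    # sufficient inside-brain condition on the bounding extent of the lesion
    if (sum(((abs(ctr - geom$center) + rad) / geom$brain_radii)^2) > 1) {
      stop("lesion ", i, " extends outside the brain ellipse")
    }
  }
  spec
}

phantom_geometry <- function(spec) {
  shape <- spec$shape
  center <- (shape + 1) / 2
  head_radii <- 0.45 * shape
  brain_radii <- 0.38 * shape
  list(center = center, head_radii = head_radii, brain_radii = brain_radii)
}

# squared normalized ellipsoid distance field ((x-c)/r)^2 summed over axes
ellipsoid_field <- function(shape, center, radii) {
  nax <- length(shape)
  ax <- lapply(seq_len(nax), function(k) ((seq_len(shape[k]) - center[k]) / radii[k])^2)
  if (nax == 2L) {
    outer(ax[[1]], ax[[2]], `+`)
  } else {
    f <- array(0, shape)
    f <- f + array(rep(ax[[1]], times = prod(shape[2:3])), shape)
    f <- f + array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape)
    f + array(rep(ax[[3]], each = prod(shape[1:2])), shape)
  }
}

smooth_field <- function(shape, sd_amp) {
  # low-frequency random field: coarse white noise, trilinear upsampled
  coarse_shape <- pmax(4L, shape %/% 16L)
  coarse <- array(stats::rnorm(prod(coarse_shape)), coarse_shape)
  if (length(shape) == 2L) {
    yi <- seq(1, coarse_shape[1], length.out = shape[1])
    xi <- seq(1, coarse_shape[2], length.out = shape[2])
    y0 <- pmin(floor(yi), coarse_shape[1] - 1L); x0 <- pmin(floor(xi), coarse_shape[2] - 1L)
    fy <- yi - y0; fx <- xi - x0
    up <- coarse[cbind(rep(y0, length(x0)), rep(x0, each = length(y0)))] *
      outer(1 - fy, 1 - fx) +
      coarse[cbind(rep(y0 + 1, length(x0)), rep(x0, each = length(y0)))] *
      outer(fy, 1 - fx) +
      coarse[cbind(rep(y0, length(x0)), rep(x0 + 1, each = length(y0)))] *
      outer(1 - fy, fx) +
      coarse[cbind(rep(y0 + 1, length(x0)), rep(x0 + 1, each = length(y0)))] *
      outer(fy, fx)
    up <- matrix(up, shape[1], shape[2])
  } else {
    up <- array(0, shape)
    for (z in seq_len(shape[1])) {
      zi <- 1 + (z - 1) / max(shape[1] - 1, 1) * (coarse_shape[1] - 1)
      z0 <- min(floor(zi), coarse_shape[1] - 1); fz <- zi - z0
      sl <- coarse[z0, , ] * (1 - fz) + coarse[z0 + 1, , ] * fz
      yi <- seq(1, coarse_shape[2], length.out = shape[2])
      xi <- seq(1, coarse_shape[3], length.out = shape[3])
      y0 <- pmin(floor(yi), coarse_shape[2] - 1L); x0 <- pmin(floor(xi), coarse_shape[3] - 1L)
      fy <- yi - y0; fx <- xi - x0
      up[z, , ] <- matrix(sl[cbind(rep(y0, length(x0)), rep(x0, each = length(y0)))], shape[2]) * outer(1 - fy, 1 - fx) +
        matrix(sl[cbind(rep(y0 + 1, length(x0)), rep(x0, each = length(y0)))], shape[2]) * outer(fy, 1 - fx) +
        matrix(sl[cbind(rep(y0, length(x0)), rep(x0 + 1, each = length(y0)))], shape[2]) * outer(1 - fy, fx) +
        matrix(sl[cbind(rep(y0 + 1, length(x0)), rep(x0 + 1, each = length(y0)))], shape[2]) * outer(fy, fx)
    }
  }
  up * sd_amp
}

#' Generate a head phantom and its lesion mask
#'
#' Deterministic given `spec$seed`: the same spec always yields bit-identical
#' image and mask.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` (an `image_volume` in HU) and `mask`
#'   (a `segmentation_mask`, union of all lesions), plus `brain_mask` and
#'   `skull_mask` giving the tissue geometry.
#' @export
make_head_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  geom <- phantom_geometry(spec)
  hu <- spec$hu

  head_f <- ellipsoid_field(shape, geom$center, geom$head_radii)
  brain_f <- ellipsoid_field(shape, geom$center, geom$brain_radii)
  head <- head_f <= 1
  brain <- brain_f <= 1
  skull <- head & !brain

  img <- array(hu$background, shape)
  img[skull] <- hu$skull
  img[brain] <- hu$parenchyma
  if (spec$texture_sd > 0) {
    tex <- with_seed(spec$seed, smooth_field(shape, spec$texture_sd))
    img[brain] <- img[brain] + tex[brain]
  }

  # paired CSF ventricles near the midline
  vshift <- 0.12 * shape[length(shape)]
  vradii <- pmax(0.06 * shape, 1.5)
  for (s in c(-1, 1)) {
    vc <- geom$center
    vc[length(shape)] <- vc[length(shape)] + s * vshift
    vf <- ellipsoid_field(shape, vc, vradii)
    img[vf <= 1] <- hu$csf
  }

  mask <- array(0, shape)
  for (les in spec$lesions) {
    ctr <- rep_len(as.numeric(les$center), length(shape))
    rad <- rep_len(as.numeric(les$radii), length(shape))
    lf <- ellipsoid_field(shape, ctr, rad)
    inside <- lf <= 1
    img[inside] <- img[inside] + les$delta
    mask[inside] <- 1
  }

  list(image = image_volume(img, intensity_units = "HU"),
       mask = segmentation_mask(mask),
       brain_mask = segmentation_mask(array(as.numeric(brain), shape)),
       skull_mask = segmentation_mask(array(as.numeric(skull), shape)))
}

#' Low-dose noise model
#'
#' Additive Gaussian noise in the image's intensity units is the default;
#' `poisson_gaussian` adds a signal-dependent variance component
#' `alpha * (v - min(v))` emulating photon statistics.
#'
#' @param kind `"gaussian"` or `"poisson_gaussian"`.
#' @param sigma noise standard deviation (>= 0), intensity units.
#' @param seed integer seed for the realization.
#' @param alpha signal-dependence coefficient for `poisson_gaussian`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian", "poisson_gaussian"),
                        sigma = 25, seed = 1L, alpha = 0.05) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("`sigma` must be >= 0")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed),
                 alpha = alpha),
            class = "noise_model")
}

#' Insert low-dose noise into a clean image
#'
#' Models the low-dose acquisition as the clean image plus a seeded noise map;
#' the clean image is returned unmodified alongside the noisy one.
#'
#' @param clean an `image_volume`.
#' @param model a [noise_model()].
#' @return A list of class `noise_pair`: `clean`, `noisy` (both
#'   `image_volume` on the same grid and units), and `model`.
#' @export
add_lowdose_noise <- function(clean, model) {
  stopifnot(inherits(clean, "image_volume"), inherits(model, "noise_model"))
  dat <- clean$data
  noisy <- with_seed(model$seed, {
    if (model$kind == "gaussian") {
      dat + stats::rnorm(length(dat), sd = model$sigma)
    } else {
      sd_map <- sqrt(model$sigma^2 + model$alpha * pmax(dat - min(dat), 0))
      dat + stats::rnorm(length(dat)) * sd_map
    }
  })
  noisy <- array(noisy, dim(dat))
  structure(
    list(clean = clean,
         noisy = image_volume(noisy, spacing = clean$spacing,
                              intensity_units = clean$intensity_units,
                              value_range = clean$value_range),
         model = model),
    class = "noise_pair"
  )
}

#' Gamma-variate arterial input function
#'
#' `c(t) = A * (t - t0)^alpha * exp(-(t - t0)/beta)` for `t > t0`, else 0,
#' rescaled so that its maximum equals `peak`.
#'
#' @param t times in seconds.
#' @param t0 bolus arrival time (s).
#' @param alpha,beta gamma-variate shape and scale.
#' @param peak maximum concentration (arbitrary HU-like units).
#' @return Concentration at `t`.
#' @export
gamma_variate_aif <- function(t, t0 = 5, alpha = 3, beta = 1.5, peak = 200) {
  tt <- pmax(t - t0, 0)
  raw <- tt^alpha * exp(-tt / beta)
  mx <- (alpha * beta)^alpha * exp(-alpha)  # analytic maximum of tt^a e^(-tt/b)
  peak * raw / mx
}

#' Simulate a 4D contrast-enhanced perfusion series
#'
#' Tissue enhancement follows the indicator-dilution forward model
#' `C(t) = f * (AIF (*) R)(t)` with exponential residue
#' `R(t) = exp(-t / MTT)` and flow `f = CBF / 6000` (1/s for CBF in
#' mL/100 g/min), discretized on the acquisition grid: the discrete residue
#' carries the exact per-frame average of R (so tissue/AIF area ratios equal
#' `f * MTT` up to the truncated tail) and the convolution is the
#' rectangle-rule Toeplitz operator also used by the deconvolution stage.
#' The baseline frame equals the phantom.
#'
#' @param phantom `image_volume` (HU) giving the baseline anatomy.
#' @param mask `segmentation_mask` of the lesion (reduced-flow) region.
#' @param times acquisition times in seconds, strictly increasing; default 20
#'   uniform frames over 45 s.
#' @param normal_cbf,lesion_cbf cerebral blood flow, mL/100 g/min.
#' @param normal_mtt,lesion_mtt mean transit time, seconds.
#' @param aif list of gamma-variate parameters passed to
#'   [gamma_variate_aif()].
#' @param noise_sd per-frame additive Gaussian noise (HU); 0 for noiseless.
#' @param seed integer seed (noise only).
#' @return An object of class `perfusion_series`: `frames` (t, then spatial
#'   axes), `times`, `aif`, `baseline`, and `truth_maps` (cbf, cbv, mtt, ttp).
#' @export
make_perfusion_series <- function(phantom, mask,
                                  times = seq(0, 45, length.out = 20),
                                  normal_cbf = 60, lesion_cbf = 20,
                                  normal_mtt = 4, lesion_mtt = 8,
                                  aif = list(t0 = 5, alpha = 3, beta = 1.5,
                                             peak = 200),
                                  noise_sd = 0, seed = 1L) {
  stopifnot(inherits(phantom, "image_volume"),
            inherits(mask, "segmentation_mask"))
  if (!same_grid(phantom, mask)) stop("phantom and mask grids differ")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (normal_mtt <= 0 || lesion_mtt <= 0) stop("MTT must be > 0")
  if (normal_cbf < 0 || lesion_cbf < 0) stop("CBF must be >= 0")

  shape <- dim(phantom$data)
  # perfused tissue = soft-tissue voxels (excludes skull and air)
  tissue <- phantom$data > -100 & phantom$data < 300
  cbf_map <- array(0, shape)
  mtt_map <- array(0, shape)
  cbf_map[tissue] <- normal_cbf
  mtt_map[tissue] <- normal_mtt
  lesion <- mask$data > 0 & tissue
  cbf_map[lesion] <- lesion_cbf
  mtt_map[lesion] <- lesion_mtt

  # discrete forward model on the acquisition grid, one curve per
  # (CBF, MTT) tissue class: C = A_rect %*% (f * bin-averaged residue)
  dt <- mean(diff(times))
  aif_s <- do.call(gamma_variate_aif, c(list(t = times), aif))
  A <- aif_toeplitz(aif_s, dt, "rect")
  classes <- unique(data.frame(cbf = cbf_map[tissue], mtt = mtt_map[tissue]))
  curve_at_times <- matrix(0, nrow(classes), length(times))
  ttp_class <- numeric(nrow(classes))
  for (i in seq_len(nrow(classes))) {
    f <- classes$cbf[i] / 6000
    if (f == 0) next
    mtt_i <- classes$mtt[i]
    x <- dt / mtt_i
    # exact average of exp(-t/MTT) over each frame-length bin
    rbar <- (mtt_i / dt) * exp(-(seq_along(times) - 1) * x) * (1 - exp(-x))
    curve_at_times[i, ] <- as.numeric(A %*% (f * rbar))
    ttp_class[i] <- times[which.max(curve_at_times[i, ])]
  }

  base <- phantom$data
  idx_class <- integer(length(base))
  tiss_idx <- which(tissue)
  key <- paste(cbf_map[tiss_idx], mtt_map[tiss_idx])
  class_key <- paste(classes$cbf, classes$mtt)
  idx_class[tiss_idx] <- match(key, class_key)
  # frames laid out (t, spatial...): frame ti occupies stride positions
  frames <- array(0, c(length(times), shape))
  fmat <- matrix(rep(as.numeric(base), each = length(times)),
                 nrow = length(times))
  fmat[, tiss_idx] <- fmat[, tiss_idx] +
    t(curve_at_times)[, idx_class[tiss_idx], drop = FALSE]
  frames[] <- fmat
  if (noise_sd > 0) {
    frames <- with_seed(seed, frames + stats::rnorm(length(frames), sd = noise_sd))
  }

  ttp_map <- array(NA_real_, shape)
  ttp_map[tiss_idx] <- ttp_class[idx_class[tiss_idx]]
  truth <- list(cbf = cbf_map,
                cbv = cbf_map * mtt_map / 60,
                mtt = mtt_map,
                ttp = ttp_map)

  structure(list(frames = frames, times = times,
                 aif = do.call(gamma_variate_aif, c(list(t = times), aif)),
                 baseline = base, truth_maps = truth,
                 spacing = phantom$spacing),
            class = "perfusion_series")
}

#' @export
print.perfusion_series <- function(x, ...) {
  cat("<perfusion_series> ", length(x$times), " frames over ",
      format(max(x$times), digits = 3), " s, grid ",
      paste(dim(x$frames)[-1], collapse = " x "), "\n", sep = "")
  invisible(x)
}

#' Write a perfusion series as 4D NIfTI plus an AIF table
#'
#' @param series a `perfusion_series`.
#' @param nifti_path path for the 4D volume (time as 4th axis).
#' @param aif_path path for a two-column CSV `time_s, aif`.
#' @return `nifti_path`, invisibly.
#' @export
write_perfusion_series <- function(series, nifti_path, aif_path) {
  fr <- series$frames
  nt <- dim(fr)[1]
  sp_dims <- dim(fr)[-1]
  # reorder to spatial-then-time for NIfTI convention
  out <- array(0, c(sp_dims, nt))
  for (ti in seq_len(nt)) {
    if (length(sp_dims) == 2L) out[, , ti] <- fr[ti, , ]
    else out[, , , ti] <- fr[ti, , , ]
  }
  img <- RNifti::asNifti(out, datatype = "float")
  RNifti::writeNifti(img, nifti_path)
  utils::write.csv(data.frame(time_s = series$times, aif = series$aif),
                   aif_path, row.names = FALSE)
  invisible(nifti_path)
}
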