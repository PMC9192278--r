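# R surface of the two-stage BM3D collaborative filter (core in src/bm3d.cpp).

#' BM3D parameters
#'
#' The classic profile: 8x8 blocks, a 39x39 search window, groups of up to
#' 16 blocks, hard-threshold multiplier 2.7, reference-block step 3. Block
#' matching uses the mean squared per-pixel difference; the default cutoff
#' `4 sigma^2 + 300` accepts same-structure patches (whose expected distance
#' under the noise is `2 sigma^2`) with margin.
#'
#' @param sigma assumed noise standard deviation (image intensity units).
#' @param block_size square block side in pixels.
#' @param search_window square search window side; must be >= `block_size`.
#' @param max_group_size maximum blocks per group; a power of two (the group
#'   axis carries an orthonormal Haar transform).
#' @param match_threshold distance cutoff (mean squared difference per
#'   pixel); `NULL` for the sigma-scaled default.
#' @param lambda3d hard-threshold multiplier applied to `sigma`.
#' @param step stride between reference blocks.
#' @return Object of class `bm3d_params`.
#' @export
bm3d_params <- function(sigma = 25, block_size = 8L, search_window = 39L,
                        max_group_size = 16L, match_threshold = NULL,
                        lambda3d = 2.7, step = 3L) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (lambda3d < 0) stop("`lambda3d` must be >= 0")
  if (block_size > search_window) stop("`block_size` must be <= `search_window`")
  if (max_group_size < 1 || bitwAnd(max_group_size, max_group_size - 1L) != 0) {
    stop("`max_group_size` must be a power of two")
  }
  if (is.null(match_threshold)) match_threshold <- 4 * sigma^2 + 300
  structure(list(sigma = sigma, block_size = as.integer(block_size),
                 search_window = as.integer(search_window),
                 max_group_size = as.integer(max_group_size),
                 match_threshold = match_threshold, lambda3d = lambda3d,
                 step = as.integer(step)),
            class = "bm3d_params")
}

#' Group blocks similar to a reference block
#'
#' Candidates inside the search window are ranked by mean squared
#' per-pixel difference to the reference block; ties break in raster
#' (row-major) order, and the reference block is always first.
#'
#' @param image an `image_volume` (2D) or matrix.
#' @param ref integer `(row, col)` of the reference block's top-left corner
#'   (1-based).
#' @param params a [bm3d_params()].
#' @return A list of class `block_group`: `coords` (n x 2 top-left
#'   positions), `distance`, `stack` (block, y, x array), and
#'   `reference_index` (always 1).
#' @export
block_match <- function(image, ref, params = bm3d_params()) {
  img <- as_image_data(image)
  k <- params$block_size
  if (ref[1] < 1 || ref[2] < 1 || ref[1] + k - 1 > nrow(img) ||
      ref[2] + k - 1 > ncol(img)) {
    stop("reference block at (", ref[1], ", ", ref[2],
         ") extends past the image border")
  }
  res <- .bm3d_block_match_cpp(img, ref[1] - 1L, ref[2] - 1L, k,
                               params$search_window, params$max_group_size,
                               params$match_threshold)
  # stack arrives as (y, x, block); reorder to (block, y, x)
  st <- aperm(res$stack, c(3, 1, 2))
  structure(list(coords = res$coords, distance = res$distance, stack = st,
                 reference_index = res$reference_index),
            class = "block_group")
}

#' One BM3D stage (hard-threshold or Wiener)
#'
#' @param noisy the noisy `image_volume` (2D) or matrix.
#' @param pilot stage-1 basic estimate; required in `"wiener"` mode, where
#'   it drives both the block matching and the Wiener shrinkage energies.
#' @param params a [bm3d_params()].
#' @param mode `"hard"` (coefficient thresholding at `lambda3d * sigma`) or
#'   `"wiener"`.
#' @return Filtered image, same class and grid as `noisy`.
#' @export
bm3d_stage <- function(noisy, pilot = NULL, params = bm3d_params(),
                       mode = c("hard", "wiener")) {
  mode <- match.arg(mode)
  img <- as_image_data(noisy)
  if (mode == "wiener") {
    if (is.null(pilot)) stop("wiener mode requires the stage-1 `pilot` estimate")
    pil <- as_image_data(pilot)
    if (!identical(dim(pil), dim(img))) stop("pilot grid mismatch")
  } else {
    pil <- img
  }
  match_img <- if (mode == "wiener") pil else img
  out <- .bm3d_stage_cpp(img, match_img, mode == "wiener", pil,
                         params$block_size, params$search_window,
                         params$max_group_size, params$match_threshold,
                         params$lambda3d, params$sigma, params$step)
  if (inherits(noisy, "image_volume")) {
    image_volume(out, spacing = noisy$spacing,
                 intensity_units = noisy$intensity_units,
                 value_range = noisy$value_range)
  } else out
}

#' Two-stage BM3D denoising
#'
#' Stage 1 hard-thresholds the grouped 3D spectra to produce a basic
#' estimate, which stage 2 uses as the matching image and Wiener pilot
#' against the original noisy input.
#'
#' @param noisy the noisy `image_volume` (2D) or matrix.
#' @param params a [bm3d_params()].
#' @return The final estimate, same class and grid as `noisy`.
#' @export
bm3d_denoise <- function(noisy, params = bm3d_params()) {
  basic <- bm3d_stage(noisy, params = params, mode = "hard")
  bm3d_stage(noisy, pilot = basic, params = params, mode = "wiener")
}
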