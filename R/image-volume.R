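#' Scalar attenuation image with grid metadata
#'
#' The universal currency of the pipeline: a 2D (y, x) or 3D (z, y, x) scalar
#' field together with voxel spacing, intensity units and the value range used
#' as the PSNR MAX.
#'
#' @param data numeric matrix (y, x) or 3D array (z, y, x); all values finite.
#' @param spacing numeric vector of voxel sizes in mm, one per axis
#'   (strictly positive). Recycled to the number of axes if length 1.
#' @param intensity_units `"HU"`, `"normalized"` (data in \[0, 1\]) or
#'   `"standardized"` (z-scored).
#' @param value_range length-2 numeric `(min, max)` used as the dynamic range
#'   for PSNR; defaults to the Hounsfield window \[-1000, 1000\] for HU data
#'   and \[0, 1\] for normalized data.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = 1,
                         intensity_units = c("HU", "normalized", "standardized"),
                         value_range = NULL) {
  intensity_units <- match.arg(intensity_units)
  if (!is.numeric(data) || is.null(dim(data)) ||
      !length(dim(data)) %in% c(2L, 3L)) {
    stop("`data` must be a numeric matrix (y, x) or 3D array (z, y, x)")
  }
  if (!all(is.finite(data))) stop("image values must all be finite")
  nax <- length(dim(data))
  spacing <- rep_len(as.numeric(spacing), nax)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  if (intensity_units == "normalized" &&
      (min(data) < 0 || max(data) > 1)) {
    stop("normalized intensities must lie in [0, 1]")
  }
  if (is.null(value_range)) {
    value_range <- switch(intensity_units,
                          HU = c(-1000, 1000),
                          normalized = c(0, 1),
                          standardized = c(-4, 4))
  }
  if (length(value_range) != 2L || value_range[2] <= value_range[1]) {
    stop("`value_range` must be (min, max) with max > min")
  }
  structure(
    list(data = data, spacing = spacing, intensity_units = intensity_units,
         value_range = as.numeric(value_range)),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume> ", paste(dim(x$data), collapse = " x "),
      " [", x$intensity_units, "], spacing ",
      paste(x$spacing, collapse = " x "), " mm, range [",
      format(min(x$data), digits = 4), ", ",
      format(max(x$data), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Binary lesion mask sharing an image grid
#'
#' @param data matrix/array with values in \{0, 1\} (logical accepted).
#' @param spacing voxel spacing in mm, as for [image_volume()].
#' @return An object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(data, spacing = 1) {
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  if (!all(data %in% c(0, 1))) stop("mask values must be 0 or 1")
  nax <- length(dim(data))
  spacing <- rep_len(as.numeric(spacing), nax)
  structure(list(data = data, spacing = spacing), class = "segmentation_mask")
}

#' @export
print.segmentation_mask <- function(x, ...) {
  cat("<segmentation_mask> ", paste(dim(x$data), collapse = " x "),
      ", ", sum(x$data), " positive voxels\n", sep = "")
  invisible(x)
}

#' @export
dim.segmentation_mask <- function(x) dim(x$data)

same_grid <- function(a, b) identical(dim(a$data), dim(b$data))

as_image_data <- function(x) {
  if (inherits(x, "image_volume") || inherits(x, "segmentation_mask")) x$data
  else x
}

#' Write an image or mask as NIfTI-1
#'
#' Axis order is recorded as (z, y, x) with 0-based voxel indices; masks are
#' written with an integer datatype.
#'
#' @param x an `image_volume` or `segmentation_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  dat <- x$data
  datatype <- if (inherits(x, "segmentation_mask")) "int16" else "float"
  attr(dat, "pixdim") <- x$spacing
  img <- RNifti::asNifti(dat, datatype = datatype)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 file as an image volume
#'
#' @param path `.nii`/`.nii.gz` file.
#' @param intensity_units units to stamp on the result.
#' @return An `image_volume`.
#' @export
read_nifti_volume <- function(path, intensity_units = "HU") {
  img <- RNifti::readNifti(path)
  dat <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)
  image_volume(dat, spacing = sp[seq_along(dim(dat))],
               intensity_units = intensity_units)
}

#' Write a 2D image as a 16-bit PNG slice
#'
#' Intensities are affinely mapped from `value_range` onto \[0, 1\] before
#' quantization.
#'
#' @param x an `image_volume` with 2D data.
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_png_slice <- function(x, path) {
  dat <- as_image_data(x)
  if (length(dim(dat)) != 2L) stop("PNG export requires a 2D slice")
  vr <- if (inherits(x, "image_volume")) x$value_range else c(0, 1)
  scaled <- (dat - vr[1]) / (vr[2] - vr[1])
  scaled <- pmin(pmax(scaled, 0), 1)
  png::writePNG(scaled, path, dpi = NULL)
  invisible(path)
}
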