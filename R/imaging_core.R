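#' Construct a 2-D image with physical pixel size
#'
#' The basic substrate of all pixel operations: a matrix of non-negative,
#' finite intensities (arbitrary units) plus the physical edge length of one
#' pixel in nanometres and a free-text channel label. STED-like recordings
#' use 25 nm pixels; epifluorescence-like recordings use 266.67 nm pixels.
#'
#' @param pixels numeric matrix of intensities (rows = y, columns = x).
#' @param pixel_size_nm length of one pixel edge in nm (> 0).
#' @param channel free-text channel label.
#' @return An object of class `image2d`: the matrix with attributes
#'   `pixel_size_nm` and `channel`.
#' @export
image2d <- function(pixels, pixel_size_nm, channel = "") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("'pixels' must be a non-empty numeric matrix")
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L ||
      pixel_size_nm <= 0)
    stop("'pixel_size_nm' must be a single positive number")
  storage.mode(pixels) <- "double"
  structure(pixels,
            pixel_size_nm = as.numeric(pixel_size_nm),
            channel = as.character(channel),
            class = c("image2d", "matrix", "array"))
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("image2d: %d x %d px, %.5g nm/px, channel '%s'\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"), attr(x, "channel")))
  cat(sprintf("  intensity range [%.5g, %.5g]\n", min(x), max(x)))
  invisible(x)
}

#' Pixel size accessor
#' @param image an `image2d`.
#' @return pixel edge length in nm.
#' @export
pixel_size <- function(image) attr(image, "pixel_size_nm")

img_like <- function(template, pixels) {
  image2d(pixels, attr(template, "pixel_size_nm"), attr(template, "channel"))
}

#' Region of interest on an image
#'
#' A boolean mask congruent with an [image2d()]; the analyzed area (a
#' membrane sheet or sub-region). The area is the selected pixel count times
#' the squared pixel edge, reported in square micrometres.
#'
#' @param mask logical matrix, same dimensions as the image it applies to.
#' @param pixel_size_nm pixel edge in nm (taken from `image` if given).
#' @param image optional `image2d` supplying dimensions/pixel size checks.
#' @return An object of class `roi` with attribute `area_um2`.
#' @export
roi <- function(mask, pixel_size_nm = NULL, image = NULL) {
  mask <- as.matrix(mask)
  if (is.numeric(mask)) mask <- mask != 0
  if (!is.logical(mask)) stop("'mask' must be logical")
  if (!is.null(image)) {
    if (!all(dim(mask) == dim(image)))
      stop("ROI mask dimensions do not match the image")
    pixel_size_nm <- pixel_size(image)
  }
  if (is.null(pixel_size_nm)) stop("supply 'pixel_size_nm' or 'image'")
  if (!any(mask)) stop("ROI selects no pixels")
  area <- sum(mask) * (pixel_size_nm / 1000)^2
  structure(mask, pixel_size_nm = pixel_size_nm, area_um2 = area,
            class = c("roi", "matrix", "array"))
}

#' ROI covering a whole image
#' @param image an `image2d`.
#' @return an [roi()] selecting every pixel.
#' @export
roi_full <- function(image) {
  roi(matrix(TRUE, nrow(image), ncol(image)), image = image)
}

#' ROI area in square micrometres
#' @param x an `roi`.
#' @export
roi_area_um2 <- function(x) attr(x, "area_um2")

check_congruent <- function(image, mask) {
  if (!all(dim(image) == dim(mask)))
    stop("image and ROI dimensions do not match")
}

## ---- Gaussian blur -------------------------------------------------------

## 1-D sampled Gaussian kernel, truncated at 4 sigma, normalized to sum 1.
gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

## Convolve the columns of a matrix with a 1-D kernel under reflective
## boundary padding (half-sample mirror: the edge pixel is repeated, making
## the operator self-adjoint so total intensity is conserved exactly).
## Written as a banded operator matrix so the whole pass is one BLAS
## multiply.
conv_cols_reflect <- function(x, kernel) {
  n <- nrow(x)
  r <- (length(kernel) - 1L) / 2L
  # index of the reflected source row for each (row, tap) pair
  op <- matrix(0, n, n)
  for (j in seq(-r, r)) {
    src <- seq_len(n) + j
    # fold repeatedly in case the kernel is wider than the image
    while (any(src < 1L | src > n)) {
      src <- ifelse(src < 1L, 1L - src, src)
      src <- ifelse(src > n, 2L * n + 1L - src, src)
    }
    w <- kernel[j + r + 1L]
    op[cbind(seq_len(n), src)] <- op[cbind(seq_len(n), src)] + w
  }
  op %*% x
}

#' Gaussian smoothing with reflective boundary handling
#'
#' Separable convolution with a sampled, normalized Gaussian kernel
#' (truncated at 4 sigma). Mirror padding keeps total intensity approximately
#' conserved near edges; on interior pixels the operation composes like the
#' continuous Gaussian semigroup. `sigma_px = 0` returns an identical copy.
#'
#' @param image an [image2d()].
#' @param sigma_px Gaussian sigma in pixel units (>= 0).
#' @return a blurred `image2d` of identical shape.
#' @export
gaussian_blur <- function(image, sigma_px) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1L || is.na(sigma_px) ||
      sigma_px < 0)
    stop("'sigma_px' must be a single non-negative number")
  if (sigma_px == 0) return(img_like(image, image))
  k <- gauss_kernel_1d(sigma_px)
  out <- conv_cols_reflect(unclass(image), k)       # blur along y
  out <- t(conv_cols_reflect(t(out), k))            # blur along x
  img_like(image, out)
}

## ---- ROI intensity statistics -------------------------------------------

#' Background-corrected ROI intensity statistics and clustering degree (rSDM)
#'
#' Subtracts a scalar background from the ROI pixels, then reports their mean,
#' sample standard deviation (n - 1 denominator) and the relative standard
#' deviation of the mean, rSDM = sd / mean — a coefficient-of-variation
#' measure of how clustered the staining is (uniform staining gives a small
#' rSDM, punctate staining a large one). Negative corrected pixels are kept so
#' the mean stays unbiased. If the corrected mean is not positive the rSDM is
#' undefined and returned as `NA` with `rsdm_defined = FALSE`, never silently
#' as 0.
#'
#' @param image an [image2d()].
#' @param roi an [roi()] congruent with `image`.
#' @param background scalar background intensity (>= 0) to subtract.
#' @param subtract_background_for_rsdm if `FALSE`, the sd/mean ratio is
#'   computed on raw (uncorrected) pixels while `mean` stays corrected.
#' @return list of class `intensity_stats`: `mean`, `sd`, `rsdm`,
#'   `rsdm_defined`, `background`, `n_pixels`.
#' @export
roi_mean_intensity <- function(image, roi, background = 0,
                               subtract_background_for_rsdm = TRUE) {
  check_congruent(image, roi)
  if (!is.numeric(background) || length(background) != 1L || background < 0)
    stop("'background' must be a single non-negative number")
  px <- as.numeric(unclass(image)[unclass(roi)])
  if (length(px) == 0L) stop("ROI selects no pixels")
  corr <- px - background
  m <- mean(corr)
  s <- stats::sd(corr)
  if (length(px) == 1L) s <- 0
  if (subtract_background_for_rsdm) {
    rm_ <- m; rs <- s
  } else {
    rm_ <- mean(px); rs <- stats::sd(px); if (length(px) == 1L) rs <- 0
  }
  defined <- rm_ > 0
  structure(list(mean = m, sd = s,
                 rsdm = if (defined) rs / rm_ else NA_real_,
                 rsdm_defined = defined,
                 background = background, n_pixels = length(px)),
            class = "intensity_stats")
}

## ---- Pearson colocalization ---------------------------------------------

#' Pearson correlation coefficient between two channels within an ROI
#'
#' Correlates the paired pixel intensities of two congruent images restricted
#' to the ROI. Zero variance in either channel is an error (the coefficient
#' is undefined there), never a silent 0.
#'
#' @param image_a,image_b congruent [image2d()] channels.
#' @param roi an [roi()] congruent with both.
#' @return scalar in \[-1, 1\].
#' @export
pcc <- function(image_a, image_b, roi) {
  check_congruent(image_a, roi); check_congruent(image_b, roi)
  a <- as.numeric(unclass(image_a)[unclass(roi)])
  b <- as.numeric(unclass(image_b)[unclass(roi)])
  if (length(a) < 2L) stop("ROI must select at least two pixels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("PCC undefined: zero variance in at least one channel within the ROI")
  stats::cor(a, b)
}

#' 180-degree rotation of an image (flip vertically and horizontally)
#' @param image an `image2d` (or plain matrix).
#' @return the rotated image, same class.
#' @export
flip180 <- function(image) {
  out <- unclass(image)[nrow(image):1L, ncol(image):1L, drop = FALSE]
  if (inherits(image, "image2d")) img_like(image, out) else out
}

#' Flipped-channel chance colocalization control
#'
#' Estimates the PCC expected from unrelated channel structure by rotating
#' the second channel by 180 degrees (flipping it vertically and
#' horizontally) before computing the Pearson correlation. The ROI mask is
#' not rotated: it is applied after flipping the second channel only, so the
#' same region is compared against displaced structure.
#'
#' @inheritParams pcc
#' @return scalar control PCC.
#' @export
pcc_flipped_control <- function(image_a, image_b, roi) {
  pcc(image_a, flip180(image_b), roi)
}
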