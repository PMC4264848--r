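#' Approximate the non-uniform background from a reference slice
#'
#' Grayscale morphological opening (erosion then dilation with a disk,
#' default radius 9) of a slice that contains no scaffold or tissue —
#' the top or bottom slice of the scan. Opening removes bright
#' structures smaller than the structuring element while keeping the
#' smooth intensity background, so the result approximates the coil
#' inhomogeneity pattern. The estimate is anti-extensive (never above
#' the reference slice) and idempotent.
#'
#' @param stack an [image_stack()].
#' @param reference_slice_index slice to use; default the last slice.
#' @param structuring_radius disk radius in pixels (default 9).
#' @param dark_fraction_warn warn if more than this fraction of
#'   reference pixels lies below half the slice median — a heuristic
#'   for scaffold-like dark structures contaminating the reference.
#' @return a `background_model`: list with `background` (matrix),
#'   `reference_slice_index` and `structuring_radius`.
#' @export
approximate_background <- function(stack, reference_slice_index = NULL,
                                   structuring_radius = 9,
                                   dark_fraction_warn = 0.05) {
  nz <- n_slices(stack)
  if (is.null(reference_slice_index)) reference_slice_index <- nz
  if (reference_slice_index < 1 || reference_slice_index > nz)
    stop("reference slice index out of range")
  ref <- get_slice(stack, reference_slice_index)
  med <- stats::median(ref)
  if (med > 0) {
    ## scaffold-like structures are dark pixels enclosed by the bright
    ## liquid region; the dark area outside the sample tube is expected
    bright <- ref >= med / 2
    hull <- EBImage::fillHull(EBImage::Image(bright * 1)) > 0.5
    if (mean(hull & !bright) > dark_fraction_warn)
      warning("reference slice contains dark structures inside the ",
              "liquid region; it may not be scaffold/tissue-free")
  }
  bg <- gray_opening(ref, disk_kernel(structuring_radius))
  structure(list(background = bg,
                 reference_slice_index = as.integer(reference_slice_index),
                 structuring_radius = as.integer(structuring_radius)),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat(sprintf(
    "background_model: %d x %d, from slice %d, SE radius %d, range [%.4g, %.4g]\n",
    nrow(x$background), ncol(x$background), x$reference_slice_index,
    x$structuring_radius, min(x$background), max(x$background)))
  invisible(x)
}

#' Subtract the background estimate from every slice
#'
#' The single 2D background image is subtracted from each slice of the
#' stack; negative results are clipped to zero (downstream thresholding
#' assumes non-negative intensities). The output is a float stack so no
#' integer wraparound can occur.
#'
#' @param stack an [image_stack()].
#' @param background a `background_model` (or a plain matrix).
#' @return corrected [image_stack()] with `bit_depth = "float"`.
#' @export
subtract_background <- function(stack, background) {
  bg <- if (inherits(background, "background_model")) background$background
        else background
  d <- dim(stack$voxels)
  if (!identical(dim(bg), d[1:2]))
    stop("background dimensions do not match the stack slices")
  out <- stack$voxels - array(bg, d)
  out[out < 0] <- 0
  image_stack(out, stack$pixel_size, stack$slice_thickness,
              bit_depth = "float")
}

#' Median-filter every slice for noise reduction
#'
#' 2D median over a disk neighbourhood (default radius 2, a 13-pixel
#' disk) applied slice by slice with reflective borders.
#'
#' @param stack an [image_stack()].
#' @param radius disk radius in pixels.
#' @return denoised [image_stack()] (same bit depth).
#' @export
median_denoise <- function(stack, radius = 2) {
  out <- stack$voxels
  for (k in seq_len(n_slices(stack)))
    out[, , k] <- median_filter_disk(out[, , k], radius)
  image_stack(out, stack$pixel_size, stack$slice_thickness,
              bit_depth = stack$bit_depth)
}

#' Full background correction and denoising sequence
#'
#' Background approximation from the reference slice, subtraction from
#' the whole stack, then median denoising — the processing applied to
#' every scan before tissue segmentation.
#'
#' @inheritParams approximate_background
#' @param median_radius disk radius of the median filter.
#' @return corrected [image_stack()] with the `background_model`
#'   attached as attribute `"background"`.
#' @export
correct_stack <- function(stack, reference_slice_index = NULL,
                          structuring_radius = 9, median_radius = 2) {
  bg <- approximate_background(stack, reference_slice_index,
                               structuring_radius)
  out <- median_denoise(subtract_background(stack, bg), median_radius)
  attr(out, "background") <- bg
  out
}
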