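#' Image stack of MRI slices
#'
#' The pipeline's universal carrier: a 3D grid of non-negative
#' intensities with physical voxel metadata. Slices are stored as
#' `voxels[row, col, slice]`; slice 1 is the first TIFF page (scaffold
#' top), the x-y origin is the top-left pixel with pixel-centred
#' coordinates.
#'
#' @param voxels 3D numeric array (rows x cols x slices) or a matrix
#'   (treated as one slice). Intensities must be finite and >= 0.
#' @param pixel_size in-plane pixel edge in mm.
#' @param slice_thickness slice-to-slice distance in mm.
#' @param bit_depth `8`, `16`, or `"float"` (unbounded non-negative).
#' @return an `image_stack` object.
#' @export
image_stack <- function(voxels, pixel_size, slice_thickness, bit_depth = 16) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a rows x cols x slices array")
  if (!all(is.finite(voxels)) || any(voxels < 0))
    stop("intensities must be finite and >= 0")
  if (!is.numeric(pixel_size) || pixel_size <= 0 ||
      !is.numeric(slice_thickness) || slice_thickness <= 0)
    stop("pixel_size and slice_thickness must be positive lengths (mm)")
  if (!identical(bit_depth, "float")) {
    bit_depth <- as.integer(bit_depth)
    if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8, 16 or \"float\"")
  }
  structure(list(voxels = voxels, pixel_size = pixel_size,
                 slice_thickness = slice_thickness, bit_depth = bit_depth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_stack: %d x %d px, %d slices (%s-bit)\n", d[1], d[2], d[3],
    as.character(x$bit_depth)))
  cat(sprintf("  pixel size %.4g mm, slice thickness %.4g mm\n",
              x$pixel_size, x$slice_thickness))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

n_slices <- function(stack) dim(stack$voxels)[3L]

get_slice <- function(stack, i) stack$voxels[, , i]

max_intensity <- function(bit_depth) {
  if (identical(bit_depth, "float")) Inf else 2^as.integer(bit_depth) - 1
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Intensities are preserved bit-exactly (the file's `[0,1]` samples
#' are rescaled to integer intensity units `0..2^bits-1`). RGB or
#' multi-channel files are rejected.
#'
#' @param path TIFF file path.
#' @param pixel_size in-plane pixel size in mm; default assumes a
#'   10 mm field of view divided by the matrix size.
#' @param slice_thickness slice thickness in mm (default 0.07).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, pixel_size = NULL, slice_thickness = 0.07) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                    error = function(e) stop("failed to read TIFF '", path,
                                             "': ", conditionMessage(e)))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 1L) stop("TIFF has no pages: ", path)
  if (length(dim(pages[[1L]])) != 2L)
    stop("expected single-channel grayscale TIFF, got multi-channel: ", path)
  bits <- attr(pages[[1L]], "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  d <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1))))
    stop("TIFF pages differ in dimensions: ", path)
  scale <- 2^bits - 1
  vox <- array(0, c(d, length(pages)))
  for (i in seq_along(pages)) vox[, , i] <- round(pages[[i]] * scale)
  if (is.null(pixel_size)) pixel_size <- 10 / d[2L]
  image_stack(vox, pixel_size, slice_thickness, bit_depth = as.integer(bits))
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' Float stacks are written 16-bit after clipping to `[0, 65535]`.
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  bits <- if (identical(stack$bit_depth, "float")) 16L else stack$bit_depth
  scale <- 2^bits - 1
  ## writeTIFF truncates when quantising, so round here and sit half an
  ## LSB above the integer to make the stored sample exact
  pages <- lapply(seq_len(n_slices(stack)), function(i) {
    k <- round(pmin(pmax(get_slice(stack, i), 0), scale))
    pmin((k + 0.499) / scale, 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Write a binary mask volume as an 8-bit 0/255 multi-page TIFF
#' @param mask logical 3D array (or matrix for a single slice).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1L))
  pages <- lapply(seq_len(dim(mask)[3L]), function(i)
    matrix(as.numeric(mask[, , i]), dim(mask)[1L], dim(mask)[2L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  invisible(path)
}

#' Read a 0/255 mask TIFF back as a logical volume
#' @param path TIFF path.
#' @return logical 3D array.
#' @export
read_mask <- function(path) {
  s <- read_stack(path, pixel_size = 1, slice_thickness = 1)
  s$voxels > max_intensity(s$bit_depth) / 2
}
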