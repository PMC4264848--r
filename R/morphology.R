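#' Disk structuring element
#'
#' Binary disk kernel containing every pixel whose centre lies within
#' `radius` of the kernel centre (Euclidean distance, so the kernel for
#' radius 1 is a plus shape and radius 2 a 13-pixel disk). This is the
#' discretisation used by all morphological operations in the package,
#' for both grayscale background estimation and binary mask smoothing.
#'
#' @param radius disk radius in pixels (>= 1, integer).
#' @return a (2*radius+1) square 0/1 matrix.
#' @export
disk_kernel <- function(radius) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L)
    stop("structuring element radius must be an integer >= 1")
  d <- seq(-radius, radius)
  k <- outer(d, d, function(dy, dx) as.numeric(dy^2 + dx^2 <= radius^2))
  storage.mode(k) <- "double"
  k
}

#' Pad a matrix by symmetric (mirror) reflection
#'
#' Border rule shared by every morphological and median operation:
#' edge rows/columns are mirrored including the edge itself
#' (`symmetric` padding), so a constant image stays constant under
#' erosion/dilation all the way to the border.
#'
#' @param m numeric matrix.
#' @param pad number of pixels to add on each side.
#' @return padded matrix of dimension `dim(m) + 2*pad`.
#' @export
pad_reflect <- function(m, pad) {
  pad <- as.integer(pad)
  if (pad < 0L) stop("pad must be >= 0")
  if (pad == 0L) return(m)
  nr <- nrow(m); nc <- ncol(m)
  if (pad > nr || pad > nc)
    stop("reflective pad larger than image dimension")
  ri <- c(pad:1, 1:nr, nr:(nr - pad + 1))
  ci <- c(pad:1, 1:nc, nc:(nc - pad + 1))
  m[ri, ci, drop = FALSE]
}

pad_radius <- function(kern) (nrow(kern) - 1L) %/% 2L

## EBImage leaves the outermost pixels dependent on its own border
## convention, so every call is wrapped in symmetric padding wide enough
## that the cropped interior is border-rule exact. EBImage also expects
## grayscale intensities in [0, 1]; erosion/dilation commute with
## positive scaling, so values are normalised in and rescaled out.
morpho_apply <- function(m, kern, fun) {
  r <- pad_radius(kern)
  p <- pad_reflect(m, r)
  M <- max(p)
  if (M > 0) p <- p / M else M <- 1
  out <- fun(p, kern) * M
  out <- out[(r + 1L):(r + nrow(m)), (r + 1L):(r + ncol(m)), drop = FALSE]
  dimnames(out) <- NULL
  as.matrix(out)
}

#' Grayscale erosion with a disk
#' @param m numeric matrix (one image slice).
#' @param kern structuring element, e.g. [disk_kernel()].
#' @return eroded matrix, same dimensions.
#' @export
gray_erode <- function(m, kern) morpho_apply(m, kern, EBImage::erode)

#' Grayscale dilation with a disk
#' @inheritParams gray_erode
#' @return dilated matrix, same dimensions.
#' @export
gray_dilate <- function(m, kern) morpho_apply(m, kern, EBImage::dilate)

#' Grayscale opening (erosion then dilation)
#'
#' Removes bright structures smaller than the structuring element while
#' preserving the smooth background; anti-extensive (result <= input)
#' and idempotent. This is the background estimator applied to the
#' scaffold-free reference slice.
#'
#' @inheritParams gray_erode
#' @return opened matrix, same dimensions.
#' @export
gray_opening <- function(m, kern) gray_dilate(gray_erode(m, kern), kern)

#' Binary opening of a 2D mask
#'
#' Same disk discretisation and border rule as the grayscale
#' operations. Used to smooth segmented objects and remove outlier
#' pixels (radius 2 by default downstream).
#'
#' @param mask logical (or 0/1) matrix.
#' @param radius disk radius in pixels.
#' @return logical matrix.
#' @export
binary_opening <- function(mask, radius) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  gray_opening(m, disk_kernel(radius)) > 0.5
}

#' Disk median filter of one slice
#'
#' 2D median over the disk neighbourhood of the given radius with
#' reflective border handling. Implemented by stacking the shifted
#' copies of the padded slice (one per kernel offset) and taking
#' row-wise medians.
#'
#' @param m numeric matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return filtered matrix, same dimensions.
#' @export
median_filter_disk <- function(m, radius) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("median filter radius must be >= 1")
  nr <- nrow(m); nc <- ncol(m)
  p <- pad_reflect(m, radius)
  off <- which(disk_kernel(radius) == 1, arr.ind = TRUE) - radius - 1L
  sh <- matrix(0, nr * nc, nrow(off))
  for (i in seq_len(nrow(off))) {
    sh[, i] <- p[(radius + 1L + off[i, 1L]):(radius + nr + off[i, 1L]),
                 (radius + 1L + off[i, 2L]):(radius + nc + off[i, 2L])]
  }
  matrix(matrixStats::rowMedians(sh), nr, nc)
}
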