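#' Circular region of interest in the slice plane
#'
#' The circle enclosing scaffold and surrounding liquid within which
#' all pixel counting happens. Coordinates are pixel-centred: pixel
#' (row 1, col 1) sits at (x, y) = (1, 1); `center_x` runs along
#' columns, `center_y` along rows.
#'
#' @param center_x,center_y circle centre in pixels.
#' @param radius circle radius in pixels (> 0).
#' @return a `circular_roi` object.
#' @export
circular_roi <- function(center_x, center_y, radius) {
  if (radius <= 0) stop("ROI radius must be > 0")
  structure(list(center_x = center_x, center_y = center_y, radius = radius),
            class = "circular_roi")
}

#' @export
print.circular_roi <- function(x, ...) {
  cat(sprintf("circular_roi: centre (%.2f, %.2f) px, radius %.2f px\n",
              x$center_x, x$center_y, x$radius))
  invisible(x)
}

#' Rasterise a circular ROI to a logical mask
#' @param roi a [circular_roi()].
#' @param nrow,ncol slice dimensions in pixels.
#' @return logical matrix; `TRUE` inside the circle.
#' @export
roi_mask <- function(roi, nrow, ncol) {
  m <- outer((seq_len(nrow) - roi$center_y)^2,
             (seq_len(ncol) - roi$center_x)^2, "+") <= roi$radius^2
  if (!any(m)) stop("ROI does not intersect the image")
  m
}

#' Fit the circular ROI automatically from the liquid region
#'
#' Convenience replacement for drawing the ROI by hand: a mid-stack
#' slice is thresholded (Otsu), the largest connected non-dark
#' component — the liquid in the sample tube, connected through the
#' scaffold pores — is hole-filled, and an area-equivalent circle
#' through its centroid is returned. A user-supplied ROI always takes
#' precedence over the fit.
#'
#' @param stack an [image_stack()].
#' @param roi optional [circular_roi()]; returned unchanged if given.
#' @param slice slice index to fit on (default: middle of the stack).
#' @return a [circular_roi()].
#' @export
fit_roi <- function(stack, roi = NULL, slice = NULL) {
  if (!is.null(roi)) {
    if (!inherits(roi, "circular_roi")) stop("roi must be a circular_roi")
    return(roi)
  }
  if (is.null(slice)) slice <- ceiling(n_slices(stack) / 2)
  m <- get_slice(stack, slice)
  mx <- max(m)
  if (mx <= 0) stop("blank slice: cannot fit an ROI, supply one manually")
  thr <- EBImage::otsu(EBImage::Image(m / mx), range = c(0, 1)) * mx
  bw <- m > thr
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0 || max(sizes) < 0.1 * length(m))
    stop("no connected bright region covering >= 10% of the image; ",
         "supply the ROI manually")
  comp <- lab == which.max(sizes)
  filled <- EBImage::fillHull(EBImage::Image(comp * 1)) > 0.5
  idx <- which(filled, arr.ind = TRUE)
  circular_roi(center_x = mean(idx[, 2]), center_y = mean(idx[, 1]),
               radius = sqrt(nrow(idx) / pi))
}

#' Segment tissue by a global intensity threshold
#'
#' Within the ROI, pixels at or above the threshold are tissue; each
#' slice is then smoothed by binary opening (disk radius 2 by default)
#' to remove outlier pixels and smooth object outlines. Applied to the
#' background-corrected, denoised stack, where only tissue remains
#' bright.
#'
#' @param corrected corrected [image_stack()].
#' @param roi a [circular_roi()].
#' @param threshold intensity threshold (> 0).
#' @param opening_radius disk radius of the smoothing opening;
#'   `0` disables it.
#' @return logical volume (tissue mask).
#' @export
segment_tissue <- function(corrected, roi, threshold, opening_radius = 2) {
  if (threshold <= 0) stop("tissue threshold must be > 0")
  d <- dim(corrected$voxels)
  rm2 <- roi_mask(roi, d[1], d[2])
  out <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    m <- (corrected$voxels[, , k] >= threshold) & rm2
    if (opening_radius >= 1 && any(m)) m <- binary_opening(m, opening_radius)
    out[, , k] <- m
  }
  out
}

#' Segment scaffold material by a low threshold
#'
#' The scaffold is the dark class: within the ROI, pixels at or below
#' `low_threshold` are scaffold. Operates on the unprocessed stack
#' (background subtraction is tuned for the bright class). Warns when
#' any slice's ROI becomes > 90 percent scaffold — the pore-closure
#' failure mode seen when scaffold-liquid contrast collapses.
#'
#' @param stack an [image_stack()] (raw).
#' @param roi a [circular_roi()].
#' @param low_threshold intensity below/at which pixels are scaffold.
#' @return logical volume (scaffold mask).
#' @export
segment_scaffold <- function(stack, roi, low_threshold) {
  d <- dim(stack$voxels)
  rm2 <- roi_mask(roi, d[1], d[2])
  out <- array(FALSE, d)
  closure <- FALSE
  for (k in seq_len(d[3])) {
    m <- (stack$voxels[, , k] <= low_threshold) & rm2
    if (mean(m[rm2]) > 0.9) closure <- TRUE
    out[, , k] <- m
  }
  if (closure)
    warning("scaffold occupies > 90% of the ROI in at least one slice: ",
            "likely pore closure from a too-high scaffold threshold ",
            "or collapsed scaffold-liquid contrast")
  out
}

#' Calibrate the tissue threshold against a bare-scaffold scan
#'
#' The tissue threshold is chosen so that a bare scaffold — no cells —
#' shows only a limited amount of false-positive signal: the smallest
#' threshold for which the fraction of pore pixels (ROI minus
#' scaffold) classified as tissue is at most `fp_tolerance`. False
#' positives are counted after the binary opening by default (that is
#' what counts as signal downstream); set `count_after_opening = FALSE`
#' to count raw suprathreshold pixels. The search runs over the
#' observed pore intensity range; monotonicity of the false-positive
#' count in the threshold makes a binary search exact.
#'
#' @param bare_corrected corrected [image_stack()] of the bare scaffold.
#' @param roi a [circular_roi()].
#' @param scaffold_mask logical volume of scaffold pixels in the bare
#'   scan.
#' @param fp_tolerance maximum tolerated false-positive fraction of
#'   pore pixels, in `(0, 1]` (default 0.001).
#' @param opening_radius radius of the smoothing opening.
#' @param count_after_opening count false positives after opening?
#' @return the calibrated intensity threshold.
#' @export
calibrate_threshold <- function(bare_corrected, roi, scaffold_mask,
                                fp_tolerance = 0.001, opening_radius = 2,
                                count_after_opening = TRUE) {
  if (fp_tolerance <= 0 || fp_tolerance > 1)
    stop("fp_tolerance must lie in (0, 1]")
  d <- dim(bare_corrected$voxels)
  if (!identical(dim(scaffold_mask), d))
    stop("scaffold mask does not match the bare stack")
  rm2 <- roi_mask(roi, d[1], d[2])
  pore <- array(rm2, d) & !scaffold_mask
  pore_px <- sum(pore)
  if (pore_px == 0) stop("no pore pixels inside the ROI")
  fp_fraction <- function(thr) {
    opn <- if (count_after_opening) opening_radius else 0
    mask <- segment_tissue(bare_corrected, roi, thr, opening_radius = opn)
    sum(mask & pore) / pore_px
  }
  vals <- sort(unique(as.numeric(bare_corrected$voxels[pore])))
  vals <- vals[vals > 0]
  cand <- c(vals, max(bare_corrected$voxels) + 1)  # guard: always 0 FP
  lo <- 1L; hi <- length(cand)
  if (fp_fraction(cand[lo]) <= fp_tolerance) return(cand[lo])
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (fp_fraction(cand[mid]) <= fp_tolerance) hi <- mid else lo <- mid
  }
  cand[hi]
}

#' Bundle co-registered segmentation masks
#'
#' Container pairing the tissue and scaffold masks with the ROI and
#' the thresholds that produced them. Tissue pixels falling on
#' scaffold pixels (possible because the two classes are thresholded
#' on different processing stages) are removed from the tissue mask so
#' the two classes are disjoint inside the ROI by construction.
#'
#' @param tissue_mask,scaffold_mask logical volumes.
#' @param roi a [circular_roi()].
#' @param tissue_threshold,scaffold_threshold the thresholds used.
#' @return a `segmentation_masks` object.
#' @export
segmentation_masks <- function(tissue_mask, scaffold_mask, roi,
                               tissue_threshold = NA_real_,
                               scaffold_threshold = NA_real_) {
  d <- dim(tissue_mask)
  if (!identical(d, dim(scaffold_mask)))
    stop("tissue and scaffold masks differ in shape")
  ## the two thresholds act on different processing stages (scaffold on
  ## the raw stack, tissue on the corrected one), so disjointness is
  ## enforced directly rather than via a threshold ordering
  tissue_mask <- tissue_mask & !scaffold_mask
  rm2 <- roi_mask(roi, d[1], d[2])
  structure(list(tissue_mask = tissue_mask, scaffold_mask = scaffold_mask,
                 roi = roi, roi_mask = rm2,
                 tissue_threshold = tissue_threshold,
                 scaffold_threshold = scaffold_threshold),
            class = "segmentation_masks")
}

#' @export
print.segmentation_masks <- function(x, ...) {
  d <- dim(x$tissue_mask)
  cat(sprintf("segmentation_masks: %d x %d x %d\n", d[1], d[2], d[3]))
  cat(sprintf("  tissue threshold %.4g, scaffold threshold %.4g\n",
              x$tissue_threshold, x$scaffold_threshold))
  cat(sprintf("  tissue px %d, scaffold px %d, ROI px/slice %d\n",
              sum(x$tissue_mask), sum(x$scaffold_mask), sum(x$roi_mask)))
  invisible(x)
}
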