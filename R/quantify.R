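#' Quantify one slice: tissue as a percentage of available pore volume
#'
#' Pixel counts restricted to the ROI. The available pore volume is
#' the number of ROI pixels not identified as scaffold, and the tissue
#' percentage is `100 * tissue_px / pore_px`. A fully occluded slice
#' (no pore pixels) is an explicit error, never a silent zero.
#'
#' @param tissue_slice,scaffold_slice logical matrices for one slice.
#' @param roi_mask logical ROI matrix.
#' @param slice_id slice identification number.
#' @return one-row data.frame: `slice_id`, `tissue_px`, `scaffold_px`,
#'   `pore_px`, `roi_px`, `tissue_pct`.
#' @export
quantify_slice <- function(tissue_slice, scaffold_slice, roi_mask,
                           slice_id = 1L) {
  roi_px <- sum(roi_mask)
  scaffold_px <- sum(scaffold_slice & roi_mask)
  tissue_px <- sum(tissue_slice & roi_mask & !scaffold_slice)
  pore_px <- roi_px - scaffold_px
  if (pore_px == 0)
    stop("slice ", slice_id, " has no available pore volume ",
         "(ROI fully identified as scaffold)")
  data.frame(slice_id = as.integer(slice_id), tissue_px = tissue_px,
             scaffold_px = scaffold_px, pore_px = pore_px, roi_px = roi_px,
             tissue_pct = 100 * tissue_px / pore_px)
}

#' Per-slice quantification table for a whole stack
#'
#' @param masks a [segmentation_masks()].
#' @return data.frame with one [quantify_slice()] record per slice.
#' @export
quantify_stack <- function(masks) {
  d <- dim(masks$tissue_mask)
  do.call(rbind, lapply(seq_len(d[3]), function(k)
    quantify_slice(masks$tissue_mask[, , k], masks$scaffold_mask[, , k],
                   masks$roi_mask, slice_id = k)))
}

#' Summarise tissue percentage per scaffold section
#'
#' Mean and sample (n-1) standard deviation of the per-slice tissue
#' percentage over each section's slice range.
#'
#' @param records per-slice data.frame from [quantify_stack()].
#' @param boundaries named list of `c(first, last)` slice ranges, e.g.
#'   from [split_sections()].
#' @return data.frame: `section`, `first`, `last`, `n_slices`,
#'   `mean_pct`, `sd_pct`.
#' @export
summarize_sections <- function(records, boundaries) {
  rs <- lapply(boundaries, function(b) sort(b))
  all_sl <- unlist(lapply(rs, function(b) b[1]:b[2]))
  if (anyDuplicated(all_sl)) stop("section slice ranges overlap")
  if (any(!all_sl %in% records$slice_id))
    stop("section boundaries outside the quantified slice range")
  do.call(rbind, lapply(names(rs), function(sec) {
    b <- rs[[sec]]
    pct <- records$tissue_pct[records$slice_id %in% (b[1]:b[2])]
    if (length(pct) == 0) stop("empty section '", sec, "'")
    data.frame(section = sec, first = b[1], last = b[2],
               n_slices = b[2] - b[1] + 1,
               mean_pct = mean(pct),
               sd_pct = if (length(pct) > 1) stats::sd(pct) else 0)
  }))
}

star_label <- function(p) {
  if (is.na(p)) "ns" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' One-way ANOVA across sections with Bonferroni post-tests
#'
#' Classical one-way ANOVA over the per-slice tissue percentages of
#' each section, followed by pairwise pooled-variance two-sample
#' t-tests whose p-values are Bonferroni-adjusted (multiplied by the
#' number of comparisons, capped at 1). Significance stars follow the
#' usual thresholds: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001.
#' When all values are identical the overall p is 1 by convention.
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2
#'   values), or a [summarize_sections()]-compatible records/boundaries
#'   pair via [compare_sections()].
#' @return a `section_anova`: list with `F`, `p`, `df`, and a
#'   `pairwise` data.frame (`group1`, `group2`, `p_adj`, `stars`).
#' @export
compare_sections_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 values")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  vals <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  df1 <- length(groups) - 1L
  df2 <- length(vals) - length(groups)
  if (stats::var(vals) == 0) {
    Fst <- 0; p <- 1
  } else {
    fit <- stats::aov(vals ~ grp)
    s <- summary(fit)[[1]]
    Fst <- s[["F value"]][1]; p <- s[["Pr(>F)"]][1]
  }
  pairs <- utils::combn(names(groups), 2)
  m <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(m), function(i) {
    a <- groups[[pairs[1, i]]]; b <- groups[[pairs[2, i]]]
    praw <- if (stats::var(c(a, b)) == 0) 1 else
      stats::t.test(a, b, var.equal = TRUE)$p.value
    padj <- min(praw * m, 1)
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               p_adj = padj, stars = star_label(padj))
  }))
  structure(list(F = Fst, p = p, df = c(df1, df2), pairwise = pw,
                 groups = groups),
            class = "section_anova")
}

#' Compare sections of a quantification table
#'
#' Convenience wrapper building the per-section groups from a
#' per-slice table and section boundaries, then running
#' [compare_sections_anova()].
#'
#' @inheritParams summarize_sections
#' @return a `section_anova`.
#' @export
compare_sections <- function(records, boundaries) {
  groups <- lapply(boundaries, function(b)
    records$tissue_pct[records$slice_id %in% (b[1]:b[2])])
  compare_sections_anova(groups)
}

#' @export
print.section_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.3g %s\n",
              x$df[1], x$df[2], x$F, x$p, star_label(x$p)))
  cat("Bonferroni-adjusted pairwise comparisons:\n")
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}

#' 4-stage projection of a tissue mask stack
#'
#' Collapses a section's binary tissue slices into one 2D map: per
#' pixel, the number of slices in which it was classified tissue,
#' binned into four equal-width stages over `1..n_slices`
#' (upper edges `ceiling(k * n / 4)`, k = 1..4); stage 0 is reserved
#' for pixels never classified tissue.
#'
#' @param tissue_mask_section logical volume (the slices of one
#'   section, or a whole stack).
#' @return a `stage_projection`: list with `counts`, `stages`,
#'   `n_slices` and `bin_edges`.
#' @export
stage_projection <- function(tissue_mask_section) {
  if (is.matrix(tissue_mask_section))
    tissue_mask_section <- array(tissue_mask_section,
                                 c(dim(tissue_mask_section), 1L))
  d <- dim(tissue_mask_section)
  if (d[3] < 1) stop("need at least one slice")
  counts <- apply(tissue_mask_section, c(1, 2), sum)
  edges <- ceiling((1:4) * d[3] / 4)
  stages <- (counts > 0) * (1 + (counts > edges[1]) + (counts > edges[2]) +
                              (counts > edges[3]))
  stages[counts == d[3]] <- 4L   # top stage always reached at full count
  storage.mode(stages) <- "integer"
  structure(list(counts = counts, stages = stages,
                 n_slices = d[3], bin_edges = edges),
            class = "stage_projection")
}

#' @export
print.stage_projection <- function(x, ...) {
  cat(sprintf("stage_projection over %d slices; bin edges %s\n",
              x$n_slices, paste(x$bin_edges, collapse = ", ")))
  tb <- table(factor(x$stages, levels = 0:4))
  cat("  pixels per stage 0..4:", paste(tb, collapse = ", "), "\n")
  invisible(x)
}

stage_palette <- function() {
  ## stage 0 black, then blue -> cyan -> yellow -> red
  matrix(c(0, 0, 0,
           0.10, 0.20, 0.80,
           0.00, 0.75, 0.85,
           0.95, 0.85, 0.10,
           0.90, 0.10, 0.10), ncol = 3, byrow = TRUE)
}

#' Write a stage projection as an indexed-colour PNG
#'
#' Five-entry palette: stage 0 black, stages 1-4 blue, cyan, yellow,
#' red.
#'
#' @param proj a [stage_projection()].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_projection_png <- function(proj, path) {
  pal <- stage_palette()
  d <- dim(proj$stages)
  img <- array(0, c(d, 3))
  for (ch in 1:3)
    img[, , ch] <- matrix(pal[proj$stages + 1L, ch], d[1], d[2])
  png::writePNG(img, path)
  invisible(path)
}

#' Plot a stage projection
#' @param x a [stage_projection()].
#' @param ... ignored.
#' @export
plot.stage_projection <- function(x, ...) {
  pal <- grDevices::rgb(stage_palette())
  graphics::image(t(x$stages)[, nrow(x$stages):1],
                  col = pal, zlim = c(0, 4), axes = FALSE, asp = 1,
                  main = sprintf("tissue stages over %d slices", x$n_slices))
  invisible(x)
}

#' Write the per-slice quantification table as CSV
#'
#' Mirrors the per-slice output table of the method: slice id, tissue
#' pixels, scaffold pixels, pore pixels, ROI pixels, tissue
#' percentage, with the per-section mean and SD appended as trailing
#' columns on each section's first slice row.
#'
#' @param records per-slice table from [quantify_stack()].
#' @param summaries optional [summarize_sections()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_quant_csv <- function(records, path, summaries = NULL) {
  out <- records
  if (!is.null(summaries)) {
    out$section <- NA_character_
    out$mean_pct <- NA_real_
    out$sd_pct <- NA_real_
    for (i in seq_len(nrow(summaries))) {
      j <- match(summaries$first[i], out$slice_id)
      out$section[out$slice_id %in%
                    (summaries$first[i]:summaries$last[i])] <-
        summaries$section[i]
      out$mean_pct[j] <- summaries$mean_pct[i]
      out$sd_pct[j] <- summaries$sd_pct[i]
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
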