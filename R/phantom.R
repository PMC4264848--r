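#' Scaffold geometry of a 0/90 degree woodpile lattice
#'
#' Describes the fused-deposition scaffold the phantom emulates: a
#' cylindrical plotted lattice whose fibers alternate direction layer
#' by layer. Defaults follow the fabrication settings of the imaged
#' constructs: 8 mm diameter x 3 mm height, 1000 um fiber-to-fiber
#' distance, ~200 um fiber diameter, 150 um layer thickness (layers
#' thinner than the fiber diameter fuse vertically).
#'
#' @param cylinder_diameter,cylinder_height cylinder size in mm.
#' @param fiber_spacing centre-to-centre fiber distance in mm.
#' @param fiber_diameter fiber diameter in mm (0 allowed: empty lattice).
#' @param layer_thickness deposited layer height in mm.
#' @param lay_down_pattern in-plane fiber angles per layer, cycled;
#'   only 0 and 90 degrees are supported.
#' @return a `scaffold_geometry` object.
#' @export
scaffold_geometry <- function(cylinder_diameter = 8, cylinder_height = 3,
                              fiber_spacing = 1.0, fiber_diameter = 0.2,
                              layer_thickness = 0.15,
                              lay_down_pattern = c(0, 90)) {
  if (cylinder_diameter <= 0 || cylinder_height <= 0 || fiber_spacing <= 0 ||
      layer_thickness <= 0)
    stop("all scaffold lengths must be > 0")
  if (fiber_diameter < 0) stop("fiber_diameter must be >= 0")
  if (fiber_diameter >= fiber_spacing)
    stop("fiber_diameter must be smaller than fiber_spacing")
  if (!all(lay_down_pattern %in% c(0, 90)))
    stop("lay_down_pattern angles must be 0 or 90 degrees")
  structure(list(cylinder_diameter = cylinder_diameter,
                 cylinder_height = cylinder_height,
                 fiber_spacing = fiber_spacing,
                 fiber_diameter = fiber_diameter,
                 layer_thickness = layer_thickness,
                 lay_down_pattern = lay_down_pattern),
            class = "scaffold_geometry")
}

#' Ground-truth tissue model for the phantom
#'
#' @param target_occupancy_by_section named fractions (`top`, `middle`,
#'   `bottom`) of the available pore volume to fill with tissue, each in
#'   `[0, 1]`. The generator lands within +/-10 percent relative of each
#'   non-zero target.
#' @param morphology `"string"` (random-walk tubes through the pores,
#'   the pattern seen in cultured constructs), `"sheet"` (a connected
#'   layer hugging the bottom face of the section) or `"blob"` (spheres).
#' @param component_scale characteristic cross-section diameter of one
#'   tissue structure, in mm.
#' @return a `tissue_model` object.
#' @export
tissue_model <- function(target_occupancy_by_section =
                           c(top = 0, middle = 0, bottom = 0.02),
                         morphology = c("string", "sheet", "blob"),
                         component_scale = 0.7) {
  morphology <- match.arg(morphology)
  occ <- target_occupancy_by_section
  if (is.null(names(occ)) || !all(names(occ) %in% c("top", "middle", "bottom")))
    stop("target_occupancy_by_section must be named with top/middle/bottom")
  if (any(occ < 0 | occ > 1)) stop("occupancies must lie in [0, 1]")
  if (component_scale <= 0) stop("component_scale must be > 0 (mm)")
  structure(list(target_occupancy_by_section = occ, morphology = morphology,
                 component_scale = component_scale),
            class = "tissue_model")
}

#' Acquisition model for the rendered stack
#'
#' Phenomenological imaging model: three intensity classes (scaffold
#' dark, liquid grey, tissue bright in native contrast), a smooth
#' multiplicative bias field emulating coil inhomogeneity, and additive
#' noise. `contrast_mode = "agent"` emulates the image-level effect of
#' an untargeted iron-oxide contrast agent: tissue-liquid contrast is
#' increased while scaffold-liquid contrast collapses.
#'
#' @param matrix_size pixels per slice side (128 or 256 typical).
#' @param field_of_view in mm (default 10, i.e. 1 cm).
#' @param slice_thickness in mm (scanner range 0.07-0.1).
#' @param n_slices number of slices; the first and last are rendered
#'   liquid-only reference slices.
#' @param intensity_levels named vector `c(scaffold=, liquid=, tissue=)`
#'   in arbitrary units; `NULL` picks mode-appropriate defaults
#'   (native 20/100/160, agent 85/100/220).
#' @param bias_amplitude peak fractional deviation of the multiplicative
#'   bias field (the field spans exactly `[-a, +a]`).
#' @param bias_length_scale correlation length in mm of the optional
#'   Gaussian random-field component.
#' @param bias_components subset of `c("polynomial", "grf")`.
#' @param noise_sigma additive noise SD in intensity units.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param contrast_mode `"native"` or `"agent"`.
#' @param tube_diameter inner diameter of the sample tube in mm; pixels
#'   outside are dark background.
#' @param background_level intensity outside the tube.
#' @param seed integer seed controlling bias coefficients and noise.
#' @return an `acquisition_model` object.
#' @export
acquisition_model <- function(matrix_size = 128, field_of_view = 10,
                              slice_thickness = 0.07, n_slices = 45,
                              intensity_levels = NULL,
                              bias_amplitude = 0.2, bias_length_scale = 4,
                              bias_components = "polynomial",
                              noise_sigma = 5,
                              noise_model = c("gaussian", "rician"),
                              contrast_mode = c("native", "agent"),
                              tube_diameter = 9.2, background_level = 5,
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  contrast_mode <- match.arg(contrast_mode)
  if (is.null(intensity_levels))
    intensity_levels <- if (contrast_mode == "native")
      c(scaffold = 20, liquid = 100, tissue = 160)
    else
      c(scaffold = 85, liquid = 100, tissue = 220)
  if (!all(c("scaffold", "liquid", "tissue") %in% names(intensity_levels)))
    stop("intensity_levels needs scaffold, liquid and tissue entries")
  if (contrast_mode == "native" &&
      !(intensity_levels["scaffold"] < intensity_levels["liquid"] &&
        intensity_levels["liquid"] < intensity_levels["tissue"]))
    stop("native contrast requires scaffold < liquid < tissue levels")
  if (bias_amplitude < 0 || bias_amplitude >= 1)
    stop("bias_amplitude must lie in [0, 1)")
  if (!all(bias_components %in% c("polynomial", "grf")))
    stop("bias_components must be a subset of c(\"polynomial\", \"grf\")")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (n_slices < 3) stop("need at least 3 slices (two reference slices)")
  if (tube_diameter > field_of_view)
    stop("sample tube does not fit in the field of view")
  seed <- as.integer(seed)
  structure(list(matrix_size = as.integer(matrix_size),
                 field_of_view = field_of_view,
                 slice_thickness = slice_thickness,
                 n_slices = as.integer(n_slices),
                 intensity_levels = intensity_levels,
                 bias_amplitude = bias_amplitude,
                 bias_length_scale = bias_length_scale,
                 bias_components = bias_components,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 contrast_mode = contrast_mode,
                 tube_diameter = tube_diameter,
                 background_level = background_level, seed = seed),
            class = "acquisition_model")
}

## evaluate RNG-dependent code without disturbing the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

phantom_meta <- function(mask) {
  m <- attr(mask, "phantom_meta")
  if (is.null(m)) stop("mask carries no phantom metadata")
  m
}

#' Generate the binary scaffold volume
#'
#' Rasterises the woodpile lattice onto the acquisition grid: layer `j`
#' holds parallel cylindrical fibers (diameter `fiber_diameter`) along
#' x or y according to the lay-down pattern, with vertical period
#' `layer_thickness`; voxels outside the cylinder are background. The
#' cylinder is centred in the field of view and in z, leaving at least
#' the first and last slice scaffold-free as background-reference
#' slices.
#'
#' @param geometry a [scaffold_geometry()].
#' @param acquisition an [acquisition_model()].
#' @return logical array (rows x cols x slices) with a `phantom_meta`
#'   attribute recording grid geometry, informative slice range and
#'   section boundaries.
#' @export
generate_scaffold_mask <- function(geometry, acquisition) {
  g <- geometry; a <- acquisition
  ps <- a$field_of_view / a$matrix_size
  st <- a$slice_thickness
  if (g$cylinder_diameter > a$tube_diameter)
    stop("scaffold cylinder (", g$cylinder_diameter,
         " mm) larger than the sample tube / field of view")
  total_z <- a$n_slices * st
  z0 <- (total_z - g$cylinder_height) / 2
  if (z0 < st)
    stop("cylinder height ", g$cylinder_height,
         " mm does not fit in ", a$n_slices, " slices of ", st,
         " mm with liquid-only reference slices at both ends")
  n <- a$matrix_size
  ctr <- a$field_of_view / 2
  xy <- (seq_len(n) - 0.5) * ps          # physical coordinate of row/col centres
  disk <- outer((xy - ctr)^2, (xy - ctr)^2, "+") <=
    (g$cylinder_diameter / 2)^2
  rfib <- g$fiber_diameter / 2
  n_layers <- ceiling(g$cylinder_height / g$layer_thickness)
  axis_z <- z0 + (seq_len(n_layers) - 1) * g$layer_thickness + rfib
  ang <- g$lay_down_pattern[((seq_len(n_layers) - 1) %%
                               length(g$lay_down_pattern)) + 1]
  s <- g$fiber_spacing
  du <- abs((xy - ctr + s / 2) %% s - s / 2)   # distance to nearest fiber axis
  vol <- array(FALSE, c(n, n, a$n_slices))
  if (rfib > 0) {
    for (k in seq_len(a$n_slices)) {
      z <- (k - 0.5) * st
      if (z < z0 || z > z0 + g$cylinder_height) next
      row_hit <- rep(FALSE, n); col_hit <- rep(FALSE, n)
      for (j in which(abs(z - axis_z) < rfib)) {
        w <- sqrt(rfib^2 - (z - axis_z[j])^2)
        if (ang[j] == 0) row_hit <- row_hit | (du <= w)   # fibers along x
        else             col_hit <- col_hit | (du <= w)   # fibers along y
      }
      if (any(row_hit) || any(col_hit))
        vol[, , k] <- (matrix(row_hit, n, n) |
                         matrix(col_hit, n, n, byrow = TRUE)) & disk
    }
  }
  inform <- which(vapply(seq_len(a$n_slices), function(k) {
    z <- (k - 0.5) * st
    z >= z0 && z <= z0 + g$cylinder_height
  }, logical(1)))
  attr(vol, "phantom_meta") <- list(
    pixel_size = ps, slice_thickness = st, z0 = z0,
    fov = a$field_of_view, centre_mm = ctr,
    cylinder_radius = g$cylinder_diameter / 2,
    tube_radius = a$tube_diameter / 2,
    informative = range(inform),
    sections = split_sections(min(inform), max(inform)))
  vol
}

#' Default top/middle/bottom section boundaries
#'
#' Splits the informative slice range into three near-equal contiguous
#' thirds; slice numbering runs from the scaffold top, so the first
#' third is the `top` section.
#'
#' @param first,last first and last informative slice index.
#' @return named list of `c(first, last)` slice ranges.
#' @export
split_sections <- function(first, last) {
  n <- last - first + 1
  if (n < 3) stop("need at least 3 informative slices for 3 sections")
  cuts <- first - 1 + round(seq(0, n, length.out = 4))
  list(top    = c(cuts[1] + 1, cuts[2]),
       middle = c(cuts[2] + 1, cuts[3]),
       bottom = c(cuts[3] + 1, cuts[4]))
}

## ball of voxel offsets within physical radius r_mm
ball_offsets <- function(r_mm, ps, st) {
  mr <- floor(r_mm / ps); mz <- floor(r_mm / st)
  g <- expand.grid(di = -mr:mr, dj = -mr:mr, dk = -mz:mz)
  g <- g[(g$di * ps)^2 + (g$dj * ps)^2 + (g$dk * st)^2 <= r_mm^2, ]
  as.matrix(g)
}

## 3D dilation of a mask by a physical ball, slicewise (anisotropic z)
dilate_ball <- function(mask, r_mm, ps, st) {
  d <- dim(mask); mz <- floor(r_mm / st)
  out <- array(FALSE, d)
  for (dz in -mz:mz) {
    rz <- sqrt(max(r_mm^2 - (dz * st)^2, 0)) / ps
    rpx <- floor(rz)
    dil2 <- array(FALSE, d)
    for (k in seq_len(d[3])) {
      m <- mask[, , k]
      dil2[, , k] <- if (!any(m)) m
      else if (rpx >= 1) gray_dilate(m * 1, disk_kernel(rpx)) > 0.5
      else m
    }
    src <- seq_len(d[3]) - dz
    ok <- src >= 1 & src <= d[3]
    out[, , ok] <- out[, , ok] | dil2[, , src[ok]]
  }
  out
}

#' Generate the ground-truth tissue volume
#'
#' Places tissue structures of the requested morphology into the pore
#' space until each section reaches its target share of the available
#' pore volume (region-of-interest pixels not occupied by scaffold).
#' Structures keep full clearance from the scaffold so they are never
#' clipped into slivers, stay inside their section's slice range, and
#' the result is strictly disjoint from the scaffold. Deterministic for
#' a given seed.
#'
#' @param scaffold_mask output of [generate_scaffold_mask()].
#' @param tissue a [tissue_model()].
#' @param seed integer seed.
#' @return logical array with the same `phantom_meta` attribute.
#' @export
generate_tissue_mask <- function(scaffold_mask, tissue, seed = 1L) {
  meta <- phantom_meta(scaffold_mask)
  with_seed(seed, {
    d <- dim(scaffold_mask)
    ps <- meta$pixel_size; st <- meta$slice_thickness
    n <- d[1]
    xy <- (seq_len(n) - 0.5) * ps
    r2 <- outer((xy - meta$centre_mm)^2, (xy - meta$centre_mm)^2, "+")
    tube_disk <- r2 <= meta$tube_radius^2
    r_ball <- tissue$component_scale / 2
    ## centres from which a full ball stays inside the scaffold cylinder
    core_disk <- r2 <= (meta$cylinder_radius - r_ball)^2
    offs <- ball_offsets(r_ball, ps, st)
    mz <- max(abs(offs[, 3]))
    blocked <- dilate_ball(scaffold_mask, r_ball, ps, st)
    out <- array(FALSE, d)
    for (sec in names(tissue$target_occupancy_by_section)) {
      occ <- tissue$target_occupancy_by_section[[sec]]
      if (occ == 0) next
      rng <- meta$sections[[sec]]
      sl <- rng[1]:rng[2]
      pore_px <- sum(tube_disk) * length(sl) -
        sum(scaffold_mask[, , sl, drop = FALSE] &
              array(tube_disk, c(n, n, length(sl))))
      target <- round(occ * pore_px)
      ksl <- sl[sl >= rng[1] + mz & sl <= rng[2] - mz]
      if (length(ksl) == 0)
        stop("component_scale too large for section '", sec,
             "' slice range; achievable maximum occupancy is 0")
      allowed <- array(FALSE, d)
      allowed[, , ksl] <- array(core_disk, c(n, n, length(ksl))) &
        !blocked[, , ksl, drop = FALSE]
      out <- switch(tissue$morphology,
        string = grow_strings(out, allowed, offs, target, d, sec, occ),
        blob   = grow_blobs(out, allowed, offs, r_ball, ps, st, target, d,
                            sec, occ),
        sheet  = grow_sheet(out, scaffold_mask, tube_disk, core_disk, rng,
                            tissue$component_scale, st, target, sec, occ))
    }
    attr(out, "phantom_meta") <- meta
    out
  })
}

stamp_ball <- function(vol, centre, offs, d) {
  i <- centre[1] + offs[, 1]; j <- centre[2] + offs[, 2]
  k <- centre[3] + offs[, 3]
  ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
  cbind(i, j, k)[ok, , drop = FALSE]
}

grow_strings <- function(out, allowed, offs, target, d, sec, occ) {
  achieved <- 0; starts <- 0
  cand <- which(allowed)
  while (achieved < target) {
    starts <- starts + 1
    if (starts > 400 || length(cand) == 0)
      stop("target occupancy ", occ, " unreachable in section '", sec,
           "'; achievable maximum reached at ",
           signif(achieved / max(target / occ, 1), 3))
    p <- arrayInd(sample(cand, 1), d)
    pos <- as.numeric(p)
    theta <- stats::runif(1, 0, 2 * pi)
    steps <- 0; stuck <- 0
    while (achieved < target && steps < 400 && stuck < 25) {
      ctr <- round(pos)
      idx <- stamp_ball(out, ctr, offs, d)
      new <- idx[!out[idx], , drop = FALSE]
      if (nrow(new) > target - achieved) {
        ## trim the final stamp to land on the target: keep the compact
        ## centre-nearest subset so the structure still survives opening
        d2 <- (new[, 1] - ctr[1])^2 + (new[, 2] - ctr[2])^2 +
          (new[, 3] - ctr[3])^2 * 4
        new <- new[order(d2)[seq_len(target - achieved)], , drop = FALSE]
      }
      out[new] <- TRUE
      achieved <- achieved + nrow(new)
      theta <- theta + stats::rnorm(1, 0, 0.45)
      stp <- c(cos(theta), sin(theta), stats::rnorm(1, 0, 0.35))
      nxt <- pos + stp
      q <- round(nxt)
      if (all(q >= 1) && all(q <= d) && allowed[q[1], q[2], q[3]]) {
        pos <- nxt; steps <- steps + 1; stuck <- 0
      } else {
        theta <- stats::runif(1, 0, 2 * pi); stuck <- stuck + 1
      }
    }
  }
  out
}

grow_blobs <- function(out, allowed, offs, r_ball, ps, st, target, d,
                       sec, occ) {
  achieved <- 0; tries <- 0
  full <- nrow(offs)
  while (achieved < target) {
    tries <- tries + 1
    cand <- which(allowed)
    if (tries > 2000 || length(cand) == 0)
      stop("target occupancy ", occ, " unreachable in section '", sec,
           "'; achievable maximum reached at ",
           signif(achieved / max(target / occ, 1), 3))
    remaining <- target - achieved
    ## shrink the last sphere so the target is not badly overshot,
    ## but never below an opening-surviving radius
    r_use <- r_ball
    if (remaining < full) {
      r_use <- max(r_ball * (remaining / full)^(1 / 3), 2.6 * ps)
    }
    o <- if (r_use < r_ball) ball_offsets(r_use, ps, st) else offs
    p <- as.numeric(arrayInd(sample(cand, 1), d))
    idx <- stamp_ball(out, p, o, d)
    new <- idx[!out[idx], , drop = FALSE]
    if (nrow(new) > remaining) {
      d2 <- (new[, 1] - p[1])^2 + (new[, 2] - p[2])^2 +
        (new[, 3] - p[3])^2 * 4
      new <- new[order(d2)[seq_len(remaining)], , drop = FALSE]
    }
    out[new] <- TRUE
    achieved <- achieved + nrow(new)
  }
  out
}

grow_sheet <- function(out, scaffold_mask, tube_disk, core_disk, rng,
                       thickness, st, target, sec, occ) {
  d <- dim(scaffold_mask)
  band <- max(rng[1], rng[2] - ceiling(thickness / st) + 1):rng[2]
  ## one pixel of in-plane clearance keeps the sheet off the scaffold
  cand <- array(FALSE, d)
  for (k in band) {
    clear <- gray_dilate(scaffold_mask[, , k] * 1, disk_kernel(1)) < 0.5
    cand[, , k] <- clear & core_disk
  }
  idx <- which(cand, arr.ind = TRUE)
  if (nrow(idx) < target)
    stop("target occupancy ", occ, " unreachable in section '", sec,
         "'; achievable maximum is ",
         signif(nrow(idx) * occ / max(target, 1), 3))
  ## grow laterally from a seed point on the section's bottom face,
  ## filling the deepest slices first (the sheet hugs the bottom)
  bot <- which(idx[, 3] == max(idx[, 3]))
  seedpt <- idx[bot[sample(length(bot), 1)], ]
  dist2 <- (idx[, 1] - seedpt[1])^2 + (idx[, 2] - seedpt[2])^2 +
    16 * (idx[, 3] - seedpt[3])^2
  take <- idx[order(dist2)[seq_len(target)], , drop = FALSE]
  out[take] <- TRUE
  out
}

#' Multiplicative bias field of the acquisition
#'
#' A smooth field `B(x, y)` spanning exactly `[-a, +a]`
#' (`a = bias_amplitude`): a seeded random second-order polynomial in
#' the slice plane, optionally summed with a Gaussian random field of
#' the configured correlation length before rescaling. The polynomial
#' component is constant along z, matching the use of a single 2D
#' background estimate for the whole stack.
#'
#' @param acquisition an [acquisition_model()].
#' @return matrix (`matrix_size` square) of fractional deviations.
#' @export
make_bias_field <- function(acquisition) {
  a <- acquisition
  n <- a$matrix_size
  if (a$bias_amplitude == 0) return(matrix(0, n, n))
  with_seed(a$seed, {
    u <- seq(-1, 1, length.out = n)
    X <- matrix(u, n, n, byrow = TRUE); Y <- matrix(u, n, n)
    P <- matrix(0, n, n)
    if ("polynomial" %in% a$bias_components) {
      cf <- stats::runif(5, -1, 1)
      P <- cf[1] * X + cf[2] * Y + cf[3] * X * Y + cf[4] * X^2 + cf[5] * Y^2
    }
    if ("grf" %in% a$bias_components) {
      sig_px <- a$bias_length_scale / (a$field_of_view / n)
      W <- matrix(stats::rnorm(n * n), n, n)
      G <- EBImage::gblur(W, sigma = sig_px)
      G <- G / max(abs(G))
      P <- if (all(P == 0)) G else P / max(abs(P)) + G
    }
    ## the amplitude describes the field across the sample: normalise
    ## over the tube region, not the (dark, irrelevant) FOV corners
    ps <- a$field_of_view / n
    xy <- (seq_len(n) - 0.5) * ps
    tube <- outer((xy - a$field_of_view / 2)^2,
                  (xy - a$field_of_view / 2)^2, "+") <=
      (a$tube_diameter / 2)^2
    rngP <- range(P[tube])
    if (diff(rngP) == 0) return(matrix(0, n, n))
    B <- a$bias_amplitude * (2 * (P - rngP[1]) / diff(rngP) - 1)
    pmin(pmax(B, -a$bias_amplitude), a$bias_amplitude)
  })
}

#' Render a phantom image stack from ground-truth masks
#'
#' Assigns each voxel its class level (background outside the tube,
#' liquid, scaffold, tissue), scales by `(1 + bias)` and adds noise,
#' clipping to the 16-bit range. The first and last slices must be
#' scaffold- and tissue-free so a background-reference slice always
#' exists.
#'
#' @param scaffold_mask,tissue_mask logical volumes from the generators
#'   (disjoint, same dimensions).
#' @param acquisition an [acquisition_model()].
#' @return an [image_stack()].
#' @export
render_stack <- function(scaffold_mask, tissue_mask, acquisition) {
  a <- acquisition
  meta <- phantom_meta(scaffold_mask)
  d <- dim(scaffold_mask)
  if (!identical(d, dim(tissue_mask)))
    stop("scaffold and tissue masks differ in shape")
  if (any(scaffold_mask & tissue_mask))
    stop("scaffold and tissue masks overlap")
  if (any(scaffold_mask[, , c(1, d[3])]) || any(tissue_mask[, , c(1, d[3])]))
    stop("first and last slice must be liquid-only reference slices")
  lv <- a$intensity_levels
  n <- a$matrix_size
  xy <- (seq_len(n) - 0.5) * (a$field_of_view / n)
  tube <- outer((xy - meta$centre_mm)^2, (xy - meta$centre_mm)^2, "+") <=
    meta$tube_radius^2
  B <- make_bias_field(a)
  ## noise uses a stream derived from the seed, separate from the bias draw
  vox <- with_seed((a$seed + 77003) %% 2147483647, {
    v <- array(0, d)
    gain <- 1 + B
    for (k in seq_len(d[3])) {
      lev <- matrix(a$background_level, n, n)
      lev[tube] <- lv[["liquid"]]
      lev[scaffold_mask[, , k]] <- lv[["scaffold"]]
      lev[tissue_mask[, , k]] <- lv[["tissue"]]
      v[, , k] <- lev * gain
    }
    if (a$noise_sigma > 0) {
      if (a$noise_model == "gaussian") {
        v <- v + stats::rnorm(length(v), 0, a$noise_sigma)
      } else {
        v <- sqrt((v + stats::rnorm(length(v), 0, a$noise_sigma))^2 +
                    stats::rnorm(length(v), 0, a$noise_sigma)^2)
      }
    }
    pmin(pmax(v, 0), 65535)
  })
  out <- image_stack(vox, pixel_size = a$field_of_view / n,
                     slice_thickness = a$slice_thickness, bit_depth = 16)
  out
}

#' Build a complete synthetic phantom
#'
#' Convenience wrapper generating scaffold and tissue masks, rendering
#' the stack, and book-keeping the ground truth (per-section pore and
#' tissue voxel counts against the true tube region of interest).
#'
#' @param geometry a [scaffold_geometry()].
#' @param tissue a [tissue_model()].
#' @param acquisition an [acquisition_model()].
#' @param seed master seed; tissue placement and rendering use streams
#'   derived from it (rendering follows `acquisition$seed`, which is
#'   set to `seed + 1`).
#' @return an `mri_phantom`: list with `stack`, `scaffold_mask`,
#'   `tissue_mask`, `bias`, `roi` (true tube circle), `sections`,
#'   `truth` (per-section ground-truth data.frame), and the three
#'   parameter objects.
#' @export
build_phantom <- function(geometry = scaffold_geometry(),
                          tissue = tissue_model(),
                          acquisition = acquisition_model(),
                          seed = acquisition$seed) {
  seed <- as.integer(seed %% 2146483646L)
  acquisition$seed <- seed + 1L
  scaf <- generate_scaffold_mask(geometry, acquisition)
  tis <- generate_tissue_mask(scaf, tissue, seed = seed)
  stack <- render_stack(scaf, tis, acquisition)
  meta <- phantom_meta(scaf)
  ps <- meta$pixel_size
  roi <- circular_roi(meta$centre_mm / ps + 0.5, meta$centre_mm / ps + 0.5,
                      meta$tube_radius / ps)
  rm2 <- roi_mask(roi, dim(scaf)[1], dim(scaf)[2])
  truth <- do.call(rbind, lapply(names(meta$sections), function(sec) {
    rng <- meta$sections[[sec]]; sl <- rng[1]:rng[2]
    roi_px <- sum(rm2) * length(sl)
    sc <- sum(scaf[, , sl, drop = FALSE] &
                array(rm2, c(dim(rm2), length(sl))))
    ti <- sum(tis[, , sl, drop = FALSE] &
                array(rm2, c(dim(rm2), length(sl))))
    data.frame(section = sec, first = rng[1], last = rng[2],
               n_slices = length(sl), roi_px = roi_px, scaffold_px = sc,
               pore_px = roi_px - sc, tissue_px = ti,
               occupancy_pct = 100 * ti / (roi_px - sc))
  }))
  structure(list(stack = stack, scaffold_mask = scaf, tissue_mask = tis,
                 bias = make_bias_field(acquisition), roi = roi,
                 sections = meta$sections, truth = truth,
                 geometry = geometry, tissue = tissue,
                 acquisition = acquisition, seed = seed),
            class = "mri_phantom")
}

#' @export
print.mri_phantom <- function(x, ...) {
  d <- dim(x$stack$voxels)
  cat(sprintf("mri_phantom: %d x %d x %d, seed %d, %s contrast\n",
              d[1], d[2], d[3], x$seed, x$acquisition$contrast_mode))
  cat(sprintf("  bias amplitude %.2f, noise sigma %.3g (%s)\n",
              x$acquisition$bias_amplitude, x$acquisition$noise_sigma,
              x$acquisition$noise_model))
  cat("  ground truth occupancy (% of pore volume):\n")
  print(x$truth[, c("section", "n_slices", "pore_px", "tissue_px",
                    "occupancy_pct")], row.names = FALSE)
  invisible(x)
}

#' Write a phantom with its ground-truth sidecar
#'
#' Writes `<base>.tif` (stack), `<base>_scaffold.tif` and
#' `<base>_tissue.tif` (0/255 masks) and `<base>.json` (all parameters,
#' seed, section boundaries, true ROI and ground-truth table).
#'
#' @param phantom an `mri_phantom`.
#' @param dir output directory (created if needed).
#' @param base file base name.
#' @return named vector of written paths, invisibly.
#' @export
write_phantom <- function(phantom, dir, base = "phantom") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, paste0(base, c(".tif", "_scaffold.tif", "_tissue.tif",
                                     ".json")))
  write_stack(phantom$stack, p[1])
  write_mask(phantom$scaffold_mask, p[2])
  write_mask(phantom$tissue_mask, p[3])
  side <- list(seed = phantom$seed,
               geometry = unclass(phantom$geometry),
               tissue = unclass(phantom$tissue),
               acquisition = unclass(phantom$acquisition),
               roi = unclass(phantom$roi),
               sections = phantom$sections,
               truth = phantom$truth)
  jsonlite::write_json(side, p[4], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  names(p) <- c("stack", "scaffold_mask", "tissue_mask", "params")
  invisible(p)
}
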