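test_that("scaffold lattice has the plotted fiber period", {
  m <- generate_scaffold_mask(scaffold_geometry(), acquisition_model())
  areas <- apply(m, 3, sum)
  sl <- m[, , which.max(areas)] * 1
  rp <- rowMeans(sl); cp <- colMeans(sl)
  prof <- if (stats::var(rp) > stats::var(cp)) rp else cp
  prof <- prof - mean(prof)
  ac <- vapply(1:20, function(l)
    sum(prof[1:(128 - l)] * prof[(1 + l):128]), numeric(1))
  ## 1 mm spacing at 10 mm / 128 px = 12.8 px period
  expect_equal(which.max(ac), 13L)
})

test_that("scaffold volume fraction matches the closed-form strip model", {
  g <- scaffold_geometry(); a <- acquisition_model()
  m <- generate_scaffold_mask(g, a)
  meta <- attr(m, "phantom_meta")
  r <- g$fiber_diameter / 2; s <- g$fiber_spacing
  nl <- ceiling(g$cylinder_height / g$layer_thickness)
  az <- meta$z0 + (seq_len(nl) - 1) * g$layer_thickness + r
  ang <- rep(g$lay_down_pattern, length.out = nl)
  inf <- meta$informative[1]:meta$informative[2]
  fr <- vapply(inf, function(k) {
    z <- (k - 0.5) * meta$slice_thickness
    wx <- max(sqrt(pmax(r^2 - (z - az[ang == 0])^2, 0)))
    wy <- max(sqrt(pmax(r^2 - (z - az[ang == 90])^2, 0)))
    cx <- min(2 * wx, s) / s; cy <- min(2 * wy, s) / s
    cx + cy - cx * cy
  }, numeric(1))
  xy <- (seq_len(128) - 0.5) * meta$pixel_size
  disk <- outer((xy - 5)^2, (xy - 5)^2, "+") <= meta$cylinder_radius^2
  observed <- sum(m) / (sum(disk) * length(inf))
  expect_equal(observed, mean(fr), tolerance = 0.1)
})

test_that("degenerate geometry gives an empty scaffold", {
  g <- scaffold_geometry(fiber_diameter = 0)
  m <- generate_scaffold_mask(g, acquisition_model())
  expect_false(any(m))
})

test_that("oversized cylinders are rejected with a clear message", {
  expect_error(
    generate_scaffold_mask(scaffold_geometry(cylinder_diameter = 12),
                           acquisition_model()),
    "larger than")
  expect_error(
    generate_scaffold_mask(scaffold_geometry(cylinder_height = 5),
                           acquisition_model()),
    "does not fit")
})

test_that("geometry invariants are validated", {
  expect_error(scaffold_geometry(fiber_diameter = 1.2), "smaller than")
  expect_error(scaffold_geometry(cylinder_diameter = -1), "> 0")
  expect_error(tissue_model(c(bottom = 1.5)), "\\[0, 1\\]")
  expect_error(acquisition_model(bias_amplitude = 1.2), "bias_amplitude")
})

test_that("tissue generation hits per-section occupancy targets", {
  for (morph in c("string", "blob")) {
    ph <- build_phantom(
      tissue = tissue_model(c(top = 0.01, middle = 0.02, bottom = 0.04),
                            morphology = morph),
      acquisition = small_acquisition(seed = 3), seed = 3)
    ach <- ph$truth$occupancy_pct / 100
    tgt <- c(bottom = 0.04, middle = 0.02, top = 0.01)[ph$truth$section]
    expect_true(all(abs(ach - tgt) / tgt <= 0.1),
                label = paste("occupancy within 10% rel for", morph))
    expect_false(any(ph$scaffold_mask & ph$tissue_mask))
  }
})

test_that("sheet morphology fills the bottom of its section", {
  ph <- small_phantom(seed = 5, occ = c(bottom = 0.03))
  sheet <- generate_tissue_mask(ph$scaffold_mask,
                                tissue_model(c(bottom = 0.03), "sheet"),
                                seed = 9)
  rng <- attr(ph$scaffold_mask, "phantom_meta")$sections$bottom
  sl <- apply(sheet, 3, sum)
  expect_true(all(which(sl > 0) >= rng[1] & which(sl > 0) <= rng[2]))
  ## mass concentrated in the lower half of the section
  expect_gt(sum(sl[((rng[1] + rng[2]) %/% 2):rng[2]]),
            sum(sl[rng[1]:((rng[1] + rng[2]) %/% 2 - 1)]))
  expect_false(any(sheet & ph$scaffold_mask))
})

test_that("zero targets give an empty tissue mask", {
  ph <- small_phantom(seed = 1, occ = c(top = 0, middle = 0, bottom = 0))
  expect_false(any(ph$tissue_mask))
})

test_that("unreachable occupancy errors and reports the achievable maximum", {
  ph <- small_phantom(seed = 1)
  expect_error(
    generate_tissue_mask(ph$scaffold_mask, tissue_model(c(bottom = 0.9)),
                         seed = 1),
    "achievable maximum")
})

test_that("tissue generation is deterministic in the seed", {
  ph <- small_phantom(seed = 2)
  t1 <- generate_tissue_mask(ph$scaffold_mask,
                             tissue_model(c(bottom = 0.02)), seed = 40)
  t2 <- generate_tissue_mask(ph$scaffold_mask,
                             tissue_model(c(bottom = 0.02)), seed = 40)
  t3 <- generate_tissue_mask(ph$scaffold_mask,
                             tissue_model(c(bottom = 0.02)), seed = 41)
  expect_identical(t1, t2)
  expect_false(identical(t1, t3))
})

test_that("noise- and bias-free rendering reproduces class levels exactly", {
  ph <- small_phantom(seed = 1, bias_amplitude = 0, noise_sigma = 0)
  liq <- liquid_voxels(ph)
  lv <- ph$acquisition$intensity_levels
  expect_true(all(ph$stack$voxels[liq] == lv[["liquid"]]))
  expect_true(all(ph$stack$voxels[ph$scaffold_mask] == lv[["scaffold"]]))
  expect_true(all(ph$stack$voxels[ph$tissue_mask] == lv[["tissue"]]))
})

test_that("bias field spans the configured amplitude over the tube", {
  a <- small_acquisition(seed = 6, bias_amplitude = 0.3, noise_sigma = 0)
  B <- make_bias_field(a)
  xy <- (seq_len(64) - 0.5) * (10 / 64)
  tube <- outer((xy - 5)^2, (xy - 5)^2, "+") <= (9.2 / 2)^2
  expect_equal(max(B[tube]), 0.3)
  expect_equal(min(B[tube]), -0.3)
  expect_true(all(abs(B) <= 0.3))
  ph <- small_phantom(seed = 6, bias_amplitude = 0.3, noise_sigma = 0)
  liq <- liquid_voxels(ph)
  v <- ph$stack$voxels
  liq_slice <- liq[, , 16]
  Bs <- ph$bias[liq_slice]
  ratio <- max(v[, , 16][liq_slice]) / min(v[, , 16][liq_slice])
  expect_equal(ratio, (1 + max(Bs)) / (1 + min(Bs)), tolerance = 1e-8)
})

test_that("rendering is deterministic and seeds only touch the noise", {
  p1 <- small_phantom(seed = 4)
  p2 <- small_phantom(seed = 4)
  expect_identical(p1$stack$voxels, p2$stack$voxels)
  a2 <- small_acquisition(seed = 99)
  s2 <- render_stack(p1$scaffold_mask, p1$tissue_mask, a2)
  expect_false(identical(p1$stack$voxels, s2$voxels))  # noise differs
})

test_that("agent mode reduces scaffold-liquid contrast", {
  an <- small_acquisition(seed = 1)
  aa <- acquisition_model(matrix_size = 64, n_slices = 32,
                          slice_thickness = 0.1, contrast_mode = "agent",
                          seed = 1)
  dn <- abs(an$intensity_levels[["scaffold"]] - an$intensity_levels[["liquid"]])
  da <- abs(aa$intensity_levels[["scaffold"]] - aa$intensity_levels[["liquid"]])
  expect_lt(da, dn)
  dtn <- an$intensity_levels[["tissue"]] - an$intensity_levels[["liquid"]]
  dta <- aa$intensity_levels[["tissue"]] - aa$intensity_levels[["liquid"]]
  expect_gt(dta, dtn)
})

test_that("reference slices are liquid-only and enforced at render time", {
  ph <- small_phantom(seed = 1)
  d3 <- dim(ph$scaffold_mask)[3]
  expect_false(any(ph$scaffold_mask[, , c(1, d3)]))
  expect_false(any(ph$tissue_mask[, , c(1, d3)]))
  bad <- ph$tissue_mask
  bad[30, 30, 1] <- TRUE
  expect_error(render_stack(ph$scaffold_mask, bad, ph$acquisition),
               "reference")
  over <- ph$scaffold_mask            # keeps the phantom metadata
  over[ph$tissue_mask] <- TRUE
  expect_error(render_stack(over, ph$tissue_mask, ph$acquisition),
               "overlap")
})

test_that("a strong bias defeats any single global threshold on raw data", {
  ph <- small_phantom(seed = 8, bias_amplitude = 0.3,
                      occ = c(top = 0.01, middle = 0.02, bottom = 0.04))
  v <- ph$stack$voxels
  liq <- liquid_voxels(ph)
  ## any threshold retaining every tissue voxel also keeps liquid voxels
  t_keep_all_tissue <- min(v[ph$tissue_mask])
  expect_gt(sum(v[liq] >= t_keep_all_tissue), 0)
})

test_that("phantom sidecar round-trips through disk", {
  ph <- small_phantom(seed = 12)
  dir <- withr::local_tempdir()
  p <- write_phantom(ph, dir)
  expect_true(all(file.exists(p)))
  side <- jsonlite::read_json(p[["params"]], simplifyVector = TRUE)
  expect_equal(side$seed, ph$seed)
  expect_identical(read_mask(p[["scaffold_mask"]]),
                   array(ph$scaffold_mask, dim(ph$scaffold_mask)))
  rt <- read_stack(p[["stack"]], slice_thickness = 0.1)
  ## float intensities survive up to 16-bit quantisation
  expect_lte(max(abs(rt$voxels - ph$stack$voxels)), 0.5 + 1e-9)
})
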