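float_stack <- function(slices, ps = 0.1, st = 0.1)
  image_stack(array(unlist(slices), c(dim(slices[[1]]), length(slices))),
              ps, st, bit_depth = "float")

test_that("tissue segmentation keeps in-ROI objects and drops outliers", {
  m <- matrix(0, 40, 40)
  m[18:22, 18:22] <- 10   # 5x5 square inside the ROI: survives opening
  m[3:7, 3:7] <- 10       # square outside the ROI
  m[25, 25] <- 10         # isolated pixel inside: removed by opening
  s <- float_stack(list(m))
  roi <- circular_roi(20, 20, 12)
  out <- segment_tissue(s, roi, threshold = 5)
  ## the in-ROI square survives the smoothing opening (corners rounded
  ## by the disk element), the out-of-ROI square and the outlier do not
  expect_identical(out[, , 1],
                   brute_open((m >= 5 & roi_mask(roi, 40, 40)) * 1, 2) > 0.5)
  expect_true(all(out[19:21, 19:21, 1]))
  expect_false(any(out[3:7, 3:7, 1]))
  expect_false(out[25, 25, 1])
  surv <- which(out[, , 1], arr.ind = TRUE)
  expect_true(all(surv[, 1] %in% 18:22 & surv[, 2] %in% 18:22))
  expect_false(any(segment_tissue(s, roi, threshold = 50)))  # all below
})

test_that("tissue pixel count is monotone in the threshold", {
  set.seed(14)
  s <- float_stack(list(matrix(stats::runif(1600, 0, 100), 40, 40)))
  roi <- circular_roi(20, 20, 15)
  counts <- vapply(c(10, 30, 50, 70, 90), function(t)
    sum(segment_tissue(s, roi, t)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("scaffold segmentation recovers ground truth on clean data", {
  ph <- small_phantom(seed = 2, bias_amplitude = 0, noise_sigma = 0)
  out <- segment_scaffold(ph$stack, ph$roi, low_threshold = 50)
  rm3 <- array(roi_mask(ph$roi, 64, 64), dim(ph$scaffold_mask))
  expect_identical(out, ph$scaffold_mask & rm3)
  expect_false(any(segment_scaffold(ph$stack, ph$roi, low_threshold = -1)))
})

test_that("scaffold count is monotone in the low threshold", {
  ph <- small_phantom(seed = 2)
  counts <- vapply(c(20, 40, 60), function(t)
    sum(segment_scaffold(ph$stack, ph$roi, t)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("pore closure triggers a warning at absurd thresholds", {
  ph <- small_phantom(seed = 2)
  expect_warning(segment_scaffold(ph$stack, ph$roi, low_threshold = 1e5),
                 "pore closure")
})

test_that("agent-mode contrast defeats scaffold thresholding", {
  ph <- build_phantom(
    tissue = tissue_model(c(bottom = 0.02)),
    acquisition = acquisition_model(matrix_size = 64, n_slices = 32,
                                    slice_thickness = 0.1,
                                    contrast_mode = "agent", seed = 3),
    seed = 3)
  v <- ph$stack$voxels
  liq <- liquid_voxels(ph)
  ## recovering every scaffold voxel forces liquid into the scaffold class
  t_all_scaffold <- max(v[ph$scaffold_mask])
  expect_gt(sum(v[liq] <= t_all_scaffold), 0)
})

test_that("calibration matches the pore-intensity quantile without opening", {
  set.seed(31)
  n <- 64
  vox <- array(stats::rnorm(n * n * 6, mean = 10, sd = 3), c(n, n, 6))
  vox[vox < 0] <- 0
  s <- image_stack(vox, 0.1, 0.1, bit_depth = "float")
  roi <- circular_roi(32, 32, 25)
  scaf <- array(FALSE, dim(vox))
  thr <- calibrate_threshold(s, roi, scaf, fp_tolerance = 0.001,
                             count_after_opening = FALSE)
  pore_vals <- vox[array(roi_mask(roi, n, n), dim(vox))]
  q <- stats::quantile(pore_vals, 0.999)
  expect_equal(thr, as.numeric(q), tolerance = 0.02)
  ## replay: the returned threshold satisfies the tolerance, the next
  ## lower observed value does not
  fp <- mean(pore_vals >= thr)
  expect_lte(fp, 0.001)
  below <- max(pore_vals[pore_vals < thr])
  expect_gt(mean(pore_vals >= below), 0.001)
})

test_that("calibration degenerate cases behave", {
  ph <- small_phantom(seed = 4, occ = c(bottom = 0), noise_sigma = 0)
  cor <- correct_stack(ph$stack)
  scaf <- segment_scaffold(ph$stack, ph$roi, 50)
  thr <- calibrate_threshold(cor, ph$roi, scaf, fp_tolerance = 0.001)
  pore <- array(roi_mask(ph$roi, 64, 64), dim(scaf)) & !scaf
  expect_lte(thr, max(cor$voxels[pore]) + 1)
  ## tolerance 1 accepts everything: minimum of the search range
  thr1 <- calibrate_threshold(cor, ph$roi, scaf, fp_tolerance = 1)
  expect_equal(thr1, min(sort(unique(cor$voxels[pore]))[
    sort(unique(cor$voxels[pore])) > 0]))
  expect_error(calibrate_threshold(cor, ph$roi, scaf, fp_tolerance = 0),
               "fp_tolerance")
})

test_that("calibrated threshold replays within tolerance on the bare stack", {
  bare <- small_phantom(seed = 17, occ = c(bottom = 0))
  cor <- correct_stack(bare$stack)
  scaf <- segment_scaffold(bare$stack, bare$roi, 50)
  thr <- calibrate_threshold(cor, bare$roi, scaf, fp_tolerance = 0.001)
  mask <- segment_tissue(cor, bare$roi, thr)
  pore <- array(roi_mask(bare$roi, 64, 64), dim(scaf)) & !scaf
  expect_lte(sum(mask & pore) / sum(pore), 0.001)
})

test_that("ROI fitting recovers the tube circle", {
  ph <- small_phantom(seed = 6)
  roi <- fit_roi(ph$stack)
  expect_lt(abs(roi$center_x - ph$roi$center_x), 2)
  expect_lt(abs(roi$center_y - ph$roi$center_y), 2)
  expect_lt(abs(roi$radius - ph$roi$radius) / ph$roi$radius, 0.03)
  manual <- circular_roi(10, 10, 5)
  expect_identical(fit_roi(ph$stack, roi = manual), manual)
  blank <- image_stack(array(0, c(16, 16, 3)), 0.1, 0.1, "float")
  expect_error(fit_roi(blank), "blank|manually")
})

test_that("segmentation masks are disjoint and ROI-bounded", {
  ph <- small_phantom(seed = 11, occ = c(top = 0.01, middle = 0.02,
                                         bottom = 0.04))
  bare <- small_phantom(seed = 11, occ = c(bottom = 0))
  res <- run_pipeline(ph$stack, bare = bare$stack,
                      config = pipeline_config(make_meshes = FALSE))
  expect_false(any(res$masks$tissue_mask & res$masks$scaffold_mask))
  rm3 <- array(res$masks$roi_mask, dim(res$masks$tissue_mask))
  expect_false(any(res$masks$tissue_mask & !rm3))
  expect_false(any(res$masks$scaffold_mask & !rm3))
})

test_that("background correction rescues tissue detection under strong bias", {
  occ <- c(top = 0.02, middle = 0.02, bottom = 0.02)
  ph <- build_phantom(tissue = tissue_model(occ),
                      acquisition = acquisition_model(bias_amplitude = 0.3,
                                                      seed = 13), seed = 13)
  bare <- build_phantom(tissue = tissue_model(c(bottom = 0)),
                        acquisition = acquisition_model(bias_amplitude = 0.3,
                                                        seed = 13), seed = 13)
  f1 <- function(pred, truth) {
    tp <- sum(pred & truth)
    if (tp == 0) return(0)
    p <- tp / sum(pred); r <- tp / sum(truth)
    2 * p * r / (p + r)
  }
  ## with preprocessing
  res <- run_pipeline(ph$stack, bare = bare$stack,
                      config = pipeline_config(make_meshes = FALSE))
  f1_cor <- f1(res$masks$tissue_mask, ph$tissue_mask)
  ## without: same calibration procedure straight on the raw stacks
  roi <- fit_roi(ph$stack)
  scaf_b <- segment_scaffold(bare$stack, roi, 50)
  thr_raw <- calibrate_threshold(bare$stack, roi, scaf_b,
                                 fp_tolerance = 0.001)
  mask_raw <- segment_tissue(ph$stack, roi, thr_raw)
  f1_raw <- f1(mask_raw & !res$masks$scaffold_mask, ph$tissue_mask)
  expect_gte(f1_cor, 0.9)
  expect_lt(f1_raw, f1_cor)
})
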