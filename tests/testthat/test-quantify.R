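test_that("slice quantification implements the pore-volume percentage", {
  roi <- matrix(FALSE, 40, 40)
  roi[1:25, 1:40] <- TRUE                      # 1000 ROI pixels
  scaf <- matrix(FALSE, 40, 40); scaf[1:20, 1:40] <- TRUE   # 800 in ROI
  tis <- matrix(FALSE, 40, 40); tis[21:22, 1:25] <- TRUE    # 50 in pore
  rec <- quantify_slice(tis, scaf, roi, slice_id = 3)
  expect_equal(rec$roi_px, 1000)
  expect_equal(rec$scaffold_px, 800)
  expect_equal(rec$pore_px, 200)
  expect_equal(rec$tissue_px, 50)
  expect_equal(rec$tissue_pct, 25)
  ## zero tissue
  rec0 <- quantify_slice(matrix(FALSE, 40, 40), scaf, roi)
  expect_equal(rec0$tissue_pct, 0)
  ## occluded slice errors
  full <- matrix(TRUE, 40, 40)
  expect_error(quantify_slice(tis, full, roi), "pore")
})

test_that("pore identity and additivity hold on a pipeline run", {
  ph <- small_phantom(seed = 3, occ = c(top = 0.01, middle = 0.02,
                                        bottom = 0.04))
  bare <- small_phantom(seed = 3, occ = c(bottom = 0))
  res <- run_pipeline(ph$stack, bare = bare$stack,
                      config = pipeline_config(make_meshes = FALSE))
  rec <- res$records
  expect_true(all(rec$pore_px == rec$roi_px - rec$scaffold_px))
  expect_true(all(rec$tissue_px <= rec$pore_px))
  expect_true(all(rec$tissue_pct >= 0 & rec$tissue_pct <= 100))
  ## per-section tissue pixels sum to the whole-stack total
  sec_sum <- sum(vapply(res$boundaries, function(b)
    sum(rec$tissue_px[rec$slice_id %in% (b[1]:b[2])]), numeric(1)))
  inf <- unlist(lapply(res$boundaries, function(b) b[1]:b[2]))
  expect_equal(sec_sum, sum(rec$tissue_px[rec$slice_id %in% inf]))
})

test_that("section summaries give textbook mean and sample SD", {
  rec <- data.frame(slice_id = 1:6,
                    tissue_pct = c(3, 3, 3, 1, 2, 3))
  s <- summarize_sections(rec, list(top = c(1, 3), bottom = c(4, 6)))
  expect_equal(s$mean_pct, c(3, 2))
  expect_equal(s$sd_pct, c(0, 1))
  expect_equal(s$n_slices, c(3, 3))
  expect_error(summarize_sections(rec, list(a = c(1, 4), b = c(4, 6))),
               "overlap")
  expect_error(summarize_sections(rec, list(a = c(1, 3), b = c(5, 9))),
               "outside")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  set.seed(8)
  a <- stats::rnorm(10, 2); b <- stats::rnorm(12, 3)
  res <- compare_sections_anova(list(a = a, b = b))
  t <- stats::t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(res$F, unname(t^2), tolerance = 1e-10)
})

test_that("three-group ANOVA matches the hand sum-of-squares oracle", {
  g <- list(top = c(1, 2, 3), middle = c(2, 3, 4), bottom = c(6, 7, 8))
  res <- compare_sections_anova(g)
  ## explicit sum-of-squares arithmetic
  vals <- unlist(g); gm <- mean(vals)
  ssb <- sum(vapply(g, function(x) length(x) * (mean(x) - gm)^2, numeric(1)))
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  Fhand <- (ssb / 2) / (ssw / 6)
  expect_equal(res$F, Fhand, tolerance = 1e-10)
  expect_equal(res$p, stats::pf(Fhand, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  ## Bonferroni: raw pairwise p times 3, capped at 1
  praw <- stats::t.test(g$top, g$middle, var.equal = TRUE)$p.value
  expect_equal(res$pairwise$p_adj[res$pairwise$group1 == "top" &
                                    res$pairwise$group2 == "middle"],
               min(3 * praw, 1))
})

test_that("identical groups give F = 0 and no stars", {
  res <- compare_sections_anova(list(a = c(2, 2, 2), b = c(2, 2, 2)))
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_true(all(res$pairwise$stars == "ns"))
  expect_error(compare_sections_anova(list(a = 1:3)), "2 groups")
  expect_error(compare_sections_anova(list(a = 1, b = 1:3)), ">= 2 values")
})

test_that("star labels follow the 0.05/0.01/0.001 thresholds", {
  g1 <- list(a = c(10, 11, 10, 11), b = c(30, 31, 30, 31))
  expect_equal(compare_sections_anova(g1)$pairwise$stars, "***")
  expect_equal(scaffoldMRI:::star_label(0.03), "*")
  expect_equal(scaffoldMRI:::star_label(0.004), "**")
  expect_equal(scaffoldMRI:::star_label(0.2), "ns")
})

test_that("stage projection bins counts as specified for n = 15", {
  n <- 15
  counts_wanted <- c(0, 1, 4, 5, 7, 8, 9, 12, 13, 15)
  stages_wanted <- c(0, 1, 1, 2, 2, 2, 3, 3, 4, 4)
  vol <- array(FALSE, c(1, length(counts_wanted), n))
  for (j in seq_along(counts_wanted))
    if (counts_wanted[j] > 0) vol[1, j, seq_len(counts_wanted[j])] <- TRUE
  pr <- stage_projection(vol)
  expect_equal(pr$bin_edges, c(4, 8, 12, 15))
  expect_equal(as.vector(pr$stages), stages_wanted)
  expect_equal(as.vector(pr$counts), counts_wanted)
})

test_that("stage projection honours its structural invariants", {
  set.seed(9)
  vol <- array(stats::runif(6 * 6 * 11) > 0.5, c(6, 6, 11))
  pr <- stage_projection(vol)
  expect_true(all((pr$stages == 0) == (pr$counts == 0)))
  ord <- order(as.vector(pr$counts))
  expect_true(all(diff(as.vector(pr$stages)[ord]) >= 0))
  ## all-empty stack projects to all-zero stages
  pr0 <- stage_projection(array(FALSE, c(4, 4, 5)))
  expect_true(all(pr0$stages == 0))
  ## a pixel present in every slice reaches the top stage
  vol2 <- array(FALSE, c(4, 4, 5)); vol2[2, 2, ] <- TRUE
  expect_equal(stage_projection(vol2)$stages[2, 2], 4L)
})

test_that("projection PNG uses the 5-colour palette", {
  vol <- array(FALSE, c(8, 8, 4)); vol[2, 2, ] <- TRUE; vol[5, 5, 1] <- TRUE
  pr <- stage_projection(vol)
  f <- withr::local_tempfile(fileext = ".png")
  write_projection_png(pr, f)
  img <- png::readPNG(f)
  cols <- unique(matrix(img, ncol = 3))
  expect_lte(nrow(cols), 5)
})

test_that("quantification CSV mirrors the per-slice table", {
  rec <- data.frame(slice_id = 1:4, tissue_px = c(0, 5, 10, 0),
                    scaffold_px = 100, pore_px = 400, roi_px = 500,
                    tissue_pct = c(0, 1.25, 2.5, 0))
  s <- summarize_sections(rec, list(top = c(1, 2), bottom = c(3, 4)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_quant_csv(rec, f, s)
  back <- utils::read.csv(f)
  expect_equal(back$tissue_pct, rec$tissue_pct)
  expect_equal(back$mean_pct[c(1, 3)], s$mean_pct)
  expect_equal(back$section, c("top", "top", "bottom", "bottom"))
})
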