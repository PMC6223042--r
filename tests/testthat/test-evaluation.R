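mk <- function(vals, d) image_volume(array(vals, d))

test_that("absolute difference maps follow their voxel cases", {
  a <- mk(100, c(3, 3, 3))
  b <- mk(40, c(3, 3, 3))
  expect_true(all(abs_difference(a, b)$data == 60))
  expect_true(all(abs_difference(a, a)$data == 0))
  expect_identical(abs_difference(a, b)$data, abs_difference(b, a)$data)
  expect_error(abs_difference(a, mk(0, c(2, 2, 2))), "grid")
})

test_that("volume error reproduces its worked values", {
  m <- body_mask(array(TRUE, c(2, 1, 1)))
  ref <- mk(c(0, 0), c(2, 1, 1))
  test <- mk(c(3, 4), c(2, 1, 1))
  expect_equal(volume_error(ref, test, m), sqrt(12.5), tolerance = 1e-12)
  expect_equal(volume_error(ref, ref, m), 0)
  # constant difference d gives |d|
  d8 <- mk(rep(7, 8), c(2, 2, 2))
  z8 <- mk(rep(0, 8), c(2, 2, 2))
  expect_equal(volume_error(z8, d8, body_mask(array(TRUE, c(2, 2, 2)))), 7)
  expect_error(volume_error(ref, test,
                            body_mask(array(FALSE, c(2, 1, 1)))), "mask")
})

test_that("tissue classification follows the HU class boundaries", {
  expect_identical(classify_tissue(-450), "air")
  expect_identical(classify_tissue(0), "soft_tissue")
  expect_identical(classify_tissue(400), "soft_bone")
  expect_identical(classify_tissue(800), "bone")
  # declared boundary conventions
  expect_identical(classify_tissue(c(-400, 250, 600, 601)),
                   c("soft_tissue", "soft_bone", "soft_bone", "bone"))
})

test_that("binned MAE reproduces its worked example", {
  ref <- mk(c(-500, 0, 300, 700), c(4, 1, 1))
  test <- mk(c(-490, 10, 310, 710), c(4, 1, 1))
  m <- body_mask(array(TRUE, c(4, 1, 1)))
  tab <- mae_by_bin(ref, test, m, 20)
  occ <- tab[tab$n > 0, ]
  expect_equal(nrow(occ), 4)
  expect_true(all(occ$mae == 10))
  expect_identical(occ$class, c("air", "soft_tissue", "soft_bone", "bone"))
  expect_equal(sum(tab$n), sum(m$data))
  # identical volumes: every occupied bin has MAE 0
  tab0 <- mae_by_bin(ref, ref, m, 20)
  expect_true(all(tab0$mae[tab0$n > 0] == 0))
  # empty bins are NA, never 0
  expect_true(all(is.na(tab$mae[tab$n == 0])))
})

test_that("bin centres collect reference HU in [centre - 10, centre + 10)", {
  ref <- mk(c(-10, -9.99, 9.99, 10), c(4, 1, 1))
  m <- body_mask(array(TRUE, c(4, 1, 1)))
  tab <- mae_by_bin(ref, ref, m, 20)
  expect_equal(tab$n[tab$bin_center == 0], 3)    # [-10, 10)
  expect_equal(tab$n[tab$bin_center == 20], 1)   # boundary goes up
})

test_that("an infinitely wide bin reproduces the overall MAE", {
  set.seed(31)
  ref <- random_volume(c(6, 6, 6))
  test <- random_volume(c(6, 6, 6))
  m <- body_mask(array(TRUE, c(6, 6, 6)))
  tab <- mae_by_bin(ref, test, m, 1e7)
  expect_equal(tab$mae[tab$n > 0], mean(abs(ref$data - test$data)),
               tolerance = 1e-9)
})

test_that("ROI means follow their worked examples", {
  v <- mk(50, c(12, 12, 3))
  expect_equal(roi_mean(v, roi_box(2, 2, 2)), 50)
  seqv <- image_volume(array(0, c(10, 10, 1)))
  seqv$data[, , 1] <- matrix(0:99, 10, 10)   # column-major 0..99
  expect_equal(roi_mean(seqv, roi_box(1, 1, 1)), 49.5)
  expect_error(roi_mean(v, roi_box(2, 5, 5)), "outside")
  # zero-noise phantom fat ROI is exactly the fat mean
  spec <- phantom_spec(jitter = 0, heterogeneity_sd = 0)
  p <- generate_pct(spec)
  fat_roi <- Filter(function(r) r$label == tissue_codes[["fat"]], p$rois)[[1]]
  expect_equal(roi_mean(p$volume, fat_roi), -100)
})

test_that("uniformity RMSD reproduces its worked values", {
  expect_equal(uniformity_rmsd(c(1, 2), c(1, 2)), 0)
  expect_equal(uniformity_rmsd(c(0, 0), c(3, 4)), sqrt(12.5),
               tolerance = 1e-12)
  expect_equal(uniformity_rmsd(5, 9), 4)
  expect_error(uniformity_rmsd(c(1, 2), c(1)), "equal length")
  expect_error(uniformity_rmsd(numeric(0), numeric(0)), "equal length")
})

test_that("RMS volume error dominates the mean absolute error", {
  set.seed(32)
  for (i in 1:5) {
    ref <- random_volume(c(6, 5, 4))
    test <- random_volume(c(6, 5, 4))
    m <- body_mask(array(TRUE, c(6, 5, 4)))
    expect_gte(volume_error(ref, test, m),
               mean(abs(ref$data - test$data)) - 1e-12)
  }
})

test_that("reports assemble consistently and round-trip through JSON", {
  set.seed(33)
  d <- c(16, 16, 4)
  ref <- random_volume(d)
  before <- image_volume(ref$data + 60, ref$spacing)
  after <- image_volume(ref$data + rnorm(prod(d), 0, 2), ref$spacing)
  m <- body_mask(array(TRUE, d))
  rois <- list(roi_box(2, 3, 3, 5, 5, 1L), roi_box(3, 8, 8, 5, 5, 2L))
  rep1 <- build_report(ref, before, after, m, rois, "DR-NCC")
  expect_equal(rep1$verr_before, 60, tolerance = 1e-9)
  expect_lt(rep1$verr_after, rep1$verr_before)
  expect_equal(nrow(rep1$roi), 2)
  p <- file.path(tempdir(), "report-roundtrip.json")
  write_report(rep1, p)
  rep2 <- read_report(p)
  expect_equal(rep2$verr_before, rep1$verr_before, tolerance = 1e-12)
  expect_equal(rep2$mae_before$mae, rep1$mae_before$mae, tolerance = 1e-12)
  expect_equal(rep2$roi$ref_mean, rep1$roi$ref_mean, tolerance = 1e-12)
  expect_identical(rep2$algo_id, "DR-NCC")
  # a perfectly corrected volume zeroes the after-statistics
  rep3 <- build_report(ref, before, ref, m, list(), "DR-MI")
  expect_equal(rep3$verr_after, 0)
  expect_true(all(rep3$mae_after$mae[rep3$mae_after$n > 0] == 0))
})
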