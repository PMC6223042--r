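mk_vol <- function(vals, d = NULL) {
  if (is.null(d)) d <- c(length(vals), 1, 1)
  image_volume(array(vals, d))
}

test_that("NCC reproduces its defining worked examples", {
  f <- mk_vol(c(1, 2, 3, 4))
  expect_equal(metric_ncc(f, f), 1.0, tolerance = 1e-12)
  m <- mk_vol(c(4, 3, 2, 1))
  expect_equal(metric_ncc(f, m), -1.0, tolerance = 1e-12)
  f2 <- mk_vol(c(0, 1, 0, 1))
  m2 <- mk_vol(c(1, 1, 0, 0))
  expect_equal(metric_ncc(f2, m2), 0.0, tolerance = 1e-12)
})

test_that("NCC raises on degenerate (constant) samples", {
  f <- mk_vol(c(5, 5, 5, 5))
  m <- mk_vol(c(1, 2, 3, 4))
  expect_error(metric_ncc(f, m), "degenerate sample")
})

test_that("NCC is invariant to positive affine intensity rescaling", {
  set.seed(7)
  f <- random_volume(c(9, 8, 7))
  m <- random_volume(c(9, 8, 7))
  base <- metric_ncc(f, m)
  m2 <- image_volume(3.7 * m$data + 120, m$spacing, m$origin)
  expect_equal(metric_ncc(f, m2), base, tolerance = 1e-10)
  f2 <- image_volume(0.25 * f$data - 40, f$spacing, f$origin)
  expect_equal(metric_ncc(f2, m), base, tolerance = 1e-10)
})

test_that("joint histogram reproduces its defining worked examples", {
  # identical two-level images: diagonal 0.5/0.5
  f <- mk_vol(c(0, 0, 1, 1))
  h <- build_joint_histogram(f, f, bins = 2, parzen = FALSE)
  expect_equal(h$p, matrix(c(0.5, 0, 0, 0.5), 2, 2), tolerance = 1e-12)
  # independent patterns: uniform 0.25 over the 4 cells
  f2 <- mk_vol(c(0, 0, 1, 1))
  m2 <- mk_vol(c(0, 1, 0, 1))
  h2 <- build_joint_histogram(f2, m2, bins = 2, parzen = FALSE)
  expect_equal(h2$p, matrix(0.25, 2, 2), tolerance = 1e-12)
  # marginals equal row/column sums
  expect_equal(h2$pf, rowSums(h2$p), tolerance = 1e-12)
  expect_equal(h2$pm, colSums(h2$p), tolerance = 1e-12)
})

test_that("Parzen-windowed histograms are normalized with correct marginals", {
  set.seed(8)
  f <- random_volume(c(8, 8, 8))
  m <- random_volume(c(8, 8, 8))
  h <- build_joint_histogram(f, m, bins = 16, parzen = TRUE)
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(h$pf, rowSums(h$p), tolerance = 1e-12)
  expect_equal(h$pm, colSums(h$p), tolerance = 1e-12)
  expect_gte(metric_mi(h), -1e-12)
})

test_that("MI reproduces its defining worked examples", {
  f <- mk_vol(c(0, 0, 1, 1))
  h <- build_joint_histogram(f, f, bins = 2, parzen = FALSE)
  expect_equal(metric_mi(h), log(2), tolerance = 1e-12)
  m <- mk_vol(c(0, 1, 0, 1))
  h2 <- build_joint_histogram(f, m, bins = 2, parzen = FALSE)
  expect_equal(metric_mi(h2), 0, tolerance = 1e-12)
})

test_that("MI never exceeds either marginal entropy", {
  set.seed(9)
  for (i in 1:5) {
    f <- random_volume(c(7, 7, 7))
    m <- random_volume(c(7, 7, 7))
    h <- build_joint_histogram(f, m, bins = 8, parzen = FALSE)
    hf <- -sum(h$pf[h$pf > 0] * log(h$pf[h$pf > 0]))
    hm <- -sum(h$pm[h$pm > 0] * log(h$pm[h$pm > 0]))
    expect_lte(metric_mi(h), min(hf, hm) + 1e-12)
  }
})

test_that("NMI reproduces its worked examples and the MI identity", {
  f <- mk_vol(c(0, 0, 1, 1))
  h <- build_joint_histogram(f, f, bins = 2, parzen = FALSE)
  expect_equal(metric_nmi(h), 2.0, tolerance = 1e-12)
  m <- mk_vol(c(0, 1, 0, 1))
  h2 <- build_joint_histogram(f, m, bins = 2, parzen = FALSE)
  expect_equal(metric_nmi(h2), 1.0, tolerance = 1e-12)
  set.seed(10)
  f3 <- random_volume(c(8, 8, 8))
  m3 <- random_volume(c(8, 8, 8))
  h3 <- build_joint_histogram(f3, m3, bins = 12, parzen = FALSE)
  hj <- -sum(h3$p[h3$p > 0] * log(h3$p[h3$p > 0]))
  expect_equal(metric_nmi(h3), 1 + metric_mi(h3) / hj, tolerance = 1e-12)
})

test_that("NMI raises when both images are constant", {
  f <- mk_vol(rep(1, 8))
  h <- build_joint_histogram(f, f, bins = 4, parzen = FALSE)
  expect_error(metric_nmi(h), "degenerate sample")
})

test_that("MI is symmetric in its arguments at identity", {
  set.seed(12)
  f <- random_volume(c(10, 9, 8))
  m <- random_volume(c(10, 9, 8))
  h1 <- build_joint_histogram(f, m, bins = 16, parzen = FALSE)
  h2 <- build_joint_histogram(m, f, bins = 16, parzen = FALSE)
  expect_equal(metric_mi(h1), metric_mi(h2), tolerance = 1e-10)
})

test_that("sampling domains respect masks and drop-outside semantics", {
  v <- mk_vol(1:27, c(3, 3, 3))
  mask <- body_mask(array(rep(c(TRUE, FALSE), length.out = 27), c(3, 3, 3)))
  dom <- sampling_domain(v, mask)
  expect_equal(dom$count, sum(mask$data))
  # sites mapping outside the moving image are removed before correlation
  f <- mk_vol(c(1, 2, 3, 4, 5, 6), c(6, 1, 1))
  tr <- transform_rigid(c(0, 0, 0), c(2, 0, 0))  # shifts 2 sites outside
  expect_equal(metric_ncc(f, f, tr), 1.0, tolerance = 1e-12)
})
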