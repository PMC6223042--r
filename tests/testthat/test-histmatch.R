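const_mask <- function(d) body_mask(array(TRUE, d))

test_that("build_cdf reproduces its worked examples", {
  # constant volume: CDF is a unit step (0 below the value's bin, 1 after)
  v <- image_volume(array(5, c(4, 4, 4)))
  h <- build_cdf(v, const_mask(c(4, 4, 4)), bins = 8)
  expect_true(all(h$cdf %in% c(0, 1)))
  expect_true(all(diff(h$cdf) >= 0))
  expect_equal(h$cdf[8], 1)
  # values {0 x2, 10 x2} in 2 bins: CDF (0.5, 1.0)
  v2 <- image_volume(array(c(0, 0, 10, 10), c(4, 1, 1)))
  h2 <- build_cdf(v2, const_mask(c(4, 1, 1)), bins = 2)
  expect_equal(h2$cdf, c(0.5, 1.0), tolerance = 1e-12)
  # total count equals mask cardinality
  ph <- default_phantom()
  pp <- preprocessed_phantom()$cbct
  h3 <- build_cdf(pp$volume, pp$mask, bins = 256)
  expect_equal(sum(h3$counts), sum(pp$mask$data))
  expect_true(all(diff(h3$cdf) >= 0))
  expect_equal(h3$cdf[length(h3$cdf)], 1, tolerance = 1e-12)
})

test_that("build_cdf rejects an empty mask", {
  v <- image_volume(array(0, c(3, 3, 3)))
  expect_error(build_cdf(v, body_mask(array(FALSE, c(3, 3, 3)))), "mask")
})

test_that("matching a histogram to itself is the identity map", {
  set.seed(21)
  v <- random_volume(c(12, 12, 8))
  h <- build_cdf(v, const_mask(c(12, 12, 8)), bins = 256)
  lut <- compute_matching_lut(h, h)
  w <- diff(range(v$data)) / 256
  expect_lt(max(abs(lut$output - lut$input)), w / 2 + 1e-9)
})

test_that("matching inverts a pure intensity shift to within half a bin", {
  set.seed(22)
  d <- c(32, 32, 8)
  v <- image_volume(array(runif(prod(d), -200, 200), d))
  shifted <- image_volume(v$data + 100, v$spacing, v$origin)
  m <- const_mask(d)
  hm <- match_histogram(shifted, v, m, bins = 1024)
  w <- diff(range(shifted$data, v$data)) / 1024
  err <- abs(hm$corrected$data - v$data)
  # half-bin accuracy across the distribution; only voxels in the nearly
  # empty extreme-tail bins can exceed it (quantile inversion degrades as
  # the local bin population approaches zero)
  expect_lte(quantile(err, 0.999), w / 2)
  expect_lte(median(err), w / 4)
})

test_that("two-level mass matching maps level to level", {
  src <- build_cdf(image_volume(array(c(0, 0, 10, 10), c(4, 1, 1))),
                   const_mask(c(4, 1, 1)), bins = 64, range = c(0, 20))
  ref <- build_cdf(image_volume(array(c(5, 5, 20, 20), c(4, 1, 1))),
                   const_mask(c(4, 1, 1)), bins = 64, range = c(0, 20))
  lut <- compute_matching_lut(src, ref)
  map <- function(x) approx(lut$input, lut$output, x, rule = 2)$y
  expect_equal(map(0), 5, tolerance = 0.5)
  expect_equal(map(10), 20, tolerance = 0.5)
})

test_that("apply_mapping transforms only masked voxels and conserves mass", {
  v <- image_volume(array(seq(-100, 155, length.out = 4^3), c(4, 4, 4)))
  mask <- body_mask(array(c(TRUE, FALSE), c(4, 4, 4)))
  lut <- structure(list(input = c(-200, 200), output = c(-100, 300)),
                   class = "intensity_mapping")
  out <- apply_mapping(v, lut, mask)
  expect_equal(out$data[!mask$data], v$data[!mask$data])
  expect_false(any(out$data[mask$data] == v$data[mask$data]))
  expect_equal(sum(mask$data), sum(mask$data))  # mask untouched
  # identity map leaves the volume unchanged
  idm <- structure(list(input = c(-2000, 2000), output = c(-2000, 2000)),
                   class = "intensity_mapping")
  expect_equal(apply_mapping(v, idm, mask)$data, v$data, tolerance = 1e-12)
})

test_that("mapped intensities preserve voxelwise ordering", {
  set.seed(23)
  v <- random_volume(c(10, 10, 6))
  ref <- random_volume(c(10, 10, 6), scale = 150)
  m <- const_mask(c(10, 10, 6))
  hm <- match_histogram(v, ref, m, bins = 512)
  x <- v$data[m$data]
  y <- hm$corrected$data[m$data]
  o <- order(x)
  expect_true(all(diff(y[o]) >= -1e-9))
})

test_that("histogram matching aligns the phantom CBCT to its reference", {
  ph <- default_phantom()
  cp <- preprocessed_phantom()$cbct
  hm <- match_histogram(cp$volume, ph$deformed_pct, cp$mask, bins = 1024)
  rng <- range(hm$corrected$data[cp$mask$data],
               ph$deformed_pct$data[cp$mask$data])
  c1 <- build_cdf(hm$corrected, cp$mask, 1024, rng)
  c2 <- build_cdf(ph$deformed_pct, cp$mask, 1024, rng)
  expect_lte(max(abs(c1$cdf - c2$cdf)), 0.02)
  # the full match operation is idempotent: a second matching pass moves
  # almost no voxel by more than 1 HU
  hm2 <- match_histogram(hm$corrected, ph$deformed_pct, cp$mask,
                         bins = 1024)
  moved <- abs(hm2$corrected$data[cp$mask$data] -
                 hm$corrected$data[cp$mask$data])
  expect_gte(mean(moved <= 1), 0.99)
})
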