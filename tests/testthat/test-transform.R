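test_that("identity and rigid transforms map points as expected", {
  pts <- matrix(rnorm(30) * 10, 10, 3)
  expect_equal(apply_transform(transform_identity(), pts), pts)
  # pure translation
  tr <- transform_rigid(c(0, 0, 0), c(1, -2, 3))
  expect_equal(apply_transform(tr, pts), sweep(pts, 2, c(1, -2, 3), "+"))
  # 90 degree rotation about z through the origin: (x, y) -> (-y, x)
  tr <- transform_rigid(c(0, 0, pi / 2), c(0, 0, 0), c(0, 0, 0))
  out <- apply_transform(tr, matrix(c(1, 0, 0), 1))
  expect_equal(as.numeric(out), c(0, 1, 0), tolerance = 1e-12)
  # rotation about a non-origin centre leaves the centre fixed
  ctr <- c(5, 6, 7)
  tr <- transform_rigid(c(0.3, -0.2, 0.1), c(0, 0, 0), ctr)
  expect_equal(as.numeric(apply_transform(tr, matrix(ctr, 1))), ctr,
               tolerance = 1e-12)
})

test_that("B-spline transform with zero coefficients is the identity", {
  grid <- cbcthm:::bspline_grid(
    image_volume(array(0, c(8, 8, 8)), c(10, 10, 10)), 30, 30)
  tr <- transform_bspline(grid$origin, rep(30, 3), grid$dim,
                          matrix(0, prod(grid$dim), 3))
  pts <- matrix(runif(30, 0, 70), 10, 3)
  expect_equal(apply_transform(tr, pts), pts)
})

test_that("B-spline displacement is bounded by the max coefficient", {
  set.seed(4)
  grid <- cbcthm:::bspline_grid(
    image_volume(array(0, c(8, 8, 8)), c(10, 10, 10)), 30, 30)
  coef <- matrix(runif(prod(grid$dim) * 3, -5, 5), ncol = 3)
  tr <- transform_bspline(grid$origin, rep(30, 3), grid$dim, coef)
  pts <- matrix(runif(600, 0, 70), 200, 3)
  u <- transform_displacement(tr, pts)
  expect_true(all(abs(u) <= 5 + 1e-12))
})

test_that("composites apply members in order", {
  t1 <- transform_rigid(c(0, 0, pi / 2), c(0, 0, 0))
  t2 <- transform_rigid(c(0, 0, 0), c(10, 0, 0))
  p <- matrix(c(1, 0, 0), 1)
  out <- apply_transform(transform_composite(t1, t2), p)
  expect_equal(as.numeric(out), c(10, 1, 0), tolerance = 1e-12)
  out2 <- apply_transform(transform_composite(t2, t1), p)
  expect_equal(as.numeric(out2), c(0, 11, 0), tolerance = 1e-12)
})

test_that("transforms round-trip through JSON", {
  set.seed(5)
  tr <- transform_composite(
    transform_rigid(c(0.02, -0.01, 0.005), c(3, -4, 5), c(50, 60, 70)),
    transform_bspline(c(-30, -30, -30), c(30, 30, 30), c(5, 4, 4),
                      matrix(rnorm(80 * 3), 80, 3)))
  p <- file.path(tempdir(), "transform-roundtrip.json")
  write_transform(tr, p)
  tr2 <- read_transform(p)
  pts <- matrix(runif(60, 0, 80), 20, 3)
  expect_equal(apply_transform(tr2, pts), apply_transform(tr, pts),
               tolerance = 1e-12)
})

test_that("dyadic coefficient refinement preserves the displacement field", {
  set.seed(6)
  dom <- image_volume(array(0, c(8, 8, 8)), c(12, 12, 12))
  grid <- cbcthm:::bspline_grid(dom, 40, 40)
  coef <- matrix(rnorm(prod(grid$dim) * 3, 0, 4), ncol = 3)
  tr <- transform_bspline(grid$origin, rep(40, 3), grid$dim, coef)
  r <- cbcthm:::refine_coefs(coef, grid$dim)
  tr2 <- transform_bspline(grid$origin, rep(20, 3), r$dim, r$coef)
  pts <- matrix(runif(300, 5, 75), 100, 3)
  expect_equal(transform_displacement(tr2, pts),
               transform_displacement(tr, pts), tolerance = 1e-10)
})
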