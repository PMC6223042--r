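test_that("resample through the identity reproduces the input", {
  set.seed(13)
  v <- random_volume(c(10, 9, 8), spacing = c(2, 2, 3))
  out <- resample(v, transform_identity(), v)
  expect_equal(out$data, v$data, tolerance = 1e-12)
})

test_that("resampling a one-voxel translation shifts the array by one voxel", {
  set.seed(14)
  v <- random_volume(c(10, 10, 6), spacing = c(2, 2, 2))
  tr <- transform_rigid(c(0, 0, 0), c(2, 0, 0))  # one voxel pitch in x
  out <- resample(v, tr, v, fill = -1000)
  expect_equal(out$data[1:9, , ], v$data[2:10, , ], tolerance = 1e-9)
  expect_true(all(out$data[10, , ] == -1000))     # border filled
})

test_that("nearest-neighbour label resampling introduces no new codes", {
  ph <- default_phantom()
  codes <- sort(unique(as.integer(ph$labels$data)))
  ref <- cbct_reference_grid(phantom_spec())
  out <- resample(ph$labels, ph$warp, ref, "nearest", fill = 0)
  expect_true(inherits(out, "label_volume"))
  expect_true(all(unique(as.integer(out$data)) %in% codes))
})

test_that("pyramid levels shrink the grid and preserve the physical origin", {
  ph <- default_phantom()
  pp <- preprocessed_phantom()$pct
  lev <- cbcthm:::pyramid_level(pp$volume, pp$mask, 2, 4)
  expect_equal(lev$vol$spacing, pp$volume$spacing * 4)
  expect_equal(lev$vol$origin, pp$volume$origin)
  expect_true(all(vol_dim(lev$vol) <= ceiling(vol_dim(pp$volume) / 4) + 1))
  expect_identical(vol_dim(lev$mask), vol_dim(lev$vol))
})

test_that("registration is deterministic for a fixed seed", {
  pp <- preprocessed_phantom()
  cfg <- registration_config("mi", levels = 1, smoothing_sigma = 4,
                             downsampling = 4, iterations = 40,
                             samples = 512, polish_samples = 2048,
                             polish_iterations = 10, seed = 77)
  a <- register_rigid(pp$cbct$volume, pp$pct$volume, cfg,
                      fixed_mask = pp$cbct$mask)
  b <- register_rigid(pp$cbct$volume, pp$pct$volume, cfg,
                      fixed_mask = pp$cbct$mask)
  expect_identical(a$angles, b$angles)
  expect_identical(a$translation, b$translation)
})
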