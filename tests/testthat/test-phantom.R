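test_that("phantom_spec rejects invalid parameters naming the field", {
  expect_error(phantom_spec(spacing = c(1, -1, 1)), "spacing")
  expect_error(phantom_spec(warp_amplitude = 30, warp_grid_spacing = 48),
               "warp_amplitude")
  expect_error(phantom_spec(jitter = -1), "jitter")
  expect_error(phantom_spec(cbct_axial_fraction = 0), "cbct_axial_fraction")
})

test_that("zero-noise phantom has exact tissue means and exact air", {
  spec <- phantom_spec(jitter = 0, heterogeneity_sd = 0)
  p <- generate_pct(spec)
  fat <- p$labels$data == tissue_codes[["fat"]]
  expect_true(all(p$volume$data[fat] == -100))
  expect_true(all(p$volume$data[p$labels$data == 0L] == -1000))
  muscle <- p$labels$data == tissue_codes[["muscle"]]
  expect_true(all(p$volume$data[muscle] == 50))
})

test_that("phantom generation is bit-identical for a fixed seed", {
  a <- generate_pct(phantom_spec(seed = 42))
  b <- generate_pct(phantom_spec(seed = 42))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$labels$data, b$labels$data)
  c <- generate_pct(phantom_spec(seed = 43))
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("soft tissue dominates the body", {
  p <- default_phantom()
  body <- p$labels$data > 0
  hu <- p$pct$data[body]
  expect_gte(mean(hu >= -400 & hu < 250), 0.8)
})

test_that("tissue labels stay inside their HU class intervals", {
  p <- default_phantom()
  cls <- classify_tissue(p$pct$data)
  for (tissue in c("fat", "muscle")) {
    sel <- p$labels$data == tissue_codes[[tissue]]
    expect_gte(mean(cls[sel] == "soft_tissue"), 0.99)
  }
  expect_gte(mean(cls[p$labels$data == tissue_codes[["soft_bone"]]] ==
                    "soft_bone"), 0.99)
  expect_gte(mean(cls[p$labels$data == tissue_codes[["bone"]]] == "bone"),
             0.99)
  expect_gte(mean(cls[p$labels$data == tissue_codes[["rectal_gas"]]] ==
                    "air"), 0.99)
})

test_that("ground-truth warp respects amplitude, boundary and determinism", {
  spec <- phantom_spec(warp_amplitude = 8)
  w <- make_ground_truth_warp(spec)
  expect_identical(make_ground_truth_warp(spec)$coef, w$coef)
  # zero amplitude gives the identity
  w0 <- make_ground_truth_warp(phantom_spec(warp_amplitude = 0))
  expect_true(all(w0$coef == 0))
  # dense sample of displacement magnitudes bounded by the amplitude
  p <- default_phantom()
  u <- transform_displacement(w, cbcthm:::grid_points(p$pct))
  expect_lte(max(sqrt(rowSums(u^2))), 8 + 1e-9)
  expect_gt(max(sqrt(rowSums(u^2))), 4)   # and the warp is substantial
})

test_that("ground-truth warp is fold-free (positive Jacobian determinant)", {
  w <- make_ground_truth_warp(phantom_spec())
  set.seed(11)
  pts <- cbind(runif(400, 20, 300), runif(400, 20, 300), runif(400, 20, 220))
  h <- 0.5
  jac <- vapply(seq_len(nrow(pts)), function(i) {
    J <- matrix(0, 3, 3)
    for (k in 1:3) {
      e <- rep(0, 3); e[k] <- h
      J[, k] <- (apply_transform(w, matrix(pts[i, ] + e, 1)) -
                   apply_transform(w, matrix(pts[i, ] - e, 1))) / (2 * h)
    }
    det(J)
  }, numeric(1))
  expect_true(all(jac > 0))
})

test_that("ROI boxes lie fully inside a single tissue region", {
  p <- default_phantom()
  expect_gte(length(p$rois), 10)
  for (r in p$rois) {
    patch <- p$labels$data[r$col:(r$col + r$width - 1),
                           r$row:(r$row + r$height - 1), r$slice]
    expect_true(all(patch == r$label))
  }
  labs <- vapply(p$rois, `[[`, integer(1), "label")
  expect_gte(sum(labs == tissue_codes[["fat"]]), 5)
  expect_gte(sum(labs == tissue_codes[["muscle"]]), 5)
})

test_that("identity degradation returns the planning CT unchanged", {
  spec <- phantom_spec(jitter = 0, heterogeneity_sd = 0, warp_amplitude = 0,
                       hu_shift = 0, shading_amplitude = 0, noise_sd = 0,
                       cbct_axial_fraction = 1)
  spec$cbct_spacing <- spec$spacing
  p <- generate_pct(spec)
  w <- make_ground_truth_warp(spec)
  cb <- degrade_to_cbct(p$volume, p$labels, w, spec)
  expect_identical(vol_dim(cb$volume), vol_dim(p$volume))
  expect_equal(cb$volume$data, p$volume$data, tolerance = 1e-9)
})

test_that("a pure HU shift moves inside-body voxels by exactly that shift", {
  spec <- phantom_spec(jitter = 0, heterogeneity_sd = 0, warp_amplitude = 0,
                       hu_shift = -60, shading_amplitude = 0, noise_sd = 0,
                       cbct_axial_fraction = 1)
  spec$cbct_spacing <- spec$spacing
  p <- generate_pct(spec)
  cb <- degrade_to_cbct(p$volume, p$labels, make_ground_truth_warp(spec),
                        spec)
  body <- cb$labels$data > 0
  expect_equal(cb$volume$data[body], p$volume$data[body] - 60,
               tolerance = 1e-9)
  expect_true(all(cb$volume$data[!body] == -1000))
})

test_that("default degradation produces a large volume HU error", {
  ph <- default_phantom()
  mask <- body_mask(ph$cbct_labels$data > 0, ph$cbct$spacing,
                    ph$cbct$origin)
  expect_gt(volume_error(ph$deformed_pct, ph$cbct, mask), 40)
})
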