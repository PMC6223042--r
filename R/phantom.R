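#' Synthetic pelvis phantom specification
#'
#' Parameters of the paired pCT/CBCT phantom generator. The default phantom
#' is a pelvis-like arrangement of parametric ellipsoids: an elliptical body
#' of muscle wrapped in a subcutaneous fat layer, two internal fat pockets,
#' two femoral-head bone ellipsoids with soft-bone rims, and a rectal gas
#' pocket. Default tissue means (air -1000, fat -100, muscle +50, soft bone
#' +400, bone +900 HU) sit at the centres of the tissue-class intervals used
#' by the evaluation module. The CBCT arm of the pair is degraded with a
#' global HU shift, a smooth multiplicative shading (cupping) field,
#' additive Gaussian noise, a reduced axial extent and its own voxel
#' spacing.
#'
#' @param shape Planning-CT grid shape (nx, ny, nz).
#' @param spacing Planning-CT voxel size, mm.
#' @param cbct_spacing CBCT voxel size, mm.
#' @param cbct_axial_fraction Fraction of the pCT axial extent covered by
#'   the CBCT (centred), in (0, 1].
#' @param tissue_hu Named mean HU per tissue (air, fat, muscle, soft_bone,
#'   bone, rectal_gas).
#' @param jitter Per-voxel (uncorrelated) Gaussian HU standard deviation
#'   inside the body.
#' @param heterogeneity_sd Standard deviation (HU) of the smooth
#'   tissue-heterogeneity field added to fat and muscle (at reduced
#'   amplitude to bone), emulating the correlated soft-tissue structure --
#'   vessels, bowel, trabeculae -- that real CT anatomy carries and that
#'   deformable registration tracks; 0 disables it.
#' @param heterogeneity_scale Correlation length (mm) of that field.
#' @param warp_amplitude Maximum ground-truth displacement magnitude, mm;
#'   must be below half `warp_grid_spacing` (fold-free warp).
#' @param warp_grid_spacing Control-grid spacing of the ground-truth
#'   deformation, mm.
#' @param hu_shift Global additive HU bias applied inside the CBCT body.
#' @param shading_amplitude Relative amplitude of the multiplicative
#'   shading field (0.1 = +-10 percent).
#' @param noise_sd CBCT additive Gaussian noise standard deviation, HU.
#' @param seed Integer seed; every generator operation is a pure function of
#'   (spec, seed).
#' @return A validated `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(96, 96, 40),
                         spacing = c(3.3984, 3.3984, 6),
                         cbct_spacing = c(3.5156, 3.5156, 5),
                         cbct_axial_fraction = 0.4,
                         tissue_hu = c(air = -1000, fat = -100, muscle = 50,
                                       soft_bone = 400, bone = 900,
                                       rectal_gas = -1000),
                         jitter = 8, heterogeneity_sd = 25,
                         heterogeneity_scale = 12, warp_amplitude = 8,
                         warp_grid_spacing = 48, hu_shift = -60,
                         shading_amplitude = 0.10, noise_sd = 20, seed = 1) {
  spec <- list(shape = as.integer(shape), spacing = as.numeric(spacing),
               cbct_spacing = as.numeric(cbct_spacing),
               cbct_axial_fraction = cbct_axial_fraction,
               tissue_hu = tissue_hu, jitter = jitter,
               heterogeneity_sd = heterogeneity_sd,
               heterogeneity_scale = heterogeneity_scale,
               warp_amplitude = warp_amplitude,
               warp_grid_spacing = warp_grid_spacing, hu_shift = hu_shift,
               shading_amplitude = shading_amplitude, noise_sd = noise_sd,
               seed = as.integer(seed))
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  req <- c("air", "fat", "muscle", "soft_bone", "bone", "rectal_gas")
  if (length(spec$shape) != 3L || any(spec$shape < 8))
    stop("invalid `shape`: need 3 axes of at least 8 voxels")
  if (any(spec$spacing <= 0) || any(spec$cbct_spacing <= 0))
    stop("invalid `spacing`: voxel sizes must be strictly positive")
  if (spec$cbct_axial_fraction <= 0 || spec$cbct_axial_fraction > 1)
    stop("invalid `cbct_axial_fraction`: must be in (0, 1]")
  if (!all(req %in% names(spec$tissue_hu)))
    stop("invalid `tissue_hu`: missing tissue means")
  if (spec$jitter < 0) stop("invalid `jitter`: must be >= 0")
  if (!is.null(spec$heterogeneity_sd) && spec$heterogeneity_sd < 0)
    stop("invalid `heterogeneity_sd`: must be >= 0")
  if (spec$warp_amplitude < 0)
    stop("invalid `warp_amplitude`: must be >= 0")
  if (spec$warp_amplitude >= spec$warp_grid_spacing / 2)
    stop("invalid `warp_amplitude`: must be below half `warp_grid_spacing`")
  if (spec$noise_sd < 0) stop("invalid `noise_sd`: must be >= 0")
  invisible(spec)
}

# Deterministic per-stage seed derived from a base seed and a label,
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

# Ellipsoid geometry of the phantom, physical mm. Fractions of the in-plane
# extent keep the anatomy proportionate across grid choices.
phantom_geometry <- function(spec) {
  ext <- (spec$shape - 1) * spec$spacing
  ctr <- ext / 2
  a <- 0.43 * ext[1]; b <- 0.34 * ext[2]
  list(
    center = ctr, ext = ext,
    body = list(c = ctr, s = c(a, b, 3 * ext[3])),
    fat_inner = list(c = ctr, s = c(0.78 * a, 0.78 * b, 3 * ext[3])),
    fat_pockets = list(
      list(c = ctr + c(-0.17 * ext[1], 0.12 * ext[2], 0),
           s = c(0.115 * ext[1], 0.09 * ext[2], 0.45 * ext[3])),
      list(c = ctr + c(0.17 * ext[1], 0.12 * ext[2], 0),
           s = c(0.115 * ext[1], 0.09 * ext[2], 0.45 * ext[3]))),
    bones = list(
      list(c = ctr + c(-0.19 * ext[1], -0.08 * ext[2], 0),
           core = c(24, 24, 0.3 * ext[3]), rim = c(32, 32, 0.33 * ext[3])),
      list(c = ctr + c(0.19 * ext[1], -0.08 * ext[2], 0),
           core = c(24, 24, 0.3 * ext[3]), rim = c(32, 32, 0.33 * ext[3]))),
    gas = list(c = ctr + c(0, 0.15 * ext[2], 0), s = c(15, 12, 0.18 * ext[3]))
  )
}

# Logical array: voxels inside an ellipsoid (centre c, semi-axes s, mm).
inside_ellipsoid <- function(X, Y, Z, e) {
  ((X - e$c[1]) / e$s[1])^2 + ((Y - e$c[2]) / e$s[2])^2 +
    ((Z - e$c[3]) / e$s[3])^2 <= 1
}

#' Generate the planning-CT phantom
#'
#' Builds the pelvis-like planning CT, its tissue label map, and
#' automatically placed ROI boxes (at least five each in fat and muscle).
#' Outside the body the HU is exactly -1000; inside, each tissue's mean HU
#' receives Gaussian jitter seeded by `spec$seed`, so the result is
#' bit-identical for a fixed spec.
#'
#' @param spec A [phantom_spec()].
#' @return List with `volume` ([image_volume()]), `labels`
#'   ([label_volume()]), `rois` (list of [roi_box()]).
#' @export
generate_pct <- function(spec) {
  validate_phantom_spec(spec)
  d <- spec$shape
  geo <- phantom_geometry(spec)
  x <- (seq_len(d[1]) - 1) * spec$spacing[1]
  y <- (seq_len(d[2]) - 1) * spec$spacing[2]
  z <- (seq_len(d[3]) - 1) * spec$spacing[3]
  X <- array(rep(x, d[2] * d[3]), d)
  Y <- array(rep(rep(y, each = d[1]), d[3]), d)
  Z <- array(rep(z, each = d[1] * d[2]), d)
  lab <- array(tissue_codes[["air"]], d)
  body <- inside_ellipsoid(X, Y, Z, geo$body)
  lab[body] <- tissue_codes[["muscle"]]
  lab[body & !inside_ellipsoid(X, Y, Z, geo$fat_inner)] <-
    tissue_codes[["fat"]]
  for (p in geo$fat_pockets)
    lab[inside_ellipsoid(X, Y, Z, p)] <- tissue_codes[["fat"]]
  for (bn in geo$bones) {
    lab[inside_ellipsoid(X, Y, Z, list(c = bn$c, s = bn$rim))] <-
      tissue_codes[["soft_bone"]]
    lab[inside_ellipsoid(X, Y, Z, list(c = bn$c, s = bn$core))] <-
      tissue_codes[["bone"]]
  }
  lab[inside_ellipsoid(X, Y, Z, geo$gas)] <- tissue_codes[["rectal_gas"]]
  means <- c(spec$tissue_hu[["air"]], spec$tissue_hu[["fat"]],
             spec$tissue_hu[["muscle"]], spec$tissue_hu[["soft_bone"]],
             spec$tissue_hu[["bone"]], spec$tissue_hu[["rectal_gas"]])
  hu <- array(means[lab + 1L], d)
  het_sd <- if (is.null(spec$heterogeneity_sd)) 0 else spec$heterogeneity_sd
  if (het_sd > 0) {
    # smooth anatomical heterogeneity, carried through the warp into the
    # CBCT arm (full amplitude in soft tissue, reduced in bone, none in gas)
    set.seed(derive_seed(spec$seed, "pct-texture"))
    w <- array(stats::rnorm(prod(d)), d)
    sig <- spec$heterogeneity_scale / spec$spacing
    tex <- cpp_gauss_smooth(as.numeric(w), d, sig)
    tex <- array(tex / stats::sd(tex), d)
    amp <- c(0, 1, 1, 0.6, 0.6, 0)[lab + 1L] * het_sd
    hu <- hu + tex * amp
  }
  if (spec$jitter > 0) {
    set.seed(derive_seed(spec$seed, "pct-noise"))
    inb <- lab > 0L
    hu[inb] <- hu[inb] + stats::rnorm(sum(inb), 0, spec$jitter)
  }
  hu[lab == 0L] <- spec$tissue_hu[["air"]]
  labels <- label_volume(lab, spec$spacing, c(0, 0, 0))
  vol <- image_volume(hu, spec$spacing, c(0, 0, 0))
  rois <- c(place_rois(labels, tissue_codes[["fat"]], 5),
            place_rois(labels, tissue_codes[["muscle"]], 5))
  list(volume = vol, labels = labels, rois = rois)
}

#' Auto-place ROI boxes inside a tissue label
#'
#' Greedy deterministic scan for `n` non-overlapping `size` x `size`
#' in-plane boxes lying entirely inside the given label: slices are visited
#' from the middle outwards, rows and columns in reading order.
#'
#' @param labels A [label_volume()].
#' @param label Tissue code the boxes must cover (see [tissue_codes]).
#' @param n Number of boxes required.
#' @param size In-plane box side, voxels.
#' @return List of `n` [roi_box()]es; errors if fewer fit.
#' @export
place_rois <- function(labels, label, n = 5, size = 10) {
  d <- vol_dim(labels)
  mid <- ceiling(d[3] / 2)
  slices <- unique(c(mid, as.integer(mid + as.vector(rbind(seq_len(d[3]),
                                                           -seq_len(d[3]))))))
  slices <- slices[slices >= 1 & slices <= d[3]]
  out <- list()
  for (s in slices) {
    sl <- labels$data[, , s] == label
    if (!any(sl)) next
    # summed-area table: box fully inside the label iff its sum == size^2
    sat <- apply(apply(sl, 2, cumsum), 1, cumsum)  # sat[j, i] = sum up to (i, j)
    boxsum <- function(cc, r) {                    # corner (col cc, row r)
      i2 <- cc + size - 1; j2 <- r + size - 1
      sat[j2, i2] -
        (if (r > 1) sat[r - 1, i2] else 0) -
        (if (cc > 1) sat[j2, cc - 1] else 0) +
        (if (r > 1 && cc > 1) sat[r - 1, cc - 1] else 0)
    }
    used <- matrix(FALSE, d[1], d[2])
    for (r in seq_len(d[2] - size + 1)) {
      for (cc in seq_len(d[1] - size + 1)) {
        if (boxsum(cc, r) != size * size) next
        xs <- cc:(cc + size - 1); ys <- r:(r + size - 1)
        if (any(used[xs, ys])) next
        used[xs, ys] <- TRUE
        out[[length(out) + 1L]] <- roi_box(s, r, cc, size, size, label)
        if (length(out) >= n) return(out)
      }
    }
  }
  if (length(out) < n)
    stop(sprintf("could only place %d of %d ROI boxes for label %d",
                 length(out), n, label))
  out
}

#' Ground-truth deformation between the phantom time points
#'
#' Cubic B-spline transform over the planning-CT domain with random
#' control-point displacements drawn from the spec's seed. Per-component
#' displacements are bounded by `warp_amplitude / sqrt(3)` so the field
#' magnitude never exceeds `warp_amplitude`; control points within one grid
#' spacing of the domain boundary (or outside it) are zeroed, so
#' displacements taper to zero in a boundary band. The amplitude bound
#' below half the grid spacing keeps the warp fold-free.
#'
#' @param spec A [phantom_spec()].
#' @return A B-spline `spatial_transform`.
#' @export
make_ground_truth_warp <- function(spec) {
  validate_phantom_spec(spec)
  ext <- (spec$shape - 1) * spec$spacing
  gs <- spec$warp_grid_spacing
  dom <- image_volume(array(0, c(2, 2, 2)), ext, c(0, 0, 0))  # geometry only
  grid <- bspline_grid(dom, gs, gs)
  ncp <- prod(grid$dim)
  set.seed(derive_seed(spec$seed, "warp"))
  coef <- matrix(stats::runif(ncp * 3, -1, 1) * spec$warp_amplitude / sqrt(3),
                 ncp, 3)
  pos <- arrayInd(seq_len(ncp), grid$dim)
  phys <- sweep(sweep(pos - 1, 2, rep(gs, 3), "*"), 2, grid$origin, "+")
  margin <- gs
  keep <- phys[, 1] >= margin & phys[, 1] <= ext[1] - margin &
    phys[, 2] >= margin & phys[, 2] <= ext[2] - margin &
    phys[, 3] >= margin & phys[, 3] <= ext[3] - margin
  coef[!keep, ] <- 0
  tr <- transform_bspline(grid$origin, rep(gs, 3), grid$dim, coef)
  # B-spline averaging shrinks the realized field well below the coefficient
  # bound; rescale so the dense-field maximum equals the requested amplitude
  # (still well below the fold-free control-displacement limit).
  if (spec$warp_amplitude > 0 && any(coef != 0)) {
    step <- spec$spacing
    xs <- seq(0, ext[1], by = step[1]); ys <- seq(0, ext[2], by = step[2])
    zs <- seq(0, ext[3], by = step[3])
    pts <- as.matrix(expand.grid(xs, ys, zs))
    mag <- sqrt(rowSums(transform_displacement(tr, pts)^2))
    mmax <- max(mag)
    if (mmax > 0) tr$coef <- coef * (spec$warp_amplitude / mmax)
  }
  tr
}

#' Reference grid of the CBCT arm of a phantom pair
#'
#' The CBCT grid shares the phantom's in-plane centre, uses the CBCT voxel
#' spacing, and covers the central `cbct_axial_fraction` of the pCT axial
#' extent.
#'
#' @param spec A [phantom_spec()].
#' @return An empty [image_volume()] carrying the CBCT grid geometry.
#' @export
cbct_reference_grid <- function(spec) {
  ext <- (spec$shape - 1) * spec$spacing
  ctr <- ext / 2
  zext <- spec$cbct_axial_fraction * ext[3]
  nd <- c(floor(ext[1] / spec$cbct_spacing[1]) + 1,
          floor(ext[2] / spec$cbct_spacing[2]) + 1,
          floor(zext / spec$cbct_spacing[3]) + 1)
  org <- ctr - (nd - 1) * spec$cbct_spacing / 2
  image_volume(array(0, nd), spec$cbct_spacing, org)
}

# Smooth in-plane shading (cupping) field plus a seeded low-frequency
# random component, normalized to [-1, 1] before scaling.
shading_field <- function(pts, geo, spec) {
  rho2 <- ((pts[, 1] - geo$center[1]) / geo$body$s[1])^2 +
    ((pts[, 2] - geo$center[2]) / geo$body$s[2])^2
  radial <- 2 * pmin(rho2, 1) - 1          # -1 at axis, +1 at body edge
  set.seed(derive_seed(spec$seed, "cbct-shading"))
  lf <- numeric(nrow(pts))
  for (k in 1:3) {
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    lambda <- stats::runif(1, 150, 300)
    phase <- stats::runif(1, 0, 2 * pi)
    lf <- lf + cos(2 * pi * (pts %*% dir) / lambda + phase)
  }
  lf <- as.numeric(lf) / max(abs(lf))
  1 + spec$shading_amplitude * (0.7 * radial + 0.3 * lf)
}

#' Degrade the planning CT into its CBCT counterpart
#'
#' Warps the planning CT by the ground-truth deformation, resamples it onto
#' the CBCT grid (different spacing, reduced axial extent), and applies the
#' CBCT artifact model inside the body: `v -> v * s(x) + b + eps`, with
#' `s` the smooth multiplicative shading field, `b` the global HU shift and
#' `eps` Gaussian noise. Outside-body voxels stay exactly -1000.
#' Deterministic for a fixed spec.
#'
#' @param pct Planning-CT [image_volume()] from [generate_pct()].
#' @param labels Matching [label_volume()].
#' @param warp Ground-truth `spatial_transform` from
#'   [make_ground_truth_warp()].
#' @param spec The [phantom_spec()].
#' @return List with `volume` (the CBCT [image_volume()]), `labels`
#'   (ground-truth labels on the CBCT grid), `deformed_pct` (noise-free
#'   warped pCT on the CBCT grid).
#' @export
degrade_to_cbct <- function(pct, labels, warp, spec) {
  stopifnot_same_grid(pct, labels, "pct and labels")
  ref <- cbct_reference_grid(spec)
  def <- resample(pct, warp, ref, "linear", -1000)
  lab <- resample(labels, warp, ref, "nearest", 0)
  body <- lab$data > 0
  v <- def$data
  if (any(body)) {
    pts <- grid_points(ref)[as.vector(body), , drop = FALSE]
    geo <- phantom_geometry(spec)
    s <- shading_field(pts, geo, spec)
    set.seed(derive_seed(spec$seed, "cbct-noise"))
    eps <- if (spec$noise_sd > 0) stats::rnorm(sum(body), 0, spec$noise_sd)
           else 0
    v[body] <- v[body] * s + spec$hu_shift + eps
  }
  v[!body] <- -1000
  list(volume = image_volume(v, ref$spacing, ref$origin), labels = lab,
       deformed_pct = def)
}

#' Generate a full phantom subject
#'
#' Convenience wrapper running [generate_pct()],
#' [make_ground_truth_warp()] and [degrade_to_cbct()] for one spec.
#'
#' @param spec A [phantom_spec()].
#' @return List with `pct`, `labels`, `rois`, `warp`, `cbct`, `cbct_labels`,
#'   `deformed_pct` (ground-truth warped pCT on the CBCT grid).
#' @export
generate_phantom_pair <- function(spec) {
  p <- generate_pct(spec)
  warp <- make_ground_truth_warp(spec)
  cb <- degrade_to_cbct(p$volume, p$labels, warp, spec)
  list(pct = p$volume, labels = p$labels, rois = p$rois, warp = warp,
       cbct = cb$volume, cbct_labels = cb$labels,
       deformed_pct = cb$deformed_pct)
}
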