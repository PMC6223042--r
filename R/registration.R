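#' Registration configuration
#'
#' Tunable parameters of the rigid and B-spline registration stages.
#' Defaults: 3 pyramid levels with Gaussian smoothing sigma (4, 2, 0.5)
#' voxels and downsampling factors (4, 2, 1) -- the finest level is kept
#' nearly unsmoothed so fine intensity texture survives; B-spline grid spacing
#' schedule (4x, 2x, 1x) of `grid_spacing`; normalized-gradient ASGD with
#' step decay `((A + 1)/(A + t))^alpha`, `A = 20`, `alpha = 0.602`, 384
#' iterations and 4096 freshly drawn off-grid samples per iteration; each
#' level ends with a deterministic quasi-Newton polish (frozen samples for
#' the 6-parameter rigid stage; complete site population with held-out
#' validation for the B-spline stage); 64 histogram bins for MI/NMI.
#'
#' @param metric `"ncc"`, `"mi"` or `"nmi"`.
#' @param levels Number of pyramid levels (>= 1).
#' @param smoothing_sigma Per-level Gaussian sigma, voxels (coarse to fine).
#' @param downsampling Per-level downsampling factor (coarse to fine).
#' @param grid_spacing Final B-spline control-grid spacing, mm.
#' @param iterations ASGD iterations per level.
#' @param samples Random fixed-image samples per iteration.
#' @param polish_samples Frozen sample count for the per-level
#'   deterministic polish.
#' @param polish_iterations Maximum polish ascent steps per level.
#' @param bins Histogram bins for MI/NMI.
#' @param asgd_A,asgd_alpha ASGD decay parameters.
#' @param seed Integer seed driving the stochastic sampler.
#' @return A `registration_config`.
#' @export
registration_config <- function(metric = c("ncc", "mi", "nmi"), levels = 3,
                                smoothing_sigma = c(4, 2, 0.5),
                                downsampling = c(4, 2, 1),
                                grid_spacing = 32, iterations = 384,
                                samples = 4096, polish_samples = 32768,
                                polish_iterations = 200, bins = 64,
                                asgd_A = 20, asgd_alpha = 0.602, seed = 1) {
  metric <- match.arg(metric)
  if (levels < 1) stop("`levels` must be >= 1")
  if (samples < 1) stop("`samples` must be >= 1")
  if (bins < 2) stop("`bins` must be >= 2")
  if (length(smoothing_sigma) != levels || length(downsampling) != levels)
    stop("`smoothing_sigma` and `downsampling` must have one entry per level")
  structure(list(metric = metric, levels = levels,
                 smoothing_sigma = smoothing_sigma,
                 downsampling = downsampling, grid_spacing = grid_spacing,
                 iterations = iterations, samples = samples,
                 polish_samples = polish_samples,
                 polish_iterations = polish_iterations, bins = bins,
                 asgd_A = asgd_A, asgd_alpha = asgd_alpha,
                 seed = as.integer(seed)),
            class = "registration_config")
}

# One pyramid level: smoothed, downsampled image plus downsampled mask.
pyramid_level <- function(vol, mask, sigma_vox, factor) {
  sm <- if (sigma_vox > 0) smooth_volume(vol, rep(sigma_vox, 3)) else vol
  if (factor <= 1) return(list(vol = sm, mask = mask))
  d <- vol_dim(vol)
  nd <- pmax(4L, as.integer(floor((d - 1) / factor) + 1))
  nspc <- vol$spacing * factor
  ref <- image_volume(array(0, nd), nspc, vol$origin)
  pts <- grid_points(ref)
  lv <- image_volume(array(interpolate_at(sm, pts, "linear", -1000), nd),
                     nspc, vol$origin)
  lm <- NULL
  if (!is.null(mask)) {
    mv <- array(interpolate_at(
      image_volume(array(as.numeric(mask$data), d), vol$spacing, vol$origin),
      pts, "nearest", 0), nd)
    lm <- body_mask(array(mv > 0.5, nd), nspc, vol$origin)
  }
  list(vol = lv, mask = lm)
}

# Adaptive stochastic gradient ascent (ASGD). grad_fn(par) returns the
# stochastic gradient of the metric to maximize, from a fresh random
# sample. Steps follow the normalized gradient with a decaying magnitude
# step0 * ((A + 1)/(A + t))^alpha, so the largest parameter moves by at
# most step0 per iteration regardless of the (unknown) gradient scale.
# The artificial time t stays low (large steps) while successive gradients
# agree and advances (decaying steps) once they start to oppose near the
# optimum; a deterministic polish afterwards supplies the final precision.
asgd_maximize <- function(par, grad_fn, iterations, step0, A = 20,
                          alpha = 0.602, bound = Inf, average = 0) {
  tcur <- 0
  gprev <- NULL
  omega <- NULL
  n_avg <- max(1L, ceiling(iterations * average))
  acc <- NULL
  for (it in seq_len(iterations)) {
    g <- grad_fn(par)
    mx <- max(abs(g))
    if (mx >= 1e-300) {   # skip flat/degenerate draws
      par <- par + (step0 * ((A + 1) / (A + tcur))^alpha) * g / mx
      if (is.finite(bound)) par <- pmin(pmax(par, -bound), bound)
      if (!is.null(gprev)) {
        # agreement keeps t low (fast traversal); oscillation advances it
        ip <- sum(g * gprev)
        if (is.null(omega)) omega <- abs(ip) + 1e-300
        omega <- 0.9 * omega + 0.1 * abs(ip)
        tcur <- max(0, tcur + 1.5 / (1 + exp(ip / omega)) - 0.5)
      }
      gprev <- g
    }
    if (average > 0 && it > iterations - n_avg)
      acc <- if (is.null(acc)) par else acc + par
  }
  # trailing (Polyak) average: unbiased jitter reduction for the
  # high-dimensional stage, where a frozen-sample polish would overfit
  if (average > 0 && !is.null(acc)) acc / n_avg else par
}

# Deterministic quasi-Newton polish on a frozen sample set. vg_fn(par)
# returns list(value, grad) (or NULL when degenerate); the frozen samples
# make the objective deterministic, so L-BFGS converges cleanly to its
# optimum instead of jittering around it like the stochastic phase.
# Returns list(par, value).
polish_maximize <- function(par, vg_fn, iterations = 60, step0 = 1,
                            bound = Inf) {
  cur <- vg_fn(par)
  if (is.null(cur)) return(list(par = par, value = NA_real_))
  fn <- function(p) {
    r <- vg_fn(p)
    if (is.null(r)) 1e10 else -r$value
  }
  gr <- function(p) {
    r <- vg_fn(p)
    if (is.null(r)) numeric(length(p)) else -r$grad
  }
  o <- stats::optim(par, fn, gr, method = "L-BFGS-B",
                    lower = -bound, upper = bound,
                    control = list(maxit = iterations, factr = 1e4))
  if (-o$value >= cur$value) list(par = o$par, value = -o$value)
  else list(par = par, value = cur$value)
}

# Metric value and d(metric)/d(moving value) per sample, for maximization.
# s carries paired fixed/moving samples; ranges are fixed per level for
# MI/NMI so the histogram geometry is stable across iterations.
metric_and_dm <- function(metric, s, bins, f_range, m_range) {
  n <- length(s$f)
  if (n < 8) return(NULL)
  if (metric == "ncc") {
    fc <- s$f - mean(s$f)
    mc <- s$m - mean(s$m)
    sf <- sum(fc^2); sm <- sum(mc^2)
    if (sf == 0 || sm == 0) return(NULL)
    ncc <- sum(fc * mc) / sqrt(sf * sm)
    dm <- (fc - ncc * sqrt(sf / sm) * mc) / sqrt(sf * sm)
    return(list(value = ncc, dm = dm))
  }
  h <- joint_histogram_from_samples(s$f, s$m, bins, parzen = TRUE,
                                    f_range = f_range, m_range = m_range)
  logp <- log(pmax(h$p, 1e-300))
  logpm <- log(pmax(h$pm, 1e-300))
  fbin <- pmin(pmax(floor((s$f - f_range[1]) / h$f_width), 0), bins - 1)
  mcoord <- pmin(pmax((s$m - m_range[1]) / h$m_width - 0.5, 0), bins - 1)
  terms <- cpp_entropy_grad_terms(as.integer(fbin), as.numeric(mcoord),
                                  logp, logpm)
  A <- terms[, 1]; B <- terms[, 2]
  if (metric == "mi") {
    mi <- metric_mi(h)
    dm <- (A - B) / (n * h$m_width)
    return(list(value = mi, dm = dm))
  }
  hj <- shannon_entropy(h$p)
  if (hj <= 0) return(NULL)
  hf <- shannon_entropy(h$pf); hm <- shannon_entropy(h$pm)
  nmi <- (hf + hm) / hj
  # dNMI/dc_i = (-B_i * H_J + (H_F + H_M) * A_i) / (N * H_J^2)
  dm <- (-B * hj + (hf + hm) * A) / (n * hj^2 * h$m_width)
  list(value = nmi, dm = dm)
}

#' Rigid 3D pre-alignment by mutual information
#'
#' Optimizes a 6-DOF rigid transform (rotation about the fixed-image centre
#' plus translation) maximizing mutual information over a multi-resolution
#' pyramid: adaptive stochastic gradient ascent with freshly drawn off-grid
#' samples each iteration, followed at each level by a deterministic polish
#' on a frozen sample set. Deterministic for a given seed.
#'
#' @param fixed,moving Preprocessed [image_volume()]s (fixed = CBCT,
#'   moving = planning CT in the standard workflow).
#' @param cfg A [registration_config()]; the metric is forced to MI for this
#'   stage.
#' @param fixed_mask Optional [body_mask()] restricting metric evaluation;
#'   the whole fixed volume is used when `NULL`.
#' @return A rigid `spatial_transform`, with attribute `metric_value`.
#' @export
register_rigid <- function(fixed, moving, cfg = registration_config("mi"),
                           fixed_mask = NULL) {
  set.seed(cfg$seed)
  center <- vol_center(fixed)
  # rotation parameters are scaled by the image radius so a unit step in any
  # scaled parameter moves points by a comparable distance in mm
  rscale <- mean(vol_extent(fixed)) / 2
  if (rscale <= 0) rscale <- 1
  par <- rep(0, 6)  # (scaled angles, translation mm)
  val <- NA_real_
  for (lev in seq_len(cfg$levels)) {
    fl <- pyramid_level(fixed, fixed_mask, cfg$smoothing_sigma[lev],
                        cfg$downsampling[lev])
    ml <- pyramid_level(moving, NULL, cfg$smoothing_sigma[lev],
                        cfg$downsampling[lev])
    f_range <- if (!is.null(fl$mask)) range(fl$vol$data[fl$mask$data])
               else range(fl$vol$data)
    m_range <- range(ml$vol$data)
    step0 <- max(fl$vol$spacing) / 2
    vg_for <- function(dom) {
      function(par) {
        tr <- transform_rigid(par[1:3] / rscale, par[4:6], center)
        s <- sample_pair(ml$vol, tr, dom, gradient = TRUE)
        md <- metric_and_dm("mi", s, cfg$bins, f_range, m_range)
        if (is.null(md)) return(NULL)
        d <- md$dm * s$grad   # N x 3: dMetric/dm_i * dI_M/dy
        xc <- sweep(s$pts, 2, center, "-")
        dR <- rotation_matrix_derivs(par[1:3] / rscale)
        g <- numeric(6)
        for (k in 1:3)
          g[k] <- sum(d * (xc %*% t(dR[[k]]))) / rscale
        g[4:6] <- colSums(d)
        list(value = md$value, grad = g)
      }
    }
    grad_fn <- function(par) {
      r <- vg_for(draw_jittered_samples(fl$vol, fl$mask, cfg$samples))(par)
      if (is.null(r)) rep(0, 6) else r$grad
    }
    par <- asgd_maximize(par, grad_fn, cfg$iterations, step0,
                         cfg$asgd_A, cfg$asgd_alpha)
    pol <- polish_maximize(
      par, vg_for(draw_jittered_samples(fl$vol, fl$mask,
                                        cfg$polish_samples)),
      cfg$polish_iterations, step0)
    par <- pol$par
    val <- pol$value
  }
  out <- transform_rigid(par[1:3] / rscale, par[4:6], center)
  attr(out, "metric_value") <- val
  out
}

# Control grid covering the fixed-image physical domain at the coarsest
# level spacing, nested across dyadic refinements. The origin sits one
# coarse spacing before the image origin so every image point has full
# 4x4x4 cubic support at every level.
bspline_grid <- function(fixed, spacing_coarse, spacing_level) {
  gorigin <- fixed$origin - spacing_coarse
  cmax <- (fixed$origin + vol_extent(fixed) - gorigin) / spacing_level
  gdim <- as.integer(floor(cmax) + 3)
  list(origin = gorigin, spacing = spacing_level, dim = gdim)
}

# Dyadic refinement of cubic B-spline coefficients along one axis:
# halved knot spacing, identical field.
refine_axis <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  dim(a) <- c(n, prod(d[-axis]))
  pad <- rbind(0, a, 0)   # implicit zero coefficients beyond the grid
  even <- (pad[1:n, , drop = FALSE] + 6 * pad[2:(n + 1), , drop = FALSE] +
             pad[3:(n + 2), , drop = FALSE]) / 8
  odd <- (pad[2:(n + 1), , drop = FALSE][-n, , drop = FALSE] +
            pad[3:(n + 2), , drop = FALSE][-n, , drop = FALSE]) / 2
  out <- matrix(0, 2 * n - 1, ncol(a))
  out[seq(1, 2 * n - 1, by = 2), ] <- even
  out[seq(2, 2 * n - 2, by = 2), ] <- odd
  dim(out) <- c(2 * n - 1, d[-axis])
  aperm(out, order(perm))
}

refine_coefs <- function(coef, gdim) {
  arrs <- lapply(1:3, function(k) array(coef[, k], gdim))
  for (ax in 1:3) arrs <- lapply(arrs, refine_axis, axis = ax)
  ndim <- dim(arrs[[1]])
  list(coef = cbind(as.numeric(arrs[[1]]), as.numeric(arrs[[2]]),
                    as.numeric(arrs[[3]])),
       dim = as.integer(ndim))
}

# Pad a coefficient grid with zero rows at the high end of each axis so it
# reaches at least `target` control points per axis.
pad_coefs <- function(coef, gdim, target) {
  arrs <- lapply(1:3, function(k) {
    a <- array(coef[, k], gdim)
    pd <- pmax(target - gdim, 0)
    if (any(pd > 0)) {
      b <- array(0, gdim + pd)
      b[seq_len(gdim[1]), seq_len(gdim[2]), seq_len(gdim[3])] <- a
      a <- b
    }
    a
  })
  list(coef = cbind(as.numeric(arrs[[1]]), as.numeric(arrs[[2]]),
                    as.numeric(arrs[[3]])),
       dim = as.integer(pmax(gdim, target)))
}

#' Multi-resolution B-spline deformable registration
#'
#' Free-form deformation on a cubic B-spline control grid placed over the
#' fixed image, refined dyadically across pyramid levels
#' (`grid_spacing * 4, * 2, * 1` for three levels), maximizing the
#' configured similarity metric (NCC, MI or NMI) by adaptive stochastic
#' gradient ascent with a fresh random sample of fixed-image sites at each
#' iteration, plus a deterministic polish per level. The result composes
#' the initial transform with the estimated displacement field: points are
#' mapped through `init`, then displaced.
#'
#' @inheritParams register_rigid
#' @param init Initial `spatial_transform` (typically the rigid stage
#'   result); composed into the returned transform.
#' @param cfg A [registration_config()] selecting the metric.
#' @return A composite `spatial_transform` (init, then B-spline), with
#'   attribute `metric_value`.
#' @export
register_bspline <- function(fixed, moving, init = transform_identity(),
                             cfg = registration_config("ncc"),
                             fixed_mask = NULL) {
  set.seed(cfg$seed + 1L)
  spacing_coarse <- cfg$grid_spacing * 2^(cfg$levels - 1)
  grid <- bspline_grid(fixed, spacing_coarse, spacing_coarse)
  coef <- matrix(0, prod(grid$dim), 3)
  val <- NA_real_
  for (lev in seq_len(cfg$levels)) {
    spc <- cfg$grid_spacing * 2^(cfg$levels - lev)
    if (lev > 1) {
      r <- refine_coefs(coef, grid$dim)
      want <- bspline_grid(fixed, spacing_coarse, spc)
      p <- pad_coefs(r$coef, r$dim, want$dim)
      coef <- p$coef
      grid <- list(origin = want$origin, spacing = rep(spc, 3), dim = p$dim)
    } else {
      grid$spacing <- rep(spc, 3)
    }
    fl <- pyramid_level(fixed, fixed_mask, cfg$smoothing_sigma[lev],
                        cfg$downsampling[lev])
    ml <- pyramid_level(moving, NULL, cfg$smoothing_sigma[lev],
                        cfg$downsampling[lev])
    f_range <- if (!is.null(fl$mask)) range(fl$vol$data[fl$mask$data])
               else range(fl$vol$data)
    m_range <- range(ml$vol$data)
    # control-point displacements live on the scale of the warp itself;
    # step relative to the full-resolution voxel, not the level voxel
    step0 <- max(fixed$spacing) / 2
    gdim <- grid$dim
    gorig <- grid$origin
    gspc <- grid$spacing
    vg_for <- function(dom) {
      z <- apply_transform(init, dom$points)
      gcoord <- sweep(sweep(z, 2, gorig, "-"), 2, gspc, "/")
      function(cf) {
        y <- z + cpp_bspline_disp(matrix(cf, ncol = 3), gdim, gcoord)
        idx <- phys_to_index(ml$vol, y)
        r <- cpp_interp3_grad(as.numeric(ml$vol$data), vol_dim(ml$vol), idx,
                              -1000)
        keep <- r$inside
        s <- list(f = dom$values[keep], m = r$value[keep],
                  grad = sweep(r$grad[keep, , drop = FALSE], 2,
                               ml$vol$spacing, "/"))
        md <- metric_and_dm(cfg$metric, s, cfg$bins, f_range, m_range)
        if (is.null(md)) return(NULL)
        d <- md$dm * s$grad
        list(value = md$value,
             grad = as.numeric(cpp_bspline_param_grad(
               gdim, gcoord[keep, , drop = FALSE], d)))
      }
    }
    grad_fn <- function(cf) {
      r <- vg_for(draw_jittered_samples(fl$vol, fl$mask, cfg$samples))(cf)
      if (is.null(r)) numeric(length(cf)) else r$grad
    }
    # fold-free validity bound on control displacements (cubic B-spline
    # FFDs stay diffeomorphic below ~grid_spacing / 2.48 per axis); no
    # frozen-sample polish here -- with thousands of parameters it would
    # overfit the frozen set, so precision comes from trailing averaging
    bound <- spc / 2.48
    coef <- pmin(pmax(as.numeric(coef), -bound), bound)
    coef <- asgd_maximize(coef, grad_fn, cfg$iterations, step0,
                          cfg$asgd_A, cfg$asgd_alpha, bound = bound,
                          average = 1 / 3)
    # deterministic polish with held-out validation: optimize on half of
    # the fixed-image sites, stop once the metric on the other half stops
    # improving -- without it the many-parameter FFD chases image noise
    full <- sampling_domain(fl$vol, fl$mask)
    odd <- seq_len(full$count) %% 2 == 1
    train <- list(points = full$points[odd, , drop = FALSE],
                  values = full$values[odd], count = sum(odd))
    heldout <- list(points = full$points[!odd, , drop = FALSE],
                    values = full$values[!odd], count = sum(!odd))
    vg_train <- vg_for(train)
    vg_val <- vg_for(heldout)
    best <- coef
    vb <- vg_val(coef)
    best_val <- if (is.null(vb)) -Inf else vb$value
    bad <- 0
    for (chunk in seq_len(ceiling(cfg$polish_iterations / 5))) {
      pol <- polish_maximize(coef, vg_train, 5, step0, bound = bound)
      if (max(abs(pol$par - coef)) < 1e-10) { coef <- pol$par; break }
      coef <- pol$par
      vv <- vg_val(coef)
      if (is.null(vv)) break
      if (vv$value > best_val) {
        best_val <- vv$value
        best <- coef
        bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= 3) break   # patience: tolerate brief validation dips
      }
    }
    coef <- matrix(best, ncol = 3)
    r <- vg_for(full)(as.numeric(coef))
    if (!is.null(r)) val <- r$value
  }
  bs <- transform_bspline(grid$origin, grid$spacing, grid$dim, coef)
  out <- transform_composite(init, bs)
  attr(out, "metric_value") <- val
  out
}

#' Resample a volume through a transform
#'
#' Evaluates the moving image at transformed reference-grid points,
#' producing the "deformed" volume on the reference grid. Linear
#' interpolation for HU volumes, nearest for label volumes; points mapping
#' outside the moving image get `fill`.
#'
#' @param moving [image_volume()] (or [label_volume()]) to resample.
#' @param transform `spatial_transform` mapping reference points to moving
#'   points.
#' @param reference [image_volume()] supplying the output grid.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Fill value outside the moving domain.
#' @return An [image_volume()] (or [label_volume()] when `moving` is one and
#'   interpolation is nearest) on the reference grid.
#' @export
resample <- function(moving, transform, reference,
                     interpolation = c("linear", "nearest"), fill = -1000) {
  interpolation <- match.arg(interpolation)
  pts <- apply_transform(transform, grid_points(reference))
  v <- interpolate_at(moving, pts, interpolation, fill)
  arr <- array(v, vol_dim(reference))
  if (inherits(moving, "label_volume") && interpolation == "nearest")
    label_volume(arr, reference$spacing, reference$origin)
  else
    image_volume(arr, reference$spacing, reference$origin)
}
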