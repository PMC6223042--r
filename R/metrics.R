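#' Sampling domain for similarity metrics
#'
#' The set of fixed-image voxel sites (physical points, with their fixed
#' intensities) over which a similarity metric is evaluated. With `n = NULL`
#' all voxels (optionally restricted to a mask) are used; otherwise `n`
#' sites are drawn uniformly without replacement.
#'
#' @param fixed The fixed [image_volume()].
#' @param mask Optional [body_mask()] restricting the sites.
#' @param n Number of sites to draw; `NULL` for full sampling.
#' @param seed Optional integer seed for the draw.
#' @return A `sampling_domain`: list with `points` (N x 3 mm), `values`
#'   (fixed HU), `count`.
#' @export
sampling_domain <- function(fixed, mask = NULL, n = NULL, seed = NULL) {
  if (!is.null(mask)) {
    stopifnot_same_grid(fixed, mask, "fixed and mask")
    sel <- which(mask$data)
  } else {
    sel <- seq_along(fixed$data)
  }
  if (length(sel) == 0L) stop("empty sampling domain")
  if (!is.null(n)) {
    if (n < 1) stop("`n` must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    if (n < length(sel)) sel <- sel[sample.int(length(sel), n)]
  }
  d <- vol_dim(fixed)
  ijk <- arrayInd(sel, d)
  pts <- sweep(sweep(ijk - 1, 2, fixed$spacing, "*"), 2, fixed$origin, "+")
  structure(list(points = pts, values = as.numeric(fixed$data[sel]),
                 count = length(sel)),
            class = "sampling_domain")
}

# Random off-grid sample sites within a mask: a voxel is drawn uniformly,
# then jittered uniformly within its extent, and the fixed intensity is
# interpolated there. Off-grid sites avoid the one-sided interpolation
# gradients that on-grid sites produce at exact alignment. Uses the current
# RNG stream.
draw_jittered_samples <- function(vol, mask, n) {
  sel <- if (!is.null(mask)) which(mask$data) else seq_along(vol$data)
  sel <- sel[sample.int(length(sel), min(n, length(sel)),
                        replace = n > length(sel))]
  d <- vol_dim(vol)
  ijk <- arrayInd(sel, d) - 1 +
    matrix(stats::runif(3 * length(sel), -0.5, 0.5), ncol = 3)
  ijk <- sweep(sweep(ijk, 2, pmax(d - 1, 1) - 1e-9, pmin), 2, 0, pmax)
  pts <- sweep(sweep(ijk, 2, vol$spacing, "*"), 2, vol$origin, "+")
  vals <- cpp_interp3(as.numeric(vol$data), d, ijk, -1000)
  list(points = pts, values = vals)
}

# Moving-image values (and optionally gradients) at transformed domain sites.
# Sites mapping outside the moving image are dropped, per the metric
# definition over the overlap domain.
sample_pair <- function(moving, transform, dom, gradient = FALSE) {
  y <- apply_transform(transform, dom$points)
  idx <- phys_to_index(moving, y)
  v <- as.numeric(moving$data)
  if (gradient) {
    r <- cpp_interp3_grad(v, vol_dim(moving), idx, -1000)
    keep <- r$inside
    list(f = dom$values[keep], m = r$value[keep],
         grad = sweep(r$grad[keep, , drop = FALSE], 2, moving$spacing, "/"),
         pts = dom$points[keep, , drop = FALSE],
         y = y[keep, , drop = FALSE], keep = keep)
  } else {
    m <- cpp_interp3(v, vol_dim(moving), idx, NA_real_)
    keep <- !is.na(m)
    list(f = dom$values[keep], m = m[keep],
         pts = dom$points[keep, , drop = FALSE],
         y = y[keep, , drop = FALSE], keep = keep)
  }
}

#' Normalized correlation coefficient between fixed and transformed moving
#'
#' Pearson correlation of fixed intensities and interpolated moving
#' intensities over the sampling domain; both means are taken over the same
#' retained sites. Lies in [-1, 1].
#'
#' @param fixed,moving [image_volume()]s.
#' @param transform A `spatial_transform` mapping fixed to moving points.
#' @param dom A [sampling_domain()].
#' @return Scalar NCC.
#' @export
metric_ncc <- function(fixed, moving, transform = transform_identity(),
                       dom = sampling_domain(fixed)) {
  s <- sample_pair(moving, transform, dom)
  if (length(s$f) < 2L) stop("degenerate sample: fewer than 2 overlapping sites")
  fc <- s$f - mean(s$f)
  mc <- s$m - mean(s$m)
  sf <- sum(fc^2); sm <- sum(mc^2)
  if (sf == 0 || sm == 0)
    stop("degenerate sample: zero intensity variance")
  sum(fc * mc) / sqrt(sf * sm)
}

#' Joint intensity histogram of a fixed/moving pair
#'
#' Equal-width bins span each image's sampled intensity range. The fixed
#' axis is hard-binned; the moving axis uses a cubic B-spline Parzen window
#' when `parzen = TRUE` (the differentiable estimator used during
#' optimization) or hard binning otherwise.
#'
#' @inheritParams metric_ncc
#' @param bins Number of bins per axis (>= 2).
#' @param parzen Use the cubic Parzen window on the moving axis.
#' @param f_range,m_range Optional fixed/moving intensity ranges; default is
#'   the range of the retained samples.
#' @return A `joint_histogram`: list with `counts`, joint probabilities `p`,
#'   marginals `pf`, `pm`, and bin geometry.
#' @export
build_joint_histogram <- function(fixed, moving,
                                  transform = transform_identity(),
                                  dom = sampling_domain(fixed), bins = 32,
                                  parzen = TRUE,
                                  f_range = NULL, m_range = NULL) {
  if (bins < 2) stop("`bins` must be >= 2")
  s <- sample_pair(moving, transform, dom)
  if (length(s$f) == 0L) stop("empty overlap domain")
  joint_histogram_from_samples(s$f, s$m, bins, parzen, f_range, m_range)
}

# Core histogram construction from paired samples.
joint_histogram_from_samples <- function(f, m, bins, parzen = TRUE,
                                         f_range = NULL, m_range = NULL) {
  if (is.null(f_range)) f_range <- range(f)
  if (is.null(m_range)) m_range <- range(m)
  fw <- diff(f_range) / bins
  mw <- diff(m_range) / bins
  if (fw <= 0) fw <- 1   # constant image: single occupied bin
  if (mw <= 0) mw <- 1
  fbin <- pmin(pmax(floor((f - f_range[1]) / fw), 0), bins - 1)
  mcoord <- pmin(pmax((m - m_range[1]) / mw - 0.5, 0), bins - 1)
  counts <- cpp_joint_hist(as.integer(fbin), as.numeric(mcoord),
                           as.integer(bins), parzen)
  p <- counts / sum(counts)
  structure(list(counts = counts, p = p, pf = rowSums(p), pm = colSums(p),
                 bins = bins, f_range = f_range, m_range = m_range,
                 f_width = fw, m_width = mw, n = length(f), parzen = parzen),
            class = "joint_histogram")
}

# Shannon entropy in nats of a probability vector/matrix.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information from a joint histogram
#'
#' `H(I_F) + H(I_M) - H(I_F, I_M)`, entropies in nats.
#'
#' @param h A `joint_histogram` from [build_joint_histogram()].
#' @return Scalar MI (nats), >= 0 up to rounding.
#' @export
metric_mi <- function(h) {
  shannon_entropy(h$pf) + shannon_entropy(h$pm) - shannon_entropy(h$p)
}

#' Normalized mutual information from a joint histogram
#'
#' `(H(I_F) + H(I_M)) / H(I_F, I_M)`, equivalently `1 + MI / H_joint`.
#'
#' @inheritParams metric_mi
#' @return Scalar NMI (dimensionless, >= 1 up to rounding).
#' @export
metric_nmi <- function(h) {
  hj <- shannon_entropy(h$p)
  if (hj <= 0)
    stop("degenerate sample: zero joint entropy (both images constant)")
  (shannon_entropy(h$pf) + shannon_entropy(h$pm)) / hj
}
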