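#' 3D image volume in physical (mm) space
#'
#' The common currency of every pipeline stage: a 3D scalar array of
#' Hounsfield units plus grid geometry. Arrays use R convention, dim
#' `(nx, ny, nz)` with 1-based indices; the physical position of voxel
#' `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`. No rotation is
#' stored on the image; orientation differences are handled by transforms.
#'
#' @param data 3D numeric array.
#' @param spacing Per-axis voxel size in mm, length 3, strictly positive.
#' @param origin Physical position (mm) of voxel (1, 1, 1), length 3.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values")
  if (any(!is.finite(data)))
    stop("`data` must be all finite")
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Integer tissue-label volume
#'
#' Same geometry as [image_volume()]; voxel values are integer tissue codes
#' (see [tissue_codes]).
#'
#' @inheritParams image_volume
#' @return An object of class `c("label_volume", "image_volume")`.
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "integer"
  v <- image_volume(data, spacing, origin)
  class(v) <- c("label_volume", class(v))
  v
}

#' Tissue label codes used by the phantom generator
#'
#' Named integer vector: air 0, fat 1, muscle 2, soft bone 3, bone 4,
#' rectal gas 5.
#' @export
tissue_codes <- c(air = 0L, fat = 1L, muscle = 2L, soft_bone = 3L,
                  bone = 4L, rectal_gas = 5L)

#' Body mask on an image grid
#'
#' Logical array with the geometry of its source volume. The shipped mask is
#' hole-filled, so interior gas pockets are inside the mask even though their
#' HU lies below the surface threshold used to build it.
#'
#' @inheritParams image_volume
#' @return An object of class `c("body_mask", "image_volume")`.
#' @export
body_mask <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  storage.mode(data) <- "logical"
  v <- structure(list(data = data, spacing = as.numeric(spacing),
                      origin = as.numeric(origin)),
                 class = c("body_mask", "image_volume"))
  v
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d, spacing %s mm, origin %s mm\n",
              class(x)[1L], d[1], d[2], d[3],
              paste(signif(x$spacing, 5), collapse = " x "),
              paste(signif(x$origin, 5), collapse = ", ")))
  if (is.numeric(x$data))
    cat(sprintf("  range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Volume dimensions
#' @param vol An [image_volume()].
#' @return Integer vector (nx, ny, nz).
#' @export
vol_dim <- function(vol) dim(vol$data)

# Physical extent covered by voxel centres, per axis (mm).
vol_extent <- function(vol) (vol_dim(vol) - 1) * vol$spacing

# TRUE if a and b share shape, spacing and origin (to tol).
same_grid <- function(a, b, tol = 1e-6) {
  identical(vol_dim(a), vol_dim(b)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stopifnot_same_grid <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share grid shape, spacing and origin", what))
  invisible(TRUE)
}

# Physical coordinates (N x 3) of all voxel centres, x fastest (array order).
grid_points <- function(vol) {
  d <- vol_dim(vol)
  cbind(
    rep.int(vol$origin[1] + (seq_len(d[1]) - 1) * vol$spacing[1], d[2] * d[3]),
    rep.int(rep(vol$origin[2] + (seq_len(d[2]) - 1) * vol$spacing[2],
                each = d[1]), d[3]),
    rep(vol$origin[3] + (seq_len(d[3]) - 1) * vol$spacing[3],
        each = d[1] * d[2])
  )
}

# Physical points (N x 3, mm) -> continuous 0-based voxel coordinates.
phys_to_index <- function(vol, pts) {
  sweep(sweep(pts, 2, vol$origin, "-"), 2, vol$spacing, "/")
}

# Physical centre of the image domain (mm).
vol_center <- function(vol) vol$origin + vol_extent(vol) / 2

#' Interpolate a volume at physical points
#'
#' @param vol An [image_volume()].
#' @param pts N x 3 matrix of physical coordinates (mm).
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Value for points outside the volume domain.
#' @return Numeric vector of length N.
#' @export
interpolate_at <- function(vol, pts, interpolation = c("linear", "nearest"),
                           fill = -1000) {
  interpolation <- match.arg(interpolation)
  idx <- phys_to_index(vol, pts)
  v <- as.numeric(vol$data)
  if (interpolation == "linear")
    cpp_interp3(v, vol_dim(vol), idx, fill)
  else
    cpp_interp3_nearest(v, vol_dim(vol), idx, fill)
}

# Gaussian-smooth a volume; sigma in voxel units per axis.
smooth_volume <- function(vol, sigma_vox) {
  sm <- cpp_gauss_smooth(as.numeric(vol$data), vol_dim(vol),
                         as.numeric(sigma_vox))
  image_volume(array(sm, vol_dim(vol)), vol$spacing, vol$origin)
}
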