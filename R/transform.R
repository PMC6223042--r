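#' Spatial transforms
#'
#' Transforms map fixed-image physical points (mm) to moving-image physical
#' points. Three kinds are provided: `identity`; `rigid`, parameterized by
#' three Euler angles (rad, applied as Rz Ry Rx) and a translation about a
#' stated rotation centre; and `bspline`, a cubic B-spline free-form
#' deformation that adds a displacement field to the input points. Composites
#' apply their members in order.
#'
#' @name spatial-transforms
NULL

#' @rdname spatial-transforms
#' @return A `spatial_transform` object.
#' @export
transform_identity <- function() {
  structure(list(kind = "identity"), class = "spatial_transform")
}

#' @rdname spatial-transforms
#' @param angles Euler angles (rad), length 3: rotation about x, y, z.
#' @param translation Translation (mm), length 3.
#' @param center Rotation centre (mm), length 3.
#' @export
transform_rigid <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(angles) == 3, length(translation) == 3, length(center) == 3)
  structure(list(kind = "rigid", angles = as.numeric(angles),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "spatial_transform")
}

#' @rdname spatial-transforms
#' @param grid_origin Physical position (mm) of control point (1, 1, 1).
#' @param grid_spacing Control-grid spacing (mm), length 3.
#' @param grid_dim Control-grid shape, length 3.
#' @param coef Control-point displacements, `prod(grid_dim)` x 3 matrix (mm),
#'   rows in array order (x fastest).
#' @export
transform_bspline <- function(grid_origin, grid_spacing, grid_dim, coef) {
  grid_dim <- as.integer(grid_dim)
  if (!is.matrix(coef) || nrow(coef) != prod(grid_dim) || ncol(coef) != 3)
    stop("`coef` must be a prod(grid_dim) x 3 matrix")
  if (any(grid_spacing <= 0)) stop("`grid_spacing` must be positive")
  structure(list(kind = "bspline", grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing), grid_dim = grid_dim,
                 coef = coef),
            class = "spatial_transform")
}

#' @rdname spatial-transforms
#' @param ... `spatial_transform` objects, applied in the given order.
#' @export
transform_composite <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !inherits(parts[[1L]], "spatial_transform"))
    parts <- parts[[1L]]
  ok <- vapply(parts, inherits, logical(1), "spatial_transform")
  if (!all(ok)) stop("all members must be spatial transforms")
  # flatten nested composites
  flat <- list()
  for (p in parts) {
    if (p$kind == "composite") flat <- c(flat, p$transforms)
    else if (p$kind != "identity") flat <- c(flat, list(p))
  }
  if (length(flat) == 0L) return(transform_identity())
  if (length(flat) == 1L) return(flat[[1L]])
  structure(list(kind = "composite", transforms = flat),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat(sprintf("<spatial_transform: %s>\n", x$kind))
  if (x$kind == "rigid")
    cat(sprintf("  angles (rad): %s; translation (mm): %s\n",
                paste(signif(x$angles, 4), collapse = ", "),
                paste(signif(x$translation, 4), collapse = ", ")))
  if (x$kind == "bspline")
    cat(sprintf("  grid %s, spacing %s mm, max |disp| %.2f mm\n",
                paste(x$grid_dim, collapse = "x"),
                paste(signif(x$grid_spacing, 4), collapse = "x"),
                max(abs(x$coef))))
  if (x$kind == "composite")
    cat(sprintf("  %d members: %s\n", length(x$transforms),
                paste(vapply(x$transforms, `[[`, "", "kind"),
                      collapse = " -> ")))
  invisible(x)
}

# Rotation matrix Rz(g) %*% Ry(b) %*% Rx(a) for angles = c(a, b, g).
rotation_matrix <- function(angles) {
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

# Derivatives of rotation_matrix w.r.t. each angle; list of three 3x3.
rotation_matrix_derivs <- function(angles) {
  a <- angles[1]; b <- angles[2]; g <- angles[3]
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  dRx <- matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3, 3)
  dRy <- matrix(c(-sin(b), 0, -cos(b), 0, 0, 0, cos(b), 0, -sin(b)), 3, 3)
  dRz <- matrix(c(-sin(g), cos(g), 0, -cos(g), -sin(g), 0, 0, 0, 0), 3, 3)
  list(Rz %*% Ry %*% dRx, Rz %*% dRy %*% Rx, dRz %*% Ry %*% Rx)
}

#' Apply a spatial transform to physical points
#'
#' @param transform A `spatial_transform`.
#' @param pts N x 3 matrix of physical coordinates (mm).
#' @return N x 3 matrix of mapped coordinates (mm).
#' @export
apply_transform <- function(transform, pts) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3)
  switch(transform$kind,
    identity = pts,
    rigid = {
      R <- rotation_matrix(transform$angles)
      ctr <- transform$center
      sweep(sweep(pts, 2, ctr, "-") %*% t(R), 2,
            ctr + transform$translation, "+")
    },
    bspline = {
      g <- sweep(sweep(pts, 2, transform$grid_origin, "-"), 2,
                 transform$grid_spacing, "/")
      pts + cpp_bspline_disp(transform$coef, transform$grid_dim, g)
    },
    composite = {
      for (tr in transform$transforms) pts <- apply_transform(tr, pts)
      pts
    },
    stop("unknown transform kind"))
}

#' Displacement field of a transform at given points
#'
#' @inheritParams apply_transform
#' @return N x 3 matrix `apply_transform(transform, pts) - pts` (mm).
#' @export
transform_displacement <- function(transform, pts) {
  apply_transform(transform, pts) - pts
}

#' Read or write a transform as JSON
#'
#' Rigid transforms store angles/translation/centre; B-spline transforms
#' store the control-grid geometry and per-point displacement triplets;
#' composites store their members in application order.
#'
#' @param transform A `spatial_transform`.
#' @param path File path.
#' @return `write_transform` returns `path` invisibly; `read_transform`
#'   returns the `spatial_transform`.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(transform_to_list(transform), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

transform_to_list <- function(tr) {
  switch(tr$kind,
    identity = list(kind = "identity"),
    rigid = list(kind = "rigid", angles = tr$angles,
                 translation = tr$translation, center = tr$center),
    bspline = list(kind = "bspline", grid_origin = tr$grid_origin,
                   grid_spacing = tr$grid_spacing, grid_dim = tr$grid_dim,
                   coef = unname(tr$coef)),
    composite = list(kind = "composite",
                     transforms = lapply(tr$transforms, transform_to_list)))
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE))
}

transform_from_list <- function(x) {
  switch(x$kind,
    identity = transform_identity(),
    rigid = transform_rigid(x$angles, x$translation, x$center),
    bspline = transform_bspline(x$grid_origin, x$grid_spacing, x$grid_dim,
                                if (is.matrix(x$coef)) x$coef
                                else do.call(rbind, lapply(x$coef, as.numeric))),
    composite = transform_composite(lapply(x$transforms,
                                           transform_from_list)),
    stop("unknown transform kind in file"))
}
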