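#' Extract the patient body mask
#'
#' Thresholds the volume at the modality-specific surface HU, applies a
#' morphological closing, keeps the largest 3D connected component (which
#' discards couch remnants and stray objects), and fills interior holes so
#' that internal gas pockets remain part of the body.
#'
#' @param vol An [image_volume()].
#' @param threshold Surface threshold in HU; voxels at or above it are
#'   foreground. Defaults: -700 for planning CT, -600 for CBCT.
#' @param closing_radius Radius (voxels) of the ball used for closing.
#' @return A [body_mask()].
#' @export
extract_body_mask <- function(vol, threshold = -700, closing_radius = 2) {
  fg <- vol$data >= threshold
  if (!any(fg)) stop("no body found: no voxels at or above the threshold")
  d <- vol_dim(vol)
  m <- as.logical(fg)
  if (closing_radius > 0) {
    m <- cpp_morph(m, d, as.integer(closing_radius), TRUE)
    m <- cpp_morph(m, d, as.integer(closing_radius), FALSE)
  }
  if (!any(m)) stop("no body found: closing removed all foreground")
  m <- cpp_largest_component(m, d)
  m <- cpp_fill_holes(m, d)
  body_mask(array(m, d), vol$spacing, vol$origin)
}

#' Set voxels outside the body to air
#'
#' @param vol An [image_volume()].
#' @param mask A [body_mask()] on the same grid.
#' @param fill HU value for outside-mask voxels (standard CT air, -1000).
#' @return The filled [image_volume()].
#' @export
apply_background_fill <- function(vol, mask, fill = -1000) {
  stopifnot_same_grid(vol, mask, "volume and mask")
  out <- vol$data
  out[!mask$data] <- fill
  image_volume(out, vol$spacing, vol$origin)
}

#' Preprocess a CT or CBCT volume
#'
#' Body-mask extraction followed by background fill to -1000 HU; the
#' automatic analogue of couch removal plus exterior thresholding.
#' Idempotent: preprocessing an already preprocessed volume with the same
#' threshold returns it unchanged.
#'
#' @param vol An [image_volume()].
#' @param modality `"pct"` or `"cbct"`; selects the default threshold
#'   (-700 / -600 HU).
#' @param threshold Optional explicit threshold overriding the modality
#'   default.
#' @param closing_radius Passed to [extract_body_mask()].
#' @return List with elements `volume` (filled) and `mask`.
#' @export
preprocess_volume <- function(vol, modality = c("pct", "cbct"),
                              threshold = NULL, closing_radius = 2) {
  modality <- match.arg(modality)
  if (is.null(threshold))
    threshold <- if (modality == "pct") -700 else -600
  mask <- extract_body_mask(vol, threshold, closing_radius)
  list(volume = apply_background_fill(vol, mask), mask = mask)
}
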