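#' Cumulative histogram of a masked volume
#'
#' Equal-width histogram over the masked intensity range with its normalized
#' cumulative distribution. Restricting to the body mask keeps the dominant
#' -1000 HU background from flattening the intensity map.
#'
#' @param vol An [image_volume()].
#' @param mask A [body_mask()] on the same grid.
#' @param bins Number of equal-width bins (>= 2).
#' @param range Optional intensity range; default is the masked value range.
#' @return A `cumulative_histogram`: list with `edges` (length bins + 1),
#'   `counts`, `cdf` (non-decreasing, last value 1), `n`.
#' @export
build_cdf <- function(vol, mask, bins = 1024, range = NULL) {
  stopifnot_same_grid(vol, mask, "volume and mask")
  if (!any(mask$data)) stop("empty mask")
  if (bins < 2) stop("`bins` must be >= 2")
  v <- vol$data[mask$data]
  if (is.null(range)) range <- base::range(v)
  if (diff(range) <= 0) range <- range + c(-0.5, 0.5)
  edges <- seq(range[1], range[2], length.out = bins + 1)
  bi <- pmin(pmax(floor((v - range[1]) / diff(range) * bins), 0), bins - 1)
  counts <- tabulate(bi + 1L, nbins = bins)
  structure(list(edges = edges, counts = counts,
                 cdf = cumsum(counts) / sum(counts), n = length(v)),
            class = "cumulative_histogram")
}

#' Cumulative-histogram matching lookup table
#'
#' For each source intensity level, the output is the smallest reference
#' level whose cumulative value reaches the source level's cumulative value,
#' linearly interpolated between reference bin edges. The resulting
#' piecewise-linear map is monotone non-decreasing and its outputs lie
#' within the reference intensity range.
#'
#' @param source,reference `cumulative_histogram`s from [build_cdf()].
#' @return An `intensity_mapping`: list with `input` and `output` HU vectors
#'   defining the piecewise-linear map.
#' @export
compute_matching_lut <- function(source, reference) {
  # Inversion nodes use populated bins only: at the upper edge of each
  # occupied bin the CDF is strictly increasing, so empty-bin plateaus
  # (which carry no voxels) cannot drag interpolated outputs downward.
  sp <- which(source$counts > 0)
  rp <- which(reference$counts > 0)
  if (length(sp) == 0L || length(rp) == 0L)
    stop("cannot match empty histograms")
  rx <- c(0, reference$cdf[rp])
  ry <- c(reference$edges[rp[1]], reference$edges[rp + 1])
  input <- c(source$edges[sp[1]], source$edges[sp + 1])
  qs <- c(0, source$cdf[sp])
  out <- stats::approx(x = rx, y = ry, xout = qs, ties = min, rule = 2)$y
  out <- cummax(out)                # monotone by construction; guard ties
  structure(list(input = input, output = out),
            class = "intensity_mapping")
}

#' Apply an intensity mapping inside a mask
#'
#' Masked voxels are transformed through the piecewise-linear map (values
#' beyond its domain clamp to the nearest endpoint); outside-mask voxels are
#' unchanged.
#'
#' @param vol An [image_volume()].
#' @param mapping An `intensity_mapping` from [compute_matching_lut()].
#' @param mask A [body_mask()] on the same grid.
#' @return The corrected [image_volume()].
#' @export
apply_mapping <- function(vol, mapping, mask) {
  stopifnot_same_grid(vol, mask, "volume and mask")
  out <- vol$data
  sel <- mask$data
  out[sel] <- stats::approx(mapping$input, mapping$output, xout = out[sel],
                            ties = min, rule = 2)$y
  image_volume(out, vol$spacing, vol$origin)
}

#' Histogram-match a CBCT against a reference volume
#'
#' Convenience wrapper: builds both masked cumulative histograms over their
#' union intensity range, computes the matching map, and applies it.
#'
#' @param vol Volume to correct (CBCT).
#' @param ref Reference volume (deformed planning CT on the same grid).
#' @param mask [body_mask()] used for both histograms and the correction.
#' @param bins Histogram bins.
#' @return List with `corrected` ([image_volume()]), `lut`
#'   (`intensity_mapping`), `source_cdf`, `reference_cdf`.
#' @export
match_histogram <- function(vol, ref, mask, bins = 1024) {
  rng <- range(vol$data[mask$data], ref$data[mask$data])
  src <- build_cdf(vol, mask, bins, rng)
  tgt <- build_cdf(ref, mask, bins, rng)
  lut <- compute_matching_lut(src, tgt)
  list(corrected = apply_mapping(vol, lut, mask), lut = lut,
       source_cdf = src, reference_cdf = tgt)
}

#' Write an intensity mapping as JSON
#' @param mapping An `intensity_mapping`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_lut <- function(mapping, path) {
  jsonlite::write_json(list(input = mapping$input, output = mapping$output),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(input = x$input, output = x$output),
            class = "intensity_mapping")
}
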