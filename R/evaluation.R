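#' Voxelwise absolute difference map
#'
#' @param ref,test [image_volume()]s on the same grid.
#' @return [image_volume()] of |ref - test|.
#' @export
abs_difference <- function(ref, test) {
  stopifnot_same_grid(ref, test)
  image_volume(abs(ref$data - test$data), ref$spacing, ref$origin)
}

#' Volume HU error (root-mean-square over a mask)
#'
#' The average HU error over the volume: the square root of the mean squared
#' HU difference between reference and test over the masked voxels.
#'
#' @param ref,test [image_volume()]s on the same grid.
#' @param mask [body_mask()] defining the evaluation domain.
#' @return Scalar HU error.
#' @export
volume_error <- function(ref, test, mask) {
  stopifnot_same_grid(ref, test)
  stopifnot_same_grid(ref, mask, "volume and mask")
  if (!any(mask$data)) stop("empty mask")
  sqrt(mean((ref$data[mask$data] - test$data[mask$data])^2))
}

#' Tissue class of an HU value
#'
#' Air below -400 HU; soft tissue in [-400, 250); soft bone in [250, 600];
#' bone above 600. Vectorized.
#'
#' @param hu Numeric HU values.
#' @return Character vector: `"air"`, `"soft_tissue"`, `"soft_bone"`,
#'   `"bone"`.
#' @export
classify_tissue <- function(hu) {
  out <- character(length(hu))
  out[hu < -400] <- "air"
  out[hu >= -400 & hu < 250] <- "soft_tissue"
  out[hu >= 250 & hu <= 600] <- "soft_bone"
  out[hu > 600] <- "bone"
  out
}

#' Mean absolute error binned by reference HU
#'
#' Voxels are assigned to equidistant bins by their reference (planning CT)
#' HU; within each bin the mean |HU_ref - HU_test| is reported. Bin edges
#' are anchored at odd multiples of half the bin width around 0 (default
#' bins [-10, 10), [10, 30), ...), so bin centre c collects reference
#' intensities in [c - 10, c + 10); boundary values go to the upper bin.
#' Empty bins inside the evaluated range carry `NA`, never 0.
#'
#' @inheritParams volume_error
#' @param bin_width Bin width in HU (default 20).
#' @return Data frame (`mae_bin_table`) with columns `bin_center`, `mae`,
#'   `n`, `class` (tissue class of the bin centre).
#' @export
mae_by_bin <- function(ref, test, mask, bin_width = 20) {
  stopifnot_same_grid(ref, test)
  stopifnot_same_grid(ref, mask, "volume and mask")
  if (!any(mask$data)) stop("empty mask")
  if (bin_width <= 0) stop("`bin_width` must be > 0")
  r <- ref$data[mask$data]
  a <- abs(r - test$data[mask$data])
  idx <- floor((r + bin_width / 2) / bin_width)   # bin centre = idx * width
  rng <- range(idx)
  centers <- seq(rng[1], rng[2]) * bin_width
  n <- tabulate(idx - rng[1] + 1L, nbins = length(centers))
  sums <- rep(0, length(centers))
  agg <- tapply(a, idx, sum)
  sums[as.integer(names(agg)) - rng[1] + 1L] <- as.numeric(agg)
  mae <- ifelse(n > 0, sums / n, NA_real_)
  structure(data.frame(bin_center = centers, mae = mae, n = n,
                       class = classify_tissue(centers)),
            class = c("mae_bin_table", "data.frame"))
}

#' Rectangular region of interest on one slice
#'
#' A box of `height` x `width` in-plane voxels (default 10 x 10) on axial
#' slice `slice`, with upper-left corner at 1-based (row, col) =
#' (y, x) voxel indices, sampling a single tissue.
#'
#' @param slice 1-based z index.
#' @param row,col 1-based y and x indices of the box corner.
#' @param height,width Box size in voxels.
#' @param label Tissue label the box samples (see [tissue_codes]).
#' @return A `roi_box`.
#' @export
roi_box <- function(slice, row, col, height = 10, width = 10,
                    label = NA_integer_) {
  structure(list(slice = as.integer(slice), row = as.integer(row),
                 col = as.integer(col), height = as.integer(height),
                 width = as.integer(width), label = as.integer(label)),
            class = "roi_box")
}

#' Mean HU within an ROI box
#'
#' @param vol An [image_volume()].
#' @param roi A [roi_box()] fully inside the volume.
#' @return Scalar mean HU over the box's in-plane voxels.
#' @export
roi_mean <- function(vol, roi) {
  d <- vol_dim(vol)
  if (roi$slice < 1 || roi$slice > d[3] ||
      roi$col < 1 || roi$col + roi$width - 1 > d[1] ||
      roi$row < 1 || roi$row + roi$height - 1 > d[2])
    stop("ROI box lies outside the volume")
  mean(vol$data[roi$col:(roi$col + roi$width - 1),
                roi$row:(roi$row + roi$height - 1), roi$slice])
}

#' Spatial-uniformity RMSD of paired ROI means
#'
#' Root-mean-square difference between paired lists of mean ROI values
#' (reference vs test), one pair per subject or per ROI.
#'
#' @param ref_means,test_means Equal-length numeric vectors.
#' @return Scalar RMSD (HU).
#' @export
uniformity_rmsd <- function(ref_means, test_means) {
  if (length(ref_means) == 0L || length(ref_means) != length(test_means))
    stop("`ref_means` and `test_means` must be nonempty and equal length")
  sqrt(mean((ref_means - test_means)^2))
}

#' Assemble the evaluation report for one subject
#'
#' Computes the volume HU error and binned-MAE table before (raw CBCT) and
#' after (corrected CBCT) histogram matching against the deformed planning
#' CT, plus per-ROI means on all three volumes; every statistic uses the
#' same masked evaluation domain on the CBCT grid.
#'
#' @param pct_def Deformed planning CT on the CBCT grid (reference).
#' @param cbct Raw (uncorrected) CBCT.
#' @param cbct_corr Corrected CBCT.
#' @param mask Shared evaluation [body_mask()].
#' @param rois List of [roi_box()]es (may be empty).
#' @param algo_id Label of the algorithm arm (e.g. "DR-NCC").
#' @param bin_width MAE bin width (HU).
#' @return An `evaluation_report`: list with `verr_before`, `verr_after`,
#'   `mae_before`, `mae_after`, `roi` (data frame of per-ROI means), and
#'   `algo_id`.
#' @export
build_report <- function(pct_def, cbct, cbct_corr, mask, rois = list(),
                         algo_id = "", bin_width = 20) {
  roi_df <- if (length(rois)) {
    data.frame(
      label = vapply(rois, `[[`, integer(1), "label"),
      slice = vapply(rois, `[[`, integer(1), "slice"),
      ref_mean = vapply(rois, function(r) roi_mean(pct_def, r), numeric(1)),
      before_mean = vapply(rois, function(r) roi_mean(cbct, r), numeric(1)),
      after_mean = vapply(rois, function(r) roi_mean(cbct_corr, r),
                          numeric(1)))
  } else {
    data.frame(label = integer(0), slice = integer(0), ref_mean = numeric(0),
               before_mean = numeric(0), after_mean = numeric(0))
  }
  structure(list(
    algo_id = algo_id,
    verr_before = volume_error(pct_def, cbct, mask),
    verr_after = volume_error(pct_def, cbct_corr, mask),
    mae_before = mae_by_bin(pct_def, cbct, mask, bin_width),
    mae_after = mae_by_bin(pct_def, cbct_corr, mask, bin_width),
    roi = roi_df), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s\n", x$algo_id))
  cat(sprintf("  V_err before HM: %.2f HU, after HM: %.2f HU\n",
              x$verr_before, x$verr_after))
  cat(sprintf("  MAE bins: %d before, %d after; ROIs: %d\n",
              nrow(x$mae_before), nrow(x$mae_after), nrow(x$roi)))
  invisible(x)
}

#' Read or write an evaluation report as JSON
#' @param report An `evaluation_report`.
#' @param path File path.
#' @return `write_report` returns `path` invisibly; `read_report` the
#'   report.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(algo_id = report$algo_id, verr_before = report$verr_before,
         verr_after = report$verr_after,
         mae_before = as.data.frame(report$mae_before),
         mae_after = as.data.frame(report$mae_after), roi = report$roi),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("mae_before", "mae_after")) {
    x[[f]] <- as.data.frame(x[[f]])
    x[[f]]$mae <- as.numeric(x[[f]]$mae)
    class(x[[f]]) <- c("mae_bin_table", "data.frame")
  }
  x$roi <- as.data.frame(x$roi)
  structure(x[c("algo_id", "verr_before", "verr_after", "mae_before",
                "mae_after", "roi")], class = "evaluation_report")
}
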