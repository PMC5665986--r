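#' Pixel-wise intersection of two binary masks
#'
#' @param mask1,mask2 logical matrices of identical dimensions.
#' @return logical matrix, TRUE where both inputs are TRUE.
#' @export
overlap_mask <- function(mask1, mask2) {
  if (!identical(dim(mask1), dim(mask2))) stop("mask dimensions differ")
  mask1 & mask2
}

#' Object-based overlap measurements for a scene
#'
#' For each reference-color cluster, records whether it co-localizes with the
#' other channel (shares at least one pixel with any other-color cluster).
#' The summary quantities are the fraction of overlapping reference clusters,
#' the number of connected overlap regions in the channel intersection mask,
#' and the total overlap area in square micrometers
#' (\code{pixels * (scale/1000)^2}).
#'
#' Area and region count are symmetric under a channel swap; the fraction is
#' direction-dependent, which is why the Interaction Factor is normally
#' reported in both directions.
#'
#' @param scene an \code{if_scene}.
#' @param connectivity connectivity used to count overlap regions (default 8,
#'   matching the segmentation default).
#' @return object of class \code{if_overlap}: list with \code{fraction},
#'   \code{n_regions}, \code{area_um2}, \code{per_cluster} (logical, one flag
#'   per reference cluster), \code{n_ref}, \code{scale}.
#' @export
overlap_stats <- function(scene, connectivity = 8) {
  stopifnot(inherits(scene, "if_scene"))
  n <- n_clusters(scene$ref)
  if (n == 0L)
    stop("no reference clusters: overlap fraction is undefined, not zero")
  other <- rasterize(scene$other)
  flags <- vapply(seq_len(n), function(k) any(other[cluster_pixels(scene$ref, k)]),
                  logical(1))
  om <- overlap_mask(rasterize(scene$ref), other)
  npx <- sum(om)
  nreg <- if (npx > 0L) max(label_components(om, connectivity)) else 0L
  structure(list(
    fraction = mean(flags),
    n_regions = nreg,
    area_um2 = npx * (scene$scale / 1000)^2,
    per_cluster = flags,
    n_ref = n,
    scale = scene$scale
  ), class = "if_overlap")
}

#' @export
print.if_overlap <- function(x, ...) {
  cat(sprintf("Overlap: %.1f%% of %d reference clusters; %d regions; %.4f um^2\n",
              100 * x$fraction, x$n_ref, x$n_regions, x$area_um2))
  invisible(x)
}

#' Manders co-localization coefficients
#'
#' M1 is the summed channel-1 intensity over pixels above both thresholds,
#' divided by the summed channel-1 intensity over pixels above the channel-1
#' threshold; M2 is the symmetric quantity for channel 2. Both lie in [0, 1].
#'
#' @param grid1,grid2 numeric intensity matrices of identical dimensions.
#' @param th1,th2 channel thresholds (mask rule is strictly \code{>}).
#' @param roi optional logical ROI matrix.
#' @return named numeric vector \code{c(M1, M2)}.
#' @export
manders <- function(grid1, grid2, th1, th2, roi = NULL) {
  if (!identical(dim(grid1), dim(grid2))) stop("grid dimensions differ")
  if (is.null(roi)) roi <- full_roi(dim(grid1))
  m1 <- (grid1 > th1) & roi
  m2 <- (grid2 > th2) & roi
  if (!any(m1) || !any(m2)) stop("no above-threshold pixels in one channel")
  d1 <- sum(grid1[m1]); d2 <- sum(grid2[m2])
  if (d1 <= 0 || d2 <= 0) stop("zero total above-threshold intensity")
  co <- m1 & m2
  c(M1 = sum(grid1[co]) / d1, M2 = sum(grid2[co]) / d2)
}

#' Pearson correlation of two channels over an ROI
#'
#' Standard product-moment correlation of the pixel intensities inside the
#' ROI (all pixels, no thresholding).
#'
#' @inheritParams manders
#' @return correlation coefficient in [-1, 1].
#' @export
pearson_coloc <- function(grid1, grid2, roi = NULL) {
  if (!identical(dim(grid1), dim(grid2))) stop("grid dimensions differ")
  if (is.null(roi)) roi <- full_roi(dim(grid1))
  v1 <- grid1[roi]; v2 <- grid2[roi]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0)
    stop("zero intensity variance inside ROI")
  stats::cor(v1, v2)
}
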