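## Conventions used throughout:
##  - raster grids are base R matrices, dim = c(height, width), indexed [row, col], 1-based;
##  - external pixel coordinates (CSV/JSON/polygon input) are 0-based, x = col - 1, y = row - 1,
##    pixel (0, 0) top-left;
##  - a cluster is a rigid pixel shape: 0-based (dr, dc) offsets from the top-left corner of its
##    bounding box, plus a 1-based (row, col) anchor for that corner. Moving the anchor never
##    changes shape or area.

#' Construct a set of clusters on a raster grid
#'
#' A cluster set is the container shared by segmentation, randomization and the
#' Interaction Factor estimator: an ordered list of rigid pixel shapes, each
#' with an anchor position, living on a common grid with a physical pixel
#' scale. Cluster order is stable; index \code{k} identifies the same cluster
#' through any re-placement.
#'
#' @param shapes list of integer matrices, one per cluster, with columns
#'   \code{(dr, dc)}: 0-based pixel offsets from the top-left corner of the
#'   cluster's bounding box. Offsets must be normalized (\code{min(dr) == 0},
#'   \code{min(dc) == 0}) and non-empty.
#' @param anchors integer matrix with one row per cluster and columns
#'   \code{(row, col)}: 1-based grid position of each bounding-box corner.
#' @param dim grid dimensions \code{c(height, width)} in pixels.
#' @param scale physical pixel size in nm per pixel (default 20, the rendered
#'   pixel size typical of SMLM reconstructions).
#' @param label channel label, e.g. \code{"green"} or \code{"red"}.
#' @return an object of class \code{if_clusters}.
#' @seealso [segment_clusters()], [rasterize()], [place_random()]
#' @export
cluster_set <- function(shapes, anchors, dim, scale = 20, label = "channel") {
  stopifnot(is.list(shapes), length(dim) == 2L, all(dim >= 1L), scale > 0)
  n <- length(shapes)
  if (n == 0L) {
    anchors <- matrix(integer(0), 0L, 2L)
  } else {
    anchors <- matrix(as.integer(anchors), ncol = 2L)
    if (nrow(anchors) != n) stop("one anchor per cluster is required")
  }
  shapes <- lapply(shapes, function(s) {
    s <- matrix(as.integer(s), ncol = 2L)
    if (nrow(s) == 0L) stop("cluster shapes must be non-empty")
    if (min(s[, 1L]) != 0L || min(s[, 2L]) != 0L)
      stop("shape offsets must be normalized to the bounding-box corner")
    s
  })
  obj <- structure(list(
    shapes = shapes,
    anchors = anchors,
    dim = as.integer(dim),
    scale = scale,
    label = label
  ), class = "if_clusters")
  validate_clusters(obj)
  obj
}

validate_clusters <- function(set) {
  h <- set$dim[1L]; w <- set$dim[2L]
  for (k in seq_along(set$shapes)) {
    s <- set$shapes[[k]]; a <- set$anchors[k, ]
    if (a[1L] < 1L || a[2L] < 1L ||
        a[1L] + max(s[, 1L]) > h || a[2L] + max(s[, 2L]) > w)
      stop("cluster ", k, " has pixels outside the grid")
  }
  invisible(set)
}

#' Number and areas of clusters in a set
#'
#' @param set an \code{if_clusters} object.
#' @return \code{n_clusters}: integer count. \code{cluster_areas}: integer
#'   vector of pixel areas, index-aligned with the set.
#' @export
n_clusters <- function(set) length(set$shapes)

#' @rdname n_clusters
#' @export
cluster_areas <- function(set) vapply(set$shapes, nrow, integer(1))

## linear-index pixel positions of cluster k (column-major, into the h x w grid)
cluster_pixels <- function(set, k) {
  s <- set$shapes[[k]]; a <- set$anchors[k, ]
  h <- set$dim[1L]
  (a[2L] - 1L + s[, 2L]) * h + a[1L] + s[, 1L]
}

## per-cluster linear offsets relative to the anchor's own linear index
shape_lin_offsets <- function(shape, h) shape[, 2L] * h + shape[, 1L]

#' @export
print.if_clusters <- function(x, ...) {
  ar <- cluster_areas(x)
  cat(sprintf("Cluster set '%s': %d clusters on %d x %d grid (%.0f nm/px)\n",
              x$label, n_clusters(x), x$dim[1L], x$dim[2L], x$scale))
  if (length(ar))
    cat(sprintf("  areas (px): min %d, median %.0f, max %d\n",
                min(ar), stats::median(ar), max(ar)))
  invisible(x)
}

#' Render a cluster set as a binary mask
#'
#' Union of all cluster pixels on the set's grid. Signals an error if any
#' cluster pixel falls outside the grid (a corrupted placement).
#'
#' @param set an \code{if_clusters} object.
#' @return logical matrix of the set's grid dimensions.
#' @export
rasterize <- function(set) {
  validate_clusters(set)
  m <- matrix(FALSE, set$dim[1L], set$dim[2L])
  for (k in seq_along(set$shapes)) m[cluster_pixels(set, k)] <- TRUE
  m
}

#' Assemble a two-channel cluster scene
#'
#' A scene pairs a reference-color cluster set with an other-color set over a
#' shared region of interest; it is the unit on which the Interaction Factor
#' is measured or simulated. By the usual convention the reference channel is
#' green, so the fitted quantity for \code{ref} is the "R-G" Interaction
#' Factor.
#'
#' @param ref reference-color \code{if_clusters}.
#' @param other other-color \code{if_clusters}.
#' @param roi logical matrix, the region of interest; defaults to the full
#'   grid.
#' @param scale nm per pixel; defaults to the scale recorded in \code{ref}.
#' @return an object of class \code{if_scene}.
#' @export
cluster_scene <- function(ref, other, roi = NULL, scale = NULL) {
  stopifnot(inherits(ref, "if_clusters"), inherits(other, "if_clusters"))
  if (!identical(ref$dim, other$dim))
    stop("reference and other channel must share grid dimensions")
  if (identical(ref$label, other$label))
    stop("channel labels must be distinct")
  if (is.null(roi)) roi <- matrix(TRUE, ref$dim[1L], ref$dim[2L])
  if (!is.logical(roi) || !identical(dim(roi), as.integer(ref$dim)))
    stop("roi must be a logical matrix matching the grid dimensions")
  if (!any(roi)) stop("roi is empty")
  structure(list(ref = ref, other = other, roi = roi,
                 dim = ref$dim, scale = if (is.null(scale)) ref$scale else scale),
            class = "if_scene")
}

#' Swap the reference and other channels of a scene
#'
#' Used to evaluate the Interaction Factor in the opposite direction (the
#' interaction can be asymmetric, so both directions are normally reported).
#'
#' @param scene an \code{if_scene}.
#' @return the scene with channels exchanged.
#' @export
swap_channels <- function(scene) {
  stopifnot(inherits(scene, "if_scene"))
  scene[c("ref", "other")] <- scene[c("other", "ref")]
  scene
}

#' @export
print.if_scene <- function(x, ...) {
  cat(sprintf("Two-color cluster scene, %d x %d px (%.0f nm/px), ROI %d px\n",
              x$dim[1L], x$dim[2L], x$scale, sum(x$roi)))
  cat(sprintf("  reference '%s': %d clusters;  other '%s': %d clusters\n",
              x$ref$label, n_clusters(x$ref), x$other$label, n_clusters(x$other)))
  tf <- attr(x, "true_f")
  if (!is.null(tf)) cat(sprintf("  simulated at IF = %.3f\n", tf))
  invisible(x)
}
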