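## Placement primitives. A cluster may be anchored anywhere its entire pixel
## shape lies inside the ROI; the valid-anchor set is computed by sliding-
## window containment against a 2D integral image of the ROI: anchors whose
## whole bounding box lies inside the ROI are valid outright, anchors whose
## box covers fewer ROI pixels than the shape's area are invalid, and only
## the remaining band along the ROI boundary is checked pixel by pixel. The
## result is exact (identical to brute-force enumeration).

roi_integral <- function(roi) {
  h <- nrow(roi); w <- ncol(roi)
  I <- matrix(0L, h + 1L, w + 1L)
  I[-1L, -1L] <- t(apply(apply(roi, 2L, cumsum), 1L, cumsum))
  I
}

#' Enumerate valid anchor positions for a cluster shape
#'
#' Positions (1-based top-left bounding-box corner) at which every pixel of
#' the shape lies inside the ROI. Placement "within the ROI" means full
#' containment of the cluster.
#'
#' @param shape integer matrix of (dr, dc) offsets (as in [cluster_set()]).
#' @param roi logical ROI matrix.
#' @param prep optional precomputed internal ROI summary (for reuse across
#'   many shapes).
#' @return integer matrix with columns (row, col); zero rows if the shape fits
#'   nowhere.
#' @export
valid_anchors <- function(shape, roi, prep = NULL) {
  lin <- valid_anchor_lin(shape, roi, prep)
  h <- nrow(roi)
  cbind(row = ((lin - 1L) %% h) + 1L, col = ((lin - 1L) %/% h) + 1L)
}

## same enumeration, returned as linear indices into the full grid (the
## representation the placement loops use)
valid_anchor_lin <- function(shape, roi, prep = NULL) {
  h <- nrow(roi); w <- ncol(roi)
  hr <- max(shape[, 1L]) + 1L; wc <- max(shape[, 2L]) + 1L
  nr <- h - hr + 1L; nc <- w - wc + 1L
  if (nr < 1L || nc < 1L) return(integer(0))
  if (is.null(prep)) prep <- roi_prep(roi)
  I <- prep$integral
  rs <- seq_len(nr); cs <- seq_len(nc)
  # ROI pixels covered by the hr x wc bounding box anchored at each position
  S <- I[rs + hr, cs + wc, drop = FALSE] - I[rs, cs + wc, drop = FALSE] -
    I[rs + hr, cs, drop = FALSE] + I[rs, cs, drop = FALSE]
  full <- S == hr * wc
  idx <- which(full)
  cr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  lin <- (cc - 1L) * h + cr
  cand <- which(!full & S >= nrow(shape))
  if (length(cand)) {
    cr <- ((cand - 1L) %% nr) + 1L
    cc <- ((cand - 1L) %/% nr) + 1L
    clin <- (cc - 1L) * h + cr
    pass <- rep(TRUE, length(cand))
    rv <- prep$vec
    for (o in shape_lin_offsets(shape, h)) pass <- pass & rv[clin + o]
    lin <- c(lin, clin[pass])
  }
  lin
}

roi_prep <- function(roi) list(integral = roi_integral(roi), vec = as.vector(roi))

## accept either the documented (row, col) matrix or an internal linear vector
as_anchor_lin <- function(x, h) {
  if (is.matrix(x)) (x[, 2L] - 1L) * h + x[, 1L] else as.integer(x)
}

anchor_sets <- function(set, roi, prep = NULL) {
  if (is.null(prep)) prep <- roi_prep(roi)
  lapply(set$shapes, valid_anchor_lin, roi = roi, prep = prep)
}

#' Place clusters uniformly at random inside the ROI
#'
#' Each cluster's anchor is drawn uniformly from its valid-anchor set (full
#' containment); shapes are translated rigidly, never rotated or deformed.
#' Clusters of the same color may overlap one another. This is the IF = 0
#' null model.
#'
#' @param set an \code{if_clusters} object.
#' @param roi logical ROI matrix matching the set's grid.
#' @param anchors optional precomputed [valid_anchors()] list (one matrix per
#'   cluster), for reuse across many randomizations.
#' @return the set with new anchor positions.
#' @export
place_random <- function(set, roi, anchors = NULL) {
  if (is.null(anchors)) anchors <- anchor_sets(set, roi)
  h <- set$dim[1L]
  for (k in seq_along(set$shapes)) {
    va <- as_anchor_lin(anchors[[k]], h)
    if (length(va) == 0L)
      stop("cluster ", k, " has no valid position inside the ROI")
    lin <- va[sample.int(length(va), 1L)]
    set$anchors[k, ] <- c(((lin - 1L) %% h) + 1L, ((lin - 1L) %/% h) + 1L)
  }
  set
}

#' Place clusters with IF-elevated overlap probability
#'
#' The placement loop behind both the Interaction Factor model and the scene
#' simulator. For each cluster: (1) draw a random position in the ROI; (2) if
#' \code{f} = 0 keep it; (3) otherwise, if the cluster overlaps at least one
#' pixel of the other channel, keep it; (5) otherwise draw \code{u} uniform on
#' [0, 1); (6) if \code{u > f} keep it; (7) otherwise repeat from (1). The
#' per-cluster overlap probability that this induces is
#' \deqn{p_k(f) = p_k(0) / (1 - (1 - p_k(0)) f),}
#' where \eqn{p_k(0)} is the cluster's overlap probability under uniform
#' placement.
#'
#' A cluster that exhausts \code{max_attempts} keeps its last drawn position;
#' the number of such clusters is returned in the \code{"attempts_exceeded"}
#' attribute (it is nonzero only in pathological settings, e.g. \code{f} near
#' 1 with an unreachable other channel).
#'
#' @param set reference-color \code{if_clusters} to place.
#' @param other_mask logical matrix of the already-placed other channel.
#' @param roi logical ROI matrix.
#' @param f Interaction Factor in [0, 1].
#' @param max_attempts placement attempts per cluster before giving up
#'   (default 10000).
#' @param anchors optional precomputed valid-anchor list.
#' @return the set with new anchors, plus attribute \code{attempts_exceeded}.
#' @export
place_with_if <- function(set, other_mask, roi, f, max_attempts = 10000,
                          anchors = NULL) {
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
    stop("f must be a single value in [0, 1]")
  stopifnot(max_attempts >= 1)
  if (!identical(dim(other_mask), dim(roi))) stop("mask dimensions differ")
  if (is.null(anchors)) anchors <- anchor_sets(set, roi)
  h <- set$dim[1L]
  omv <- as.vector(other_mask)
  exceeded <- 0L
  for (k in seq_along(set$shapes)) {
    va <- as_anchor_lin(anchors[[k]], h)
    nk <- length(va)
    if (nk == 0L)
      stop("cluster ", k, " has no valid position inside the ROI")
    off <- shape_lin_offsets(set$shapes[[k]], h)
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      lin <- va[if (nk == 1L) 1L else sample.int(nk, 1L)]
      if (f == 0) break
      if (any(omv[lin + off])) break
      if (stats::runif(1L) > f) break
      if (attempt >= max_attempts) { exceeded <- exceeded + 1L; break }
    }
    set$anchors[k, ] <- c(((lin - 1L) %% h) + 1L, ((lin - 1L) %/% h) + 1L)
  }
  attr(set, "attempts_exceeded") <- exceeded
  set
}

#' Randomize a scene
#'
#' Re-places a scene's clusters: the other-color set uniformly at random (or
#' kept at its original positions when \code{randomize_both = FALSE}), then
#' the reference-color set by [place_with_if()] against the resulting other
#' mask. With \code{f = 0} and \code{randomize_both = TRUE} this produces the
#' fully random null scene.
#'
#' @param scene an \code{if_scene}.
#' @param f Interaction Factor for the reference placement (default 0).
#' @param randomize_both randomize the other channel too? (default TRUE).
#' @param max_attempts see [place_with_if()].
#' @return a new \code{if_scene} with identical shapes and new positions.
#' @export
randomize_scene <- function(scene, f = 0, randomize_both = TRUE,
                            max_attempts = 10000) {
  stopifnot(inherits(scene, "if_scene"))
  rcs <- roi_prep(scene$roi)
  other <- if (randomize_both) {
    place_random(scene$other, scene$roi, anchors = anchor_sets(scene$other, scene$roi, rcs))
  } else scene$other
  ref <- place_with_if(scene$ref, rasterize(other), scene$roi, f = f,
                       max_attempts = max_attempts,
                       anchors = anchor_sets(scene$ref, scene$roi, rcs))
  out <- cluster_scene(ref, other, scene$roi, scale = scene$scale)
  attr(out, "true_f") <- f
  attr(out, "attempts_exceeded") <- attr(ref, "attempts_exceeded")
  out
}
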