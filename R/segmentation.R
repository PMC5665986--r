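#' Otsu threshold of an intensity grid
#'
#' Exhaustive search over candidate thresholds for the value that maximizes
#' the between-class variance of the (optionally ROI-restricted) intensity
#' histogram. The downstream mask rule is strictly \code{value > threshold}.
#'
#' @param grid numeric matrix of non-negative intensities.
#' @param roi optional logical matrix restricting the histogram; default full
#'   grid.
#' @return the threshold value (one of the intensity values present). Ties are
#'   broken toward the smallest threshold.
#' @examples
#' g <- matrix(10, 10, 10); g[1:2, 1:5] <- 200
#' otsu_threshold(g)                 # strictly between 10 and 200
#' @export
otsu_threshold <- function(grid, roi = NULL) {
  v <- if (is.null(roi)) as.vector(grid) else grid[roi]
  if (!all(is.finite(v))) stop("intensities must be finite")
  u <- sort(unique(v))
  if (length(u) < 2L) stop("constant image inside ROI: no threshold exists")
  cnt <- tabulate(match(v, u), nbins = length(u))
  cw <- cumsum(cnt)                  # class-1 weight (<= u[i])
  cm <- cumsum(cnt * u)              # class-1 first moment
  N <- cw[length(u)]; M <- cm[length(u)]
  i <- seq_len(length(u) - 1L)
  w1 <- cw[i] / N
  m1 <- cm[i] / cw[i]
  m2 <- (M - cm[i]) / (N - cw[i])
  bcv <- w1 * (1 - w1) * (m1 - m2)^2
  u[which.max(bcv)]
}

#' Label connected components of a binary mask
#'
#' Two-pass union-find labeling with selectable pixel connectivity. Labels are
#' assigned in scan order: component 1 is the first encountered scanning rows
#' top to bottom, left to right.
#'
#' @param mask logical matrix.
#' @param connectivity 4 (edge neighbors) or 8 (edge + diagonal neighbors).
#' @return integer matrix of the same dimensions; 0 = background, components
#'   numbered 1..m in scan order.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.logical(mask), is.matrix(mask), connectivity %in% c(4, 8))
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask)
  K <- length(fg)
  out <- matrix(0L, h, w)
  if (K == 0L) return(out)
  rank <- matrix(0L, h, w)
  rank[fg] <- seq_len(K)

  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  edges <- list()
  for (o in offs) {
    dr <- o[1L]; dc <- o[2L]
    r1 <- seq_len(h - dr)
    c1 <- if (dc >= 0L) seq_len(w - dc) else seq.int(1L - dc, w)
    a <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    if (any(a)) {
      ij <- which(a, arr.ind = TRUE)
      ra <- r1[ij[, 1L]]; ca <- c1[ij[, 2L]]
      edges[[length(edges) + 1L]] <-
        cbind(rank[cbind(ra, ca)], rank[cbind(ra + dr, ca + dc)])
    }
  }
  parent <- seq_len(K)
  find <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  if (length(edges)) {
    edges <- do.call(rbind, edges)
    for (e in seq_len(nrow(edges))) {
      ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(K), find, integer(1))

  # scan-order (row-major) relabeling
  rr <- ((fg - 1L) %% h) + 1L
  cc <- ((fg - 1L) %/% h) + 1L
  ord <- order(rr, cc)
  first <- roots[ord][!duplicated(roots[ord])]
  out[fg] <- match(roots, first)
  out
}

#' Segment a thresholded channel into a filtered cluster set
#'
#' Connected components of \code{(grid > threshold) & roi}, with components
#' smaller than \code{min_area} pixels excluded (the filter is strict: an
#' area-4 component is retained under the default). Clusters are ordered by
#' scan order of their first pixel, giving stable indices for the random
#' overlap probabilities.
#'
#' @param grid numeric intensity matrix; may be omitted if \code{mask} is
#'   given directly.
#' @param threshold intensity threshold; the mask rule is strictly
#'   \code{grid > threshold}.
#' @param roi optional logical ROI matrix; clusters are clipped to it.
#' @param mask optional logical matrix used in place of
#'   \code{grid > threshold}.
#' @param min_area minimum component area in pixels (default 4).
#' @param connectivity component connectivity, 4 or 8 (default 8).
#' @param scale nm per pixel recorded in the result (default 20).
#' @param label channel label for the resulting set.
#' @return an \code{if_clusters} object (possibly with 0 clusters).
#' @export
segment_clusters <- function(grid = NULL, threshold = NULL, roi = NULL,
                             mask = NULL, min_area = 4, connectivity = 8,
                             scale = 20, label = "channel") {
  if (is.null(mask)) {
    stopifnot(is.matrix(grid), !is.null(threshold))
    if (threshold < min(grid) || threshold > max(grid))
      stop("threshold outside the intensity range")
    mask <- grid > threshold
  }
  if (!is.null(roi)) {
    if (!identical(dim(roi), dim(mask))) stop("roi dimensions do not match")
    mask <- mask & roi
  }
  lab <- label_components(mask, connectivity = connectivity)
  m <- max(lab)
  shapes <- list(); anchors <- NULL
  if (m > 0L) {
    h <- nrow(lab)
    pix <- which(lab > 0L)
    grp <- split(pix, factor(lab[pix], levels = seq_len(m)))
    keep <- which(vapply(grp, length, integer(1)) >= min_area)
    shapes <- vector("list", length(keep))
    anchors <- matrix(0L, length(keep), 2L)
    for (j in seq_along(keep)) {
      p <- grp[[keep[j]]]
      r <- ((p - 1L) %% h) + 1L
      c <- ((p - 1L) %/% h) + 1L
      a <- c(min(r), min(c))
      shapes[[j]] <- cbind(r - a[1L], c - a[2L])
      anchors[j, ] <- a
    }
  }
  cluster_set(shapes, if (is.null(anchors)) matrix(integer(0), 0, 2) else anchors,
              dim = dim(mask), scale = scale, label = label)
}
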