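#' Region-of-interest masks
#'
#' An ROI is a logical matrix over the image grid, typically a manually drawn
#' nucleus outline. Three constructors are provided: the full grid, a filled
#' polygon, and an ellipse (the default synthetic ROI).
#'
#' @param dim grid dimensions \code{c(height, width)}.
#' @return logical matrix of dimensions \code{dim}.
#' @export
full_roi <- function(dim) matrix(TRUE, dim[1L], dim[2L])

#' @rdname full_roi
#' @param vertices numeric matrix (or list of pairs) of polygon vertices in
#'   0-based pixel coordinates \code{(x, y)}, pixel (0, 0) top-left. At least
#'   3 vertices; the polygon must enclose a non-zero area.
#' @details A pixel belongs to a polygon ROI if its center lies inside the
#'   polygon under the even-odd rule, or exactly on the boundary. The
#'   axis-aligned rectangle (0,0)--(9,9) therefore covers exactly 100 pixels.
#' @export
polygon_roi <- function(vertices, dim) {
  v <- matrix(as.numeric(unlist(vertices)), ncol = 2L, byrow = is.list(vertices))
  if (nrow(v) < 3L) stop("polygon needs at least 3 vertices")
  xs <- v[, 1L]; ys <- v[, 2L]
  n <- nrow(v)
  area2 <- sum(xs * ys[c(2:n, 1L)] - xs[c(2:n, 1L)] * ys)
  if (abs(area2) < 1e-12) stop("degenerate polygon: zero area")
  h <- dim[1L]; w <- dim[2L]
  px <- rep(seq_len(w) - 1, each = h)   # pixel-center x, column-major layout
  py <- rep(seq_len(h) - 1, times = w)
  inside <- logical(h * w)
  onedge <- logical(h * w)
  eps <- 1e-9
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[j]; y2 <- ys[j]
    # even-odd crossing of a rightward ray from the pixel center
    cond <- (y1 > py) != (y2 > py)
    if (any(cond)) {
      idx <- which(cond)
      xint <- x1 + (py[idx] - y1) * (x2 - x1) / (y2 - y1)
      hit <- idx[px[idx] < xint]
      inside[hit] <- !inside[hit]
    }
    # points exactly on the segment count as inside
    cross <- abs((x2 - x1) * (py - y1) - (y2 - y1) * (px - x1))
    seg <- cross < eps &
      px >= min(x1, x2) - eps & px <= max(x1, x2) + eps &
      py >= min(y1, y2) - eps & py <= max(y1, y2) + eps
    onedge <- onedge | seg
  }
  m <- matrix(inside | onedge, h, w)
  if (!any(m)) stop("polygon ROI contains no pixel centers")
  m
}

#' @rdname full_roi
#' @param semi ellipse semi-axes \code{c(a, b)} in pixels (x- and y-direction).
#' @param center ellipse center in 0-based pixel coordinates \code{(x, y)};
#'   defaults to the grid center.
#' @export
ellipse_roi <- function(dim = c(400, 400), semi = c(180, 140), center = NULL) {
  h <- dim[1L]; w <- dim[2L]
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  x <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  y <- matrix(rep(seq_len(h) - 1, times = w), h, w)
  m <- ((x - center[1L]) / semi[1L])^2 + ((y - center[2L]) / semi[2L])^2 <= 1
  if (!any(m)) stop("ellipse ROI contains no pixel centers")
  m
}

#' Load a region of interest
#'
#' Accepts a mask image path (PNG or TIFF, nonzero pixels = inside), a path to
#' a JSON file holding a list of \code{[x, y]} polygon vertices, a vertex
#' matrix/list directly, or \code{NULL} for the full grid.
#'
#' @param source mask image path, JSON path, vertex matrix/list, or
#'   \code{NULL}.
#' @param dim grid dimensions \code{c(height, width)} the ROI must match.
#' @return logical matrix of dimensions \code{dim}; errors if the resulting
#'   mask is empty or its dimensions disagree with \code{dim}.
#' @export
load_roi <- function(source, dim) {
  if (is.null(source)) return(full_roi(dim))
  if (is.character(source)) {
    if (grepl("\\.json$", source, ignore.case = TRUE)) {
      v <- jsonlite::fromJSON(source)
      return(polygon_roi(v, dim))
    }
    img <- read_raster(source)
    g <- if (is.list(img)) img[[1L]] else img
    if (length(base::dim(g)) == 3L) g <- g[, , 1L]
    if (!identical(base::dim(g), as.integer(dim)))
      stop("ROI mask dimensions do not match the image")
    m <- g != 0
    if (!any(m)) stop("ROI mask is empty (all pixels false)")
    return(m)
  }
  polygon_roi(source, dim)
}
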