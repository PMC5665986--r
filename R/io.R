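## Raster reading: PNG via the png package, TIFF (single- or multi-page) via
## the tiff package. Intensities are returned as integers at the original bit
## depth; readPNG's [0,1] scaling is undone using the recorded bit depth.

read_raster <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    bd <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    arr <- round(img * (2^bd - 1))
    storage.mode(arr) <- "integer"
    return(arr)
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    pages <- lapply(pages, function(p) { storage.mode(p) <- "integer"; p })
    if (length(pages) == 1L) return(pages[[1L]])
    return(pages)
  }
  stop("unsupported raster format (TIFF or PNG expected): ", path)
}

select_channel <- function(img, sel) {
  if (is.list(img)) {                      # multi-page TIFF: pages by number
    if (!is.numeric(sel)) stop("multi-page TIFF channels are selected by page number")
    sel <- as.integer(sel)
    if (sel < 1L || sel > length(img)) stop("page selector out of range: ", sel)
    g <- img[[sel]]
    if (length(dim(g)) == 3L) g <- g[, , 1L, drop = TRUE]
    return(g)
  }
  d <- dim(img)
  if (length(d) == 2L) stop("image has a single channel; selector '", sel,
                            "' cannot be honored")
  if (is.character(sel)) {
    sel <- match(toupper(sel), c("R", "G", "B", "A"))
    if (is.na(sel)) stop("channel selector must be one of R, G, B, A or an index")
  }
  sel <- as.integer(sel)
  if (sel < 1L || sel > d[3L]) stop("channel selector out of range: ", sel)
  img[, , sel, drop = TRUE]
}

#' Load two channels from a raster image
#'
#' Reads a two-color fluorescence image and extracts the two channels to be
#' analyzed: color planes of an RGB(A) PNG/TIFF (selectors "R", "G", "B", "A"
#' or plane index), or pages of a multi-page grayscale TIFF (1-based page
#' numbers).
#'
#' @param path image file (TIFF or PNG).
#' @param channels length-2 vector of channel selectors, reference channel
#'   first; default \code{c("G", "R")} (green reference, red other).
#' @return list of two integer intensity matrices of identical dimensions,
#'   named by the selectors.
#' @export
load_channels <- function(path, channels = c("G", "R")) {
  if (length(channels) != 2L) stop("exactly two channel selectors are required")
  img <- read_raster(path)
  g1 <- select_channel(img, channels[[1L]])
  g2 <- select_channel(img, channels[[2L]])
  if (!identical(dim(g1), dim(g2))) stop("selected channels have mismatched dimensions")
  stats::setNames(list(g1, g2), as.character(channels))
}

#' Export a cluster set as a label image and a feature table
#'
#' \code{write_label_image} writes a 16-bit grayscale TIFF in which background
#' is 0 and the pixels of cluster \code{k} carry the value \code{k}.
#' \code{cluster_table} returns per-cluster features (areas, centroids,
#' bounding boxes) in 0-based pixel coordinates.
#'
#' @param set an \code{if_clusters} object.
#' @param path output TIFF path.
#' @export
write_label_image <- function(set, path) {
  if (n_clusters(set) > 65535L) stop("more than 65535 clusters")
  lab <- matrix(0L, set$dim[1L], set$dim[2L])
  for (k in seq_along(set$shapes)) lab[cluster_pixels(set, k)] <- k
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_label_image
#' @return \code{cluster_table}: data frame with columns \code{id},
#'   \code{area_px}, \code{centroid_x}, \code{centroid_y}, \code{bbox_x},
#'   \code{bbox_y}, \code{bbox_w}, \code{bbox_h}.
#' @export
cluster_table <- function(set) {
  n <- n_clusters(set)
  out <- data.frame(id = seq_len(n), area_px = integer(n),
                    centroid_x = numeric(n), centroid_y = numeric(n),
                    bbox_x = integer(n), bbox_y = integer(n),
                    bbox_w = integer(n), bbox_h = integer(n))
  for (k in seq_len(n)) {
    s <- set$shapes[[k]]; a <- set$anchors[k, ]
    x <- a[2L] - 1L + s[, 2L]           # 0-based external coords
    y <- a[1L] - 1L + s[, 1L]
    out$area_px[k] <- nrow(s)
    out$centroid_x[k] <- mean(x); out$centroid_y[k] <- mean(y)
    out$bbox_x[k] <- min(x); out$bbox_y[k] <- min(y)
    out$bbox_w[k] <- max(x) - min(x) + 1L
    out$bbox_h[k] <- max(y) - min(y) + 1L
  }
  out
}

#' Write a scene as an RGB image
#'
#' Renders the reference cluster set into the green channel and the other set
#' into the red channel (binary, full intensity), matching the usual two-color
#' display convention.
#'
#' @param scene an \code{if_scene}.
#' @param path output path ending in .png or .tif/.tiff.
#' @export
write_scene_image <- function(scene, path) {
  stopifnot(inherits(scene, "if_scene"))
  h <- scene$dim[1L]; w <- scene$dim[2L]
  arr <- array(0, c(h, w, 3L))
  arr[, , 1L] <- rasterize(scene$other) * 1
  arr[, , 2L] <- rasterize(scene$ref) * 1
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(arr, path)
  } else {
    tiff::writeTIFF(arr, path, bits.per.sample = 8L)
  }
  invisible(path)
}
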