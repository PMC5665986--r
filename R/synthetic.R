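## Synthetic two-color scenes: ellipse-shaped clusters with log-normally
## distributed sizes, placed inside an elliptical ROI at a prescribed
## Interaction Factor. This is the fixture generator used for all validation
## experiments; no external image data is needed.

#' Sample ellipse specifications for synthetic clusters
#'
#' Semi-major axes are drawn log-normally (median \code{exp(meanlog)} px);
#' the semi-minor axis is the semi-major times a uniform aspect ratio, and
#' orientations are uniform on [0, pi). The defaults give a mean cluster area
#' of about 40 px, i.e. diffraction-scale clusters at 20 nm/px.
#'
#' @param n number of ellipses.
#' @param meanlog,sdlog log-normal parameters of the semi-major axis in
#'   pixels (defaults \code{log(3.75)}, 0.3).
#' @param aspect range of the semi-minor/semi-major ratio (default
#'   \code{c(0.5, 1)}).
#' @param scale multiplicative factor applied to both sampled axes (the
#'   cluster-size scaling knob of the validation experiments; default 1).
#' @return data frame with columns \code{semi_major}, \code{semi_minor},
#'   \code{theta}.
#' @export
sample_ellipses <- function(n, meanlog = log(3.75), sdlog = 0.3,
                            aspect = c(0.5, 1), scale = 1) {
  stopifnot(n >= 0, scale > 0, sdlog >= 0)
  a <- stats::rlnorm(n, meanlog, sdlog)
  ratio <- stats::runif(n, aspect[1L], aspect[2L])
  data.frame(semi_major = a * scale,
             semi_minor = a * ratio * scale,
             theta = stats::runif(n, 0, pi))
}

#' Rasterize an ellipse into a cluster shape
#'
#' A pixel belongs to the ellipse if its center satisfies the rotated-ellipse
#' inequality \eqn{(u/a)^2 + (v/b)^2 \le 1}, where \eqn{(u, v)} are the pixel
#' center's coordinates in the ellipse frame. The raster area tracks
#' \eqn{\pi a b} up to discretization.
#'
#' @param semi_major,semi_minor semi-axes in pixels.
#' @param theta orientation in radians (rotation of the major axis from the
#'   x-axis).
#' @return integer shape matrix of (dr, dc) offsets as used by
#'   [cluster_set()].
#' @export
rasterize_ellipse <- function(semi_major, semi_minor, theta = 0) {
  a <- semi_major; b <- semi_minor
  stopifnot(a > 0, b > 0)
  ex <- ceiling(sqrt((a * cos(theta))^2 + (b * sin(theta))^2))
  ey <- ceiling(sqrt((a * sin(theta))^2 + (b * cos(theta))^2))
  xs <- seq.int(-ex, ex); ys <- seq.int(-ey, ey)
  x <- rep(xs, times = length(ys)); y <- rep(ys, each = length(xs))
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  if (!any(keep)) stop("ellipse rasterized to an empty shape")
  dr <- y[keep]; dc <- x[keep]
  cbind(dr - min(dr), dc - min(dc))
}

#' Generate a synthetic two-color ellipse-cluster scene at a prescribed IF
#'
#' Draws \code{n_other} other-color and \code{n_ref} reference-color ellipse
#' clusters, places the other set uniformly at random inside the ROI, and
#' places the reference set by [place_with_if()] at Interaction Factor
#' \code{f}. Ellipses that rasterize below \code{min_area} pixels are
#' resampled, so generated counts equal requested counts and every generated
#' cluster would survive the segmentation filter.
#'
#' @param n_ref,n_other cluster counts (defaults 100 and 100).
#' @param f target Interaction Factor in [0, 1] (reference vs other).
#' @param roi logical ROI matrix; default an ellipse of semi-axes (180, 140)
#'   on the grid.
#' @param dim grid dimensions, default \code{c(400, 400)} (8 x 8 um at
#'   20 nm/px).
#' @param scale nm per pixel (default 20).
#' @param size_scale_ref,size_scale_other multiplicative axis scalings per
#'   channel (default 1).
#' @param meanlog,sdlog,aspect axis distribution, see [sample_ellipses()].
#' @param min_area minimum raster area in pixels (default 4, matching the
#'   segmentation filter).
#' @param max_attempts see [place_with_if()].
#' @param seed optional integer seed.
#' @param labels channel labels, reference first (default green/red).
#' @return an \code{if_scene} with attributes \code{true_f} (the prescribed
#'   IF), \code{attempts_exceeded} and \code{specs} (the sampled ellipse
#'   parameters per channel).
#' @export
simulate_scene <- function(n_ref = 100, n_other = 100, f = 0, roi = NULL,
                           dim = c(400, 400), scale = 20,
                           size_scale_ref = 1, size_scale_other = 1,
                           meanlog = log(3.75), sdlog = 0.3, aspect = c(0.5, 1),
                           min_area = 4, max_attempts = 10000, seed = NULL,
                           labels = c("green", "red")) {
  if (!is.numeric(f) || f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(roi)) roi <- ellipse_roi(dim)
  if (!identical(base::dim(roi), as.integer(dim)))
    stop("roi dimensions do not match dim")

  draw_shapes <- function(n, size_scale) {
    shapes <- vector("list", n)
    specs <- sample_ellipses(n, meanlog, sdlog, aspect, scale = size_scale)
    for (k in seq_len(n)) {
      repeat {
        s <- rasterize_ellipse(specs$semi_major[k], specs$semi_minor[k],
                               specs$theta[k])
        if (nrow(s) >= min_area) break
        new <- sample_ellipses(1L, meanlog, sdlog, aspect, scale = size_scale)
        specs[k, ] <- new[1L, ]
      }
      shapes[[k]] <- s
    }
    list(shapes = shapes, specs = specs)
  }

  oth <- draw_shapes(n_other, size_scale_other)
  ref <- draw_shapes(n_ref, size_scale_ref)
  dummy <- function(shapes, label) {
    n <- length(shapes)
    anch <- matrix(1L, n, 2L)          # placeholder anchors, replaced below
    # dummy anchors must be in-grid; shapes are small relative to the grid
    cluster_set(shapes, anch, dim = dim, scale = scale, label = label)
  }
  rcs <- roi_prep(roi)
  other_set <- dummy(oth$shapes, labels[2L])
  a_oth <- anchor_sets(other_set, roi, rcs)
  if (any(lengths(a_oth) == 0L))
    stop("a sampled cluster does not fit inside the ROI; enlarge the ROI or ",
         "shrink the size distribution")
  other_set <- place_random(other_set, roi, anchors = a_oth)

  ref_set <- dummy(ref$shapes, labels[1L])
  a_ref <- anchor_sets(ref_set, roi, rcs)
  if (any(lengths(a_ref) == 0L))
    stop("a sampled cluster does not fit inside the ROI; enlarge the ROI or ",
         "shrink the size distribution")
  ref_set <- place_with_if(ref_set, rasterize(other_set), roi, f = f,
                           max_attempts = max_attempts, anchors = a_ref)

  scn <- cluster_scene(ref_set, other_set, roi, scale = scale)
  attr(scn, "true_f") <- f
  attr(scn, "attempts_exceeded") <- attr(ref_set, "attempts_exceeded")
  attr(scn, "specs") <- list(ref = ref$specs, other = oth$specs)
  scn
}
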