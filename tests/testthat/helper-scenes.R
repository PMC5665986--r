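# Builders for toy fixtures used across the test files. Everything is
# constructed in code; pixel coordinates below are 1-based (row, col).

# cluster set from a list of absolute pixel matrices (row, col)
set_from_pixels <- function(pixel_sets, dim, scale = 20, label = "green") {
  shapes <- list(); anchors <- NULL
  for (px in pixel_sets) {
    px <- matrix(as.integer(px), ncol = 2L)
    a <- c(min(px[, 1L]), min(px[, 2L]))
    shapes[[length(shapes) + 1L]] <- cbind(px[, 1L] - a[1L], px[, 2L] - a[2L])
    anchors <- rbind(anchors, a)
  }
  cluster_set(shapes, anchors, dim = dim, scale = scale, label = label)
}

mask_from_pixels <- function(pixel_sets, dim) {
  m <- matrix(FALSE, dim[1L], dim[2L])
  for (px in pixel_sets) {
    px <- matrix(as.integer(px), ncol = 2L)
    m[px] <- TRUE
  }
  m
}

# small synthetic scene for estimator tests (fast to fit)
small_scene <- function(f = 0, seed = 1, n = 30) {
  simulate_scene(n_ref = n, n_other = n, f = f, dim = c(180, 180),
                 roi = ellipse_roi(c(180, 180), semi = c(80, 65)),
                 seed = seed)
}

# brute-force valid anchor enumeration (independent oracle for placement)
brute_anchors <- function(shape, roi) {
  h <- nrow(roi); w <- ncol(roi)
  out <- NULL
  for (r in seq_len(h)) for (c in seq_len(w)) {
    rr <- r + shape[, 1L]; cc <- c + shape[, 2L]
    if (max(rr) <= h && max(cc) <= w && all(roi[cbind(rr, cc)]))
      out <- rbind(out, c(r, c))
  }
  if (is.null(out)) matrix(integer(0), 0L, 2L) else out
}
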