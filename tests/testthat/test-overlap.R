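test_that("rasterize takes the union of cluster pixels", {
  dim <- c(10, 10)
  expect_equal(sum(rasterize(cluster_set(list(), matrix(integer(0), 0, 2), dim))), 0)

  disjoint <- set_from_pixels(list(cbind(1, 1:5), cbind(5, 1:7)), dim)
  expect_equal(sum(rasterize(disjoint)), 12)

  shared <- set_from_pixels(list(cbind(1, 1:5), cbind(1, 4:10)), dim)  # 2 px shared
  expect_equal(sum(rasterize(shared)), 10)
})

test_that("overlap_mask is the pixel-wise intersection", {
  set.seed(2)
  a <- matrix(runif(16) > 0.5, 4, 4)
  expect_identical(overlap_mask(a, a), a)
  expect_false(any(overlap_mask(a, !a)))
  b <- matrix(runif(16) > 0.5, 4, 4)
  got <- overlap_mask(a, b)
  for (i in 1:4) for (j in 1:4) expect_identical(got[i, j], a[i, j] && b[i, j])
  expect_error(overlap_mask(a, matrix(TRUE, 3, 3)), "differ")
})

test_that("overlap statistics match hand enumeration on a toy scene", {
  dim <- c(12, 12)
  # 3 reference clusters; two of them touch the other channel
  ref <- set_from_pixels(list(
    rbind(c(2, 2), c(2, 3), c(3, 2), c(3, 3)),              # overlaps 1 px
    rbind(c(6, 6), c(6, 7), c(7, 6), c(7, 7), c(8, 6)),     # overlaps 5 px
    rbind(c(11, 11), c(11, 12), c(12, 11), c(12, 12))), dim, label = "green")
  oth <- set_from_pixels(list(
    rbind(c(3, 3), c(3, 4), c(4, 3), c(4, 4)),
    cbind(6:8, 6), cbind(6:8, 7)), dim, label = "red")
  scn <- cluster_scene(ref, oth, scale = 20)
  st <- overlap_stats(scn)
  expect_equal(st$per_cluster, c(TRUE, TRUE, FALSE))
  expect_equal(st$fraction, 2 / 3)
  expect_equal(st$n_regions, 2L)
  # overlap pixels: (3,3) plus {(6,6),(6,7),(7,6),(7,7),(8,6)} = 6 px
  expect_equal(st$area_um2, 6 * (20 / 1000)^2)
})

test_that("full coverage and disjoint channels give the extreme fractions", {
  dim <- c(8, 8)
  ref <- set_from_pixels(list(rbind(c(2, 2)), rbind(c(5, 5))), dim, label = "green")
  all_cover <- segment_clusters(mask = matrix(TRUE, 8, 8), min_area = 4)
  all_cover$label <- "red"
  expect_equal(overlap_stats(cluster_scene(ref, all_cover))$fraction, 1)
  far <- set_from_pixels(list(rbind(c(8, 8))), dim, label = "red")
  st <- overlap_stats(cluster_scene(ref, far))
  expect_equal(st$fraction, 0)
  expect_equal(st$n_regions, 0L)
  expect_equal(st$area_um2, 0)
})

test_that("a scene with no reference clusters is an error, not zero", {
  dim <- c(8, 8)
  empty <- cluster_set(list(), matrix(integer(0), 0, 2), dim, label = "green")
  oth <- set_from_pixels(list(rbind(c(5, 5))), dim, label = "red")
  expect_error(overlap_stats(cluster_scene(empty, oth)), "undefined")
})

test_that("overlap area and region count are symmetric; fraction is not", {
  set.seed(5)
  for (i in 1:5) {
    scn <- simulate_scene(n_ref = 12, n_other = 25, f = 0.5, dim = c(100, 100),
                          roi = ellipse_roi(c(100, 100), c(45, 38)))
    a <- overlap_stats(scn); b <- overlap_stats(swap_channels(scn))
    expect_equal(a$area_um2, b$area_um2)
    expect_equal(a$n_regions, b$n_regions)
    expect_lte(a$area_um2,
               min(sum(rasterize(scn$ref)), sum(rasterize(scn$other))) * (scn$scale / 1000)^2)
  }
})

test_that("Manders coefficients follow their intensity-weighted definition", {
  g <- matrix(0, 3, 3)
  g[1, 1] <- 10; g[1, 2] <- 20; g[1, 3] <- 30
  h <- matrix(0, 3, 3)
  h[1, 2] <- 50; h[1, 3] <- 50                # co-localized with the 20 and 30
  m <- manders(g, h, th1 = 5, th2 = 5)
  expect_equal(unname(m["M1"]), 50 / 60)
  expect_equal(unname(m["M2"]), 1)

  expect_equal(unname(manders(g, g, 5, 5)), c(1, 1))
  far <- matrix(0, 3, 3); far[3, 1] <- 99
  expect_equal(unname(manders(g, far, 5, 5)), c(0, 0))
  expect_error(manders(g, matrix(0, 3, 3), 5, 5), "above-threshold")
})

test_that("Pearson correlation matches its closed form on toy grids", {
  g <- matrix(c(1, 4, 2, 8, 5, 7), 2, 3)
  expect_equal(pearson_coloc(g, 2 * g + 5), 1)
  expect_equal(pearson_coloc(g, -g + 3), -1)
  h <- matrix(c(2, 1, 7, 3, 9, 4), 2, 3)
  x <- as.vector(g); y <- as.vector(h)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_coloc(g, h), r_hand)
  expect_error(pearson_coloc(g, matrix(1, 2, 3)), "variance")
})

test_that("Manders increases with other-channel density on random scenes", {
  set.seed(9)
  m1_at <- function(n_other) {
    vals <- replicate(4, {
      scn <- simulate_scene(n_ref = 15, n_other = n_other, f = 0, dim = c(120, 120),
                            roi = ellipse_roi(c(120, 120), c(55, 45)))
      g1 <- rasterize(scn$ref) * 100
      g2 <- rasterize(scn$other) * 100
      manders(g1, g2, 50, 50, scn$roi)["M1"]
    })
    mean(vals)
  }
  expect_gt(m1_at(120), m1_at(15))
})
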