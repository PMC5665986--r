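test_that("valid anchor enumeration equals brute force on irregular ROIs", {
  set.seed(21)
  roi <- matrix(runif(26 * 24) > 0.4, 26, 24)
  for (i in 1:6) {
    sp <- sample_ellipses(1, meanlog = log(2.5))
    s <- rasterize_ellipse(sp$semi_major, sp$semi_minor, sp$theta)
    va <- valid_anchors(s, roi)
    bf <- brute_anchors(s, roi)
    expect_equal(nrow(va), nrow(bf))
    if (nrow(bf) > 0)
      expect_equal(unname(va[order(va[, 1], va[, 2]), , drop = FALSE]),
                   unname(bf[order(bf[, 1], bf[, 2]), , drop = FALSE]))
  }
})

test_that("random placement is uniform over the valid anchor set", {
  # 1-px cluster on a 10 x 10 rectangular ROI: 100 valid anchors
  roi <- matrix(FALSE, 14, 14); roi[3:12, 3:12] <- TRUE
  set <- set_from_pixels(list(rbind(c(3, 3))), c(14, 14))
  expect_equal(nrow(valid_anchors(set$shapes[[1]], roi)), 100)
  set.seed(31)
  draws <- replicate(20000, {
    p <- place_random(set, roi)
    (p$anchors[1, 2] - 1L) * 14L + p$anchors[1, 1]
  })
  counts <- table(factor(draws, levels = sort(unique(as.vector(
    outer(3:12, (3:12 - 1) * 14, `+`))))))
  expect_length(counts, 100)
  expect_gt(stats::chisq.test(as.vector(counts))$p.value, 0.001)
})

test_that("a cluster the size of the ROI has a single deterministic anchor", {
  roi <- matrix(FALSE, 10, 10); roi[2:5, 3:7] <- TRUE
  s <- as.matrix(expand.grid(dr = 0:3, dc = 0:4))
  set <- cluster_set(list(unname(s)), rbind(c(1L, 1L)), c(10, 10))
  va <- valid_anchors(set$shapes[[1]], roi)
  expect_equal(nrow(va), 1)
  expect_equal(unname(va[1, ]), c(2, 3))
  p <- place_random(set, roi)
  expect_equal(unname(p$anchors[1, ]), c(2, 3))
})

test_that("randomization preserves shapes and stays inside the ROI", {
  set.seed(41)
  scn <- simulate_scene(n_ref = 20, n_other = 20, f = 0.4, dim = c(120, 120),
                        roi = ellipse_roi(c(120, 120), c(55, 45)))
  for (f in c(0, 0.5, 0.9)) {
    rs <- randomize_scene(scn, f = f)
    expect_equal(sort(cluster_areas(rs$ref)), sort(cluster_areas(scn$ref)))
    expect_equal(rs$ref$shapes, scn$ref$shapes)     # rigid: no rotation/deformation
    expect_true(all(scn$roi[rasterize(rs$ref)]))
    expect_true(all(scn$roi[rasterize(rs$other)]))
  }
})

test_that("f = 0 reduces to uniform placement and seeds make runs identical", {
  set.seed(51)
  scn <- simulate_scene(n_ref = 10, n_other = 10, f = 0, dim = c(100, 100),
                        roi = ellipse_roi(c(100, 100), c(45, 38)))
  roi <- scn$roi
  set.seed(7); a <- place_with_if(scn$ref, rasterize(scn$other), roi, f = 0)
  set.seed(7); b <- place_random(scn$ref, roi)
  expect_equal(a$anchors, b$anchors)

  set.seed(8); s1 <- randomize_scene(scn, f = 0.7)
  set.seed(8); s2 <- randomize_scene(scn, f = 0.7)
  expect_equal(s1$ref$anchors, s2$ref$anchors)
  expect_equal(s1$other$anchors, s2$other$anchors)
})

test_that("f = 1 with a reachable other channel always lands on an overlap", {
  roi <- matrix(TRUE, 12, 12)
  other <- matrix(FALSE, 12, 12); other[5:8, 5:8] <- TRUE
  set <- set_from_pixels(rep(list(rbind(c(1, 1), c(1, 2))), 30), c(12, 12))
  set.seed(61)
  placed <- place_with_if(set, other, roi, f = 1)
  expect_equal(attr(placed, "attempts_exceeded"), 0L)
  for (k in 1:30) expect_true(any(other[cluster_pixels(placed, k)]))
})

test_that("an unreachable overlap at f = 1 exhausts attempts without failing", {
  roi <- matrix(TRUE, 6, 6)
  set <- set_from_pixels(list(rbind(c(1, 1))), c(6, 6))
  set.seed(71)
  placed <- place_with_if(set, matrix(FALSE, 6, 6), roi, f = 1, max_attempts = 50)
  expect_equal(attr(placed, "attempts_exceeded"), 1L)
  expect_true(roi[placed$anchors])
})

test_that("overlap frequency under place_with_if follows the geometric-series law", {
  # single 1-px cluster, ROI of 100 anchors, other mask covering 20 of them:
  # p0 = 0.2 exactly (verified by enumeration); expect p0 / (1 - (1-p0) f)
  roi <- matrix(FALSE, 14, 14); roi[3:12, 3:12] <- TRUE
  other <- matrix(FALSE, 14, 14); other[3:6, 3:7] <- TRUE   # 20 px inside ROI
  s <- rbind(c(0L, 0L))
  p0 <- mean(apply(valid_anchors(s, roi), 1, function(a) other[a[1], a[2]]))
  expect_equal(p0, 0.2)
  batch <- set_from_pixels(rep(list(rbind(c(3, 3))), 1000), c(14, 14))
  set.seed(81)
  for (f in c(0.3, 0.7)) {
    hits <- 0L; n <- 0L
    for (b in 1:10) {
      placed <- place_with_if(batch, other, roi, f = f)
      hits <- hits + sum(vapply(1:1000, function(k)
        any(other[cluster_pixels(placed, k)]), logical(1)))
      n <- n + 1000L
    }
    expected <- p0 / (1 - (1 - p0) * f)
    se <- sqrt(expected * (1 - expected) / n)
    expect_lt(abs(hits / n - expected), 3 * se)
  }
})

test_that("empirical overlap frequency is non-decreasing in f", {
  roi <- matrix(FALSE, 14, 14); roi[3:12, 3:12] <- TRUE
  other <- matrix(FALSE, 14, 14); other[3:6, 3:7] <- TRUE
  batch <- set_from_pixels(rep(list(rbind(c(3, 3))), 2000), c(14, 14))
  set.seed(91)
  freq <- vapply(c(0, 0.4, 0.8, 0.95), function(f) {
    placed <- place_with_if(batch, other, roi, f = f)
    mean(vapply(1:2000, function(k) any(other[cluster_pixels(placed, k)]),
                logical(1)))
  }, numeric(1))
  expect_true(all(diff(freq) > -0.02))    # monotone up to Monte-Carlo noise
})
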