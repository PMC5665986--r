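test_that("expected overlap reduces to the mean p0 at f = 0 and to 1 at f = 1", {
  set.seed(101)
  p0 <- runif(40, 0.05, 0.95)
  expect_equal(overlap_from_if(p0, 0), mean(p0))
  expect_equal(overlap_from_if(p0, 1), 1)
  # zero-probability clusters contribute 0 at every f, including f = 1
  expect_equal(overlap_from_if(c(0, 0.5), 1), 0.5)
  expect_equal(overlap_from_if(c(0, 0), 0.7), 0)
  expect_error(overlap_from_if(p0, 1.2), "0, 1")
})

test_that("expected overlap matches the truncated geometric series", {
  # p_k(f) = p0 * sum_i [(1 - p0) f]^i, summed numerically to machine depth
  series <- function(p0, f) {
    x <- (1 - p0) * f
    p0 * sum(x^(0:5000))
  }
  for (p0 in c(0.05, 0.2, 0.5)) for (f in c(0, 0.25, 0.5, 0.9)) {
    expect_equal(overlap_from_if(p0, f), series(p0, f), tolerance = 1e-10)
  }
  expect_equal(overlap_from_if(0.2, 0.5), 1 / 3)
})

test_that("inversion matches the single-cluster closed form", {
  # for one cluster, f = (1 - p0/P) / (1 - p0)
  for (p0 in c(0.1, 0.2, 0.6)) for (f_true in c(0.15, 0.5, 0.85)) {
    P <- overlap_from_if(p0, f_true)
    closed <- (1 - p0 / P) / (1 - p0)
    expect_equal(closed, f_true, tolerance = 1e-12)   # sanity of the oracle
    expect_equal(if_from_overlap(p0, P), f_true, tolerance = 1e-5)
  }
  expect_equal(if_from_overlap(0.2, 1 / 3), 0.5, tolerance = 1e-5)
})

test_that("observed overlap at, below, or above the attainable range clamps", {
  p0 <- c(0.1, 0.3, 0.5)
  expect_equal(if_from_overlap(p0, mean(p0)), 0)          # at the random level
  expect_equal(if_from_overlap(p0, 0.05), 0)              # below random
  expect_equal(if_from_overlap(p0, 1), 1)
  # some clusters can never overlap: the attainable sup is mean(p0 > 0)
  p0z <- c(0, 0, 0.2, 0.4)
  expect_equal(if_from_overlap(p0z, 0.6), 1)
  expect_equal(if_from_overlap(c(0, 1), 0.6), 1)          # degenerate profile
  expect_equal(if_from_overlap(c(0, 1), 0.4), 0)
})

test_that("round-trip inversion recovers f on random profiles", {
  set.seed(111)
  for (i in 1:200) {
    n <- sample(25:200, 1)
    p0 <- runif(n, 0.01, 0.99)
    f <- runif(1, 0, 0.99)
    expect_lt(abs(if_from_overlap(p0, overlap_from_if(p0, f)) - f), 1e-5)
  }
})

test_that("expected overlap is strictly increasing in f for interior profiles", {
  set.seed(121)
  for (i in 1:20) {
    p0 <- runif(30, 0.05, 0.95)
    curve <- overlap_from_if(p0, seq(0, 1, by = 0.05))
    expect_true(all(diff(curve) > 0))
  }
})

test_that("the empirical p-value counts simulations at or above the observation", {
  prof <- structure(list(p0 = c(0.2, 0.3), n_sims = 4L, n_ref = 2L,
                         per_sim_fraction = c(0.1, 0.2, 0.3, 0.4)),
                    class = "if_profile")
  expect_equal(empirical_p_value(prof, 0.25), 0.5)
  expect_equal(empirical_p_value(prof, 0), 1)
  expect_equal(empirical_p_value(prof, 0.45), 0)
  expect_equal(empirical_p_value(prof, 0.4), 0.25)   # ties count
})

test_that("profile probabilities hit the exact trivial limits", {
  dim <- c(40, 40)
  roi <- matrix(TRUE, 40, 40)
  ref <- set_from_pixels(list(rbind(c(5, 5)), rbind(c(20, 20))), dim, label = "green")
  # other channel covers the whole ROI
  full <- segment_clusters(mask = roi, min_area = 4)
  full$label <- "red"
  scn <- cluster_scene(ref, full, roi)
  prof <- estimate_profile(scn, n_sims = 10)
  expect_equal(prof$p0, c(1, 1))
  # empty other channel
  empty <- cluster_set(list(), matrix(integer(0), 0, 2), dim, label = "red")
  prof0 <- estimate_profile(cluster_scene(ref, empty, roi), n_sims = 10)
  expect_equal(prof0$p0, c(0, 0))
})

test_that("probabilities and p-values are quantized to 1/n_sims", {
  scn <- small_scene(f = 0.5, seed = 131)
  fit <- interaction_factor(scn, n_sims = 50, seed = 132)
  for (d in fit$fits) {
    expect_true(all(abs(d$profile$p0 * 50 - round(d$profile$p0 * 50)) < 1e-9))
    expect_true(abs(d$p_value * 50 - round(d$p_value * 50)) < 1e-9)
  }
})

test_that("the full fit is deterministic under a fixed seed", {
  scn <- small_scene(f = 0.7, seed = 141)
  f1 <- interaction_factor(scn, n_sims = 20, seed = 9)
  f2 <- interaction_factor(scn, n_sims = 20, seed = 9)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$fits[[1]]$profile$p0, f2$fits[[1]]$profile$p0)
  expect_identical(f1$fits[[1]]$p_value, f2$fits[[1]]$p_value)
})

test_that("a channel-symmetric scene yields matching directional estimates", {
  set.seed(151)
  scn <- small_scene(f = 0.6, seed = 151)
  # make the channels identical cluster sets (perfect overlap, symmetric)
  twin <- scn$ref; twin$label <- "red"
  sym <- cluster_scene(scn$ref, twin, scn$roi)
  fit <- interaction_factor(sym, n_sims = 30, seed = 152)
  cf <- coef(fit)
  expect_equal(unname(cf[1]), unname(cf[2]), tolerance = 0.05)
  expect_equal(fit$fits[[1]]$observed_fraction, 1)
})

test_that("fits recover the simulated IF within Monte-Carlo tolerance", {
  scn <- small_scene(f = 0.9, seed = 161, n = 40)
  fit <- interaction_factor(scn, n_sims = 50, seed = 162, direction = "forward")
  expect_gt(coef(fit)[1], 0.75)
  expect_lte(coef(fit)[1], 1)
  expect_lte(fit$fits[[1]]$p_value, 0.02)

  scn0 <- small_scene(f = 0, seed = 163, n = 40)
  fit0 <- interaction_factor(scn0, n_sims = 50, seed = 164, direction = "forward")
  expect_lt(coef(fit0)[1], 0.5)
})

test_that("fit methods expose the model coherently", {
  scn <- small_scene(f = 0.8, seed = 171)
  fit <- interaction_factor(scn, n_sims = 25, seed = 172)
  expect_named(coef(fit), c("IF[ref=green]", "IF[ref=red]"))
  s <- summary(fit)
  expect_s3_class(s, "summary.if_fit")
  expect_equal(nrow(s$table), 2)
  expect_equal(s$table$IF, unname(coef(fit)))
  # predict at f = 0 equals the mean random overlap probability
  expect_equal(predict(fit, f = 0), mean(fit$fits[[1]]$profile$p0))
  # simulate returns scenes with conserved cluster areas
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2)
  expect_equal(sort(cluster_areas(sims[[1]]$ref)), sort(cluster_areas(scn$ref)))
  expect_output(print(fit), "reference 'green'")
  expect_output(print(s), "Overlap regions")
})

test_that("fitting an empty channel is an explicit error", {
  dim <- c(30, 30)
  ref <- set_from_pixels(list(rbind(c(5, 5))), dim, label = "green")
  empty <- cluster_set(list(), matrix(integer(0), 0, 2), dim, label = "red")
  expect_error(interaction_factor(cluster_scene(ref, empty)), "at least one cluster")
})
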