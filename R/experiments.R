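## Desk-scale validation experiments: density invariance, accuracy grids,
## significance versus sample size, repeatability, and the overlap-versus-IF
## curve. Each experiment is reproducible bit-exactly from (config, seed) and
## returns tidy data frames; nothing is plotted as a side effect.

## t-test flavor used throughout: Bartlett pre-test for equal variances,
## Welch's t-test when variances differ, Student's otherwise.
pretested_t_test <- function(x, y) {
  eq <- tryCatch(stats::bartlett.test(list(x, y))$p.value >= 0.05,
                 error = function(e) TRUE)
  stats::t.test(x, y, var.equal = eq)$p.value
}

scene_args <- function(base_spec) {
  if (is.null(base_spec)) list() else base_spec
}

run_cell <- function(f, images, n_sims, base_spec, extra = list()) {
  vapply(seq_len(images), function(i) {
    args <- c(list(f = f), extra, scene_args(base_spec))
    scn <- do.call(simulate_scene, args)
    fit <- interaction_factor(scn, n_sims = n_sims, direction = "forward")
    d <- fit$fits[[1L]]
    c(f_hat = d$f_hat, observed_P = d$observed_fraction)
  }, c(f_hat = 0, observed_P = 0))
}

#' Density-invariance sweep
#'
#' Generates images at fixed Interaction Factor(s) while varying the
#' other-channel cluster count, estimates the IF of each image, and
#' regresses the estimate on the count. The IF should be flat in density
#' (non-significant slope) while the raw overlap fraction increases.
#'
#' @param true_f vector of simulated Interaction Factors (default
#'   \code{c(0, 0.9)}).
#' @param n_other_levels other-channel cluster counts (default
#'   \code{c(25, 50, 100, 200)}).
#' @param images_per_cell images per (f, level) cell (default 10).
#' @param n_sims random simulations per IF estimate (default 50).
#' @param base_spec named list of extra [simulate_scene()] arguments.
#' @param seed integer seed.
#' @return class \code{if_sweep}: \code{per_image} (tidy data frame),
#'   \code{summary} (means/SDs per cell), \code{regressions} (per f: slope,
#'   slope p-value).
#' @export
density_sweep <- function(true_f = c(0, 0.9),
                          n_other_levels = c(25, 50, 100, 200),
                          images_per_cell = 10, n_sims = 50,
                          base_spec = NULL, seed = NULL) {
  stopifnot(length(n_other_levels) >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (f in true_f) for (lev in n_other_levels) {
    res <- run_cell(f, images_per_cell, n_sims, base_spec,
                    extra = list(n_other = lev))
    rows[[length(rows) + 1L]] <- data.frame(
      true_f = f, n_other = lev, image = seq_len(images_per_cell),
      f_hat = res["f_hat", ], observed_P = res["observed_P", ])
  }
  per_image <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_image,
                                      per_image[c("true_f", "n_other")], drop = TRUE),
    function(d) data.frame(true_f = d$true_f[1L], n_other = d$n_other[1L],
                           mean_f_hat = mean(d$f_hat), sd_f_hat = stats::sd(d$f_hat),
                           mean_P = mean(d$observed_P))))
  summ <- summ[order(summ$true_f, summ$n_other), ]
  rownames(summ) <- NULL
  regressions <- NULL
  if (length(n_other_levels) >= 2L) {
    regressions <- do.call(rbind, lapply(split(per_image, per_image$true_f),
      function(d) {
        fit <- stats::lm(f_hat ~ n_other, data = d)
        cf <- summary(fit)$coefficients
        data.frame(true_f = d$true_f[1L], slope = cf["n_other", "Estimate"],
                   slope_p = cf["n_other", "Pr(>|t|)"])
      }))
    rownames(regressions) <- NULL
  }
  structure(list(per_image = per_image, summary = summ,
                 regressions = regressions),
            class = "if_sweep")
}

#' @export
print.if_sweep <- function(x, ...) {
  cat("Density sweep\n")
  print(x$summary, row.names = FALSE, digits = 3)
  if (!is.null(x$regressions)) {
    cat("Regression of f_hat on cluster count:\n")
    print(x$regressions, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Accuracy grid: R-squared of calculated versus simulated IF
#'
#' For each (size scaling, cluster count) cell, simulates images across the
#' requested IF levels and reports the coefficient of determination of the
#' regression calculated-IF = simulated-IF, computed both per image and on
#' the cell means.
#'
#' @param sizes other-channel axis scalings (default \code{c(0.5, 1, 1.5)}).
#' @param counts other-channel cluster counts (default \code{c(25, 100, 200)}).
#' @param f_levels simulated IF levels, at least 2 (default
#'   \code{c(0, 0.25, 0.5, 0.75, 0.9)}).
#' @param images_per_cell images per (size, count, f) combination (default 5).
#' @inheritParams density_sweep
#' @return list with \code{per_image} data frame and two matrices
#'   \code{r2_per_image}, \code{r2_cell_means} (rows = sizes, cols = counts).
#' @export
accuracy_grid <- function(sizes = c(0.5, 1, 1.5), counts = c(25, 100, 200),
                          f_levels = c(0, 0.25, 0.5, 0.75, 0.9),
                          images_per_cell = 5, n_sims = 50,
                          base_spec = NULL, seed = NULL) {
  if (length(f_levels) < 2L) stop("at least two IF levels are required for R^2")
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (sz in sizes) for (ct in counts) for (f in f_levels) {
    res <- run_cell(f, images_per_cell, n_sims, base_spec,
                    extra = list(n_other = ct, size_scale_other = sz))
    rows[[length(rows) + 1L]] <- data.frame(
      size_scale = sz, n_other = ct, true_f = f,
      image = seq_len(images_per_cell), f_hat = res["f_hat", ])
  }
  per_image <- do.call(rbind, rows)
  r2 <- function(truth, est) {
    ss_res <- sum((est - truth)^2)
    ss_tot <- sum((truth - mean(truth))^2)
    if (ss_tot == 0) stop("degenerate truth variance")
    1 - ss_res / ss_tot
  }
  m1 <- matrix(NA_real_, length(sizes), length(counts),
               dimnames = list(size = sizes, count = counts))
  m2 <- m1
  for (i in seq_along(sizes)) for (j in seq_along(counts)) {
    d <- per_image[per_image$size_scale == sizes[i] & per_image$n_other == counts[j], ]
    m1[i, j] <- r2(d$true_f, d$f_hat)
    means <- tapply(d$f_hat, d$true_f, mean)
    m2[i, j] <- r2(as.numeric(names(means)), as.numeric(means))
  }
  list(per_image = per_image, r2_per_image = m1, r2_cell_means = m2)
}

#' Significance versus sample size
#'
#' For every pair of IF levels and every group size, repeatedly simulates two
#' groups of images, estimates their IFs and applies the variance-pretested
#' t-test; reports the mean p-value per (pair, group size).
#'
#' @param f_levels IF levels compared pairwise (default
#'   \code{c(0, 0.25, 0.5, 0.75, 0.9)}).
#' @param group_sizes images per group (default \code{c(5, 10, 20)}).
#' @param repeats comparisons averaged per cell (default 5).
#' @inheritParams density_sweep
#' @return list of mean-p matrices, one per group size (rows/cols = IF
#'   levels), plus the tidy per-comparison data frame.
#' @export
significance_grid <- function(f_levels = c(0, 0.25, 0.5, 0.75, 0.9),
                              group_sizes = c(5, 10, 20), repeats = 5,
                              n_sims = 50, base_spec = NULL, seed = NULL) {
  stopifnot(all(group_sizes >= 2))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (gs in group_sizes) {
    for (i in seq_along(f_levels)) for (j in seq.int(i, length(f_levels))) {
      for (rep in seq_len(repeats)) {
        g1 <- run_cell(f_levels[i], gs, n_sims, base_spec)["f_hat", ]
        g2 <- run_cell(f_levels[j], gs, n_sims, base_spec)["f_hat", ]
        rows[[length(rows) + 1L]] <- data.frame(
          group_size = gs, f1 = f_levels[i], f2 = f_levels[j], rep = rep,
          p = pretested_t_test(g1, g2))
      }
    }
  }
  per_comparison <- do.call(rbind, rows)
  mats <- lapply(group_sizes, function(gs) {
    m <- matrix(NA_real_, length(f_levels), length(f_levels),
                dimnames = list(f_levels, f_levels))
    d <- per_comparison[per_comparison$group_size == gs, ]
    for (i in seq_along(f_levels)) for (j in seq.int(i, length(f_levels))) {
      v <- mean(d$p[d$f1 == f_levels[i] & d$f2 == f_levels[j]])
      m[i, j] <- v; m[j, i] <- v
    }
    m
  })
  names(mats) <- paste0("n", group_sizes)
  list(mean_p = mats, per_comparison = per_comparison)
}

#' Repeatability of the Interaction Factor estimate
#'
#' Recomputes the IF of one fixed scene with independent randomization seeds
#' and reports the spread. Variation is largest for scenes near random
#' overlap and shrinks as \code{n_sims} grows.
#'
#' @param scene an \code{if_scene}.
#' @param n_repeats number of repeated estimates (default 20).
#' @param n_sims random simulations per estimate (default 50).
#' @param seed integer seed.
#' @return list with \code{f_hat} (vector), \code{range}, \code{sd}.
#' @export
repeatability <- function(scene, n_repeats = 20, n_sims = 50, seed = NULL) {
  stopifnot(n_repeats >= 2)
  if (!is.null(seed)) set.seed(seed)
  f_hat <- vapply(seq_len(n_repeats), function(i)
    interaction_factor(scene, n_sims = n_sims,
                       direction = "forward")$fits[[1L]]$f_hat, numeric(1))
  list(f_hat = f_hat, range = max(f_hat) - min(f_hat), sd = stats::sd(f_hat))
}

#' Simulated versus analytic overlap curve
#'
#' For each IF on a grid, re-places the scene's clusters at that IF and
#' records the simulated overlap percentage of the reference clusters; the
#' analytic expectation from the scene's random overlap profile is overlaid.
#'
#' @param scene an \code{if_scene}.
#' @param f_grid IF grid in [0, 1) (default \code{seq(0, 0.9, by = 0.1)}).
#' @param sims_per_f simulated scenes per grid point (default 20).
#' @param n_sims simulations used for the analytic profile (default 50).
#' @param seed integer seed.
#' @return list with \code{curve} (data frame: f, mean/sd/se of simulated
#'   overlap fraction, analytic fraction) and \code{max_abs_diff}.
#' @export
if_curve <- function(scene, f_grid = seq(0, 0.9, by = 0.1), sims_per_f = 20,
                     n_sims = 50, seed = NULL) {
  stopifnot(all(f_grid >= 0), all(f_grid < 1))
  if (!is.null(seed)) set.seed(seed)
  prof <- estimate_profile(scene, n_sims = n_sims)
  prep <- roi_prep(scene$roi)
  a_ref <- anchor_sets(scene$ref, scene$roi, prep)
  a_oth <- anchor_sets(scene$other, scene$roi, prep)
  rows <- lapply(f_grid, function(f) {
    sims <- vapply(seq_len(sims_per_f), function(i) {
      other <- place_random(scene$other, scene$roi, anchors = a_oth)
      om <- rasterize(other)
      ref <- place_with_if(scene$ref, om, scene$roi, f = f, anchors = a_ref)
      mean(vapply(seq_len(n_clusters(ref)), function(k)
        any(om[cluster_pixels(ref, k)]), logical(1)))
    }, numeric(1))
    data.frame(f = f, mean_P = mean(sims), sd_P = stats::sd(sims),
               se_P = stats::sd(sims) / sqrt(sims_per_f),
               analytic_P = overlap_from_if(prof, f))
  })
  curve <- do.call(rbind, rows)
  list(curve = curve, max_abs_diff = max(abs(curve$mean_P - curve$analytic_P)),
       profile = prof)
}
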