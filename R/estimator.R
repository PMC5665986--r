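#' Estimate per-cluster random overlap probabilities
#'
#' Runs \code{n_sims} independent uniform randomizations of the scene and, for
#' each reference cluster \eqn{k}, records the fraction of simulations in
#' which it overlapped (shared at least one pixel with) the other channel.
#' These \eqn{p_k(0)} values are the only parameters of the overlap-versus-IF
#' relationship; with the default 50 simulations each probability is resolved
#' on a grid of 0.02.
#'
#' @param scene an \code{if_scene}; its \code{ref} set defines the reference
#'   direction.
#' @param n_sims number of random simulations (default 50).
#' @param randomize_both randomize the other channel in each simulation
#'   (default TRUE), or keep it at its original positions.
#' @return object of class \code{if_profile}: list with \code{p0} (length
#'   n-ref vector, index-aligned with the cluster set), \code{per_sim_fraction}
#'   (length \code{n_sims} vector of simulated overlap fractions, used for the
#'   empirical p-value), \code{n_sims}, \code{n_ref}.
#' @export
estimate_profile <- function(scene, n_sims = 50, randomize_both = TRUE) {
  stopifnot(inherits(scene, "if_scene"), n_sims >= 1)
  n_ref <- n_clusters(scene$ref)
  if (n_ref == 0L) stop("no reference clusters")
  h <- scene$dim[1L]; w <- scene$dim[2L]
  rcs <- roi_prep(scene$roi)
  a_ref <- anchor_sets(scene$ref, scene$roi, rcs)
  if (any(lengths(a_ref) == 0L))
    stop("a reference cluster has no valid position inside the ROI")
  off_ref <- lapply(scene$ref$shapes, shape_lin_offsets, h = h)

  if (randomize_both) {
    a_oth <- anchor_sets(scene$other, scene$roi, rcs)
    if (any(lengths(a_oth) == 0L))
      stop("an other-channel cluster has no valid position inside the ROI")
    off_oth <- lapply(scene$other$shapes, shape_lin_offsets, h = h)
    n_oth <- n_clusters(scene$other)
  } else {
    fixed_mask <- as.vector(rasterize(scene$other))
  }

  flags <- matrix(FALSE, n_ref, n_sims)
  for (s in seq_len(n_sims)) {
    if (randomize_both) {
      mask <- logical(h * w)
      for (j in seq_len(n_oth)) {
        va <- a_oth[[j]]
        mask[va[sample.int(length(va), 1L)] + off_oth[[j]]] <- TRUE
      }
    } else {
      mask <- fixed_mask
    }
    for (k in seq_len(n_ref)) {
      va <- a_ref[[k]]
      flags[k, s] <- any(mask[va[sample.int(length(va), 1L)] + off_ref[[k]]])
    }
  }
  structure(list(p0 = rowMeans(flags),
                 per_sim_fraction = colMeans(flags),
                 n_sims = as.integer(n_sims),
                 n_ref = n_ref),
            class = "if_profile")
}

#' @export
print.if_profile <- function(x, ...) {
  cat(sprintf("Random overlap profile: %d clusters, %d simulations\n",
              x$n_ref, x$n_sims))
  cat(sprintf("  mean p_k(0) = %.3f (range %.3f-%.3f)\n",
              mean(x$p0), min(x$p0), max(x$p0)))
  invisible(x)
}

profile_p0 <- function(profile) {
  if (inherits(profile, "if_profile")) profile$p0 else as.numeric(profile)
}

#' Expected overlap fraction at a given Interaction Factor
#'
#' The analytic overlap-versus-IF relationship: the expected fraction of
#' overlapping reference clusters at Interaction Factor \code{f} is the mean
#' over clusters of
#' \deqn{p_k(f) = \frac{p_k(0)}{1 - (1 - p_k(0)) f}.}
#' A cluster with \eqn{p_k(0) = 0} contributes 0 at every \code{f} (its
#' geometric placement series never terminates by overlap); a cluster with
#' \eqn{p_k(0) > 0} contributes 1 at \code{f = 1}.
#'
#' @param profile an \code{if_profile}, or a bare numeric vector of
#'   \eqn{p_k(0)} values.
#' @param f Interaction Factor in [0, 1] (vectorized).
#' @return expected overlap fraction(s) in [0, 1].
#' @export
overlap_from_if <- function(profile, f) {
  p <- profile_p0(profile)
  if (any(!is.finite(f)) || any(f < 0) || any(f > 1)) stop("f must lie in [0, 1]")
  vapply(f, function(fi) {
    terms <- ifelse(p == 0, 0, p / (1 - (1 - p) * fi))
    mean(terms)
  }, numeric(1))
}

#' Invert the overlap relationship: Interaction Factor from observed overlap
#'
#' Solves \code{overlap_from_if(profile, f) = observed} for \code{f} by
#' bisection on [0, 1] (the relationship is continuous and strictly
#' increasing whenever some \eqn{p_k(0)} lies in (0, 1)). Observed overlap at
#' or below the random level maps to 0 — overlap below chance is not
#' distinguished from no interaction — and observed overlap at or above the
#' attainable maximum maps to 1.
#'
#' @inheritParams overlap_from_if
#' @param observed observed fraction of overlapping reference clusters, in
#'   [0, 1].
#' @param tol bisection tolerance on f (default 1e-6).
#' @return the estimated Interaction Factor in [0, 1].
#' @export
if_from_overlap <- function(profile, observed, tol = 1e-6) {
  p <- profile_p0(profile)
  if (length(p) < 1L) stop("empty profile")
  if (!is.finite(observed) || observed < 0 || observed > 1)
    stop("observed fraction must lie in [0, 1]")
  lo_val <- mean(p)                 # P at f = 0
  hi_val <- mean(p > 0)             # P at f = 1
  if (observed <= lo_val) return(0)
  if (observed >= hi_val) return(1)
  if (all(p %in% c(0, 1)))
    stop("profile is degenerate (all p_k(0) are 0 or 1): observed overlap ",
         "between the attainable bounds cannot be inverted")
  lo <- 0; hi <- 1
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    if (overlap_from_if(p, mid) < observed) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Empirical p-value of the observed overlap
#'
#' Proportion of the random (IF = 0) simulations whose overlap fraction was
#' greater than or equal to the observed fraction. Quantized to multiples of
#' \code{1/n_sims}.
#'
#' @param profile an \code{if_profile} with recorded per-simulation fractions.
#' @param observed observed overlap fraction.
#' @return p-value in [0, 1].
#' @export
empirical_p_value <- function(profile, observed) {
  stopifnot(inherits(profile, "if_profile"))
  mean(profile$per_sim_fraction >= observed)
}

fit_direction <- function(scene, n_sims, randomize_both, connectivity) {
  obs <- overlap_stats(scene, connectivity = connectivity)
  prof <- estimate_profile(scene, n_sims = n_sims, randomize_both = randomize_both)
  list(reference = scene$ref$label,
       other = scene$other$label,
       f_hat = if_from_overlap(prof, obs$fraction),
       observed_fraction = obs$fraction,
       p_value = empirical_p_value(prof, obs$fraction),
       profile = prof,
       observed = obs)
}

#' Fit the Interaction Factor of a two-color cluster scene
#'
#' The main fitting function. For each direction (each channel taken in turn
#' as the reference color), it (i) measures the observed fraction of
#' reference clusters overlapping the other channel, (ii) estimates the
#' per-cluster random overlap probabilities from \code{n_sims} uniform
#' randomizations of the cluster positions inside the ROI, (iii) inverts the
#' analytic overlap-versus-IF relationship at the observed fraction, and
#' (iv) computes an empirical p-value against the random simulations.
#'
#' The resulting Interaction Factor lies in [0, 1]: 0 means the observed
#' co-localization is attributable to chance placement at the scene's cluster
#' density, 1 means complete co-localization. Unlike the raw overlap
#' fraction, Manders or Pearson coefficients, it is insensitive to cluster
#' density.
#'
#' @param scene an \code{if_scene} (from [segment_clusters()] +
#'   [cluster_scene()], or [simulate_scene()]).
#' @param n_sims number of random simulations per direction (default 50,
#'   resolving probabilities and p-values to 0.02).
#' @param randomize_both randomize both channels in the null simulations
#'   (default TRUE); if FALSE the other channel stays at its observed
#'   positions and only the reference channel is randomized.
#' @param direction \code{"both"} (default), \code{"forward"} (scene's
#'   \code{ref} as reference only) or \code{"reverse"}.
#' @param seed optional integer seed for reproducibility.
#' @param connectivity connectivity used for overlap-region counting.
#' @return an object of class \code{if_fit}; see [coef.if_fit()],
#'   [summary.if_fit()], [plot.if_fit()], [simulate.if_fit()].
#' @examples
#' scn <- simulate_scene(n_ref = 40, n_other = 40, f = 0.8, dim = c(160, 160),
#'                       roi = ellipse_roi(c(160, 160), c(70, 60)), seed = 1)
#' fit <- interaction_factor(scn, n_sims = 25, seed = 2)
#' coef(fit)
#' @export
interaction_factor <- function(scene, n_sims = 50, randomize_both = TRUE,
                               direction = c("both", "forward", "reverse"),
                               seed = NULL, connectivity = 8) {
  stopifnot(inherits(scene, "if_scene"))
  direction <- match.arg(direction)
  if (!is.null(seed)) set.seed(seed)
  if (n_clusters(scene$ref) == 0L || n_clusters(scene$other) == 0L)
    stop("both channels need at least one cluster")
  fits <- list()
  if (direction %in% c("both", "forward"))
    fits[[scene$ref$label]] <- fit_direction(scene, n_sims, randomize_both, connectivity)
  if (direction %in% c("both", "reverse"))
    fits[[scene$other$label]] <- fit_direction(swap_channels(scene), n_sims,
                                               randomize_both, connectivity)
  structure(list(fits = fits, scene = scene, n_sims = as.integer(n_sims),
                 randomize_both = randomize_both, seed = seed,
                 call = match.call()),
            class = "if_fit")
}

#' Extract fitted Interaction Factors
#'
#' @param object an \code{if_fit}.
#' @param ... unused.
#' @return named numeric vector, one Interaction Factor per reference
#'   direction, named \code{IF[ref=<channel>]}.
#' @export
coef.if_fit <- function(object, ...) {
  stats::setNames(vapply(object$fits, `[[`, numeric(1), "f_hat"),
                  sprintf("IF[ref=%s]", names(object$fits)))
}

#' @export
print.if_fit <- function(x, ...) {
  cat("Interaction Factor fit (", x$n_sims, " random simulations",
      if (!x$randomize_both) ", other channel fixed", ")\n", sep = "")
  for (nm in names(x$fits)) {
    d <- x$fits[[nm]]
    cat(sprintf("  reference %-8s IF = %.3f   overlap = %5.1f%%   p = %.3f\n",
                paste0("'", nm, "':"), d$f_hat, 100 * d$observed_fraction,
                d$p_value))
  }
  invisible(x)
}

#' Summarize an Interaction Factor fit
#'
#' @param object an \code{if_fit}.
#' @param ... unused.
#' @return a \code{summary.if_fit} object: per-direction table of IF,
#'   observed overlap percentage, p-value, cluster counts and mean random
#'   overlap probability, plus the shared overlap-region count and area.
#' @export
summary.if_fit <- function(object, ...) {
  dirs <- lapply(names(object$fits), function(nm) {
    d <- object$fits[[nm]]
    data.frame(reference = nm, other = d$other,
               n_ref = d$observed$n_ref,
               IF = d$f_hat,
               percent_overlap = 100 * d$observed_fraction,
               mean_p0 = mean(d$profile$p0),
               p_value = d$p_value)
  })
  first <- object$fits[[1L]]$observed
  structure(list(table = do.call(rbind, dirs),
                 n_regions = first$n_regions,
                 area_um2 = first$area_um2,
                 n_sims = object$n_sims, seed = object$seed),
            class = "summary.if_fit")
}

#' @export
print.summary.if_fit <- function(x, ...) {
  cat("Interaction Factor summary (", x$n_sims, " simulations)\n", sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  cat(sprintf("Overlap regions: %d; overlap area: %.4f um^2\n",
              x$n_regions, x$area_um2))
  invisible(x)
}

#' Predicted overlap fraction at a given Interaction Factor
#'
#' Evaluates the fitted analytic overlap curve of a direction at new
#' Interaction Factor values.
#'
#' @param object an \code{if_fit}.
#' @param f Interaction Factor value(s) in [0, 1]; defaults to the fitted
#'   value.
#' @param reference which direction's profile to use (channel label); default
#'   the first fitted direction.
#' @param ... unused.
#' @return expected overlap fraction(s).
#' @export
predict.if_fit <- function(object, f = NULL, reference = NULL, ...) {
  ref <- if (is.null(reference)) 1L else reference
  d <- object$fits[[ref]]
  if (is.null(d)) stop("no fitted direction '", reference, "'")
  if (is.null(f)) f <- d$f_hat
  overlap_from_if(d$profile, f)
}

#' Plot the fitted overlap-versus-IF curve
#'
#' Draws, for each fitted direction, the analytic expected overlap percentage
#' as a function of the Interaction Factor, with the observed overlap and the
#' fitted IF marked.
#'
#' @param x an \code{if_fit}.
#' @param ... passed to \code{matplot}.
#' @export
plot.if_fit <- function(x, ...) {
  f <- seq(0, 1, by = 0.01)
  curves <- sapply(x$fits, function(d) 100 * overlap_from_if(d$profile, f))
  graphics::matplot(f, curves, type = "l", lty = 1, lwd = 2,
                    col = seq_along(x$fits) + 1L,
                    xlab = "Interaction Factor",
                    ylab = "expected overlap of reference clusters (%)", ...)
  for (i in seq_along(x$fits)) {
    d <- x$fits[[i]]
    graphics::abline(h = 100 * d$observed_fraction, col = i + 1L, lty = 3)
    graphics::points(d$f_hat, 100 * overlap_from_if(d$profile, d$f_hat),
                     pch = 19, col = i + 1L)
  }
  graphics::legend("topleft", bty = "n", lwd = 2, col = seq_along(x$fits) + 1L,
                   legend = sprintf("ref = %s", names(x$fits)))
  invisible(x)
}

#' Simulate scenes from a fitted Interaction Factor
#'
#' Generates randomized versions of the fitted scene at the fitted (or any
#' requested) Interaction Factor, using the same placement procedure the
#' model assumes.
#'
#' @param object an \code{if_fit}.
#' @param nsim number of scenes (default 1).
#' @param seed optional integer seed.
#' @param f Interaction Factor for the simulated scenes; defaults to the
#'   first fitted direction's estimate.
#' @param ... unused.
#' @return list of \code{if_scene} objects.
#' @export
simulate.if_fit <- function(object, nsim = 1, seed = NULL, f = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(f)) f <- object$fits[[1L]]$f_hat
  lapply(seq_len(nsim), function(i)
    randomize_scene(object$scene, f = f,
                    randomize_both = object$randomize_both))
}
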