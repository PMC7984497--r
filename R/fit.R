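#' Estimate water-rich and fat-rich cluster centers
#'
#' Two-centroid estimation on the `(W, F)` intensity pairs of the
#' soft-tissue voxels, with deterministic initialization: the water seed is
#' the centroid of voxels whose water fraction `W / (W + F)` lies above its
#' 90th percentile, the fat seed the centroid below the 10th. Centroids are
#' refined by alternating nearest-center assignment and mean updates until
#' the largest centroid motion falls below `tol` times the intensity range,
#' or `max_iter` iterations. The returned `water_center` is the converged
#' centroid with the larger water fraction.
#'
#' Voxels with zero total signal carry no water-fat information and are
#' excluded before seeding.
#'
#' @param dixon a [dixon_volume()].
#' @param soft_mask logical [vol3d]: the soft-tissue voxels to cluster
#'   (bone is excluded by design — the classification line is defined by
#'   soft tissue only).
#' @param tol convergence tolerance as a fraction of the intensity range.
#' @param max_iter maximum refinement iterations.
#' @return A list with `water_center`, `fat_center` (numeric `(W, F)`
#'   pairs), `iterations`, `converged`, `sizes` (cluster sizes), `n`.
#' @export
estimate_cluster_centers <- function(dixon, soft_mask, tol = 1e-6,
                                     max_iter = 100L) {
  stopifnot(is_dixon_volume(dixon))
  stopifnot_vol3d(soft_mask, "soft_mask")
  assert_same_grid(dixon$water, soft_mask, "dixon and soft mask")
  sel <- soft_mask$data
  if (!any(sel)) stop("soft mask is empty", call. = FALSE)
  w <- as.numeric(dixon$water$data[sel])
  f <- as.numeric(dixon$fat$data[sel])
  tot <- w + f
  keep <- tot > 0
  w <- w[keep]; f <- f[keep]
  if (length(w) < 2L)
    stop("degenerate clusters: fewer than two voxels with signal",
         call. = FALSE)
  rng <- max(max(w) - min(w), max(f) - min(f))
  if (rng == 0)
    stop("degenerate clusters: constant intensity within the soft mask",
         call. = FALSE)
  ratio <- w / (w + f)
  q <- stats::quantile(ratio, c(0.1, 0.9), names = FALSE)
  hi <- ratio >= q[2]; lo <- ratio <= q[1]
  if (!any(hi) || !any(lo))
    stop("degenerate clusters: water-fraction percentiles are empty",
         call. = FALSE)
  centers <- rbind(c(mean(w[hi]), mean(f[hi])),
                   c(mean(w[lo]), mean(f[lo])))
  if (all(centers[1, ] == centers[2, ]))
    stop("degenerate clusters: identical seeds", call. = FALSE)
  iterations <- 0L
  converged <- FALSE
  assign1 <- NULL
  for (it in seq_len(max_iter)) {
    iterations <- it
    d1 <- (w - centers[1, 1])^2 + (f - centers[1, 2])^2
    d2 <- (w - centers[2, 1])^2 + (f - centers[2, 2])^2
    assign1 <- d1 <= d2
    if (!any(assign1) || all(assign1))
      stop("degenerate clusters: one cluster is empty", call. = FALSE)
    new_centers <- rbind(c(mean(w[assign1]), mean(f[assign1])),
                         c(mean(w[!assign1]), mean(f[!assign1])))
    motion <- max(abs(new_centers - centers))
    centers <- new_centers
    if (motion < tol * rng) { converged <- TRUE; break }
  }
  wf <- centers[, 1] / (centers[, 1] + centers[, 2])
  water_idx <- which.max(wf)
  sizes <- c(sum(assign1), sum(!assign1))
  list(water_center = centers[water_idx, ],
       fat_center = centers[3L - water_idx, ],
       iterations = iterations, converged = converged,
       sizes = c(water = sizes[water_idx], fat = sizes[3L - water_idx]),
       n = length(w))
}

#' Fit the water-fat classification model to a Dixon volume
#'
#' Estimates the water-rich and fat-rich cluster centers from the
#' soft-tissue voxels (see [estimate_cluster_centers()]) and wraps them in
#' an [hu_model] together with the HU endpoints of the soft-tissue and bone
#' continua. The fitted object carries the estimation diagnostics and can
#' generate synthetic CTs through [predict.hu_model()].
#'
#' @inheritParams estimate_cluster_centers
#' @param ... HU endpoints and `d_max` passed to [hu_model()].
#' @return An [hu_model] with a `fit` element (`n`, `iterations`,
#'   `converged`, `sizes`) and the data summary used by [plot.hu_model()].
#' @examples
#' ph <- build_phantom(phantom_spec(shape = c(24, 32, 32),
#'                                  spacing_mm = rep(5, 3)))
#' dx <- simulate_dixon(ph, noise_sigma = 0, seed = 1)
#' fit <- fit_hu_model(dx, ph$masks$soft)
#' fit
#' @export
fit_hu_model <- function(dixon, soft_mask, tol = 1e-6, max_iter = 100L,
                         ...) {
  est <- estimate_cluster_centers(dixon, soft_mask, tol = tol,
                                  max_iter = max_iter)
  model <- hu_model(water_center = est$water_center,
                    fat_center = est$fat_center, ...)
  model$fit <- est[c("n", "iterations", "converged", "sizes")]
  sel <- soft_mask$data
  w <- as.numeric(dixon$water$data[sel])
  f <- as.numeric(dixon$fat$data[sel])
  idx <- if (length(w) > 20000L) {
    round(seq(1L, length(w), length.out = 20000L))
  } else seq_along(w)
  model$fit$sample <- cbind(w = w[idx], f = f[idx])
  model
}

#' @export
summary.hu_model <- function(object, ...) {
  out <- list(coef = coef(object), fit = object$fit)
  class(out) <- "summary.hu_model"
  out
}

#' @export
print.summary.hu_model <- function(x, ...) {
  cat("Water-fat classification model\n\nCoefficients:\n")
  print(x$coef)
  if (!is.null(x$fit)) {
    cat(sprintf("\nCluster estimation: n = %d soft-tissue voxels, %d iterations (%s)\n",
                x$fit$n, x$fit$iterations,
                if (x$fit$converged) "converged" else "not converged"))
    cat(sprintf("  cluster sizes: water %d, fat %d\n",
                x$fit$sizes["water"], x$fit$sizes["fat"]))
  }
  invisible(x)
}

#' Scatter plot of the water-fat classification
#'
#' Plots the `(W, F)` sample retained by [fit_hu_model()] with the two
#' cluster centers and the classification line.
#'
#' @param x a fitted [hu_model].
#' @param ... further arguments to [graphics::plot()].
#' @export
plot.hu_model <- function(x, ...) {
  if (is.null(x$fit$sample))
    stop("no stored sample: plot() requires a model from fit_hu_model()",
         call. = FALSE)
  s <- x$fit$sample
  graphics::plot(s[, "w"], s[, "f"], pch = ".", col = "grey40",
                 xlab = "water intensity", ylab = "fat intensity", ...)
  graphics::segments(x$water_center[1], x$water_center[2],
                     x$fat_center[1], x$fat_center[2], col = "red", lwd = 2)
  graphics::points(rbind(x$water_center, x$fat_center), pch = 18,
                   col = "red", cex = 2)
  invisible(x)
}
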