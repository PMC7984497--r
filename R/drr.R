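#' Linear attenuation coefficient from Hounsfield units
#'
#' `mu = mu_water * (1 + hu / 1000)`, floored at zero: water (0 HU) maps to
#' `mu_water`, air (-1000 HU) to zero.
#'
#' @param hu numeric HU values.
#' @param mu_water attenuation of water in 1/mm (default 0.02, a typical
#'   megavoltage-range value).
#' @return Attenuation coefficients in 1/mm.
#' @export
hu_to_attenuation <- function(hu, mu_water = 0.02) {
  if (mu_water <= 0) stop("mu_water must be positive", call. = FALSE)
  pmax(mu_water * (1 + hu / 1000), 0)
}

#' Digitally reconstructed radiograph by parallel-beam projection
#'
#' Orthographic line integrals of the attenuation map: each output pixel is
#' the sum along the projection axis of `hu_to_attenuation(voxel) *
#' spacing_along_axis`. `"AP"` projects along the anterior-posterior (y)
#' axis onto a `(z, x)` image; `"RL"` projects along the right-left (x)
#' axis onto a `(z, y)` image. Both DRRs of a comparison share this
#' geometry, which is what the correlation analysis requires.
#'
#' @param vol a [vol3d] in HU.
#' @param axis `"AP"` or `"RL"`.
#' @param mu_water water attenuation in 1/mm.
#' @return An object of class `"drr_image"`: list with `data` (2D matrix of
#'   path-integrated attenuation), `pixel_spacing` (mm), `projection_axis`.
#' @export
compute_drr <- function(vol, axis = c("AP", "RL"), mu_water = 0.02) {
  stopifnot_vol3d(vol, "vol")
  axis <- match.arg(axis)
  mu <- hu_to_attenuation(vol$data, mu_water)
  ax_idx <- if (axis == "AP") 2L else 3L
  img <- apply(mu, setdiff(1:3, ax_idx), sum) * vol$spacing[ax_idx]
  px <- vol$spacing[setdiff(1:3, ax_idx)]
  structure(list(data = img, pixel_spacing = px, projection_axis = axis),
            class = "drr_image")
}

#' @export
print.drr_image <- function(x, ...) {
  cat(sprintf("<drr_image> %s projection, %d x %d px at %s mm\n",
              x$projection_axis, nrow(x$data), ncol(x$data),
              paste(format(x$pixel_spacing, digits = 3), collapse = " x ")))
  invisible(x)
}

#' Pearson correlation of two images
#'
#' Standard product-moment correlation over all pixels; the DRR similarity
#' metric.
#'
#' @param a,b numeric arrays of identical shape with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_cc <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("images must have identical shapes", call. = FALSE)
  av <- as.numeric(a); bv <- as.numeric(b)
  if (stats::sd(av) == 0 || stats::sd(bv) == 0)
    stop("undefined correlation: an image has zero variance", call. = FALSE)
  stats::cor(av, bv)
}

# 1D parabolic sub-sample refinement around an interior grid maximum of a
# similarity profile: vertex of the parabola through (-1, c_minus),
# (0, c0), (1, c_plus), clamped to half a sample
parabolic_offset <- function(c_minus, c0, c_plus) {
  denom <- c_minus - 2 * c0 + c_plus
  if (!is.finite(denom) || denom >= -1e-15) return(0)
  off <- 0.5 * (c_minus - c_plus) / denom
  max(-0.5, min(0.5, off))
}

#' Register two DRRs by exhaustive translation search
#'
#' Integer-pixel translations within `+/- search_px` per axis are scored by
#' [pearson_cc()] on the overlap region (at least half the image must
#' overlap); the best shift is refined per axis by a parabolic fit to the
#' correlation profile. Ties break toward the smallest shift magnitude,
#' then lexicographically.
#'
#' @param fixed,moving [compute_drr()] images with equal pixel spacing.
#' @param search_px non-negative integer search radius in pixels.
#' @return List with `shift_mm` (length-2, axis order of the image rows and
#'   columns), `shift_px`, and `pcc` at the optimum.
#' @export
register_drr_2d <- function(fixed, moving, search_px = 5L) {
  stopifnot(inherits(fixed, "drr_image"), inherits(moving, "drr_image"))
  if (any(abs(fixed$pixel_spacing - moving$pixel_spacing) > 1e-6))
    stop("DRRs must share pixel spacing", call. = FALSE)
  if (!identical(dim(fixed$data), dim(moving$data)))
    stop("DRRs must share shape", call. = FALSE)
  if (search_px < 0) stop("search_px must be non-negative", call. = FALSE)
  fd <- fixed$data; md <- moving$data
  d <- dim(fd)
  shifts <- expand.grid(di = -search_px:search_px, dj = -search_px:search_px)
  score <- rep(NA_real_, nrow(shifts))
  min_overlap <- 0.5 * prod(d)
  for (k in seq_len(nrow(shifts))) {
    di <- shifts$di[k]; dj <- shifts$dj[k]
    # moving content sits at +shift; sample it at p + shift to match fixed
    fi <- max(1, 1 - di):min(d[1], d[1] - di)
    fj <- max(1, 1 - dj):min(d[2], d[2] - dj)
    if (length(fi) * length(fj) < min_overlap) next
    fsub <- fd[fi, fj, drop = FALSE]
    msub <- md[fi + di, fj + dj, drop = FALSE]
    if (stats::sd(fsub) == 0 || stats::sd(msub) == 0) next
    score[k] <- stats::cor(as.numeric(fsub), as.numeric(msub))
  }
  if (all(is.na(score)))
    stop("registration failure: no valid overlap", call. = FALSE)
  best <- max(score, na.rm = TRUE)
  cand <- which(!is.na(score) & score >= best - 1e-12)
  mag <- shifts$di[cand]^2 + shifts$dj[cand]^2
  cand <- cand[order(mag, shifts$di[cand], shifts$dj[cand])][1]
  di <- shifts$di[cand]; dj <- shifts$dj[cand]
  get_score <- function(i, j) {
    k <- which(shifts$di == i & shifts$dj == j)
    if (length(k) == 1 && !is.na(score[k])) score[k] else NA_real_
  }
  ref <- c(0, 0)
  if (score[cand] < 1 - 1e-12) {  # an exact match needs no refinement
    for (axis in 1:2) {
      lo <- get_score(di - (axis == 1), dj - (axis == 2))
      hi <- get_score(di + (axis == 1), dj + (axis == 2))
      if (!is.na(lo) && !is.na(hi))
        ref[axis] <- parabolic_offset(lo, score[cand], hi)
    }
  }
  px <- c(di, dj) + ref
  list(shift_px = px, shift_mm = px * fixed$pixel_spacing,
       pcc = score[cand])
}
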