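#' Water-fat classification model for continuous-HU mapping
#'
#' The model holds the two estimated cluster centers on the water-vs-fat
#' intensity scatter plot, and the Hounsfield-unit endpoints of the two
#' tissue continua. Soft-tissue voxels are mapped by their scalar projection
#' `t` onto the classification line (the segment joining the water-rich and
#' fat-rich centers): `t = 0` at the water center gives `hu_muscle`, `t = 1`
#' at the fat center gives `hu_fat`, linearly in between, with `t` clamped
#' to `[0, 1]`. Bone voxels are mapped by their perpendicular distance `d`
#' from that line: `d = 0` gives `hu_spongy` (light spongy bone), `d >=
#' d_max` gives `hu_cortical` (dense cortical bone), linearly in between —
#' dense bone presents as low Dixon signal, far from the soft-tissue line.
#'
#' The HU endpoints are configuration defaults placed in standard tissue-HU
#' ranges; they are not calibrated values, and every one of them is a free
#' parameter.
#'
#' @param water_center,fat_center numeric length-2 `(W, F)` intensity pairs;
#'   must differ.
#' @param hu_muscle HU assigned at the water center (default +40).
#' @param hu_fat HU assigned at the fat center (default -100).
#' @param hu_spongy bone HU floor at distance 0 (default +100).
#' @param hu_cortical bone HU cap (default +1500).
#' @param d_max perpendicular distance (signal units) at which the cortical
#'   cap is reached; default `NULL` means the distance between the two
#'   cluster centers.
#' @param hu_air HU assigned outside the body outline (default -1000).
#' @return An object of class `"hu_model"`.
#' @seealso [fit_hu_model()] to estimate the centers from data,
#'   [predict.hu_model()] to generate an sCT.
#' @examples
#' m <- hu_model(water_center = c(100, 0), fat_center = c(0, 100))
#' line_coordinates(50, 50, m)   # midpoint of the line: t = 0.5, d = 0
#' soft_tissue_hu(50, 50, m)     # -> -30 HU
#' @export
hu_model <- function(water_center, fat_center,
                     hu_muscle = 40, hu_fat = -100,
                     hu_spongy = 100, hu_cortical = 1500,
                     d_max = NULL, hu_air = -1000) {
  water_center <- as.numeric(water_center)
  fat_center <- as.numeric(fat_center)
  if (length(water_center) != 2L || length(fat_center) != 2L)
    stop("cluster centers must be (W, F) pairs", call. = FALSE)
  sep <- sqrt(sum((fat_center - water_center)^2))
  if (sep == 0)
    stop("water and fat centers must differ", call. = FALSE)
  if (is.null(d_max)) d_max <- sep
  if (!(hu_fat < hu_muscle && hu_muscle < hu_spongy &&
        hu_spongy < hu_cortical))
    stop("HU endpoints must satisfy hu_fat < hu_muscle < hu_spongy < hu_cortical",
         call. = FALSE)
  if (d_max <= 0) stop("d_max must be positive", call. = FALSE)
  structure(list(water_center = water_center, fat_center = fat_center,
                 hu_muscle = hu_muscle, hu_fat = hu_fat,
                 hu_spongy = hu_spongy, hu_cortical = hu_cortical,
                 d_max = d_max, hu_air = hu_air),
            class = "hu_model")
}

is_hu_model <- function(x) inherits(x, "hu_model")

#' @export
print.hu_model <- function(x, ...) {
  cat("Water-fat classification model\n")
  cat(sprintf("  water center (W, F): (%.2f, %.2f)   -> %+.0f HU (muscle)\n",
              x$water_center[1], x$water_center[2], x$hu_muscle))
  cat(sprintf("  fat center   (W, F): (%.2f, %.2f)   -> %+.0f HU (fat)\n",
              x$fat_center[1], x$fat_center[2], x$hu_fat))
  cat(sprintf("  bone: %+.0f HU (spongy, d = 0) to %+.0f HU (cortical, d >= %.2f)\n",
              x$hu_spongy, x$hu_cortical, x$d_max))
  cat(sprintf("  air outside body: %+.0f HU\n", x$hu_air))
  if (!is.null(x$fit))
    cat(sprintf("  fitted on %d soft-tissue voxels (%d iterations, %s)\n",
                x$fit$n, x$fit$iterations,
                if (x$fit$converged) "converged" else "not converged"))
  invisible(x)
}

#' @export
coef.hu_model <- function(object, ...) {
  c(water_w = object$water_center[1], water_f = object$water_center[2],
    fat_w = object$fat_center[1], fat_f = object$fat_center[2],
    hu_muscle = object$hu_muscle, hu_fat = object$hu_fat,
    hu_spongy = object$hu_spongy, hu_cortical = object$hu_cortical,
    d_max = object$d_max, hu_air = object$hu_air)
}

#' Line coordinates of intensity pairs
#'
#' Computes, for each `(w, f)` intensity pair, the scalar projection `t`
#' onto the classification line (0 at the water center, 1 at the fat
#' center, unclamped) and the non-negative perpendicular distance `d` from
#' the infinite line through the two centers.
#'
#' @param w,f numeric vectors of water and fat intensities (recycled
#'   together).
#' @param model an [hu_model].
#' @return A list with numeric components `t` and `d`.
#' @export
line_coordinates <- function(w, f, model) {
  stopifnot(is_hu_model(model))
  vx <- model$fat_center[1] - model$water_center[1]
  vy <- model$fat_center[2] - model$water_center[2]
  L2 <- vx * vx + vy * vy
  px <- w - model$water_center[1]
  py <- f - model$water_center[2]
  t <- (px * vx + py * vy) / L2
  d <- abs(px * vy - py * vx) / sqrt(L2)
  list(t = t, d = d)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Continuous soft-tissue HU from Dixon intensities
#'
#' `hu = hu_muscle + clamp(t, 0, 1) * (hu_fat - hu_muscle)`: water-dominant
#' voxels map to the muscle endpoint, fat-dominant voxels to the fat
#' endpoint, mixed voxels linearly in between.
#'
#' @inheritParams line_coordinates
#' @return Numeric vector of HU values.
#' @export
soft_tissue_hu <- function(w, f, model) {
  lc <- line_coordinates(w, f, model)
  model$hu_muscle + clamp01(lc$t) * (model$hu_fat - model$hu_muscle)
}

#' Continuous bone HU from Dixon intensities
#'
#' `hu = hu_spongy + clamp(d / d_max, 0, 1) * (hu_cortical - hu_spongy)`:
#' bone voxels near the soft-tissue classification line map to light spongy
#' bone, voxels far from it (low signal) to dense cortical bone.
#'
#' @inheritParams line_coordinates
#' @return Numeric vector of HU values.
#' @export
bone_hu <- function(w, f, model) {
  lc <- line_coordinates(w, f, model)
  model$hu_spongy + clamp01(lc$d / model$d_max) *
    (model$hu_cortical - model$hu_spongy)
}

#' Five-class bulk-density table
#'
#' The legacy bulk-density mode assigns one HU per tissue class: air, fat,
#' soft tissue, spongy bone, cortical bone. Soft-tissue voxels split on the
#' clamped line coordinate `t` (fat when `t > t_split`), bone voxels on the
#' normalized line distance (cortical when `d / d_max > d_split`).
#'
#' @param hu named numeric of length 5 in the order air, fat, soft, spongy,
#'   cortical; values must be strictly increasing.
#' @param t_split soft/fat split threshold on `t` (default 0.5).
#' @param d_split spongy/cortical split threshold on `d / d_max`
#'   (default 0.5).
#' @return An object of class `"bulk_density_table"`.
#' @export
bulk_density_table <- function(hu = c(air = -1000, fat = -100, soft = 40,
                                      spongy = 200, cortical = 1200),
                               t_split = 0.5, d_split = 0.5) {
  if (length(hu) != 5L)
    stop("the bulk-density table has exactly five classes", call. = FALSE)
  if (any(diff(hu) <= 0))
    stop("bulk HU values must be strictly increasing (air, fat, soft, spongy, cortical)",
         call. = FALSE)
  names(hu) <- c("air", "fat", "soft", "spongy", "cortical")
  structure(list(hu = hu, t_split = t_split, d_split = d_split),
            class = "bulk_density_table")
}

#' @export
print.bulk_density_table <- function(x, ...) {
  cat("Bulk-density table (HU):\n")
  print(x$hu)
  cat(sprintf("  fat/soft split at t > %.2f; cortical/spongy at d/d_max > %.2f\n",
              x$t_split, x$d_split))
  invisible(x)
}
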