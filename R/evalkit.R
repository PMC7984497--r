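#' Tissue-specific mean absolute error between sCT and CT
#'
#' `MAE_X = mean(|sct - ct|)` over the voxels of compartment `X`, computed
#' for bone, soft tissue and the whole body contour. An empty compartment
#' is reported as `NA` (absent), never as zero.
#'
#' @param ct,sct [vol3d] volumes in HU on one grid.
#' @param masks a [mask_set()].
#' @return An object of class `"mae_report"`: list with `mae_bone`,
#'   `mae_soft`, `mae_body` and voxel counts `n_bone`, `n_soft`, `n_body`.
#' @export
tissue_mae <- function(ct, sct, masks) {
  stopifnot_vol3d(ct, "ct"); stopifnot_vol3d(sct, "sct")
  stopifnot(inherits(masks, "mask_set"))
  assert_same_grid(ct, sct, "ct and sct")
  assert_same_grid(ct, masks$body, "ct and masks")
  err <- abs(sct$data - ct$data)
  cmp <- function(m) if (any(m)) mean(err[m]) else NA_real_
  out <- list(mae_bone = cmp(masks$bone$data),
              mae_soft = cmp(masks$soft$data),
              mae_body = cmp(masks$body$data),
              n_bone = sum(masks$bone$data),
              n_soft = sum(masks$soft$data),
              n_body = sum(masks$body$data))
  class(out) <- "mae_report"
  out
}

#' @export
print.mae_report <- function(x, ...) {
  cat("Tissue-specific MAE (HU):\n")
  cat(sprintf("  bone: %8.2f  (%d voxels)\n", x$mae_bone, x$n_bone))
  cat(sprintf("  soft: %8.2f  (%d voxels)\n", x$mae_soft, x$n_soft))
  cat(sprintf("  body: %8.2f  (%d voxels)\n", x$mae_body, x$n_body))
  invisible(x)
}

axis_index <- c(SI = 1L, AP = 2L, RL = 3L)

#' Translation-only bone-based 3D alignment
#'
#' Exhaustive integer-voxel translation search within `+/- search_mm` per
#' axis, maximizing normalized cross-correlation between `fixed` and the
#' shifted `moving` over the bone mask (dilated by `dilate_voxels` to
#' include bone edges), followed by per-axis parabolic sub-voxel
#' refinement. Ties break toward the smallest shift magnitude, then
#' lexicographically. The returned offset is the translation of the moving
#' volume's content relative to the fixed volume, i.e.
#' `rigid_align_3d(ct, simulate_cbct(ct, s), ...)` recovers `s`.
#'
#' @param fixed,moving [vol3d] volumes on one grid.
#' @param bone_mask logical [vol3d]; the similarity is evaluated on these
#'   voxels (dilated).
#' @param search_mm search radius in mm (applied per axis).
#' @param dilate_voxels dilation of the bone mask (default 2).
#' @return Numeric length-3 offset in mm, `(LR, AP, SI)` order.
#' @export
rigid_align_3d <- function(fixed, moving, bone_mask, search_mm = 12.5,
                           dilate_voxels = 2L) {
  stopifnot_vol3d(fixed, "fixed"); stopifnot_vol3d(moving, "moving")
  stopifnot_vol3d(bone_mask, "bone_mask")
  assert_same_grid(fixed, moving, "fixed and moving")
  assert_same_grid(fixed, bone_mask, "fixed and bone mask")
  if (!any(bone_mask$data)) stop("bone mask is empty", call. = FALSE)
  d <- dim(fixed$data)
  r <- pmax(0L, floor(search_mm / fixed$spacing))
  if (any(2 * r + 1 > d))
    stop("search window exceeds the volume", call. = FALSE)
  mask <- dilate_mask(bone_mask$data, dilate_voxels)
  ind <- which(mask, arr.ind = TRUE)
  fvals_all <- fixed$data[mask]
  mv <- moving$data
  nz <- d[1]; nzy <- d[1] * d[2]
  grid <- expand.grid(dz = -r[1]:r[1], dy = -r[2]:r[2], dx = -r[3]:r[3])
  score <- rep(NA_real_, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    pz <- ind[, 1] + grid$dz[k]
    py <- ind[, 2] + grid$dy[k]
    px <- ind[, 3] + grid$dx[k]
    ok <- pz >= 1 & pz <= d[1] & py >= 1 & py <= d[2] & px >= 1 & px <= d[3]
    if (sum(ok) < max(8, 0.25 * nrow(ind))) next
    mvals <- mv[pz[ok] + (py[ok] - 1) * nz + (px[ok] - 1) * nzy]
    fvals <- fvals_all[ok]
    if (stats::sd(fvals) == 0 || stats::sd(mvals) == 0) next
    score[k] <- stats::cor(fvals, mvals)
  }
  if (all(is.na(score)))
    stop("alignment failure: no valid search position", call. = FALSE)
  best <- max(score, na.rm = TRUE)
  cand <- which(!is.na(score) & score >= best - 1e-12)
  mag <- grid$dz[cand]^2 + grid$dy[cand]^2 + grid$dx[cand]^2
  cand <- cand[order(mag, grid$dz[cand], grid$dy[cand], grid$dx[cand])][1]
  t_vox <- c(grid$dz[cand], grid$dy[cand], grid$dx[cand])
  lookup <- function(dz, dy, dx) {
    k <- which(grid$dz == dz & grid$dy == dy & grid$dx == dx)
    if (length(k) == 1 && !is.na(score[k])) score[k] else NA_real_
  }
  ref <- c(0, 0, 0)
  if (score[cand] < 1 - 1e-12) {  # an exact match needs no refinement
    for (axis in 1:3) {
      e <- c(0, 0, 0); e[axis] <- 1
      lo <- lookup(t_vox[1] - e[1], t_vox[2] - e[2], t_vox[3] - e[3])
      hi <- lookup(t_vox[1] + e[1], t_vox[2] + e[2], t_vox[3] + e[3])
      if (!is.na(lo) && !is.na(hi))
        ref[axis] <- parabolic_offset(lo, score[cand], hi)
    }
  }
  offset_zyx <- (t_vox + ref) * fixed$spacing
  rev(offset_zyx)  # (LR, AP, SI)
}

#' Difference of CBCT alignment offsets with CT vs sCT as reference
#'
#' `rigid_align_3d(ct, cbct) - rigid_align_3d(sct, cbct)`, per axis: the
#' geometric penalty of using the sCT instead of the CT as the alignment
#' reference for an on-treatment CBCT.
#'
#' @param ct,sct,cbct [vol3d] volumes on one grid.
#' @param bone_mask logical [vol3d].
#' @param search_mm search radius in mm.
#' @return Numeric length-3 `(dLR, dAP, dSI)` in mm.
#' @export
cbct_offset_difference <- function(ct, sct, cbct, bone_mask,
                                   search_mm = 12.5) {
  rigid_align_3d(ct, cbct, bone_mask, search_mm) -
    rigid_align_3d(sct, cbct, bone_mask, search_mm)
}

reverse_along <- function(a, axis) {
  idx <- list(seq_len(dim(a)[1]), seq_len(dim(a)[2]), seq_len(dim(a)[3]))
  idx[[axis]] <- rev(idx[[axis]])
  do.call(`[`, c(list(a), idx))
}

cumsum_along <- function(a, axis) {
  out <- switch(axis,
    apply(a, c(2, 3), cumsum),
    aperm(apply(a, c(1, 3), cumsum), c(2, 1, 3)),
    aperm(apply(a, c(1, 2), cumsum), c(2, 3, 1)))
  out
}

#' Ray-cast exponential dose proxy
#'
#' A deliberately simple stand-in for a treatment-planning dose engine,
#' used to exercise the CT-vs-sCT dose comparison workflow — it makes no
#' claim of clinical fidelity. Each beam enters through one face of the
#' volume and attenuates exponentially: the transmitted fluence after `k`
#' voxels along a ray is `d0 * exp(-sum(mu * spacing))`. With
#' `deposit = "kerma"` (default) the dose scored in a voxel is the
#' transmitted fluence times the voxel's relative attenuation
#' `mu / mu_water` — locally absorbed energy, which gives air cavities the
#' near-zero dose they show in a real calculation. With
#' `deposit = "fluence"` the transmitted fluence itself is scored (so an
#' all-air volume records `d0` everywhere).
#'
#' @param ct a [vol3d] in HU.
#' @param beams list of beams, each a list with `axis` (`"AP"`, `"RL"` or
#'   `"SI"`), `direction` (+1 enters at the low-index face, -1 at the
#'   high-index face) and optional `field_mask` (2D logical matrix over the
#'   perpendicular plane; `NULL` irradiates the whole face).
#' @param mu_water water attenuation in 1/mm.
#' @param d0 entrance dose per beam (Gy).
#' @param deposit `"kerma"` or `"fluence"`.
#' @return A [vol3d] dose grid (Gy), the sum over beams.
#' @export
dose_proxy <- function(ct, beams, mu_water = 0.02, d0 = 2,
                       deposit = c("kerma", "fluence")) {
  stopifnot_vol3d(ct, "ct")
  deposit <- match.arg(deposit)
  if (length(beams) < 1) stop("at least one beam is required", call. = FALSE)
  mu <- hu_to_attenuation(ct$data, mu_water)
  d <- dim(mu)
  total <- array(0, d)
  for (b in beams) {
    axis <- unname(axis_index[as.character(b$axis)])
    if (is.na(axis))
      stop(sprintf("unknown beam axis '%s'", b$axis), call. = FALSE)
    dir <- b$direction %||% 1
    m <- if (dir > 0) mu else reverse_along(mu, axis)
    path <- cumsum_along(m * ct$spacing[axis], axis)
    fl <- d0 * exp(-path)
    dose <- if (deposit == "kerma") fl * m / mu_water else fl
    if (dir < 0) dose <- reverse_along(dose, axis)
    if (!is.null(b$field_mask)) {
      fm <- b$field_mask
      perp <- setdiff(1:3, axis)
      if (!identical(dim(fm), d[perp]))
        stop("field_mask shape must match the perpendicular plane",
             call. = FALSE)
      if (!any(fm)) stop("empty field mask", call. = FALSE)
      fm3 <- aperm(array(rep(fm, d[axis]), c(d[perp], d[axis])),
                   order(c(perp, axis)))
      dose <- dose * fm3
    }
    total <- total + dose
  }
  with_data(ct, total)
}

# dose received by at least `frac` of the structure volume: linear
# interpolation on the descending-sorted voxel doses at cumulative volume
# fractions i/n
dose_at_volume_fraction <- function(sorted_desc, frac) {
  n <- length(sorted_desc)
  stats::approx(x = seq_len(n) / n, y = sorted_desc, xout = frac,
                rule = 2)$y
}

#' Dose-volume histogram metrics for one structure
#'
#' `d_max` is the hottest voxel, `d_mean` the mean, `d_95` and `d_53` the
#' maximum dose received by at least 95% / 53% of the structure volume
#' (sorted-dose linear interpolation), and `d_1cc` the maximum dose
#' received by at least 1 cm^3 (voxel volume from the grid spacing). A
#' structure smaller than 1 cm^3 reports `d_1cc = d_max` with
#' `d1cc_capped = TRUE` and a warning.
#'
#' @param dose a [vol3d] dose grid (Gy).
#' @param structure logical [vol3d], nonempty.
#' @return An object of class `"dvh_metrics"`: list with `d_max`, `d_mean`,
#'   `d_95`, `d_53`, `d_1cc`, `d1cc_capped`, `n_voxels`, `volume_cc`.
#' @export
dvh_metrics <- function(dose, structure) {
  stopifnot_vol3d(dose, "dose"); stopifnot_vol3d(structure, "structure")
  assert_same_grid(dose, structure, "dose and structure")
  sel <- structure$data
  if (!any(sel)) stop("structure mask is empty", call. = FALSE)
  dv <- sort(dose$data[sel], decreasing = TRUE)
  vox_cc <- prod(dose$spacing) / 1000
  vol_cc <- length(dv) * vox_cc
  capped <- vol_cc < 1
  if (capped)
    warning("structure smaller than 1 cm^3: d_1cc reported as d_max",
            call. = FALSE)
  out <- list(d_max = dv[1],
              d_mean = mean(dv),
              d_95 = dose_at_volume_fraction(dv, 0.95),
              d_53 = dose_at_volume_fraction(dv, 0.53),
              d_1cc = if (capped) dv[1]
                      else dose_at_volume_fraction(dv, 1 / vol_cc),
              d1cc_capped = capped,
              n_voxels = length(dv),
              volume_cc = vol_cc)
  class(out) <- "dvh_metrics"
  out
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf("DVH metrics (%.1f cc): Dmax %.3f, Dmean %.3f, D95 %.3f, D53 %.3f, D1cc %.3f Gy%s\n",
              x$volume_cc, x$d_max, x$d_mean, x$d_95, x$d_53, x$d_1cc,
              if (x$d1cc_capped) " (D1cc capped at Dmax)" else ""))
  invisible(x)
}

#' DVH metrics for a set of structures
#'
#' @param dose a [vol3d] dose grid.
#' @param structures named list of logical [vol3d] masks.
#' @return A named list of [dvh_metrics()] results, class
#'   `"dose_metrics_report"`.
#' @export
dose_metrics_report <- function(dose, structures) {
  out <- lapply(structures, function(s) dvh_metrics(dose, s))
  class(out) <- "dose_metrics_report"
  out
}

dvh_metric_names <- c("d_max", "d_mean", "d_95", "d_53", "d_1cc")

#' Percent DVH differences, sCT relative to CT
#'
#' `100 * (sct - ct) / ct` per metric per structure; a zero CT metric gives
#' `NA` (undefined, reported as absent). Accepts either single
#' [dvh_metrics()] objects or matching [dose_metrics_report()] lists.
#'
#' @param metrics_ct,metrics_sct metrics computed on the CT / sCT dose.
#' @return For single structures, a named numeric of percent differences;
#'   for reports, a named list of such vectors.
#' @export
percent_dose_diff <- function(metrics_ct, metrics_sct) {
  if (inherits(metrics_ct, "dose_metrics_report")) {
    stopifnot(inherits(metrics_sct, "dose_metrics_report"),
              identical(names(metrics_ct), names(metrics_sct)))
    return(mapply(percent_dose_diff, metrics_ct, metrics_sct,
                  SIMPLIFY = FALSE))
  }
  stopifnot(inherits(metrics_ct, "dvh_metrics"),
            inherits(metrics_sct, "dvh_metrics"))
  ct <- unlist(metrics_ct[dvh_metric_names])
  sct <- unlist(metrics_sct[dvh_metric_names])
  out <- 100 * (sct - ct) / ct
  out[ct == 0] <- NA_real_
  out
}

#' Assemble a structured evaluation report
#'
#' Collects whatever evaluation pieces are available — tissue MAE, DVH
#' percent differences, DRR correlations, alignment offsets — into one
#' versioned, JSON-serializable report.
#'
#' @param mae optional [tissue_mae()] result.
#' @param dose_diff optional [percent_dose_diff()] result (report form).
#' @param drr_pcc optional named numeric of per-axis DRR Pearson
#'   correlations.
#' @param offsets optional `(dLR, dAP, dSI)` mm from
#'   [cbct_offset_difference()].
#' @return An object of class `"sct_report"`.
#' @export
make_report <- function(mae = NULL, dose_diff = NULL, drr_pcc = NULL,
                        offsets = NULL) {
  rep <- list(schema_version = "1.0")
  if (!is.null(mae))
    rep$mae <- list(bone = mae$mae_bone, soft = mae$mae_soft,
                    body = mae$mae_body)
  if (!is.null(dose_diff)) rep$dose_percent_diff <- dose_diff
  if (!is.null(drr_pcc)) rep$drr_pcc <- as.list(drr_pcc)
  if (!is.null(offsets))
    rep$alignment_offset_mm <- list(lr = offsets[[1]], ap = offsets[[2]],
                                    si = offsets[[3]])
  class(rep) <- "sct_report"
  rep
}

#' @export
print.sct_report <- function(x, ...) {
  cat(sprintf("sCT evaluation report (schema %s)\n", x$schema_version))
  if (!is.null(x$mae)) {
    cat("  MAE (HU):\n")
    for (nm in names(x$mae))
      cat(sprintf("    %-5s %8.2f\n", nm, x$mae[[nm]]))
  }
  if (!is.null(x$drr_pcc)) {
    cat("  DRR PCC:",
        paste(sprintf("%s %.4f", names(x$drr_pcc),
                      unlist(x$drr_pcc)), collapse = ", "), "\n")
  }
  if (!is.null(x$alignment_offset_mm))
    cat(sprintf("  CBCT offset difference (LR, AP, SI): (%.2f, %.2f, %.2f) mm\n",
                x$alignment_offset_mm$lr, x$alignment_offset_mm$ap,
                x$alignment_offset_mm$si))
  if (!is.null(x$dose_percent_diff)) {
    cat("  DVH percent differences (sCT vs CT):\n")
    for (nm in names(x$dose_percent_diff)) {
      v <- x$dose_percent_diff[[nm]]
      cat(sprintf("    %-8s %s\n", nm,
                  paste(sprintf("%s %+0.2f%%", names(v), v),
                        collapse = ", ")))
    }
  }
  invisible(x)
}

#' Serialize / parse an evaluation report as JSON
#'
#' @param report an [make_report()] object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return `report_to_json()`: the JSON string (invisibly when written to
#'   file); `report_from_json()`: the parsed `"sct_report"`.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "sct_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @rdname report_to_json
#' @param json JSON string or file path.
#' @export
report_from_json <- function(json) {
  parsed <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  structure(parsed, class = "sct_report")
}
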