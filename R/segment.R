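#' Segment the body outline from Dixon images
#'
#' Thresholds the in-phase channel at a configurable fraction of its Otsu
#' threshold, keeps the largest connected component, applies morphological
#' closing, and fills internal holes per axial slice — so enclosed air
#' (e.g. rectal gas) is merged into the body outline and will later be
#' mapped as soft tissue.
#'
#' @param dixon a [dixon_volume()].
#' @param otsu_fraction threshold as a fraction of the Otsu threshold of
#'   the in-phase signal (default 0.2).
#' @param closing_radius radius (voxels) of the morphological closing.
#' @return Logical [vol3d] body mask (one connected component).
#' @export
segment_body <- function(dixon, otsu_fraction = 0.2, closing_radius = 2L) {
  stopifnot(is_dixon_volume(dixon))
  ip <- dixon$in_phase$data
  thr <- otsu_fraction * otsu_threshold(ip)
  mask <- ip > thr
  if (!any(mask))
    stop("segmentation failure: no voxels above the body threshold",
         call. = FALSE)
  mask <- largest_component(mask)
  mask <- close_mask(mask, closing_radius)
  mask <- fill_holes_slicewise(mask)
  with_data(dixon$in_phase, mask)
}

#' Intensity-and-morphology bone-mask surrogate
#'
#' A stand-in for model-based bone segmentation (which requires a
#' proprietary statistical shape model): candidate bone voxels are body
#' voxels whose in-phase signal falls below `bone_fraction` times the
#' body-median in-phase signal, excluding a peripheral rind (erosion of the
#' body mask) and the neighbourhood of internal air (near-zero signal).
#' Candidates are cleaned by morphological opening and minimum-component
#' size filtering, then enclosed cavities are filled: only the cortical
#' shell is dark enough to threshold, and filling recovers the trabecular
#' core it encloses. All downstream operations also accept an externally
#' supplied bone mask, so this surrogate is never load-bearing.
#'
#' @param dixon a [dixon_volume()].
#' @param body logical [vol3d] body mask.
#' @param bone_fraction in-phase threshold as a fraction of the body-median
#'   in-phase signal (default 0.35).
#' @param rind_voxels peripheral exclusion: erosion radius of the body mask
#'   (default 2).
#' @param air_fraction in-phase level below which a voxel counts as
#'   internal air (fraction of the body median, default 0.05).
#' @param air_min_voxels internal air must form a connected component of at
#'   least this many voxels (default 20) — isolated noise-dark voxels
#'   inside cortical bone are not air.
#' @param opening_radius radius of the cleaning opening (default 1).
#' @param min_component_voxels discard candidate components smaller than
#'   this (default 50).
#' @return Logical [vol3d] bone mask (possibly empty), a subset of `body`.
#' @export
segment_bone_surrogate <- function(dixon, body, bone_fraction = 0.35,
                                   rind_voxels = 2L, air_fraction = 0.05,
                                   air_min_voxels = 20L,
                                   opening_radius = 1L,
                                   min_component_voxels = 50L) {
  stopifnot(is_dixon_volume(dixon))
  stopifnot_vol3d(body, "body")
  assert_same_grid(dixon$in_phase, body, "dixon and body mask")
  ip <- dixon$in_phase$data
  bm <- body$data
  med <- stats::median(ip[bm])
  cand <- bm & ip < bone_fraction * med
  cand <- cand & erode_mask(bm, rind_voxels)
  air <- bm & ip < air_fraction * med
  if (any(air)) {
    lab <- label_components(air)
    sizes <- tabulate(lab[lab > 0])
    air <- array(lab > 0 & lab %in% which(sizes >= air_min_voxels),
                 dim(lab))
  }
  if (any(air)) cand <- cand & !dilate_mask(air, 1L)
  # fill cavities enclosed by detected shell before opening: the shell may
  # be only 1-2 voxels thick and would not survive the opening on its own
  if (any(cand)) cand <- fill_holes(cand)
  cand <- open_mask(cand, opening_radius)
  if (any(cand)) {
    lab <- label_components(cand)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component_voxels)
    cand <- array(lab %in% keep & lab > 0, dim(lab))
  }
  cand <- cand & bm
  with_data(body, cand)
}
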