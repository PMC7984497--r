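#' Generate a continuous-HU synthetic CT
#'
#' Voxelwise HU assignment on the Dixon grid: voxels outside the body
#' outline receive `hu_air`; bone-mask voxels receive [bone_hu()] (distance
#' from the classification line); all remaining body voxels — the
#' soft-tissue compartment, which deliberately includes any air enclosed by
#' the body outline — receive [soft_tissue_hu()] (projection onto the
#' line). Mapping internal air as soft tissue replicates the validated
#' clinical software's behaviour, including its known limitation for
#' rectal gas.
#'
#' @param dixon a [dixon_volume()].
#' @param masks a [mask_set()] on the same grid.
#' @param model an [hu_model].
#' @return A [vol3d] of Hounsfield units.
#' @export
generate_sct <- function(dixon, masks, model) {
  stopifnot(is_dixon_volume(dixon), inherits(masks, "mask_set"),
            is_hu_model(model))
  assert_same_grid(dixon$water, masks$body, "dixon and masks")
  w <- dixon$water$data
  f <- dixon$fat$data
  out <- array(model$hu_air, dim(w))
  soft <- masks$soft$data
  bone <- masks$bone$data
  if (any(soft))
    out[soft] <- soft_tissue_hu(w[soft], f[soft], model)
  if (any(bone))
    out[bone] <- bone_hu(w[bone], f[bone], model)
  with_data(dixon$water, out)
}

#' Generate a five-class bulk-density synthetic CT
#'
#' The legacy mode: one HU per tissue class. Outside the body gives air;
#' soft-tissue voxels give the fat HU when the clamped line coordinate
#' exceeds `table$t_split`, else the soft-tissue HU; bone voxels give the
#' cortical HU when `d / d_max` exceeds `table$d_split`, else the spongy
#' HU. The output takes at most the table's five values.
#'
#' @inheritParams generate_sct
#' @param table a [bulk_density_table()].
#' @return A [vol3d] of Hounsfield units with at most five distinct values.
#' @export
generate_sct_bulk <- function(dixon, masks, model,
                              table = bulk_density_table()) {
  stopifnot(is_dixon_volume(dixon), inherits(masks, "mask_set"),
            is_hu_model(model), inherits(table, "bulk_density_table"))
  assert_same_grid(dixon$water, masks$body, "dixon and masks")
  w <- dixon$water$data
  f <- dixon$fat$data
  out <- array(table$hu[["air"]], dim(w))
  soft <- masks$soft$data
  bone <- masks$bone$data
  if (any(soft)) {
    lc <- line_coordinates(w[soft], f[soft], model)
    out[soft] <- ifelse(clamp01(lc$t) > table$t_split,
                        table$hu[["fat"]], table$hu[["soft"]])
  }
  if (any(bone)) {
    lc <- line_coordinates(w[bone], f[bone], model)
    out[bone] <- ifelse(lc$d / model$d_max > table$d_split,
                        table$hu[["cortical"]], table$hu[["spongy"]])
  }
  with_data(dixon$water, out)
}

#' Predict method: synthetic CT from a fitted classification model
#'
#' Dispatches to [generate_sct()] (`mode = "continuous"`, the default) or
#' [generate_sct_bulk()] (`mode = "bulk"`).
#'
#' @param object an [hu_model], typically from [fit_hu_model()].
#' @param dixon a [dixon_volume()].
#' @param masks a [mask_set()].
#' @param mode `"continuous"` or `"bulk"`.
#' @param table [bulk_density_table()] used in bulk mode.
#' @param ... unused.
#' @return A [vol3d] of Hounsfield units.
#' @export
predict.hu_model <- function(object, dixon, masks,
                             mode = c("continuous", "bulk"),
                             table = bulk_density_table(), ...) {
  mode <- match.arg(mode)
  if (mode == "continuous") generate_sct(dixon, masks, object)
  else generate_sct_bulk(dixon, masks, object, table)
}

#' Residuals of a synthetic CT against a reference CT
#'
#' Voxelwise `sct - ct` differences restricted to the body mask; the basis
#' of the tissue-specific mean-absolute-error evaluation.
#'
#' @param object an [hu_model].
#' @param dixon a [dixon_volume()].
#' @param masks a [mask_set()].
#' @param ct reference CT ([vol3d], HU).
#' @param ... passed to [predict.hu_model()].
#' @return Numeric vector of HU differences over body voxels.
#' @export
residuals.hu_model <- function(object, dixon, masks, ct, ...) {
  sct <- predict(object, dixon, masks, ...)
  assert_same_grid(sct, ct, "sCT and CT")
  (sct$data - ct$data)[masks$body$data]
}
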