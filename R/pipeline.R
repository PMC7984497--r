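#' Run the phantom-to-report pipeline
#'
#' Wires the package's stages into one reproducible run: build the digital
#' phantom, forward-simulate Dixon channels, segment (or take the truth
#' masks), fit the classification model, generate the sCT, compute DRRs,
#' and evaluate (tissue MAE, DRR correlation, CBCT alignment offsets, dose
#' proxy + DVH differences). Every artifact is written under `out_dir`
#' together with a YAML sidecar recording the configuration, seed and
#' package version; the log records the estimated cluster centers and the
#' headline metrics.
#'
#' @param config `NULL` (bundled demo configuration), a path to a YAML
#'   file, or a configuration list. Recognized top-level keys: `stages`
#'   (subset of `phantom`, `segment`, `sct`, `drr`, `eval`), `phantom`
#'   (arguments to [phantom_spec()]), `sct` (`mode`, `use_truth_masks`),
#'   `drr` (`axes`, `mu_water`), `eval` (`dose`, `cbct`, `search_mm`).
#' @param out_dir output directory, created if needed.
#' @param seed root RNG seed; all stage seeds derive from it.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the run's objects (`truth`, `dixon`,
#'   `masks`, `model`, `sct`, `report`, `paths`).
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("dixonsct_run"),
                         seed = 1L, quiet = FALSE) {
  cfg <- load_pipeline_config(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  paths <- list()
  res <- list()

  spec_args <- cfg$phantom %||% list()
  spec_args$seed <- seed
  spec <- do.call(phantom_spec, spec_args)
  truth <- build_phantom(spec)
  res$truth <- truth
  say("phantom: %s grid, %d body voxels",
      paste(dim(truth$ct$data), collapse = "x"),
      sum(truth$masks$body$data))
  dixon <- simulate_dixon(truth, seed = seed)
  res$dixon <- dixon
  if ("phantom" %in% stages) {
    paths$ct <- file.path(out_dir, "ct.nii.gz")
    write_volume(truth$ct, paths$ct)
    write_volume(dixon$water, file.path(out_dir, "water.nii.gz"))
    write_volume(dixon$fat, file.path(out_dir, "fat.nii.gz"))
    write_volume(dixon$in_phase, file.path(out_dir, "in_phase.nii.gz"))
    mask_dir <- file.path(out_dir, "masks")
    dir.create(mask_dir, showWarnings = FALSE)
    write_volume(truth$masks$body, file.path(mask_dir, "body.nii.gz"))
    write_volume(truth$masks$bone, file.path(mask_dir, "bone.nii.gz"))
    for (nm in names(truth$masks$structures))
      write_volume(truth$masks$structures[[nm]],
                   file.path(mask_dir, paste0(nm, ".nii.gz")))
  }

  sct_cfg <- cfg$sct %||% list()
  use_truth <- isTRUE(sct_cfg[["use_truth_masks"]])
  if ("segment" %in% stages && !use_truth) {
    body <- segment_body(dixon)
    bone <- segment_bone_surrogate(dixon, body)
    masks <- mask_set(body, bone, structures = truth$masks$structures)
    say("segment: body %d voxels, bone %d voxels",
        sum(body$data), sum(bone$data))
  } else {
    masks <- truth$masks
  }
  res$masks <- masks

  model_args <- sct_cfg[["model"]] %||% list()
  model <- do.call(fit_hu_model,
                   c(list(dixon = dixon, soft_mask = masks$soft),
                     model_args))
  res$model <- model
  say("cluster centers: water (%.2f, %.2f), fat (%.2f, %.2f)",
      model$water_center[1], model$water_center[2],
      model$fat_center[1], model$fat_center[2])

  mode <- sct_cfg[["mode"]] %||% "continuous"
  sct <- predict(model, dixon, masks, mode = mode)
  res$sct <- sct
  if ("sct" %in% stages) {
    paths$sct <- file.path(out_dir, "sct.nii.gz")
    write_volume(sct, paths$sct)
  }

  drr_cfg <- cfg$drr %||% list()
  mu_water <- drr_cfg$mu_water %||% 0.02
  drr_pcc <- NULL
  if ("drr" %in% stages) {
    axes <- unlist(drr_cfg$axes) %||% c("AP", "RL")
    drr_pcc <- vapply(axes, function(ax) {
      dc <- compute_drr(truth$ct, ax, mu_water)
      ds <- compute_drr(sct, ax, mu_water)
      pearson_cc(dc$data, ds$data)
    }, 0)
    names(drr_pcc) <- axes
    say("DRR PCC: %s",
        paste(sprintf("%s %.4f", axes, drr_pcc), collapse = ", "))
  }

  report <- NULL
  if ("eval" %in% stages) {
    eval_cfg <- cfg$eval %||% list()
    mae <- tissue_mae(truth$ct, sct, truth$masks)
    say("MAE (HU): bone %.1f, soft %.1f, body %.1f",
        mae$mae_bone, mae$mae_soft, mae$mae_body)
    offsets <- NULL
    cb <- eval_cfg$cbct %||% list()
    if (!identical(cb$enabled %||% TRUE, FALSE)) {
      shift <- unlist(cb$shift_mm) %||% c(3, -2.5, 5)
      cbct <- simulate_cbct(truth$ct, shift,
                            noise_sigma_hu = cb$noise_sigma_hu %||% 20,
                            seed = seed + 101L)
      offsets <- cbct_offset_difference(truth$ct, sct, cbct,
                                        truth$masks$bone,
                                        search_mm = eval_cfg$search_mm %||%
                                          4 * max(truth$ct$spacing))
      say("CBCT offset difference (LR, AP, SI): (%.2f, %.2f, %.2f) mm",
          offsets[1], offsets[2], offsets[3])
    }
    dose_diff <- NULL
    dz <- eval_cfg$dose %||% list()
    if (!identical(dz$enabled %||% TRUE, FALSE) &&
        !is.null(truth$masks$structures$ptv)) {
      beams <- default_box_beams(dz$n_beams %||% 4L)
      dose_ct <- dose_proxy(truth$ct, beams, mu_water)
      dose_sct <- dose_proxy(sct, beams, mu_water)
      strs <- truth$masks$structures[intersect(c("ptv", "bladder", "rectum"),
                                     names(truth$masks$structures))]
      mr_ct <- dose_metrics_report(dose_ct, strs)
      mr_sct <- dose_metrics_report(dose_sct, strs)
      dose_diff <- percent_dose_diff(mr_ct, mr_sct)
      say("PTV D95 percent difference: %+.3f%%", dose_diff$ptv["d_95"])
    }
    report <- make_report(mae = mae, dose_diff = dose_diff,
                          drr_pcc = drr_pcc, offsets = offsets)
    paths$report <- file.path(out_dir, "report.json")
    report_to_json(report, paths$report)
  }
  res$report <- report

  sidecar <- list(package = "dixonsct",
                  version = as.character(utils::packageVersion("dixonsct")),
                  seed = seed,
                  config = strip_for_yaml(cfg),
                  cluster_centers = list(water = as.numeric(model$water_center),
                                         fat = as.numeric(model$fat_center)))
  yaml::write_yaml(sidecar, file.path(out_dir, "run.yaml"))
  res$paths <- paths
  invisible(res)
}

# beams of the simple box arrangement: 2 = opposed lateral, 4 = box
default_box_beams <- function(n) {
  beams <- list(list(axis = "RL", direction = 1),
                list(axis = "RL", direction = -1),
                list(axis = "AP", direction = 1),
                list(axis = "AP", direction = -1))
  beams[seq_len(min(n, 4L))]
}

load_pipeline_config <- function(config) {
  cfg <- if (is.null(config)) {
    yaml::read_yaml(system.file("extdata", "demo_config.yaml",
                                package = "dixonsct"))
  } else if (is.character(config)) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    yaml::read_yaml(config)
  } else if (is.list(config)) {
    config
  } else stop("'config' must be NULL, a file path, or a list",
              call. = FALSE)
  known <- c("stages", "phantom", "sct", "drr", "eval")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  cfg$stages <- unlist(cfg$stages) %||%
    c("phantom", "segment", "sct", "drr", "eval")
  bad_stage <- setdiff(cfg$stages, c("phantom", "segment", "sct", "drr",
                                     "eval"))
  if (length(bad_stage))
    stop(sprintf("unknown stage(s): %s", paste(bad_stage, collapse = ", ")),
         call. = FALSE)
  if (!is.null(cfg$phantom)) {
    bad_ph <- setdiff(names(cfg$phantom), names(formals(phantom_spec)))
    if (length(bad_ph))
      stop(sprintf("unknown phantom field(s): %s",
                   paste0("phantom.", bad_ph, collapse = ", ")),
           call. = FALSE)
  }
  cfg
}

strip_for_yaml <- function(x) {
  if (is.list(x)) lapply(x, strip_for_yaml)
  else if (is.function(x) || inherits(x, "hu_model")) NULL
  else x
}
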