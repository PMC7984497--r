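#' Specification of the digital pelvis phantom
#'
#' Describes a pelvis-like anatomy used as ground truth throughout the
#' package: an ellipsoidal body with a subcutaneous fat rind and a smooth
#' fat-fraction transition zone, two femoral heads (cortical shell +
#' trabecular core), a pelvic-ring torus, an anterior bladder, a posterior
#' rectum with an optional enclosed air cavity, and a spherical planning
#' target volume (PTV). Geometry is deterministic; stochasticity enters
#' only through the forward Dixon simulator ([simulate_dixon()]).
#'
#' All positions and sizes are in mm, world coordinates centered on the
#' grid, `(z, y, x) = (SI, AP, RL)` order. Defaults give a 160 x 240 x 240
#' mm volume at 2.5 mm isotropic spacing.
#'
#' @param shape grid dimensions `(z, y, x)`.
#' @param spacing_mm voxel size `(z, y, x)` in mm.
#' @param body_semiaxes_mm body ellipsoid semi-axes `(z, y, x)`.
#' @param fat_rind_mm thickness of the subcutaneous fat layer (fat fraction
#'   1).
#' @param transition_mm thickness of the fat-fraction ramp between rind and
#'   muscle.
#' @param femur_offset_mm `(z, y, |x|)` center of each femoral head (the
#'   pair sits at +/- x).
#' @param femur_radius_mm,femur_shell_mm femoral head radius and cortical
#'   shell thickness.
#' @param ring_center_mm,ring_major_mm,ring_tube_mm,ring_shell_mm pelvic
#'   ring torus: center, major (ring) radius in the axial plane, tube
#'   radius, cortical shell thickness.
#' @param bladder_center_mm,bladder_semiaxes_mm,bladder_hu bladder
#'   ellipsoid and its near-water HU.
#' @param rectum_center_yx_mm,rectum_radius_mm,rectum_halflength_mm rectum
#'   cylinder (axis along z).
#' @param air_cavity logical: include an enclosed rectal gas pocket.
#' @param air_center_mm,air_radius_mm,air_halflength_mm gas pocket cylinder
#'   (must lie inside the rectum lumen). The default places it in the
#'   superior rectum.
#' @param ptv,ptv_center_mm,ptv_radius_mm spherical PTV structure.
#' @param trabecular_hu HU of trabecular (spongy-range) bone cores.
#' @param noise_sigma Gaussian channel noise s.d. as a fraction of the
#'   reference soft-tissue signal S0 (see [simulate_dixon()]).
#' @param bias_field logical: multiplicative low-order polynomial bias per
#'   channel (off by default).
#' @param bias_amplitude peak relative amplitude of the bias field.
#' @param seed default RNG seed for the simulators.
#' @param model the generating [hu_model]; defaults to [phantom_model()].
#' @return An object of class `"phantom_spec"` (a validated list).
#' @export
phantom_spec <- function(shape = c(64, 96, 96),
                         spacing_mm = c(2.5, 2.5, 2.5),
                         body_semiaxes_mm = c(150, 85, 110),
                         fat_rind_mm = 12,
                         transition_mm = 8,
                         femur_offset_mm = c(-10, 8, 68),
                         femur_radius_mm = 22,
                         femur_shell_mm = 5,
                         ring_center_mm = c(12, 0, 0),
                         ring_major_mm = 60,
                         ring_tube_mm = 13,
                         ring_shell_mm = 4,
                         bladder_center_mm = c(0, -30, 0),
                         bladder_semiaxes_mm = c(25, 28, 30),
                         bladder_hu = 0,
                         rectum_center_yx_mm = c(25, 0),
                         rectum_radius_mm = 16,
                         rectum_halflength_mm = 40,
                         air_cavity = TRUE,
                         air_center_mm = c(34, 25, 0),
                         air_radius_mm = 6,
                         air_halflength_mm = 7,
                         ptv = TRUE,
                         ptv_center_mm = c(0, 15, 0),
                         ptv_radius_mm = 24,
                         trabecular_hu = 400,
                         noise_sigma = 0.02,
                         bias_field = FALSE,
                         bias_amplitude = 0.1,
                         seed = 1L,
                         model = phantom_model()) {
  spec <- as.list(environment())
  if (length(spec$shape) != 3L || any(spec$shape < 8))
    stop("'shape' must be three dimensions of at least 8", call. = FALSE)
  if (any(spec$spacing_mm <= 0)) stop("spacing must be positive",
                                      call. = FALSE)
  if (spec$noise_sigma < 0) stop("noise_sigma must be non-negative",
                                 call. = FALSE)
  if (!is_hu_model(model)) stop("'model' must be an hu_model", call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

#' Generating classification model of the digital phantom
#'
#' The forward Dixon model is the exact inverse of the continuous HU
#' mapping: soft tissue with fat fraction `FF` is placed at
#' `water_center + FF * (fat_center - water_center)` so the line coordinate
#' `t` equals `FF`, and bone is placed at the perpendicular distance that
#' inverts its truth HU, on the low-signal side of the line. Non-negative
#' signals bound the representable distance by the line's distance from the
#' intensity origin (`S0 / sqrt(2)` here), so the generating model uses
#' `d_max = 65` signal units rather than the default center separation.
#'
#' @param S0 reference soft-tissue total signal (arbitrary units).
#' @param d_max perpendicular-distance scale of the bone continuum.
#' @param ... further arguments to [hu_model()].
#' @return An [hu_model].
#' @export
phantom_model <- function(S0 = 100, d_max = 65, ...) {
  hu_model(water_center = c(S0, 0), fat_center = c(0, S0),
           d_max = d_max, ...)
}

# world-coordinate arrays (z, y, x), grid centered at 0
coord_arrays <- function(shape, spacing) {
  cz <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * spacing[1]
  cy <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * spacing[2]
  cx <- (seq_len(shape[3]) - (shape[3] + 1) / 2) * spacing[3]
  list(z = array(rep(cz, times = shape[2] * shape[3]), shape),
       y = array(rep(rep(cy, each = shape[1]), times = shape[3]), shape),
       x = array(rep(cx, each = shape[1] * shape[2]), shape),
       origin = c(cz[1], cy[1], cx[1]))
}

#' Build the ground-truth phantom
#'
#' Deterministically constructs the truth CT (HU), the tissue masks and the
#' fat-fraction map from a [phantom_spec()]. HU assignment: air outside the
#' body; fat rind at the fat endpoint; muscle at the muscle endpoint; a
#' linear fat-fraction ramp between them; bladder at its near-water HU;
#' enclosed rectal gas at air HU (flagged in `masks$structures$internal_air`
#' but part of the soft compartment, as the mapping will treat it); bone as
#' a cortical shell at the cortical endpoint over a trabecular core.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `"phantom_truth"`: list with `ct` ([vol3d]),
#'   `masks` ([mask_set]), `fat_fraction` ([vol3d] in `[0, 1]`), `model`
#'   (the generating [hu_model]) and `spec`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  m <- spec$model
  sh <- spec$shape; sp <- spec$spacing_mm
  cc <- coord_arrays(sh, sp)
  Z <- cc$z; Y <- cc$y; X <- cc$x

  ax <- spec$body_semiaxes_mm
  rho <- sqrt((Z / ax[1])^2 + (Y / ax[2])^2 + (X / ax[3])^2)
  body <- rho <= 1

  char_r <- min(ax[2], ax[3])
  u1 <- 1 - spec$fat_rind_mm / char_r
  u0 <- u1 - spec$transition_mm / char_r
  ff <- array(0, sh)
  ramp <- body & rho > u0 & rho <= u1
  ff[ramp] <- (rho[ramp] - u0) / (u1 - u0)
  ff[body & rho > u1] <- 1

  # bladder
  bc <- spec$bladder_center_mm; bs <- spec$bladder_semiaxes_mm
  bladder <- ((Z - bc[1]) / bs[1])^2 + ((Y - bc[2]) / bs[2])^2 +
    ((X - bc[3]) / bs[3])^2 <= 1
  ff_bladder <- (spec$bladder_hu - m$hu_muscle) / (m$hu_fat - m$hu_muscle)
  if (ff_bladder < 0 || ff_bladder > 1)
    stop("bladder HU must lie within the soft-tissue continuum",
         call. = FALSE)
  ff[bladder] <- ff_bladder

  # rectum (mask only; wall is muscle-like, FF 0)
  rc <- spec$rectum_center_yx_mm
  rectum <- sqrt((Y - rc[1])^2 + (X - rc[2])^2) <= spec$rectum_radius_mm &
    abs(Z) <= spec$rectum_halflength_mm
  ff[rectum & !bladder] <- 0

  # enclosed rectal gas pocket
  internal_air <- array(FALSE, sh)
  if (isTRUE(spec$air_cavity)) {
    ac <- spec$air_center_mm
    internal_air <- sqrt((Y - ac[2])^2 + (X - ac[3])^2) <= spec$air_radius_mm &
      abs(Z - ac[1]) <= spec$air_halflength_mm
    if (any(internal_air & !rectum))
      stop("air cavity must lie inside the rectum", call. = FALSE)
  }

  # bone: femoral heads + pelvic ring torus, cortical shells
  fo <- spec$femur_offset_mm
  bone <- array(FALSE, sh); cortical <- array(FALSE, sh)
  for (sx in c(-1, 1)) {
    dd <- sqrt((Z - fo[1])^2 + (Y - fo[2])^2 + (X - sx * fo[3])^2)
    sphere <- dd <= spec$femur_radius_mm
    bone <- bone | sphere
    cortical <- cortical |
      (sphere & dd > spec$femur_radius_mm - spec$femur_shell_mm)
  }
  tc <- spec$ring_center_mm
  dring <- sqrt((sqrt((X - tc[3])^2 + (Y - tc[2])^2) - spec$ring_major_mm)^2 +
                (Z - tc[1])^2)
  tube <- dring <= spec$ring_tube_mm
  bone <- bone | tube
  cortical <- cortical | (tube & dring > spec$ring_tube_mm - spec$ring_shell_mm)
  cortical <- cortical & bone

  for (nm in c("bladder", "rectum", "internal_air")) {
    organ <- get(nm)
    if (any(organ & !body))
      stop(sprintf("%s extends outside the body", nm), call. = FALSE)
  }
  if (any(bone & !body)) stop("bone extends outside the body", call. = FALSE)
  if (any(internal_air & bone))
    stop("air cavity intersects bone", call. = FALSE)

  # truth HU
  ct <- array(m$hu_air, sh)
  soft <- body & !bone
  ct[soft] <- m$hu_muscle + ff[soft] * (m$hu_fat - m$hu_muscle)
  ct[internal_air & soft] <- m$hu_air
  ct[bone] <- spec$trabecular_hu
  ct[cortical] <- m$hu_cortical

  ff[!soft | internal_air] <- 0

  grid <- function(a) vol3d(a, spacing = sp, origin = cc$origin)
  structures <- list(bladder = grid(bladder & soft),
                     rectum = grid(rectum & soft),
                     internal_air = grid(internal_air & soft),
                     cortical = grid(cortical))
  if (isTRUE(spec$ptv)) {
    pc <- spec$ptv_center_mm
    ptv <- sqrt((Z - pc[1])^2 + (Y - pc[2])^2 + (X - pc[3])^2) <=
      spec$ptv_radius_mm
    if (any(ptv & !body)) stop("PTV extends outside the body", call. = FALSE)
    structures$ptv <- grid(ptv)
  }
  masks <- mask_set(body = grid(body), bone = grid(bone),
                    structures = structures)
  structure(list(ct = grid(ct), masks = masks, fat_fraction = grid(ff),
                 model = m, spec = spec),
            class = "phantom_truth")
}

#' @export
print.phantom_truth <- function(x, ...) {
  d <- dim(x$ct$data)
  cat(sprintf("<phantom_truth> %d x %d x %d (z,y,x) at %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$ct$spacing, digits = 3), collapse = " x ")))
  print(x$masks)
  cat(sprintf("  truth CT in [%g, %g] HU\n", min(x$ct$data), max(x$ct$data)))
  invisible(x)
}

#' Forward-simulate Dixon signals from the phantom truth
#'
#' The exact inverse of the continuous HU mapping. Soft-tissue voxels with
#' fat fraction `FF` receive the signal
#' `water_center + FF * (fat_center - water_center)` (so the noiseless line
#' coordinate `t` equals `FF`); bone voxels are placed at the perpendicular
#' distance from the classification line that inverts their truth HU, on
#' the low-signal side; air (outside the body and enclosed gas) gives zero
#' signal. Gaussian noise of s.d. `noise_sigma * S0` is added per channel
#' and clipped at zero; an optional smooth multiplicative bias field can be
#' applied per channel. The in-phase channel is `W + F`.
#'
#' @param truth a [build_phantom()] result.
#' @param model generating [hu_model]; defaults to the phantom's.
#' @param noise_sigma relative noise s.d.; defaults to the spec's.
#' @param seed RNG seed; defaults to the spec's.
#' @return A [dixon_volume()].
#' @export
simulate_dixon <- function(truth, model = truth$model,
                           noise_sigma = truth$spec$noise_sigma,
                           seed = truth$spec$seed) {
  stopifnot(inherits(truth, "phantom_truth"), is_hu_model(model))
  if (noise_sigma < 0) stop("noise_sigma must be non-negative",
                            call. = FALSE)
  sh <- dim(truth$ct$data)
  wc <- model$water_center; fc <- model$fat_center
  S0 <- mean(c(sum(wc), sum(fc)))
  W <- array(0, sh); F <- array(0, sh)

  soft <- truth$masks$soft$data & !truth$masks$structures$internal_air$data
  ffv <- truth$fat_fraction$data[soft]
  W[soft] <- wc[1] + ffv * (fc[1] - wc[1])
  F[soft] <- wc[2] + ffv * (fc[2] - wc[2])

  bone <- truth$masks$bone$data
  if (any(bone)) {
    hu <- truth$ct$data[bone]
    d <- clamp01((hu - model$hu_spongy) /
                 (model$hu_cortical - model$hu_spongy)) * model$d_max
    v <- fc - wc
    nhat <- c(v[2], -v[1]) / sqrt(sum(v^2))
    if (sum(nhat) > 0) nhat <- -nhat  # low-signal side of the line
    mid <- (wc + fc) / 2
    W[bone] <- mid[1] + d * nhat[1]
    F[bone] <- mid[2] + d * nhat[2]
  }

  set.seed(seed)
  if (isTRUE(truth$spec$bias_field)) {
    cc <- coord_arrays(sh, truth$ct$spacing)
    for (ch in c("W", "F")) {
      co <- stats::runif(9, -1, 1)
      nz <- function(a) a / max(abs(a), 1e-12)
      bias <- 1 + truth$spec$bias_amplitude *
        nz(co[1] * cc$z + co[2] * cc$y + co[3] * cc$x +
           co[4] * cc$z * cc$y + co[5] * cc$y * cc$x + co[6] * cc$z * cc$x +
           co[7] * cc$z^2 + co[8] * cc$y^2 + co[9] * cc$x^2)
      if (ch == "W") W <- W * bias else F <- F * bias
    }
  }
  if (noise_sigma > 0) {
    n <- prod(sh)
    W <- W + array(stats::rnorm(n, 0, noise_sigma * S0), sh)
    F <- F + array(stats::rnorm(n, 0, noise_sigma * S0), sh)
  }
  W <- pmax(W, 0); F <- pmax(F, 0)
  grid <- function(a) vol3d(array(a, sh), truth$ct$spacing, truth$ct$origin)
  dixon_volume(grid(W), grid(F))
}

#' Simulate an on-treatment CBCT as a shifted, noisy copy of a CT
#'
#' Translates the CT by `shift_mm` (trilinear interpolation, air fill
#' outside the volume) and adds Gaussian HU noise; a stand-in for
#' on-treatment cone-beam CT in the alignment-offset analysis.
#'
#' @param ct a [vol3d] in HU.
#' @param shift_mm translation in mm, `(LR, AP, SI)` order.
#' @param noise_sigma_hu additive HU noise s.d.
#' @param seed RNG seed.
#' @param fill HU filled in where the shift samples outside the volume.
#' @return A [vol3d] on the same grid.
#' @export
simulate_cbct <- function(ct, shift_mm, noise_sigma_hu = 0, seed = 1L,
                          fill = -1000) {
  stopifnot_vol3d(ct, "ct")
  if (length(shift_mm) != 3L) stop("shift_mm must be length 3 (LR, AP, SI)",
                                   call. = FALSE)
  shift_vox <- rev(as.numeric(shift_mm)) / ct$spacing  # (z,y,x)
  a <- translate_array(ct$data, shift_vox, fill)
  if (noise_sigma_hu > 0) {
    set.seed(seed)
    a <- a + array(stats::rnorm(length(a), 0, noise_sigma_hu), dim(a))
  }
  with_data(ct, a)
}

# fractional translation via separable linear interpolation, one axis at a
# time; shift_vox is (z,y,x) in voxels, content moves by +shift
translate_array <- function(a, shift_vox, fill) {
  for (axis in 1:3) {
    s <- shift_vox[axis]
    if (s == 0) next
    i0 <- floor(s); frac <- s - i0
    off <- function(k) {
      dd <- c(0, 0, 0); dd[axis] <- k
      shift_array(a, dd[1], dd[2], dd[3], fill)
    }
    a <- if (frac == 0) off(i0) else (1 - frac) * off(i0) + frac * off(i0 + 1)
  }
  a
}

#' Simulate Dixon channels from a fitted model and phantom truth
#'
#' `simulate()` method delegating to [simulate_dixon()]; returns a list of
#' `nsim` independent [dixon_volume()] realizations.
#'
#' @param object an [hu_model].
#' @param nsim number of realizations.
#' @param seed base RNG seed; realization `i` uses `seed + i - 1`.
#' @param truth a [build_phantom()] result.
#' @param noise_sigma relative channel noise s.d.
#' @param ... unused.
#' @export
simulate.hu_model <- function(object, nsim = 1, seed = 1L, truth,
                              noise_sigma = truth$spec$noise_sigma, ...) {
  lapply(seq_len(nsim), function(i)
    simulate_dixon(truth, model = object, noise_sigma = noise_sigma,
                   seed = seed + i - 1L))
}
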