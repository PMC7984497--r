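#' 3D scalar volume on a regular grid
#'
#' `vol3d` is the volumetric container used throughout the package for CT and
#' synthetic-CT Hounsfield units, MR signal channels, dose grids and binary
#' masks. The data array is indexed `(z, y, x)` with axis semantics
#' `(SI, AP, RL)` — superior-inferior, anterior-posterior, right-left — and
#' world coordinates are LPS millimetres. This is the one canonical place the
#' convention is stated; every I/O routine converts to and from it, and
#' offsets reported by the alignment routines use the reverse `(LR, AP, SI)`
#' order conventional in image-guided radiotherapy.
#'
#' Voxel indices are 0-based in world-coordinate formulas; the value of voxel
#' `(i, j, k)` is located at its center, i.e. at
#' `origin + c(i, j, k) * spacing` mm.
#'
#' @param data numeric 3D array, indexed `(z, y, x)`. Logical arrays are
#'   accepted for masks and kept logical.
#' @param spacing numeric length-3, voxel size in mm per axis, `(z, y, x)`
#'   order. Must be strictly positive.
#' @param origin numeric length-3, world coordinate (mm, LPS) of the center
#'   of voxel `(0, 0, 0)`, in `(z, y, x)` order.
#' @return An object of class `"vol3d"`: a list with elements `data`,
#'   `spacing`, `origin`.
#' @examples
#' v <- vol3d(array(0, c(4, 4, 4)), spacing = c(2.5, 2.5, 2.5))
#' dim(v)
#' @export
vol3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array", call. = FALSE)
  if (!is.logical(data)) storage.mode(data) <- "double"
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values", call. = FALSE)
  if (!is.logical(data) && any(!is.finite(data)))
    stop("volume data must be finite everywhere", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "vol3d")
}

#' @export
dim.vol3d <- function(x) dim(x$data)

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d (z,y,x), spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x "),
              paste(format(x$origin, digits = 4), collapse = ", ")))
  rng <- range(as.numeric(x$data))
  cat(sprintf("  %s values in [%g, %g]\n",
              if (is.logical(x$data)) "logical" else "numeric", rng[1], rng[2]))
  invisible(x)
}

#' @export
as.array.vol3d <- function(x, ...) x$data

is_vol3d <- function(x) inherits(x, "vol3d")

stopifnot_vol3d <- function(x, what = "volume") {
  if (!is_vol3d(x)) stop(sprintf("'%s' must be a vol3d object", what),
                         call. = FALSE)
  invisible(x)
}

#' Replace the data array of a volume, keeping its grid
#'
#' @param vol a [vol3d] supplying spacing and origin.
#' @param data replacement array of identical dimensions.
#' @return A [vol3d] on the same grid.
#' @export
with_data <- function(vol, data) {
  stopifnot_vol3d(vol)
  if (!identical(dim(data), dim(vol$data)))
    stop("replacement data must match the volume's dimensions", call. = FALSE)
  vol3d(data, vol$spacing, vol$origin)
}

#' Test whether two volumes live on the same grid
#'
#' Shapes must be identical and spacing and origin must agree within
#' `tol_mm` on every axis. All multi-volume operations in the package call
#' this before combining volumes.
#'
#' @param a,b [vol3d] objects.
#' @param tol_mm tolerance in mm for spacing and origin agreement.
#' @return `TRUE` or `FALSE`.
#' @export
check_grid_compatible <- function(a, b, tol_mm = 1e-6) {
  stopifnot_vol3d(a, "a"); stopifnot_vol3d(b, "b")
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) <= tol_mm) &&
    all(abs(a$origin - b$origin) <= tol_mm)
}

assert_same_grid <- function(a, b, what = "volumes", tol_mm = 1e-6) {
  if (!check_grid_compatible(a, b, tol_mm))
    stop(sprintf("%s are not on the same grid", what), call. = FALSE)
  invisible(TRUE)
}

#' World coordinates of voxel centers along one axis
#'
#' @param vol a [vol3d].
#' @param axis 1 (z/SI), 2 (y/AP) or 3 (x/RL).
#' @return Numeric vector of mm coordinates.
#' @export
voxel_coords <- function(vol, axis) {
  stopifnot_vol3d(vol)
  n <- dim(vol$data)[axis]
  vol$origin[axis] + (seq_len(n) - 1) * vol$spacing[axis]
}

#' Co-registered Dixon water/fat/in-phase channels
#'
#' Bundles the water (`W`) and fat (`F`) signal channels of a Dixon
#' acquisition, plus the in-phase channel (`IP = W + F` when not supplied).
#' All three must share one grid and signals must be non-negative.
#'
#' @param water,fat [vol3d] signal channels.
#' @param in_phase optional [vol3d]; computed as `water + fat` when `NULL`.
#' @return An object of class `"dixon_volume"`.
#' @export
dixon_volume <- function(water, fat, in_phase = NULL) {
  stopifnot_vol3d(water, "water"); stopifnot_vol3d(fat, "fat")
  assert_same_grid(water, fat, "water and fat channels")
  if (any(water$data < 0) || any(fat$data < 0))
    stop("Dixon signals must be non-negative", call. = FALSE)
  if (is.null(in_phase)) {
    in_phase <- with_data(water, water$data + fat$data)
  } else {
    stopifnot_vol3d(in_phase, "in_phase")
    assert_same_grid(water, in_phase, "water and in-phase channels")
    if (any(in_phase$data < 0))
      stop("Dixon signals must be non-negative", call. = FALSE)
  }
  structure(list(water = water, fat = fat, in_phase = in_phase),
            class = "dixon_volume")
}

#' @export
print.dixon_volume <- function(x, ...) {
  d <- dim(x$water$data)
  cat(sprintf("<dixon_volume> %d x %d x %d (z,y,x), spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$water$spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  water in [%g, %g], fat in [%g, %g]\n",
              min(x$water$data), max(x$water$data),
              min(x$fat$data), max(x$fat$data)))
  invisible(x)
}

is_dixon_volume <- function(x) inherits(x, "dixon_volume")

#' Tissue mask bundle: body, bone, derived soft tissue
#'
#' `soft` is always derived as `body & !bone`; the constructor enforces
#' `bone` being a subset of `body`. Additional named structure masks
#' (e.g. `ptv`, `bladder`, `rectum`, `internal_air`) ride along in
#' `structures` and share the same grid.
#'
#' @param body,bone logical [vol3d] masks; `bone` may be `NULL` (no bone
#'   compartment: `soft == body`).
#' @param structures named list of additional logical [vol3d] masks.
#' @return An object of class `"mask_set"` with elements `body`, `bone`,
#'   `soft`, `structures`.
#' @export
mask_set <- function(body, bone = NULL, structures = list()) {
  stopifnot_vol3d(body, "body")
  if (!is.logical(body$data)) stop("'body' must be a logical mask", call. = FALSE)
  if (is.null(bone)) bone <- with_data(body, array(FALSE, dim(body$data)))
  stopifnot_vol3d(bone, "bone")
  if (!is.logical(bone$data)) stop("'bone' must be a logical mask", call. = FALSE)
  assert_same_grid(body, bone, "body and bone masks")
  if (any(bone$data & !body$data))
    stop("bone mask must be a subset of the body mask", call. = FALSE)
  for (nm in names(structures)) {
    stopifnot_vol3d(structures[[nm]], nm)
    assert_same_grid(body, structures[[nm]], sprintf("body and %s masks", nm))
  }
  soft <- with_data(body, body$data & !bone$data)
  structure(list(body = body, bone = bone, soft = soft,
                 structures = structures),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> body %d, bone %d, soft %d voxels\n",
              sum(x$body$data), sum(x$bone$data), sum(x$soft$data)))
  if (length(x$structures))
    cat("  structures:", paste(sprintf("%s (%d)", names(x$structures),
        vapply(x$structures, function(s) sum(s$data), 0)), collapse = ", "),
        "\n")
  invisible(x)
}

#' Soft tissue as body minus bone
#'
#' Everything within the body outline that is outside the bone mask is soft
#' tissue; body is partitioned exactly into bone and soft.
#'
#' @param body,bone logical [vol3d] masks with `bone` a subset of `body`.
#' @return Logical [vol3d] mask `body & !bone`.
#' @export
derive_soft_tissue <- function(body, bone) {
  stopifnot_vol3d(body, "body"); stopifnot_vol3d(bone, "bone")
  assert_same_grid(body, bone, "body and bone masks")
  if (any(bone$data & !body$data))
    stop("bone mask must be a subset of the body mask", call. = FALSE)
  with_data(body, body$data & !bone$data)
}
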