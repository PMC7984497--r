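#' Read a 3D volume from NIfTI or MetaImage
#'
#' Supported formats: NIfTI-1 (`.nii`, `.nii.gz`) via \pkg{oro.nifti}, and
#' MetaImage (`.mha`, `.mhd` + `.raw`). File data are stored x-fastest; they
#' are permuted into the package's internal `(z, y, x)` index order (see
#' [vol3d]). Spacing and origin are taken from the header as written, i.e.
#' round-trips through [write_volume()] preserve the package's LPS
#' convention; no RAS reorientation is attempted.
#'
#' @param path file path.
#' @param format `"nifti"`, `"metaimage"`, or `NULL` to guess from the
#'   extension.
#' @return A [vol3d] with data cast to double.
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  format <- format %||% guess_format(path)
  out <- switch(format,
    nifti = read_nifti_vol(path),
    metaimage = read_metaimage_vol(path),
    stop(sprintf("unknown format '%s'", format), call. = FALSE))
  out
}

#' Write a 3D volume to NIfTI or MetaImage
#'
#' The inverse of [read_volume()]; data are written as 64-bit float
#' (NIfTI) or `MET_DOUBLE` (MetaImage) so round-trips are bit-exact.
#' Logical masks are written as 0/1.
#'
#' @param vol a [vol3d].
#' @param path output path; parent directory must exist.
#' @param format `"nifti"`, `"metaimage"`, or `NULL` to guess from the
#'   extension.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot_vol3d(vol)
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)),
         call. = FALSE)
  format <- format %||% guess_format(path)
  switch(format,
    nifti = write_nifti_vol(vol, path),
    metaimage = write_metaimage_vol(vol, path),
    stop(sprintf("unknown format '%s'", format), call. = FALSE))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.(mha|mhd)$", lower)) return("metaimage")
  stop(sprintf("cannot guess volume format from '%s'", path), call. = FALSE)
}

# internal array (z,y,x) <-> file order (x,y,z)
zyx_to_xyz <- function(a) aperm(a, c(3L, 2L, 1L))
xyz_to_zyx <- function(a) aperm(a, c(3L, 2L, 1L))

read_nifti_vol <- function(path) {
  img <- oro.nifti::readNIfTI(path, reorient = FALSE)
  a <- img@.Data
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) dim(a) <- dim(a)[1:3]
  if (length(dim(a)) != 3L)
    stop(sprintf("expected a 3D image, got %d dimensions: %s",
                 length(dim(a)), path), call. = FALSE)
  storage.mode(a) <- "double"
  sp_xyz <- img@pixdim[2:4]
  or_xyz <- c(img@qoffset_x, img@qoffset_y, img@qoffset_z)
  vol3d(xyz_to_zyx(a), spacing = rev(sp_xyz), origin = rev(or_xyz))
}

write_nifti_vol <- function(vol, path) {
  a <- vol$data
  if (is.logical(a)) { a <- a + 0; dim(a) <- dim(vol$data) }
  img <- oro.nifti::nifti(zyx_to_xyz(a), datatype = 64L, bitpix = 64L)
  img@pixdim <- c(1, rev(vol$spacing), 0, 0, 0, 0)
  or_xyz <- rev(vol$origin)
  img@qoffset_x <- or_xyz[1]; img@qoffset_y <- or_xyz[2]
  img@qoffset_z <- or_xyz[3]
  img@qform_code <- 1L; img@sform_code <- 0L
  # writeNIfTI appends .nii.gz itself; hand it the bare stem
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  gz <- grepl("\\.nii\\.gz$", tolower(path))
  oro.nifti::writeNIfTI(img, stem, gzipped = gz)
  invisible(path)
}

metaimage_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
                     MET_SHORT = "integer", MET_USHORT = "integer",
                     MET_INT = "integer", MET_UINT = "integer",
                     MET_FLOAT = "double", MET_DOUBLE = "double")
metaimage_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L,
                     MET_USHORT = 2L, MET_INT = 4L, MET_UINT = 4L,
                     MET_FLOAT = 4L, MET_DOUBLE = 8L)
metaimage_signed <- c(MET_UCHAR = FALSE, MET_CHAR = TRUE, MET_SHORT = TRUE,
                      MET_USHORT = FALSE, MET_INT = TRUE, MET_UINT = FALSE,
                      MET_FLOAT = TRUE, MET_DOUBLE = TRUE)

read_metaimage_vol <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop(sprintf("truncated MetaImage header: %s", path), call. = FALSE)
    kv <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L)
      stop(sprintf("malformed MetaImage header line: '%s'", line),
           call. = FALSE)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  ndims <- as.integer(hdr$NDims %||% "0")
  if (ndims != 3L)
    stop(sprintf("expected a 3D image, got NDims=%d: %s", ndims, path),
         call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing %||% "1 1 1", "\\s+")[[1]])
  or <- as.numeric(strsplit(hdr$Offset %||% hdr$Position %||% "0 0 0",
                            "\\s+")[[1]])
  type <- hdr$ElementType %||% "MET_DOUBLE"
  if (!type %in% names(metaimage_types))
    stop(sprintf("unsupported MetaImage ElementType '%s'", type),
         call. = FALSE)
  msb <- toupper(hdr$ElementByteOrderMSB %||%
                 hdr$BinaryDataByteOrderMSB %||% "FALSE") == "TRUE"
  n <- prod(dims)
  datafile <- hdr$ElementDataFile
  if (identical(datafile, "LOCAL")) {
    raw_con <- con
  } else {
    raw_con <- file(file.path(dirname(path), datafile), "rb")
    on.exit(close(raw_con), add = TRUE)
  }
  vals <- readBin(raw_con, metaimage_types[[type]], n = n,
                  size = metaimage_sizes[[type]],
                  signed = metaimage_signed[[type]],
                  endian = if (msb) "big" else "little")
  if (length(vals) != n)
    stop(sprintf("MetaImage data block too short: %s", path), call. = FALSE)
  a <- array(as.double(vals), dim = dims)  # x fastest
  vol3d(xyz_to_zyx(a), spacing = rev(sp), origin = rev(or))
}

write_metaimage_vol <- function(vol, path) {
  a <- vol$data
  if (is.logical(a)) { a <- a + 0; dim(a) <- dim(vol$data) }
  dims <- rev(dim(a))
  mhd <- grepl("\\.mhd$", tolower(path))
  datafile <- if (mhd) paste0(tools::file_path_sans_ext(basename(path)),
                              ".raw") else "LOCAL"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %s", paste(dims, collapse = " ")),
           sprintf("ElementSpacing = %s",
                   paste(format(rev(vol$spacing), digits = 17),
                         collapse = " ")),
           sprintf("Offset = %s",
                   paste(format(rev(vol$origin), digits = 17),
                         collapse = " ")),
           "ElementType = MET_DOUBLE",
           sprintf("ElementDataFile = %s", datafile))
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (!mhd) {
    writeBin(as.vector(zyx_to_xyz(a)), con, size = 8L, endian = "little")
    close(con)
  } else {
    close(con)
    rawcon <- file(file.path(dirname(path), datafile), "wb")
    writeBin(as.vector(zyx_to_xyz(a)), rawcon, size = 8L, endian = "little")
    close(rawcon)
  }
  invisible(path)
}
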