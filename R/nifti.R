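# Minimal NIfTI-1 single-file (.nii / .nii.gz) I/O for axis-aligned volumes.
# No R NIfTI package ships with this stack, so the 348-byte header is read
# and written directly. Only what this tool needs is supported: 3D arrays,
# diagonal sform affines, datatypes uint8 / int16 / int32 / float32 /
# float64, little-endian on write, either endianness on read. Internal grid
# units are cm; NIfTI files are written and read in mm.

nifti_open <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a volume as NIfTI-1
#'
#' Writes a 3D volume with a diagonal sform affine (spacing on the diagonal,
#' origin in the translation column), spatial units mm (the in-memory cm
#' grid is converted). Masks should be written with `datatype = "uint8"`.
#'
#' @param vol An [image_volume()], or a plain 3D array (then `grid` is
#'   required).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param grid [voxel_grid()] when `vol` is a bare array.
#' @param datatype `"float64"`, `"float32"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, grid = NULL,
                        datatype = c("float64", "float32", "uint8")) {
  datatype <- match.arg(datatype)
  if (inherits(vol, "image_volume")) { grid <- vol$grid; values <- vol$values }
  else { values <- as.array(vol) }
  if (is.null(grid)) stop("grid required when writing a bare array")
  stopifnot(length(dim(values)) == 3L, all(dim(values) == grid$dims))
  dt <- switch(datatype, float64 = c(64L, 64L), float32 = c(16L, 32L),
               uint8 = c(2L, 8L))
  con <- nifti_open(path, "wb"); on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  sp_mm <- grid$spacing * 10; or_mm <- grid$origin * 10
  w_i32(348L); w_raw(35L); w_raw(1L)                       # header, dim_info
  w_i16(c(3L, grid$dims, 1L, 1L, 1L, 1L))                  # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)                             # intent
  w_i16(dt[1]); w_i16(dt[2]); w_i16(0L)                    # datatype, bitpix
  w_f32(c(1, sp_mm, 1, 1, 1, 1))                           # pixdim (qfac 1)
  w_f32(352); w_f32(1); w_f32(0)                           # vox_offset, scl
  w_i16(0L); w_raw(1L); writeBin(as.raw(2L), con)          # slice, xyzt=mm
  w_f32(c(0, 0, 0, 0)); w_i32(c(0L, 0L))                   # cal/gl
  desc <- charToRaw("logdoseqa")
  writeBin(c(desc, raw(80L - length(desc))), con); w_raw(24L)
  w_i16(0L); w_i16(1L)                                     # qform 0, sform 1
  w_f32(rep(0, 6))                                         # quatern/qoffset
  w_f32(c(sp_mm[1], 0, 0, or_mm[1]))
  w_f32(c(0, sp_mm[2], 0, or_mm[2]))
  w_f32(c(0, 0, sp_mm[3], or_mm[3]))
  w_raw(16L)
  writeBin(c(charToRaw("n+1"), raw(1L)), con)
  w_raw(4L)                                                # extension flag
  if (datatype == "uint8")
    writeBin(as.raw(as.integer(round(values))), con)
  else
    writeBin(as.numeric(values), con, size = dt[2] %/% 8L, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D `.nii`/`.nii.gz` file with a diagonal affine into an
#' [image_volume()]. Scale slope/intercept are applied; mm coordinates are
#' converted to the internal cm convention.
#'
#' @param path Input path.
#' @param kind The [image_volume()] kind to tag the result with.
#' @return An [image_volume()].
#' @export
read_nifti <- function(path, kind = "dose_gy") {
  if (!file.exists(path)) stop("NIfTI file not found: ", path)
  con <- nifti_open(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348L)
  if (length(hdr) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr[1:4], "integer", size = 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                     n = n, size = 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                     n = n, size = 4L, endian = endian)
  dim8 <- rd_i16(40L, 8L)
  if (dim8[1] < 3L) stop("expected a 3D volume in ", path)
  dims <- dim8[2:4]
  if (dim8[1] > 3L && any(dim8[5:(1 + dim8[1])] > 1L))
    stop("only 3D volumes are supported (", path, ")")
  datatype <- rd_i16(70L, 1L)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L); scl_inter <- rd_f32(116L, 1L)
  sform_code <- rd_i16(254L, 1L)
  if (sform_code > 0L) {
    srow <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L))
    offdiag <- srow[, 1:3]; diag(offdiag) <- 0
    if (any(abs(offdiag) > 1e-4 * max(abs(srow[, 1:3]))))
      stop("only axis-aligned (diagonal) affines are supported: ", path)
    sp_mm <- abs(diag(srow[, 1:3])); or_mm <- srow[, 4]
    if (any(diag(srow[, 1:3]) < 0))
      stop("negative axis directions are not supported: ", path)
  } else {
    sp_mm <- abs(pixdim[2:4]); or_mm <- c(0, 0, 0)
  }
  skip <- vox_offset - 348L
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  n <- prod(dims)
  values <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2L, endian = endian)),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4L, endian = endian)),
    "16" = readBin(con, "double", n = n, size = 4L, endian = endian),
    "64" = readBin(con, "double", n = n, size = 8L, endian = endian),
    stop("unsupported NIfTI datatype ", datatype, " in ", path))
  if (length(values) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    values <- values * scl_slope + scl_inter
  grid <- voxel_grid(origin = or_mm / 10, spacing = sp_mm / 10, dims = dims)
  image_volume(grid, array(values, dims), kind = kind)
}

#' Write a structure mask set as one NIfTI file per ROI
#'
#' Each label becomes `<dir>/<roi>.nii.gz` (uint8) and the ROI names are
#' recorded in `<dir>/labels.json`.
#'
#' @param masks A [structure_mask()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mask_set <- function(masks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(masks$labels))
    write_nifti(masks$labels[[nm]], file.path(dir, paste0(nm, ".nii.gz")),
                grid = masks$grid, datatype = "uint8")
  jsonlite::write_json(names(masks$labels), file.path(dir, "labels.json"))
  invisible(dir)
}

#' Read a structure mask set written by [write_mask_set()]
#'
#' @param dir Directory containing `<roi>.nii.gz` files and `labels.json`.
#' @return A [structure_mask()].
#' @export
read_mask_set <- function(dir) {
  lbl_file <- file.path(dir, "labels.json")
  names <- if (file.exists(lbl_file))
    unlist(jsonlite::read_json(lbl_file, simplifyVector = TRUE))
  else sub("\\.nii(\\.gz)?$", "", list.files(dir, pattern = "\\.nii(\\.gz)?$"))
  if (!length(names)) stop("no mask files found in ", dir)
  vols <- lapply(names, function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    if (!file.exists(p)) p <- file.path(dir, paste0(nm, ".nii"))
    if (!file.exists(p)) stop("missing mask file for ROI '", nm, "' in ", dir)
    read_nifti(p, kind = "projected")
  })
  structure_mask(vols[[1]]$grid, stats::setNames(lapply(vols, `[[`, "values"), names))
}
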