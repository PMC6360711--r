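# Minimal NIfTI-1 reader/writer.
#
# No NIfTI package is available in the target library, so the format is
# handled directly: single-file .nii / .nii.gz, 3D or 4D, the common
# datatypes, sform affines. Data are stored float32 and computed float64.
# Quaternion (qform-only) orientations are reduced to the sform/pixdim
# information actually used here; files written by this package always
# carry an sform.

nifti_datatypes <- list(
  `2` = list(what = "integer", size = 1L, signed = FALSE),
  `4` = list(what = "integer", size = 2L, signed = TRUE),
  `8` = list(what = "integer", size = 4L, signed = TRUE),
  `16` = list(what = "double", size = 4L, signed = TRUE),
  `64` = list(what = "double", size = 8L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE))

#' Read a NIfTI-1 volume
#'
#' Reads a 3D (or, via [read_series()], 4D) single-file NIfTI-1 image,
#' `.nii` or `.nii.gz`. Scale slope/intercept are applied; the affine is
#' taken from the sform when set, otherwise a diagonal affine is built
#' from the pixdims.
#'
#' @param path Path to the image.
#' @param expect_dims Required dimensionality (3 or 4), or `NULL`.
#' @return List with `data` (numeric array), `affine` (4 x 4 matrix),
#'   `voxel_size_mm` (length 3).
#' @export
read_volume <- function(path, expect_dims = 3L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header", call. = FALSE)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sz != 348L) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sz != 348L) stop("not a NIfTI-1 file: ", path, call. = FALSE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("unsupported NIfTI magic '", magic, "'", call. = FALSE)
  }
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n, 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "double", n, 4L, endian = endian)
  dims <- rd_i16(40L, 8L)
  ndim <- dims[1]
  if (ndim < 3L || ndim > 4L) {
    stop("only 3D/4D NIfTI supported, got ", ndim, "D", call. = FALSE)
  }
  if (!is.null(expect_dims) && ndim != expect_dims) {
    stop("expected a ", expect_dims, "D image, got ", ndim, "D: ", path,
         call. = FALSE)
  }
  shape <- pmax(dims[2:(1 + ndim)], 1L)
  datatype <- rd_i16(70L, 1L)
  dt <- nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, call. = FALSE)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  sform_code <- rd_i16(254L, 1L)
  srow <- matrix(rd_f32(280L, 12L), nrow = 3, byrow = TRUE)
  skip <- round(vox_offset) - 348L
  if (skip > 0L) readBin(con, "raw", skip)
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("truncated NIfTI data: ", path, call. = FALSE)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(as.double(vals), dim = shape)
  affine <- if (sform_code > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else {
    diag(c(pixdim[2:4], 1))
  }
  list(data = data, affine = affine,
       voxel_size_mm = sqrt(colSums(affine[1:3, 1:3]^2)))
}

#' Read a 4D NIfTI-1 series
#'
#' @param path Path to a 4D image (t as the 4th dimension).
#' @return List with `series` (a [difference_series()]) and `affine`.
#' @export
read_series <- function(path) {
  v <- read_volume(path, expect_dims = 4L)
  list(series = difference_series(v$data, voxel_size_mm = v$voxel_size_mm),
       affine = v$affine)
}

#' Write a 3D or 4D array as NIfTI-1
#'
#' Writes a single-file `.nii` or `.nii.gz` (decided by the extension),
#' float32 storage, with the given affine recorded as sform (code 1).
#'
#' @param data Numeric 3D or 4D array. `NA` values are stored as NaN.
#' @param path Destination path.
#' @param affine 4 x 4 affine; default diagonal from `voxel_size_mm`.
#' @param voxel_size_mm Voxel size used when no affine is given.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(data, path, affine = NULL,
                         voxel_size_mm = c(3, 3, 3)) {
  ndim <- length(dim(data))
  if (!ndim %in% c(3L, 4L)) stop("data must be 3D or 4D", call. = FALSE)
  if (is.null(affine)) affine <- diag(c(voxel_size_mm, 1))
  shape <- dim(data)
  dims <- integer(8)
  dims[1] <- ndim
  dims[2:(1 + ndim)] <- shape
  dims[(2 + ndim):8][dims[(2 + ndim):8] == 0L] <- 1L
  pixdim <- rep(1, 8)
  pixdim[2:4] <- sqrt(colSums(affine[1:3, 1:3]^2))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w_i32 <- function(x) writeBin(as.integer(x), con, 4L, endian = "little")
  w_i16 <- function(x) writeBin(as.integer(x), con, 2L, endian = "little")
  w_f32 <- function(x) writeBin(as.double(x), con, 4L, endian = "little")
  w_raw <- function(n) writeBin(raw(n), con)
  w_i32(348L)                       # sizeof_hdr
  w_raw(28L)                        # data_type, db_name
  w_i32(0L); w_i16(0L); w_raw(2L)   # extents, session_error, regular, dim_info
  w_i16(dims)                       # dim[8]
  w_f32(c(0, 0, 0)); w_i16(0L)      # intent_p*, intent_code
  w_i16(16L); w_i16(32L); w_i16(0L) # datatype float32, bitpix, slice_start
  w_f32(pixdim)                     # pixdim[8]
  w_f32(352); w_f32(1); w_f32(0)    # vox_offset, scl_slope, scl_inter
  w_i16(0L); w_raw(2L)              # slice_end, slice_code, xyzt_units
  w_f32(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_i32(c(0L, 0L))                  # glmax, glmin
  w_raw(104L)                       # descrip, aux_file
  w_i16(c(0L, 1L))                  # qform_code, sform_code
  w_f32(rep(0, 6))                  # quatern, qoffset
  w_f32(t(affine[1:3, ]))           # srow_x/y/z
  w_raw(16L)                        # intent_name
  writeBin(charToRaw("n+1"), con); w_raw(1L)  # magic
  w_raw(4L)                         # no extensions
  vals <- as.double(data)
  vals[is.na(vals)] <- NaN
  writeBin(vals, con, 4L, endian = "little")
  invisible(path)
}

#' @rdname write_volume
#' @param series A [difference_series()] to write as a 4D image.
#' @export
write_series <- function(series, path, affine = NULL) {
  write_volume(series$data, path, affine = affine,
               voxel_size_mm = series$voxel_size_mm)
}

# shared guard: inputs must already be co-registered
check_affines_match <- function(a1, a2, what = "inputs") {
  if (max(abs(a1 - a2)) > 1e-4) {
    stop(what, " are not co-registered (affines differ); ",
         "resample upstream before correction", call. = FALSE)
  }
  invisible(TRUE)
}
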