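# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# The pre-installed R stack ships no NIfTI package, so the subset of the
# format this pipeline needs is implemented here: 3-D/4-D images, datatypes
# uint8 / int16 / int32 / float32 / float64, sform affine, little- or
# big-endian on read (always little-endian on write), scl_slope/scl_inter
# honoured on read.

NIFTI_DTYPES <- list(
  `2`  = list(what = "integer", size = 1L, signed = FALSE, r = "uint8"),
  `4`  = list(what = "integer", size = 2L, signed = TRUE,  r = "int16"),
  `8`  = list(what = "integer", size = 4L, signed = TRUE,  r = "int32"),
  `16` = list(what = "double",  size = 4L, signed = TRUE,  r = "float32"),
  `64` = list(what = "double",  size = 8L, signed = TRUE,  r = "float64")
)

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Write a 3-D or 4-D array as a NIfTI-1 image
#'
#' @param data numeric or logical array with 3 or 4 dimensions.
#' @param grid a [volume_grid()] carrying voxel size and the RAS affine.
#' @param path output path, `.nii` or `.nii.gz`.
#' @param datatype one of `"float32"` (default), `"float64"`, `"int32"`,
#'   `"int16"`, `"uint8"`.
#' @return invisibly, `path`.
#' @export
write_nifti <- function(data, grid, path, datatype = "float32") {
  stopifnot(inherits(grid, "volume_grid"))
  nd <- length(dim(data))
  if (!nd %in% c(3L, 4L)) stopf("write_nifti: data must be 3-D or 4-D, got %d-D", nd)
  if (!all(dim(data)[1:3] == grid$shape)) {
    stopf("write_nifti: data spatial dims (%s) do not match grid shape (%s)",
          paste(dim(data)[1:3], collapse = "x"), paste(grid$shape, collapse = "x"))
  }
  code <- switch(datatype,
    uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L,
    stopf("write_nifti: unsupported datatype '%s'", datatype))
  spec <- NIFTI_DTYPES[[as.character(code)]]
  dims <- c(nd, dim(data), rep(1L, 7L - nd))
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  wi(348L, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)            # data_type, db_name
  wi(0L, 4); wi(0L, 2)              # extents, session_error
  wc("r", 1); wc("", 1)             # regular, dim_info
  wi(dims, 2)                       # dim[8]
  wf(c(0, 0, 0)); wi(0L, 2)         # intent_p1-3, intent_code
  wi(code, 2); wi(spec$size * 8L, 2); wi(0L, 2)  # datatype, bitpix, slice_start
  wf(c(1, grid$voxel_size, rep(1, 4)))           # pixdim[8] (qfac = 1)
  wf(352); wf(1); wf(0)             # vox_offset, scl_slope, scl_inter
  wi(0L, 2); wc("", 1)              # slice_end, slice_code
  writeBin(as.raw(2L + 16L), con)   # xyzt_units: mm + sec
  wf(c(0, 0, 0, 0))                 # cal_max, cal_min, slice_duration, toffset
  wi(c(0L, 0L), 4)                  # glmax, glmin
  wc("hdmri", 80); wc("", 24)       # descrip, aux_file
  wi(0L, 2); wi(2L, 2)              # qform_code = 0, sform_code = 2
  wf(rep(0, 6))                     # quaterns + qoffsets
  wf(grid$affine[1, ]); wf(grid$affine[2, ]); wf(grid$affine[3, ])
  wc("", 16); wc("n+1", 4)          # intent_name, magic
  writeBin(raw(4), con)             # extension flag
  storage <- if (spec$what == "integer") as.integer(round(data)) else as.double(data)
  writeBin(storage, con, size = spec$size, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 image
#'
#' @param path `.nii` or `.nii.gz` file.
#' @return list with `data` (array, slope/intercept applied) and `grid`
#'   (a [volume_grid()]; affine from the sform when set, else diagonal pixdim).
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stopf("read_nifti: no such file: %s", path)
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 352L)
  peek <- readBin(hdr_raw[1:4], "integer", size = 4L, endian = "little")
  endian <- if (peek == 348L) "little" else "big"
  ri <- function(off, n, size) readBin(hdr_raw[(off + 1):(off + n * size)],
                                       "integer", n = n, size = size, endian = endian)
  rf <- function(off, n) readBin(hdr_raw[(off + 1):(off + n * 4)],
                                 "double", n = n, size = 4L, endian = endian)
  if (ri(0, 1, 4) != 348L) stopf("read_nifti: not a NIfTI-1 file: %s", path)
  dims <- ri(40, 8, 2)
  nd <- dims[1]
  if (!nd %in% c(2L, 3L, 4L)) stopf("read_nifti: unsupported rank %d", nd)
  shape <- pmax(dims[2:(nd + 1)], 1L)
  code <- ri(70, 1, 2)
  spec <- NIFTI_DTYPES[[as.character(code)]]
  if (is.null(spec)) stopf("read_nifti: unsupported datatype code %d", code)
  pixdim <- rf(76, 8)
  vox_offset <- rf(108, 1)
  scl_slope <- rf(112, 1)
  scl_inter <- rf(116, 1)
  sform_code <- ri(254, 1, 2)
  affine <- diag(4)
  if (sform_code > 0L) {
    affine[1, ] <- rf(280, 4); affine[2, ] <- rf(296, 4); affine[3, ] <- rf(312, 4)
  } else {
    diag(affine)[1:3] <- pixdim[2:4]
  }
  n_vals <- prod(shape)
  skip <- as.integer(vox_offset) - 352L
  if (skip > 0L) readBin(con, "raw", n = skip)
  vals <- readBin(con, spec$what, n = n_vals, size = spec$size,
                  signed = spec$signed, endian = endian)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = shape)
  shape3 <- c(shape, rep(1L, 3))[1:3]
  grid <- volume_grid(shape3, voxel_size = abs(pixdim[2:4]), affine = affine)
  list(data = data, grid = grid)
}
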