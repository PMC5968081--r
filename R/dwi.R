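# The 4-D diffusion-weighted dataset container and its readers/writers.

#' Diffusion-weighted dataset
#'
#' @param grid a [volume_grid()].
#' @param signal 4-D non-negative array (x, y, z, volume).
#' @param scheme a [gradient_scheme()]; entry count must equal the 4th dimension.
#' @param mask 3-D logical array; default: voxels where the first b = 0 volume
#'   is positive.
#' @return object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(grid, signal, scheme, mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"), inherits(scheme, "gradient_scheme"))
  if (length(dim(signal)) != 4L) stopf("dwi_dataset: signal must be 4-D")
  if (!all(dim(signal)[1:3] == grid$shape)) stopf("dwi_dataset: signal spatial dims do not match grid")
  if (dim(signal)[4] != length(scheme)) {
    stopf("dwi_dataset: %d volumes but %d scheme entries", dim(signal)[4], length(scheme))
  }
  if (any(signal < 0)) stopf("dwi_dataset: negative signal values")
  if (is.null(mask)) {
    b0 <- which(scheme$b == 0)[1]
    mask <- signal[, , , b0] > 0
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!all(dim(mask) == grid$shape)) stopf("dwi_dataset: mask shape does not match grid")
  structure(list(grid = grid, signal = signal, scheme = scheme, mask = mask),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  cat(sprintf("<dwi_dataset> %s voxels, %d volumes, %d masked\n",
              paste(x$grid$shape, collapse = "x"), dim(x$signal)[4], sum(x$mask)))
  invisible(x)
}

#' Read a diffusion-weighted dataset from disk
#'
#' @param image_path 4-D NIfTI image.
#' @param scheme_path canonical scheme TSV (see [write_scheme()]).
#' @param mask_path optional 3-D NIfTI mask (nonzero = inside).
#' @return a [dwi_dataset()].
#' @export
read_dwi <- function(image_path, scheme_path, mask_path = NULL) {
  img <- read_nifti(image_path)
  if (length(dim(img$data)) != 4L) stopf("read_dwi: %s is not a 4-D image", image_path)
  scheme <- read_scheme(scheme_path)
  if (length(scheme) != dim(img$data)[4]) {
    stopf("read_dwi: scheme has %d rows but image has %d volumes",
          length(scheme), dim(img$data)[4])
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- read_nifti(mask_path)
    mask <- m$data != 0
  }
  dwi_dataset(img$grid, img$data, scheme, mask)
}

#' Write a diffusion-weighted dataset (image + scheme [+ mask])
#'
#' @param dwi a [dwi_dataset()].
#' @param image_path,scheme_path,mask_path output paths (`mask_path` optional).
#' @return invisibly, `image_path`.
#' @export
write_dwi <- function(dwi, image_path, scheme_path, mask_path = NULL) {
  write_nifti(dwi$signal, dwi$grid, image_path, datatype = "float32")
  write_scheme(dwi$scheme, scheme_path)
  if (!is.null(mask_path)) {
    write_nifti(array(as.integer(dwi$mask), dim = dim(dwi$mask)), dwi$grid,
                mask_path, datatype = "uint8")
  }
  invisible(image_path)
}

# Per-voxel mean over the b = 0 volumes.
b0_mean <- function(dwi) {
  idx <- which(dwi$scheme$b == 0)
  if (length(idx) == 0L) stopf("no b = 0 volumes in scheme")
  if (length(idx) == 1L) return(dwi$signal[, , , idx])
  apply(dwi$signal[, , , idx, drop = FALSE], 1:3, mean)
}
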