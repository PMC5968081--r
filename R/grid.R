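# Volume geometry and hippocampal subfield label maps.

#' Volume grid geometry
#'
#' Describes a regular 3-D voxel grid: integer shape, voxel size in mm, and a
#' 4x4 affine mapping 0-based voxel indices to world coordinates in mm (RAS).
#' Voxel (0,0,0) maps to the affine translation column.
#'
#' @param shape integer triple, number of voxels per axis.
#' @param voxel_size positive real triple, mm. Default 0.3 mm isotropic, the
#'   spatial resolution of the ex vivo protocol this package targets.
#' @param affine optional 4x4 voxel-to-world matrix; default is a diagonal RAS
#'   affine built from `voxel_size` with the origin at voxel (0,0,0).
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(0.3, 0.3, 0.3), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size <- as.double(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size
  }
  affine <- matrix(as.double(affine), 4, 4)
  if (abs(det(affine)) < 1e-12) stopf("volume_grid: affine is singular")
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels at %s mm\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x")))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-6) {
  all(a$shape == b$shape) && all(abs(a$affine - b$affine) < tol)
}

#' Convert 0-based voxel indices to world mm
#'
#' @param grid a [volume_grid()].
#' @param ijk n x 3 matrix of (possibly fractional) 0-based voxel indices.
#' @return n x 3 matrix of world coordinates (mm).
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' Convert world mm to (fractional) 0-based voxel indices
#' @rdname voxel_to_world
#' @param xyz n x 3 matrix of world coordinates (mm).
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  h <- cbind(xyz, 1) %*% t(solve(grid$affine))
  h[, 1:3, drop = FALSE]
}

#' Canonical 22-region hippocampal subfield legend
#'
#' The canonical parcellation has 22 regions across the three rostro-caudal
#' parts of the hippocampal formation: 7 in the head, 8 in the body (which
#' adds the fimbria), and 7 in the tail (which lacks the entorhinal cortex).
#'
#' @return data.frame with columns `label`, `part` (head/body/tail), `structure`.
#' @export
hippocampus_legend <- function() {
  head_s <- c("Entorhinal cortex", "Subicular complex", "CA1", "CA2/CA3",
              "Dentate gyrus", "Alveus", "Lacunosum-molecular layer")
  body_s <- c("Entorhinal cortex", "Subicular complex", "CA1", "CA2/CA3",
              "Dentate gyrus", "Alveus", "Fimbria", "Lacunosum-molecular layer")
  tail_s <- c("Subicular complex", "CA1", "CA2/CA3",
              "Dentate gyrus", "Alveus", "Fimbria", "Lacunosum-molecular layer")
  data.frame(
    label = 1:22,
    part = c(rep("head", 7L), rep("body", 8L), rep("tail", 7L)),
    structure = c(head_s, body_s, tail_s),
    stringsAsFactors = FALSE
  )
}

#' Labelled volume of hippocampal subfields
#'
#' @param grid a [volume_grid()].
#' @param labels 3-D non-negative integer array; 0 is background.
#' @param legend data.frame with columns `label`, `part`, `structure`.
#'   Default [hippocampus_legend()].
#' @return object of class `label_map`.
#' @export
label_map <- function(grid, labels, legend = hippocampus_legend()) {
  stopifnot(inherits(grid, "volume_grid"))
  labels <- array(as.integer(labels), dim = dim(labels))
  if (!all(dim(labels) == grid$shape)) stopf("label_map: labels shape does not match grid")
  if (any(labels < 0L)) stopf("label_map: negative labels")
  stopifnot(all(c("label", "part", "structure") %in% names(legend)))
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(present, legend$label)
  if (length(missing) > 0L) {
    stopf("label_map: labels present in volume but absent from legend: %s",
          paste(missing, collapse = ", "))
  }
  structure(list(grid = grid, labels = labels, legend = legend), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d regions over %s voxels\n",
              nrow(x$legend), paste(x$grid$shape, collapse = "x")))
  invisible(x)
}
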