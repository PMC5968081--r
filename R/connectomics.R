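# Subfield connectivity matrices from tractograms, and bundle extraction by
# region-of-interest intersection filtering.

#' Connectivity matrix container
#'
#' Symmetric K x K streamline-count matrix with a zero diagonal
#' (self-connections are excluded; efferent and afferent projections cannot
#' be distinguished, so the matrix is symmetric by construction).
#'
#' @param counts K x K nonnegative integer matrix.
#' @param legend data.frame with columns label, part, structure (canonical:
#'   the 22-region [hippocampus_legend()]), in matrix row order.
#' @param provenance optional descriptor of the source tractogram.
#' @return object of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(counts, legend = hippocampus_legend(), provenance = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stopf("connectivity_matrix: counts must be square")
  if (nrow(counts) != nrow(legend)) stopf("connectivity_matrix: legend/matrix size mismatch")
  if (any(counts < 0)) stopf("connectivity_matrix: negative counts")
  if (any(diag(counts) != 0)) stopf("connectivity_matrix: nonzero diagonal")
  if (any(abs(counts - t(counts)) > 0)) stopf("connectivity_matrix: not symmetric")
  rn <- paste(legend$part, legend$structure, sep = ": ")
  dimnames(counts) <- list(rn, rn)
  structure(list(counts = counts, legend = legend, provenance = provenance),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %d regions, %d connections\n",
              nrow(x$counts), sum(x$counts[upper.tri(x$counts)])))
  invisible(x)
}

# label at each streamline endpoint (0 when outside the grid or background)
endpoint_labels <- function(tractogram, labels) {
  shp <- labels$grid$shape
  ends <- t(vapply(tractogram$streamlines, function(p) {
    c(p[1, ], p[nrow(p), ])
  }, numeric(6)))
  lab_at <- function(xyz) {
    vx <- round(world_to_voxel(labels$grid, xyz))
    inb <- vx[, 1] >= 0 & vx[, 1] < shp[1] & vx[, 2] >= 0 & vx[, 2] < shp[2] &
      vx[, 3] >= 0 & vx[, 3] < shp[3]
    out <- integer(nrow(vx))
    if (any(inb)) {
      lin <- 1 + vx[inb, 1] + shp[1] * (vx[inb, 2] + shp[2] * vx[inb, 3])
      out[inb] <- labels$labels[lin]
    }
    out
  }
  cbind(lab_at(ends[, 1:3, drop = FALSE]), lab_at(ends[, 4:6, drop = FALSE]))
}

#' Build the subfield connectivity matrix from a tractogram
#'
#' Each streamline contributes its endpoint label pair: if both endpoints lie
#' in different nonzero regions, counts\[a, b\] and counts\[b, a\] are both
#' incremented. Same-label or unlabelled endpoints contribute nothing. No
#' length normalization is applied by default; `log_length_normalize = TRUE`
#' divides each cell by the log of the mean length of its contributing fibres
#' (an option for low-SNR whole-brain style data, off here on purpose).
#'
#' @param tractogram a `tractogram`.
#' @param labels a [label_map()].
#' @param log_length_normalize logical, default FALSE.
#' @return a [connectivity_matrix()] (counts are reals when normalized).
#' @export
build_matrix <- function(tractogram, labels, log_length_normalize = FALSE) {
  stopifnot(inherits(tractogram, "tractogram"), inherits(labels, "label_map"))
  K <- nrow(labels$legend)
  counts <- matrix(0, K, K)
  lens <- matrix(0, K, K)
  if (length(tractogram$streamlines) > 0) {
    ep <- endpoint_labels(tractogram, labels)
    sl_len <- streamline_lengths(tractogram)
    use <- ep[, 1] > 0 & ep[, 2] > 0 & ep[, 1] != ep[, 2]
    if (any(use)) {
      a <- match(ep[use, 1], labels$legend$label)
      b <- match(ep[use, 2], labels$legend$label)
      L <- sl_len[use]
      for (i in seq_along(a)) {
        counts[a[i], b[i]] <- counts[a[i], b[i]] + 1
        counts[b[i], a[i]] <- counts[b[i], a[i]] + 1
        lens[a[i], b[i]] <- lens[a[i], b[i]] + L[i]
        lens[b[i], a[i]] <- lens[b[i], a[i]] + L[i]
      }
    }
  }
  if (log_length_normalize) {
    nz <- counts > 0
    mean_len <- lens[nz] / counts[nz]
    denom <- log(pmax(mean_len, exp(1)))   # guard log <= 1
    counts[nz] <- counts[nz] / denom
  }
  connectivity_matrix(counts, labels$legend,
                      provenance = tractogram$provenance)
}

#' Bundle selector
#'
#' @param start_labels,end_labels nonempty label sets for the two endpoint
#'   regions.
#' @param waypoint_labels list of label sets that a kept streamline must each
#'   traverse (any voxel of the polyline).
#' @param exclusion_labels label set a kept streamline must not touch.
#' @return object of class `bundle_selector`.
#' @export
bundle_selector <- function(start_labels, end_labels, waypoint_labels = list(),
                            exclusion_labels = integer(0)) {
  start_labels <- as.integer(start_labels); end_labels <- as.integer(end_labels)
  exclusion_labels <- as.integer(exclusion_labels)
  if (length(start_labels) == 0L || length(end_labels) == 0L) {
    stopf("bundle_selector: start and end label sets must be nonempty")
  }
  if (length(intersect(c(start_labels, end_labels, unlist(waypoint_labels)),
                       exclusion_labels)) > 0L) {
    stopf("bundle_selector: exclusion set overlaps start/end/waypoints")
  }
  structure(list(start_labels = start_labels, end_labels = end_labels,
                 waypoint_labels = lapply(waypoint_labels, as.integer),
                 exclusion_labels = exclusion_labels),
            class = "bundle_selector")
}

# labels traversed by a polyline (any point's voxel)
traversed_labels <- function(poly, labels) {
  shp <- labels$grid$shape
  vx <- round(world_to_voxel(labels$grid, poly))
  inb <- vx[, 1] >= 0 & vx[, 1] < shp[1] & vx[, 2] >= 0 & vx[, 2] < shp[2] &
    vx[, 3] >= 0 & vx[, 3] < shp[3]
  if (!any(inb)) return(integer(0))
  lin <- 1 + vx[inb, 1] + shp[1] * (vx[inb, 2] + shp[2] * vx[inb, 3])
  unique(labels$labels[lin])
}

#' Extract a bundle by region-of-interest intersection
#'
#' Keeps streamlines with one endpoint in the start set and the other in the
#' end set (order-insensitive; the two endpoints must fall in different sets
#' or carry different labels), traversing at least one voxel of every
#' waypoint set, and touching no exclusion voxel. Idempotent: filtering a
#' filtered bundle with the same selector returns it unchanged.
#'
#' @param tractogram a `tractogram`.
#' @param selector a [bundle_selector()].
#' @param labels a [label_map()].
#' @return a `tractogram` containing the kept streamlines.
#' @export
filter_bundle <- function(tractogram, selector, labels) {
  stopifnot(inherits(selector, "bundle_selector"), inherits(labels, "label_map"))
  if (length(tractogram$streamlines) == 0L) return(tractogram)
  ep <- endpoint_labels(tractogram, labels)
  keep <- logical(nrow(ep))
  for (i in seq_len(nrow(ep))) {
    a <- ep[i, 1]; b <- ep[i, 2]
    fwd <- a %in% selector$start_labels && b %in% selector$end_labels
    rev <- b %in% selector$start_labels && a %in% selector$end_labels
    if (!(fwd || rev)) next
    if (a == b && setequal(selector$start_labels, selector$end_labels)) next
    trav <- traversed_labels(tractogram$streamlines[[i]], labels)
    if (length(selector$exclusion_labels) && any(trav %in% selector$exclusion_labels)) next
    ok <- TRUE
    for (wp in selector$waypoint_labels) {
      if (!any(trav %in% wp)) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  out <- tractogram
  out$streamlines <- tractogram$streamlines[keep]
  out$provenance$bundle_selector <- unclass(selector)
  out
}

#' Head/body/tail summaries of a connectivity matrix
#'
#' @param matrix a [connectivity_matrix()].
#' @return list with `degree` (per-region row sums, data.frame) and
#'   `part_totals` (within/between aggregates over head, body, tail; each
#'   connection counted once).
#' @export
matrix_summaries <- function(matrix) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  leg <- matrix$legend
  degree <- data.frame(label = leg$label, part = leg$part, structure = leg$structure,
                       degree = rowSums(matrix$counts), stringsAsFactors = FALSE)
  parts <- c("head", "body", "tail")
  pt <- expand.grid(part_a = parts, part_b = parts, stringsAsFactors = FALSE)
  pt <- pt[as.integer(factor(pt$part_a, parts)) <= as.integer(factor(pt$part_b, parts)), ]
  pt$total <- vapply(seq_len(nrow(pt)), function(i) {
    ra <- which(leg$part == pt$part_a[i]); rb <- which(leg$part == pt$part_b[i])
    sub <- matrix$counts[ra, rb, drop = FALSE]
    if (pt$part_a[i] == pt$part_b[i]) sum(sub[upper.tri(sub)]) else sum(sub)
  }, 0)
  rownames(pt) <- NULL
  list(degree = degree, part_totals = pt)
}

#' Write / read a connectivity matrix as TSV
#'
#' TSV with a header row and first column of "part: structure" region names;
#' write -> read is an exact round trip.
#'
#' @param matrix a [connectivity_matrix()].
#' @param path file path.
#' @return `write_matrix_tsv`: invisibly `path`; `read_matrix_tsv`: a
#'   [connectivity_matrix()].
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  leg <- matrix$legend
  if (anyNA(leg$structure) || anyNA(leg$part)) stopf("write_matrix_tsv: incomplete legend")
  rn <- paste(leg$part, leg$structure, sep = ": ")
  lines <- c(paste(c("region", rn), collapse = "\t"),
             vapply(seq_len(nrow(matrix$counts)), function(i) {
               paste(c(rn[i], format(matrix$counts[i, ], digits = 15, trim = TRUE,
                                     scientific = FALSE)), collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param legend legend to attach on read (default [hippocampus_legend()]).
#' @export
read_matrix_tsv <- function(path, legend = hippocampus_legend()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rn <- paste(legend$part, legend$structure, sep = ": ")
  if (!identical(unname(df[[1]]), rn)) stopf("read_matrix_tsv: region names do not match legend")
  connectivity_matrix(unname(counts), legend)
}
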