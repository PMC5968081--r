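# TCK tractogram format: text header, Float32LE point triples, streamlines
# separated by a NaN triple, file terminated by an Inf triple.

#' Write a tractogram in TCK format
#'
#' @param tractogram a `tractogram` (world-mm polylines).
#' @param path output `.tck` path.
#' @return invisibly, `path`.
#' @export
write_tck <- function(tractogram, path) {
  stopifnot(inherits(tractogram, "tractogram"))
  n <- length(tractogram$streamlines)
  header <- c(
    "mrtrix tracks",
    "datatype: Float32LE",
    sprintf("count: %d", n),
    sprintf("step_size: %.6g", tractogram$step_size),
    sprintf("hdmri_model: %s", tractogram$provenance$model %||% "unknown"),
    sprintf("hdmri_algorithm: %s", tractogram$provenance$algorithm %||% "unknown")
  )
  # compute the data offset: header + "file: . OFFSET" + "END" lines
  offset <- 0L
  repeat {
    file_line <- sprintf("file: . %d", offset)
    txt <- paste0(paste(c(header, file_line, "END"), collapse = "\n"), "\n")
    need <- nchar(txt, type = "bytes")
    if (need <= offset) break
    offset <- need
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(txt, con, eos = NULL)
  pad <- offset - nchar(txt, type = "bytes")
  if (pad > 0) writeBin(raw(pad), con)
  for (sl in tractogram$streamlines) {
    writeBin(as.double(t(sl)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4L, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a TCK tractogram
#'
#' @param path `.tck` file.
#' @return a `tractogram` (streamlines in world mm; provenance from the header
#'   where present).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks")) stopf("read_tck: not a TCK file: %s", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stopf("read_tck: unterminated header")
    if (identical(line, "END")) break
    kv <- regmatches(line, regexpr(": ", line), invert = TRUE)[[1]]
    if (length(kv) == 2L) fields[[kv[1]]] <- kv[2]
  }
  offset <- as.integer(sub("^\\. ", "", fields$file))
  if (!identical(fields$datatype, "Float32LE")) {
    stopf("read_tck: unsupported datatype %s", fields$datatype)
  }
  seek(con, offset)
  vals <- readBin(con, "double", n = file.size(path), size = 4L, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  fin <- is.finite(pts[, 1])
  ends <- which(!fin & !is.nan(pts[, 1]))   # Inf terminator
  breaks <- which(is.nan(pts[, 1]))
  streamlines <- list()
  start <- 1L
  for (b in sort(c(breaks, ends))) {
    if (b > start) streamlines[[length(streamlines) + 1L]] <- pts[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
    if (b %in% ends) break
  }
  structure(list(streamlines = streamlines,
                 step_size = suppressWarnings(as.double(fields$step_size %||% NA)),
                 provenance = list(model = fields$hdmri_model %||% NA,
                                   algorithm = fields$hdmri_algorithm %||% NA)),
            class = "tractogram")
}
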