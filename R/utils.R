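# Internal numeric helpers shared across modules.

#' @keywords internal
"_PACKAGE"

.hdmri_env <- new.env(parent = emptyenv())

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Gauss-Legendre nodes and weights on [-1, 1]
#'
#' Golub-Welsch: eigen-decomposition of the symmetric tridiagonal Jacobi
#' matrix of the Legendre recurrence. Cached per order.
#'
#' @param n number of nodes.
#' @return list with `nodes` and `weights`, both length `n`.
#' @keywords internal
gauss_legendre <- function(n) {
  key <- paste0("gl", n)
  cached <- .hdmri_env[[key]]
  if (!is.null(cached)) return(cached)
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  nodes <- e$values
  weights <- 2 * e$vectors[1, ]^2
  ord <- order(nodes)
  out <- list(nodes = nodes[ord], weights = weights[ord])
  .hdmri_env[[key]] <- out
  out
}

# Row-wise L2 normalisation of an n x 3 matrix; zero rows left untouched.
normalize_rows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  ok <- nrm > 0
  m[ok, ] <- m[ok, , drop = FALSE] / nrm[ok]
  m
}

# Draw a 32-bit-safe child seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 16807) %% 2147483562L) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Write a stage sidecar log
#'
#' Every pipeline stage records its full configuration and RNG seed next to
#' its outputs so a run can be reproduced bit-exactly.
#'
#' @param path output path of the main artifact (log written as `<path>.log.json`).
#' @param stage stage name.
#' @param params named list of parameters (must be JSON-serialisable).
#' @return invisibly, the log path.
#' @export
write_sidecar_log <- function(path, stage, params) {
  log_path <- paste0(path, ".log.json")
  payload <- list(
    stage = stage,
    package = "hdmri",
    version = as.character(utils::packageVersion("hdmri")),
    params = params
  )
  jsonlite::write_json(payload, log_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(log_path)
}
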