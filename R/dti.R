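# Diffusion tensor fitting and derived scalar maps (FA, MD, colour-encoded
# direction).

#' Fit the diffusion tensor voxelwise
#'
#' Weighted linear least squares on the log signal: an ordinary LS pass on
#' log S = log S0 - b g' D g followed by one reweighting pass with weights
#' equal to the squared predicted signal (the standard WLS estimator).
#' Nonpositive signal samples are excluded per voxel; a voxel with fewer than
#' 7 usable measurements is left invalid. Negative tensor eigenvalues are
#' clamped to zero and the clamp events counted in attribute `n_clamped`.
#'
#' @param dwi a [dwi_dataset()].
#' @param shell_selector optional predicate on b selecting the measurements to
#'   use (e.g. `function(b) b == 0 | b == 4500`); default uses all volumes.
#' @return object of class `tensor_field`: `tensors` (4-D array, 6 unique
#'   components Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `s0`, `e1` (principal
#'   eigenvector, 4-D), `evals` (4-D, descending), `valid`, `grid`, `mask`.
#' @export
fit_dti <- function(dwi, shell_selector = NULL) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  keep <- if (is.null(shell_selector)) rep(TRUE, length(dwi$scheme)) else shell_selector(dwi$scheme$b)
  b <- dwi$scheme$b[keep]
  g <- dwi$scheme$directions[keep, , drop = FALSE]
  if (!any(b == 0)) stopf("fit_dti: selected shell has no b = 0 volume")
  if (all(b == 0)) stopf("fit_dti: selected shell has no diffusion-weighted volume")
  ndir <- nrow(unique(round(g[b > 0, , drop = FALSE], 6)))
  if (ndir < 6L) stopf("fit_dti: need >= 6 unique directions, got %d", ndir)
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  shp <- dwi$grid$shape
  nvol <- sum(keep)
  sig <- matrix(dwi$signal[, , , keep, drop = FALSE], ncol = nvol)
  idx <- which(dwi$mask)
  tensors <- array(NA_real_, c(shp, 6))
  e1 <- array(NA_real_, c(shp, 3))
  evals <- array(NA_real_, c(shp, 3))
  s0 <- array(NA_real_, shp)
  valid <- array(FALSE, shp)
  n_clamped <- 0L
  nxyz <- prod(shp)
  for (v in idx) {
    y <- sig[v, ]
    use <- y > 0
    if (sum(use) < 7L) next
    ly <- log(y[use])
    Xu <- X[use, , drop = FALSE]
    cf <- tryCatch(stats::lm.fit(Xu, ly)$coefficients, error = function(e) NULL)
    if (is.null(cf) || any(!is.finite(cf))) next
    w <- exp(2 * as.vector(Xu %*% cf))           # squared predicted signal
    cf <- tryCatch(stats::lm.wfit(Xu, ly, w)$coefficients, error = function(e) cf)
    if (any(!is.finite(cf))) next
    D <- matrix(c(cf[2], cf[5], cf[6],
                  cf[5], cf[3], cf[7],
                  cf[6], cf[7], cf[4]), 3, 3)
    ed <- eigen(D, symmetric = TRUE)
    lam <- ed$values
    if (any(lam < 0)) { n_clamped <- n_clamped + 1L; lam <- pmax(lam, 0) }
    tensors[c(v, v + nxyz, v + 2 * nxyz, v + 3 * nxyz, v + 4 * nxyz, v + 5 * nxyz)] <-
      c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
    e1[c(v, v + nxyz, v + 2 * nxyz)] <- ed$vectors[, 1]
    evals[c(v, v + nxyz, v + 2 * nxyz)] <- lam
    s0[v] <- exp(cf[1])
    valid[v] <- TRUE
  }
  out <- structure(list(tensors = tensors, s0 = s0, e1 = e1, evals = evals,
                        valid = valid, grid = dwi$grid, mask = dwi$mask),
                   class = "tensor_field")
  attr(out, "n_clamped") <- n_clamped
  out
}

# FA from eigenvalues (rows of an n x 3 matrix).
fa_from_evals <- function(lam) {
  md <- rowMeans(lam)
  num <- sqrt(rowSums((lam - md)^2))
  den <- sqrt(rowSums(lam^2))
  fa <- sqrt(3 / 2) * num / den
  fa[den == 0] <- 0
  clamp(fa, 0, 1)
}

#' Scalar maps from a tensor field
#'
#' MD = trace/3; FA in the standard invariant form
#' sqrt(3/2) * ||lambda - MD|| / ||lambda||; CED = |principal eigenvector|
#' componentwise scaled by FA, mapped to RGB as x -> red, y -> green,
#' z -> blue. Invalid voxels get 0.
#'
#' @param field a `tensor_field` from [fit_dti()].
#' @return list with 3-D arrays `fa`, `md` and 4-D `ced` (3 channels in \[0,1\]).
#' @export
tensor_metrics <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  shp <- field$grid$shape
  nxyz <- prod(shp)
  lam <- matrix(field$evals, ncol = 3)
  fa <- array(0, shp); md <- array(0, shp)
  ced <- array(0, c(shp, 3))
  ok <- which(field$valid)
  if (length(ok)) {
    fa_v <- fa_from_evals(lam[ok, , drop = FALSE])
    fa[ok] <- fa_v
    md[ok] <- rowMeans(lam[ok, , drop = FALSE])
    ev <- matrix(field$e1, ncol = 3)[ok, , drop = FALSE]
    for (k in 1:3) ced[ok + (k - 1) * nxyz] <- abs(ev[, k]) * fa_v
  }
  list(fa = fa, md = md, ced = ced)
}
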