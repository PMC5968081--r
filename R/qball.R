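# Analytical Q-ball: single-shell ODF reconstruction in the real even-order
# SH basis with Laplace-Beltrami regularization, and ODF peak extraction.

#' Fit analytical Q-ball ODFs voxelwise
#'
#' Signal SH coefficients are the Laplace-Beltrami-regularized least-squares
#' solution c = (B'B + lambda L^2)^-1 B' s on the selected single shell, with
#' L the diagonal of l(l+1) per coefficient and s the b0-normalised signal.
#' The Funk-Radon transform is applied analytically per degree (Funk-Hecke):
#' odf coefficients c'_lm = 2 pi P_l(0) c_lm, with P_l(0) the Legendre
#' polynomial at zero. The ODF is scaled so its l = 0 term corresponds to
#' unit integral over the sphere.
#'
#' @param dwi a [dwi_dataset()].
#' @param order even SH order (default 8, 45 coefficients).
#' @param lambda_reg Laplace-Beltrami regularization factor (default 0.006).
#' @param shell_b b-value of the shell to use; default the single nonzero
#'   shell if unique, else an error asking for an explicit choice.
#' @return object of class `sh_field`: `coefficients` (4-D array, last dim =
#'   number of coefficients), `order`, `basis` descriptor, `grid`, `mask`.
#' @export
fit_aqbi <- function(dwi, order = 8L, lambda_reg = 0.006, shell_b = NULL) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  if (order %% 2 != 0) stopf("fit_aqbi: order must be even")
  bs <- unique(round(dwi$scheme$b[dwi$scheme$b > 0]))
  if (is.null(shell_b)) {
    if (length(bs) != 1L) {
      stopf("fit_aqbi: multi-shell input (b = %s); pass shell_b",
            paste(bs, collapse = ", "))
    }
    shell_b <- bs
  }
  sel <- abs(dwi$scheme$b - shell_b) < 0.5
  g <- dwi$scheme$directions[sel, , drop = FALSE]
  ncoef <- sh_n_coef(order)
  if (nrow(g) < ncoef) {
    stopf("fit_aqbi: %d directions < %d coefficients at order %d", nrow(g), ncoef, order)
  }
  B <- sh_basis(g, order)
  tab <- sh_index_table(order)
  LL <- (tab$l * (tab$l + 1))^2
  solver <- solve(crossprod(B) + lambda_reg * diag(LL), t(B))
  frt <- 2 * pi * legendre_p0(tab$l)

  shp <- dwi$grid$shape
  s0 <- b0_mean(dwi)
  sig <- matrix(dwi$signal[, , , sel, drop = FALSE], ncol = sum(sel))
  idx <- which(dwi$mask & s0 > 0)
  coef <- array(NA_real_, c(shp, ncoef))
  nxyz <- prod(shp)
  unit_c0 <- 1 / sqrt(4 * pi)
  for (v in idx) {
    cs <- as.vector(solver %*% (sig[v, ] / s0[v]))
    od <- frt * cs
    if (is.finite(od[1]) && od[1] > 0) od <- od * (unit_c0 / od[1])
    coef[v + (seq_len(ncoef) - 1) * nxyz] <- od
  }
  structure(list(coefficients = coef, order = order,
                 basis = "real symmetric SH, even degrees, m = -l..l, descoteaux-style",
                 lambda_reg = lambda_reg, shell_b = shell_b,
                 grid = dwi$grid, mask = dwi$mask & s0 > 0),
            class = "sh_field")
}

#' @export
print.sh_field <- function(x, ...) {
  cat(sprintf("<sh_field> order %d (%d coefficients), %d voxels\n",
              x$order, sh_n_coef(x$order), sum(x$mask)))
  invisible(x)
}

#' Fit the signal SH coefficients only (no Funk-Radon transform)
#'
#' Utility for tests of interpolation exactness; same regularized solver as
#' [fit_aqbi()] but returning the signal-space coefficients.
#'
#' @inheritParams fit_aqbi
#' @param signal numeric vector of samples on the shell directions.
#' @param dirs n x 3 unit directions.
#' @return coefficient vector.
#' @export
sh_fit_signal <- function(signal, dirs, order = 8L, lambda_reg = 0) {
  B <- sh_basis(dirs, order)
  tab <- sh_index_table(order)
  LL <- (tab$l * (tab$l + 1))^2
  as.vector(solve(crossprod(B) + lambda_reg * diag(LL), t(B) %*% signal))
}

#' Extract ODF peaks on a tessellated sphere
#'
#' The ODF is evaluated on the tessellation vertices; peaks are strict local
#' maxima over the neighbour graph, antipodally merged, pruned below
#' `relative_threshold` times the voxel's largest peak, and greedily selected
#' (descending amplitude) under a minimum pairwise angular separation, keeping
#' at most `max_peaks`.
#'
#' @param field an `sh_field` from [fit_aqbi()].
#' @param sphere a [sphere_tessellation()] (default subdiv 4, 1281 antipodal
#'   pairs).
#' @param relative_threshold peaks below this fraction of the largest are
#'   dropped (default 0.5).
#' @param min_separation minimum angle between retained peaks, degrees
#'   (default 25).
#' @param max_peaks maximum peaks per voxel (default 3).
#' @return object of class `peak_set`: `directions` (5-D: x,y,z,peak,3),
#'   `amplitudes` (4-D), `n_peaks` (3-D), `grid`.
#' @export
extract_peaks <- function(field, sphere = sphere_tessellation(4L),
                          relative_threshold = 0.5, min_separation = 25,
                          max_peaks = 3L) {
  stopifnot(inherits(field, "sh_field"), inherits(sphere, "sphere_tessellation"))
  stopifnot(relative_threshold >= 0, relative_threshold <= 1, min_separation >= 0)
  Bs <- sh_basis(sphere$vertices, field$order)
  shp <- field$grid$shape
  nxyz <- prod(shp)
  ncoef <- sh_n_coef(field$order)
  cmat <- matrix(field$coefficients, ncol = ncoef)
  idx <- which(field$mask)
  dir_arr <- array(NA_real_, c(shp, max_peaks, 3))
  amp_arr <- array(NA_real_, c(shp, max_peaks))
  npk <- array(0L, shp)
  cos_sep <- cos(min_separation * pi / 180)
  for (v in idx) {
    vals <- as.vector(Bs %*% cmat[v, ])
    pk <- find_odf_peaks(vals, sphere, relative_threshold, cos_sep, max_peaks)
    if (nrow(pk$dirs) == 0L) next
    npk[v] <- nrow(pk$dirs)
    for (p in seq_len(nrow(pk$dirs))) {
      amp_arr[v + (p - 1) * nxyz] <- pk$amps[p]
      for (k in 1:3) dir_arr[v + ((p - 1) + (k - 1) * max_peaks) * nxyz] <- pk$dirs[p, k]
    }
  }
  structure(list(directions = dir_arr, amplitudes = amp_arr, n_peaks = npk,
                 grid = field$grid, max_peaks = max_peaks),
            class = "peak_set")
}

# Strict-local-maximum peak finding on precomputed vertex amplitudes.
find_odf_peaks <- function(vals, sphere, relative_threshold, cos_sep, max_peaks) {
  n <- length(vals)
  is_max <- vapply(seq_len(n), function(i) {
    nb <- sphere$neighbors[[i]]
    all(vals[i] > vals[nb])
  }, TRUE)
  cand <- which(is_max)
  if (length(cand) == 0L) return(list(dirs = matrix(0, 0, 3), amps = numeric(0)))
  # antipodal merge: keep one representative per pair
  rep_id <- pmin(cand, sphere$antipode[cand])
  keep <- !duplicated(rep_id)
  cand <- cand[keep]
  ord <- order(vals[cand], decreasing = TRUE)
  cand <- cand[ord]
  amax <- vals[cand[1]]
  cand <- cand[vals[cand] >= relative_threshold * amax]
  sel <- integer(0)
  for (i in cand) {
    d <- sphere$vertices[i, ]
    ok <- TRUE
    for (j in sel) {
      if (abs(sum(d * sphere$vertices[j, ])) >= cos_sep) { ok <- FALSE; break }
    }
    if (ok) sel <- c(sel, i)
    if (length(sel) >= max_peaks) break
  }
  list(dirs = sphere$vertices[sel, , drop = FALSE], amps = vals[sel])
}

#' Evaluate an SH field's ODF amplitudes at one voxel
#'
#' @param field an `sh_field`.
#' @param voxel integer triple, 1-based voxel index.
#' @param dirs n x 3 unit directions.
#' @return amplitude vector.
#' @export
odf_amplitudes <- function(field, voxel, dirs) {
  ncoef <- sh_n_coef(field$order)
  cs <- field$coefficients[voxel[1], voxel[2], voxel[3], ]
  as.vector(sh_basis(dirs, field$order) %*% cs)
}
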