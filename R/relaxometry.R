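# T2 relaxometry: multi-echo spin-echo fitting, histogram mode analysis, and
# voxelwise T2-decay compensation of higher-TE diffusion shells.

#' Multi-echo spin-echo series
#'
#' @param grid a [volume_grid()].
#' @param signal 4-D non-negative array (x, y, z, echo).
#' @param echo_times strictly increasing echo times (ms), length >= 2 matching
#'   the 4th dimension.
#' @return object of class `msme_series`.
#' @export
msme_series <- function(grid, signal, echo_times) {
  stopifnot(inherits(grid, "volume_grid"))
  if (length(dim(signal)) != 4L) stopf("msme_series: signal must be 4-D")
  if (!all(dim(signal)[1:3] == grid$shape)) stopf("msme_series: signal dims do not match grid")
  echo_times <- as.double(echo_times)
  if (length(echo_times) < 2L) stopf("msme_series: need at least 2 echoes")
  if (dim(signal)[4] != length(echo_times)) stopf("msme_series: echo count mismatch")
  if (any(diff(echo_times) <= 0)) stopf("msme_series: echo_times must be strictly increasing")
  structure(list(grid = grid, signal = signal, echo_times = echo_times),
            class = "msme_series")
}

#' Quantitative T2 map
#'
#' @param grid a [volume_grid()].
#' @param t2 3-D array of T2 (ms); positive wherever `valid`.
#' @param s0 3-D array of TE = 0 signal.
#' @param valid 3-D logical array flagging voxels with a usable fit. Voxels
#'   where the decay could not be estimated are flagged, never silently zeroed.
#' @return object of class `t2_map`.
#' @export
t2_map <- function(grid, t2, s0, valid) {
  stopifnot(inherits(grid, "volume_grid"))
  stopifnot(all(dim(t2) == grid$shape), all(dim(s0) == grid$shape),
            all(dim(valid) == grid$shape))
  valid <- array(as.logical(valid), dim = dim(valid))
  if (any(valid & !(t2 > 0), na.rm = TRUE)) stopf("t2_map: nonpositive T2 flagged valid")
  structure(list(grid = grid, t2 = t2, s0 = s0, valid = valid), class = "t2_map")
}

#' Fit a voxelwise mono-exponential T2 decay
#'
#' Per voxel, a log-linear least-squares fit of log S = log S0 - TE/T2 gives
#' the starting point, then a damped (Levenberg-Marquardt) Gauss-Newton
#' refinement of S0 * exp(-TE/T2) on the raw signal. Nonpositive samples are
#' excluded (not clamped) before the log fit; a voxel is invalid when fewer
#' than 2 usable echoes remain, or when the fitted decay is non-positive
#' (e.g. a constant series, for which T2 is unbounded).
#'
#' @param series an [msme_series()].
#' @param mask 3-D logical array of voxels to fit; must be nonempty.
#' @param max_iter LM iterations (default 50).
#' @return a [t2_map()].
#' @export
fit_t2_map <- function(series, mask = NULL, max_iter = 50L) {
  stopifnot(inherits(series, "msme_series"))
  te <- series$echo_times
  ne <- length(te)
  if (ne < 2L) stopf("fit_t2_map: need at least 2 echoes")
  if (is.null(mask)) mask <- array(TRUE, dim = series$grid$shape)
  if (!any(mask)) stopf("fit_t2_map: empty mask")
  idx <- which(mask)
  sig <- matrix(aperm(series$signal, c(4, 1, 2, 3)), nrow = ne)[, idx, drop = FALSE]
  nv <- length(idx)

  # log-linear initialisation, voxels in columns; exclude nonpositive samples
  pos <- sig > 0
  usable <- colSums(pos) >= 2L
  r2 <- rep(NA_real_, nv); ls0 <- rep(NA_real_, nv)
  for (j in which(usable)) {
    k <- pos[, j]
    cf <- stats::lm.fit(cbind(1, -te[k]), log(sig[k, j]))$coefficients
    ls0[j] <- cf[1]; r2[j] <- cf[2]
  }
  # a voxel whose fitted decay is below ~1% over the echo range carries no
  # usable T2 information (a constant series has an unbounded T2): invalid
  r2_min <- 0.01 / (max(te) - min(te))
  ok <- usable & is.finite(r2) & r2 > r2_min
  s0 <- exp(ls0)

  # vectorised LM refinement of (S0, R2 = 1/T2) on the exponential model
  if (any(ok)) {
    jj <- which(ok)
    S0 <- s0[jj]; R2 <- r2[jj]
    y <- sig[, jj, drop = FALSE]
    lam <- rep(1e-3, length(jj))
    sse <- colSums((S0 * exp(-te %o% R2) - y)^2)
    for (it in seq_len(max_iter)) {
      E <- exp(-te %o% R2)                    # ne x nv
      r <- sweep(E, 2, S0, `*`) - y
      # J columns: dS0 = E, dR2 = -S0 * te * E
      g1 <- colSums(E * r)
      g2 <- colSums(-(te * E) * r) * S0
      a11 <- colSums(E^2)
      a22 <- colSums((te * E)^2) * S0^2
      a12 <- colSums(-te * E^2) * S0
      d11 <- a11 * (1 + lam); d22 <- a22 * (1 + lam)
      det <- d11 * d22 - a12^2
      det[abs(det) < 1e-300] <- NA
      dS0 <- -( d22 * g1 - a12 * g2) / det
      dR2 <- -(-a12 * g1 + d11 * g2) / det
      S0n <- S0 + ifelse(is.finite(dS0), dS0, 0)
      R2n <- R2 + ifelse(is.finite(dR2), dR2, 0)
      bad <- !is.finite(R2n) | R2n <= 0 | !is.finite(S0n) | S0n <= 0
      S0n[bad] <- S0[bad]; R2n[bad] <- R2[bad]
      sse_n <- colSums((sweep(exp(-te %o% R2n), 2, S0n, `*`) - y)^2)
      accept <- is.finite(sse_n) & sse_n <= sse & !bad
      S0[accept] <- S0n[accept]; R2[accept] <- R2n[accept]
      lam <- ifelse(accept, pmax(lam / 4, 1e-10), pmin(lam * 8, 1e8))
      improved <- sse[accept] - sse_n[accept]
      sse[accept] <- sse_n[accept]
      if (all(!accept) || max(c(improved, 0)) < 1e-14 * max(sse, 1e-300)) break
    }
    s0[jj] <- S0; r2[jj] <- R2
  }

  shp <- series$grid$shape
  t2a <- array(NA_real_, shp); s0a <- array(NA_real_, shp)
  va <- array(FALSE, shp)
  t2v <- 1 / r2
  t2a[idx] <- ifelse(ok, t2v, NA_real_)
  s0a[idx] <- ifelse(ok, s0, NA_real_)
  va[idx] <- ok
  t2_map(series$grid, t2a, s0a, va)
}

#' Locate the main modes of a scalar map's histogram
#'
#' Kernel-density estimate (Gaussian kernel, Silverman's rule-of-thumb
#' bandwidth, 512-point grid) over the masked values; modes are the strict
#' local maxima of the density, returned as the `n_modes` highest, in
#' ascending order of location. If fewer maxima exist than requested the
#' existing ones are returned with a warning.
#'
#' @param map 3-D numeric array (e.g. a T2 map in ms).
#' @param mask 3-D logical array; must select at least 2 finite values.
#' @param n_modes 1 or 2.
#' @return numeric vector of mode locations (ascending).
#' @export
histogram_modes <- function(map, mask, n_modes = 2L) {
  stopifnot(n_modes %in% c(1L, 2L))
  vals <- map[mask]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L) stopf("histogram_modes: empty (or near-empty) mask")
  d <- stats::density(vals, bw = "nrd0", n = 512)
  y <- d$y
  int <- which(y[2:511] > y[1:510] & y[2:511] > y[3:512]) + 1L
  if (length(int) == 0L) int <- which.max(y)
  if (length(int) < n_modes) {
    warning(sprintf("histogram_modes: %d mode(s) requested but only %d found",
                    n_modes, length(int)))
    n_modes <- length(int)
  }
  top <- int[order(y[int], decreasing = TRUE)][seq_len(n_modes)]
  sort(d$x[top])
}

#' Compensate the T2 decay of a higher-TE shell
#'
#' Multiplies every volume voxelwise by exp(delta_te / T2(v)), undoing the
#' extra T2 weighting a shell acquired at TE = TE_ref + delta_te carries
#' relative to the reference (lowest-TE) shell. Voxels with an invalid T2
#' fit are left unchanged and flagged in the returned attribute
#' `uncompensated` (count).
#'
#' @param shell a [dwi_dataset()] (typically the volumes of one shell).
#' @param t2map a [t2_map()] on the same grid.
#' @param delta_te TE(shell) - TE(reference shell), ms, >= 0.
#' @return a [dwi_dataset()] with compensated signal.
#' @export
compensate_t2 <- function(shell, t2map, delta_te) {
  stopifnot(inherits(shell, "dwi_dataset"), inherits(t2map, "t2_map"))
  if (!grids_equal(shell$grid, t2map$grid)) stopf("compensate_t2: grid mismatch")
  if (!is_scalar_num(delta_te) || delta_te < 0) stopf("compensate_t2: delta_te must be >= 0")
  fac <- array(1, dim = shell$grid$shape)
  v <- t2map$valid
  fac[v] <- exp(delta_te / t2map$t2[v])
  sig <- shell$signal * as.vector(fac)   # recycles over the 4th dim
  out <- dwi_dataset(shell$grid, sig, shell$scheme, shell$mask)
  attr(out, "uncompensated") <- sum(!v & shell$mask)
  out
}

#' Compensate a whole multi-shell dataset to its lowest-TE shell
#'
#' Applies [compensate_t2()] per shell group with delta_te = TE(shell) -
#' min(TE), leaving the reference shell untouched.
#'
#' @param dwi a multi-shell [dwi_dataset()].
#' @param t2map a [t2_map()].
#' @return a [dwi_dataset()] with all shells on the reference shell's T2 weighting.
#' @export
compensate_t2_dataset <- function(dwi, t2map) {
  te_ref <- min(dwi$scheme$TE)
  sig <- dwi$signal
  fac_cache <- list()
  v <- t2map$valid
  for (j in seq_len(dim(sig)[4])) {
    dte <- dwi$scheme$TE[j] - te_ref
    if (dte <= 0) next
    key <- format(dte, digits = 12)
    if (is.null(fac_cache[[key]])) {
      f <- array(1, dim = dwi$grid$shape)
      f[v] <- exp(dte / t2map$t2[v])
      fac_cache[[key]] <- f
    }
    sig[, , , j] <- sig[, , , j] * fac_cache[[key]]
  }
  dwi_dataset(dwi$grid, sig, dwi$scheme, dwi$mask)
}
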