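# Four-compartment ex vivo NODDI: Watson-dispersed intra-cellular sticks,
# tortuous extra-cellular tensor, isotropic free water, and a stationary
# compartment that stays unattenuated by diffusion weighting (fixed-tissue
# water trapped in glial cells).
#
# Nested fraction parametrisation:
#   A = (1 - f_iso) [ (1 - f'_stat) (f*_ic A_ic + (1 - f*_ic) A_ec) + f'_stat ]
#       + f_iso A_iso
# with global fractions
#   f_stat = (1 - f_iso) f'_stat
#   f_ic   = (1 - f_iso)(1 - f'_stat) f*_ic
#   f_ec   = (1 - f_iso)(1 - f'_stat)(1 - f*_ic)
# so that f_ic + f_ec + f_stat + f_iso = 1 exactly.

#' Default fixed diffusivities of the ex vivo model (mm^2/s)
#'
#' `D_PAR_EXVIVO` is the intrinsic parallel (stick) diffusivity, set to the
#' mean tissue diffusivity of fixed grey matter at room temperature;
#' `D_ISO_EXVIVO` is the free-water diffusivity at 20 C.
#' @export
D_PAR_EXVIVO <- 0.16e-3

#' @rdname D_PAR_EXVIVO
#' @export
D_ISO_EXVIVO <- 2.0e-3

#' NODDI parameter set for one voxel
#'
#' @param f_iso free-water fraction in \[0, 1\].
#' @param f_stat_prime nested stationary fraction f'_stat in \[0, 1\].
#' @param f_ic_star nested intra-cellular fraction f*_ic in \[0, 1\].
#' @param odi orientation dispersion index in (0, 1\]; alternative to `kappa`.
#' @param mu unit 3-vector mean orientation.
#' @param kappa Watson concentration (>= 0); derived from `odi` if missing.
#' @param d_parallel,d_iso fixed diffusivities (mm^2/s).
#' @param s0 non-diffusion-weighted signal.
#' @return object of class `noddi_params`.
#' @export
noddi_params <- function(f_iso, f_stat_prime, f_ic_star, odi = NULL, mu = c(0, 0, 1),
                         kappa = NULL, d_parallel = D_PAR_EXVIVO, d_iso = D_ISO_EXVIVO,
                         s0 = 1) {
  for (f in c(f_iso, f_stat_prime, f_ic_star)) {
    if (!is_scalar_num(f) || f < 0 || f > 1) stopf("noddi_params: fractions must be in [0, 1]")
  }
  if (is.null(kappa)) {
    if (is.null(odi)) stopf("noddi_params: give odi or kappa")
    kappa <- odi_to_kappa(odi)
  }
  if (kappa < 0) stopf("noddi_params: kappa must be >= 0")
  mu <- as.double(mu)
  nrm <- sqrt(sum(mu^2))
  if (abs(nrm - 1) > 1e-6) {
    if (nrm == 0) stopf("noddi_params: mu must be a unit vector")
    mu <- mu / nrm
  }
  structure(list(f_iso = f_iso, f_stat_prime = f_stat_prime, f_ic_star = f_ic_star,
                 kappa = kappa, odi = kappa_to_odi(kappa), mu = mu,
                 d_parallel = d_parallel, d_iso = d_iso, s0 = s0),
            class = "noddi_params")
}

#' Global compartment fractions from the nested parametrisation
#'
#' @param f_iso,f_stat_prime,f_ic_star nested fractions in \[0, 1\].
#' @return named list (f_ic, f_ec, f_stat); together with f_iso they sum to 1.
#' @export
derive_fractions <- function(f_iso, f_stat_prime, f_ic_star) {
  for (f in list(f_iso, f_stat_prime, f_ic_star)) {
    if (any(f < 0 | f > 1, na.rm = TRUE)) stopf("derive_fractions: inputs must be in [0, 1]")
  }
  f_stat <- (1 - f_iso) * f_stat_prime
  f_ic <- (1 - f_iso) * (1 - f_stat_prime) * f_ic_star
  f_ec <- (1 - f_iso) * (1 - f_stat_prime) * (1 - f_ic_star)
  list(f_ic = f_ic, f_ec = f_ec, f_stat = f_stat)
}

# Compartment attenuations for a scheme given (kappa, mu, f_ic_star).
# Returns list(a_ic, a_ec, a_iso), each length(scheme).
noddi_kernels <- function(scheme, kappa, mu, f_ic_star,
                          d_parallel = D_PAR_EXVIVO, d_iso = D_ISO_EXVIVO) {
  b <- scheme$b
  ca <- as.vector(scheme$directions %*% mu)
  ca[b == 0] <- 0
  a_ic <- watson_stick_attenuation(b * d_parallel, ca, kappa)
  a_ic[b == 0] <- 1
  tau1 <- watson_tau1(kappa)
  d_perp <- d_parallel * (1 - f_ic_star)        # tortuosity
  # Watson-averaged axially symmetric tensor:
  # g'<D>g = d_perp + (d_par - d_perp) * [ (1-tau1)/2 + (3 tau1 - 1)/2 * (g'mu)^2 ]
  gdg <- d_perp + (d_parallel - d_perp) * ((1 - tau1) / 2 + (3 * tau1 - 1) / 2 * ca^2)
  a_ec <- exp(-b * gdg)
  a_iso <- exp(-b * d_iso)
  list(a_ic = a_ic, a_ec = a_ec, a_iso = a_iso)
}

#' Forward four-compartment NODDI signal attenuation
#'
#' A = f_ic A_ic + f_ec A_ec + f_iso A_iso + f_stat, with A_ic the
#' Watson-average of the stick decay exp(-b d_par (g'u)^2), A_ec the decay of
#' the Watson-averaged tortuous tensor (d_perp = d_par (1 - f*_ic)), A_iso =
#' exp(-b d_iso), and the stationary compartment contributing 1 at every b.
#' A(b = 0) = 1 exactly.
#'
#' @param params a [noddi_params()].
#' @param scheme a [gradient_scheme()].
#' @return attenuation vector in \[0, 1\], one value per scheme entry.
#' @export
noddi_forward <- function(params, scheme) {
  stopifnot(inherits(params, "noddi_params"), inherits(scheme, "gradient_scheme"))
  fr <- derive_fractions(params$f_iso, params$f_stat_prime, params$f_ic_star)
  k <- noddi_kernels(scheme, params$kappa, params$mu, params$f_ic_star,
                     params$d_parallel, params$d_iso)
  A <- fr$f_ic * k$a_ic + fr$f_ec * k$a_ec + params$f_iso * k$a_iso + fr$f_stat
  A[scheme$b == 0] <- 1
  A
}

#' Fit configuration for [fit_noddi()]
#'
#' @param grid_fractions fraction grid for the coarse search (default 0..1 by 0.1).
#' @param grid_odi ODI grid for the coarse search.
#' @param d_parallel,d_iso fixed diffusivities (mm^2/s).
#' @param maxit Nelder-Mead iteration budget for the refinement.
#' @param refine logical; skip the nonlinear refinement if FALSE.
#' @return list of settings.
#' @export
noddi_fit_config <- function(grid_fractions = seq(0, 1, by = 0.1),
                             grid_odi = c(0.04, 0.16, 0.36, 0.64, 0.84),
                             d_parallel = D_PAR_EXVIVO, d_iso = D_ISO_EXVIVO,
                             maxit = 800L, refine = TRUE) {
  list(grid_fractions = grid_fractions, grid_odi = grid_odi,
       d_parallel = d_parallel, d_iso = d_iso, maxit = maxit, refine = refine)
}

# map R -> (0,1)
.sq <- function(t) 1 / (1 + exp(-t))
.sq_inv <- function(p) stats::qlogis(clamp(p, 0.005, 0.995))

# Least squares of z ~ x1*b1 + x2*b2 with (b1, b2) in the simplex triangle
# {b1 >= 0, b2 >= 0, b1 + b2 <= 1}: unconstrained solve, then the best of the
# three active-edge solutions if outside. Returns c(b1, b2).
ls_triangle <- function(x1, x2, z) {
  a11 <- sum(x1 * x1); a22 <- sum(x2 * x2); a12 <- sum(x1 * x2)
  g1 <- sum(x1 * z); g2 <- sum(x2 * z)
  det <- a11 * a22 - a12^2
  if (det > 1e-300) {
    b1 <- (a22 * g1 - a12 * g2) / det
    b2 <- (a11 * g2 - a12 * g1) / det
    if (b1 >= 0 && b2 >= 0 && b1 + b2 <= 1) return(c(b1, b2))
  }
  sse_of <- function(b) sum((z - b[1] * x1 - b[2] * x2)^2)
  cand <- list(
    c(clamp(if (a11 > 0) g1 / a11 else 0, 0, 1), 0),            # b2 = 0
    c(0, clamp(if (a22 > 0) g2 / a22 else 0, 0, 1)),            # b1 = 0
    { d <- x1 - x2; den <- sum(d * d)                           # b1 + b2 = 1
      t <- if (den > 0) clamp(sum(d * (z - x2)) / den, 0, 1) else 0
      c(t, 1 - t) }
  )
  cand[[which.min(vapply(cand, sse_of, 0))]]
}

# Fit one voxel: y = attenuation vector, mu0 = orientation init.
fit_noddi_voxel <- function(y, scheme, mu0, cfg) {
  fg <- cfg$grid_fractions
  odis <- cfg$grid_odi
  b <- scheme$b
  a_iso <- exp(-b * cfg$d_iso)
  nf <- length(fg)
  # weights for all (f_iso, f'_stat) pairs at one f*_ic: 4 x nf^2
  fi <- rep(fg, times = nf); fs <- rep(fg, each = nf)
  starts <- NULL            # per (odi, f*_ic) cell: best (f_iso, f'_stat) SSE
  for (odi in odis) {
    kap <- odi_to_kappa(odi)
    ca <- as.vector(scheme$directions %*% mu0); ca[b == 0] <- 0
    a_ic <- watson_stick_attenuation(b * cfg$d_parallel, ca, kap); a_ic[b == 0] <- 1
    tau1 <- watson_tau1(kap)
    for (fstar in fg) {
      d_perp <- cfg$d_parallel * (1 - fstar)
      gdg <- d_perp + (cfg$d_parallel - d_perp) *
        ((1 - tau1) / 2 + (3 * tau1 - 1) / 2 * ca^2)
      a_ec <- exp(-b * gdg)
      W <- rbind((1 - fi) * (1 - fs) * fstar,
                 (1 - fi) * (1 - fs) * (1 - fstar),
                 fi,
                 (1 - fi) * fs)
      pred <- cbind(a_ic, a_ec, a_iso, 1) %*% W
      sse <- colSums((pred - y)^2)
      j <- which.min(sse)
      starts <- rbind(starts, data.frame(sse = sse[j], f_iso = fi[j],
                                         f_stat_prime = fs[j],
                                         f_ic_star = fstar, odi = odi))
    }
  }
  starts <- starts[order(starts$sse), ]
  best <- as.list(starts[1, ])
  # second start from a distant f*_ic basin: the refinement can fall into a
  # local minimum (typically f*_ic -> 1), which a distant restart escapes
  far <- starts[abs(starts$f_ic_star - best$f_ic_star) >= 0.3, ]
  alt <- if (nrow(far) > 0) as.list(far[1, ]) else NULL
  # nonlinear refinement by variable projection: given (f*_ic, ODI, mu) the
  # model is A = 1 + f_iso (a_iso - 1) + m (a_mix - 1) with m the combined
  # Watson-compartment mass (1 - f_iso)(1 - f'_stat); (f_iso, m) solve a
  # 2-variable constrained least squares exactly, so Nelder-Mead only
  # searches 4 parameters.
  dwi_rows <- which(b > 0)
  x_iso <- a_iso[dwi_rows] - 1
  z <- y[dwi_rows] - 1
  linear_part <- function(fstar, odi, mu) {
    kap <- odi_to_kappa(clamp(odi, 1e-5, 1))
    ca <- as.vector(scheme$directions[dwi_rows, , drop = FALSE] %*% mu)
    a_ic <- watson_stick_attenuation(b[dwi_rows] * cfg$d_parallel, ca, kap)
    tau1 <- watson_tau1(kap)
    d_perp <- cfg$d_parallel * (1 - fstar)
    gdg <- d_perp + (cfg$d_parallel - d_perp) *
      ((1 - tau1) / 2 + (3 * tau1 - 1) / 2 * ca^2)
    a_mix <- fstar * a_ic + (1 - fstar) * exp(-b[dwi_rows] * gdg)
    beta <- ls_triangle(x_iso, a_mix - 1, z)
    sse <- sum((z - beta[1] * x_iso - beta[2] * (a_mix - 1))^2) +
      sum((y[b == 0] - 1)^2)
    list(f_iso = beta[1], m = beta[2], sse = sse)
  }
  th0 <- acos(clamp(mu0[3], -1, 1)); ph0 <- atan2(mu0[2], mu0[1])
  obj <- function(x) {
    mu <- c(sin(x[3]) * cos(x[4]), sin(x[3]) * sin(x[4]), cos(x[3]))
    linear_part(.sq(x[1]), .sq(x[2]), mu)$sse
  }
  conv <- TRUE; iters <- 0L
  xhat <- c(.sq_inv(best$f_ic_star), .sq_inv(best$odi), th0, ph0)
  if (cfg$refine) {
    opt <- NULL
    for (st in c(list(best), if (!is.null(alt)) list(alt))) {
      x0 <- c(.sq_inv(st$f_ic_star), .sq_inv(st$odi), th0, ph0)
      o <- stats::optim(x0, obj, method = "Nelder-Mead",
                        control = list(maxit = cfg$maxit, reltol = 1e-12))
      if (is.null(opt) || o$value < opt$value) opt <- o
      if (opt$value < 1e-9) break   # at the global optimum already (SSE >= 0)
    }
    xhat <- opt$par
    conv <- opt$convergence == 0L
    iters <- opt$counts[1]
  }
  mu <- c(sin(xhat[3]) * cos(xhat[4]), sin(xhat[3]) * sin(xhat[4]), cos(xhat[3]))
  if (mu[3] < 0) mu <- -mu   # canonical hemisphere (antipodally symmetric)
  lp <- linear_part(.sq(xhat[1]), .sq(xhat[2]), mu)
  if (cfg$refine && lp$sse > best$sse) {
    # keep the grid optimum when the refinement failed to improve on it
    conv <- FALSE
    mu <- mu0; if (mu[3] < 0) mu <- -mu
    return(list(f_iso = best$f_iso, f_stat_prime = best$f_stat_prime,
                f_ic_star = best$f_ic_star, odi = best$odi, mu = mu,
                sse = best$sse, converged = conv, iterations = iters))
  }
  f_iso <- clamp(lp$f_iso, 0, 1)
  m <- clamp(lp$m, 0, 1 - f_iso)
  f_stat_prime <- if (f_iso < 1) clamp(1 - m / (1 - f_iso), 0, 1) else 0
  list(f_iso = f_iso, f_stat_prime = f_stat_prime, f_ic_star = .sq(xhat[1]),
       odi = .sq(xhat[2]), mu = mu, sse = lp$sse, converged = conv,
       iterations = iters)
}

#' Fit the four-compartment ex vivo NODDI model voxelwise
#'
#' Per voxel: S0 is the mean over b = 0 volumes and the data are converted to
#' attenuations by division; the mean orientation is initialised from the DTI
#' principal eigenvector (lowest shell); a coarse grid over
#' (f_iso, f'_stat, f*_ic, ODI) selects the best sum-of-squares start; a
#' Nelder-Mead refinement then optimises all five free parameters (the three
#' nested fractions through a logistic transform, the orientation through
#' spherical angles). Fit diagnostics (residual norm, iterations, convergence
#' flag) are recorded per voxel.
#'
#' @param dwi a multi-shell [dwi_dataset()] (>= 2 nonzero shells; a single
#'   shell triggers a warning: free-water and stationary fractions are then
#'   poorly identified).
#' @param config a [noddi_fit_config()].
#' @return object of class `noddi_map`: arrays `f_iso`, `f_stat_prime`,
#'   `f_ic_star`, `f_ic`, `f_ec`, `f_stat`, `odi`, `mu` (4-D, 3 components),
#'   `s0`, plus diagnostics `rss`, `iterations`, `converged`.
#' @export
fit_noddi <- function(dwi, config = noddi_fit_config()) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  bshells <- unique(round(dwi$scheme$b[dwi$scheme$b > 0]))
  if (length(bshells) < 2L) {
    warning("fit_noddi: single-shell input; f_iso vs f_stat are poorly identified")
  }
  shp <- dwi$grid$shape
  s0 <- b0_mean(dwi)
  idx <- which(dwi$mask & s0 > 0)
  if (length(idx) == 0L) stopf("fit_noddi: no usable voxels (mask empty or S0 <= 0)")
  nvol <- dim(dwi$signal)[4]
  sig <- matrix(dwi$signal, ncol = nvol)

  # orientation init from DTI on the lowest nonzero shell
  b_lo <- min(bshells)
  keep <- dwi$scheme$b == 0 | abs(dwi$scheme$b - b_lo) < 0.5
  dti <- fit_dti(dwi_dataset(dwi$grid, dwi$signal[, , , keep, drop = FALSE],
                             subset_scheme(dwi$scheme, keep), dwi$mask))

  mk <- function() array(NA_real_, shp)
  out <- list(f_iso = mk(), f_stat_prime = mk(), f_ic_star = mk(),
              f_ic = mk(), f_ec = mk(), f_stat = mk(), odi = mk(),
              mu = array(NA_real_, c(shp, 3)), s0 = s0, rss = mk(),
              iterations = mk(), converged = array(FALSE, shp))
  nxyz <- prod(shp)
  for (v in idx) {
    y <- sig[v, ] / s0[v]
    mu0 <- dti$e1[c(v, v + nxyz, v + 2 * nxyz)]
    if (any(!is.finite(mu0)) || sum(mu0^2) < 0.5) mu0 <- c(0, 0, 1)
    fit <- fit_noddi_voxel(y, dwi$scheme, mu0, config)
    fr <- derive_fractions(fit$f_iso, fit$f_stat_prime, fit$f_ic_star)
    out$f_iso[v] <- fit$f_iso; out$f_stat_prime[v] <- fit$f_stat_prime
    out$f_ic_star[v] <- fit$f_ic_star
    out$f_ic[v] <- fr$f_ic; out$f_ec[v] <- fr$f_ec; out$f_stat[v] <- fr$f_stat
    out$odi[v] <- fit$odi
    out$mu[c(v, v + nxyz, v + 2 * nxyz)] <- fit$mu
    out$rss[v] <- fit$sse
    out$iterations[v] <- fit$iterations
    out$converged[v] <- fit$converged
  }
  out$grid <- dwi$grid
  out$mask <- array(FALSE, shp); out$mask[idx] <- TRUE
  class(out) <- "noddi_map"
  out
}

#' @export
print.noddi_map <- function(x, ...) {
  cat(sprintf("<noddi_map> %d fitted voxels; median f_ic = %.3f\n",
              sum(x$mask), stats::median(x$f_ic[x$mask])))
  invisible(x)
}

#' Per-region statistics of a scalar map
#'
#' Mean, SD and voxel count of a scalar map per labelled region, in the
#' canonical legend order (part, structure).
#'
#' @param map 3-D numeric array.
#' @param labels a [label_map()] on the same grid.
#' @param mask optional extra 3-D logical mask intersected with each region.
#' @return data.frame with columns label, part, structure, mean, sd, n_voxels.
#' @export
region_statistics <- function(map, labels, mask = NULL) {
  stopifnot(inherits(labels, "label_map"))
  if (!all(dim(map) == labels$grid$shape)) stopf("region_statistics: grid mismatch")
  if (is.null(mask)) mask <- array(TRUE, dim = labels$grid$shape)
  leg <- labels$legend
  res <- lapply(seq_len(nrow(leg)), function(i) {
    sel <- labels$labels == leg$label[i] & mask
    vals <- map[sel]
    vals <- vals[is.finite(vals)]
    data.frame(label = leg$label[i], part = leg$part[i], structure = leg$structure[i],
               mean = if (length(vals)) mean(vals) else NA_real_,
               sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
               n_voxels = length(vals), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
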