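# Synthetic digital phantom: a stylized layered hippocampus-like geometry
# with ground-truth microstructure and fibre orientations, plus forward
# simulation of the multi-echo spin-echo and three-shell PGSE acquisitions
# with Rician noise.
#
# The geometry is a layered slab, not an anatomically faithful hippocampus:
# the long (anterior-posterior) axis is z, the laminar axis is y, and the
# 22-region legend is reused so every downstream code path (region tables,
# connectivity matrices) is exercised unchanged. It contains, by construction:
# a high-f_ic coherent white-matter sheet (alveus/fimbria-like), a low-f_ic /
# high-f_stat pyramidal-like layer, a dispersed moderate-f_ic molecular-like
# layer, a two-population 90-degree crossing block, a free-water rim, and a
# monotone anterior->posterior f*_ic gradient in the grey-matter labels
# (reversed in the white-matter labels).

#' Add Rician noise to nonnegative values
#'
#' Returns sqrt((v + n1)^2 + n2^2) with n1, n2 ~ Normal(0, sigma): the
#' magnitude of a complex signal with independent Gaussian noise on both
#' channels. sigma = 0 returns the input unchanged.
#'
#' @param values nonnegative numeric array or vector.
#' @param sigma noise standard deviation, >= 0.
#' @param rng_seed optional integer seed; if NULL the current RNG stream is used.
#' @return array of the same shape.
#' @export
add_rician_noise <- function(values, sigma, rng_seed = NULL) {
  if (!is_scalar_num(sigma) || sigma < 0) stopf("add_rician_noise: sigma must be >= 0")
  if (sigma == 0) return(values)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n <- length(values)
  out <- sqrt((values + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(values))) dim(out) <- dim(values)
  out
}

#' Phantom specification
#'
#' Defaults state the emulated acquisition scenario: a 24 x 24 x 48 voxel
#' grid at 0.3 mm isotropic, shell SNRs 9.9 / 7.6 / 4.2 (measured b0 SNRs of
#' the three shells, in increasing-b order), ex vivo diffusivities, and an
#' anterior-posterior neurite-density gradient of 0.01 per mm.
#'
#' @param grid a [volume_grid()].
#' @param gradient_slope change of f*_ic per mm along the anterior-posterior
#'   (z) axis; positive means anterior grey matter is denser.
#' @param snr_per_shell b0 SNR per shell, increasing-b order; empty for noiseless.
#' @param rng_seed integer seed for the noise streams.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = volume_grid(c(24, 24, 48)),
                         gradient_slope = 0.01,
                         snr_per_shell = c(9.9, 7.6, 4.2),
                         rng_seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"))
  structure(list(grid = grid, gradient_slope = gradient_slope,
                 snr_per_shell = snr_per_shell, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# Per-structure baseline microstructure. The laminar contrasts follow the
# layer pattern the pipeline is meant to resolve: layer-I-like white matter
# f*_ic 0.6, pyramidal-like layer 0.12, molecular-like layer 0.32.
phantom_tissue_table <- function() {
  data.frame(
    structure = c("Entorhinal cortex", "Subicular complex", "CA1", "CA2/CA3",
                  "Dentate gyrus", "Alveus", "Fimbria", "Lacunosum-molecular layer"),
    class = c("grey", "grey", "grey", "grey", "grey", "white", "white", "grey"),
    f_iso = c(0.05, 0.05, 0.05, 0.05, 0.05, 0.02, 0.02, 0.05),
    f_stat_prime = c(0.25, 0.25, 0.45, 0.45, 0.30, 0.05, 0.05, 0.15),
    f_ic_star = c(0.35, 0.30, 0.12, 0.12, 0.25, 0.60, 0.60, 0.32),
    odi = c(0.40, 0.40, 0.30, 0.30, 0.45, 0.06, 0.06, 0.55),
    t2 = c(46.4, 46.4, 46.4, 46.4, 46.4, 36.3, 36.3, 46.4),
    stringsAsFactors = FALSE
  )
}

#' Build the layered hippocampus-like ground truth
#'
#' @param spec a [phantom_spec()].
#' @return object of class `ground_truth`: `labels` (a [label_map()]), `mask`
#'   (simulated voxels incl. the free-water rim), per-voxel parameter arrays
#'   (`f_iso`, `f_stat_prime`, `f_ic_star`, `odi`, `kappa`), orientations
#'   `mu1`, `mu2` (4-D, 3 components; `mu2` NA outside the crossing block),
#'   `w1` (weight of population 1; 1 where single population), `t2`, `s0`,
#'   `grid`, `spec`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  shp <- spec$grid$shape
  if (any(shp < c(12, 12, 18))) stopf("build_phantom: grid too small for the layered geometry")
  nx <- shp[1]; ny <- shp[2]; nz <- shp[3]
  labels <- array(0L, shp)
  legend <- hippocampus_legend()
  tis <- phantom_tissue_table()

  # sample box with a one-voxel free-water rim inside it
  bx <- 2:(nx - 1); by <- 2:(ny - 1); bz <- 2:(nz - 1)
  tx <- 3:(nx - 2); ty <- 3:(ny - 2); tz <- 3:(nz - 2)
  mask <- array(FALSE, shp); mask[bx, by, bz] <- TRUE
  tissue <- array(FALSE, shp); tissue[tx, ty, tz] <- TRUE
  rim <- mask & !tissue

  # anterior (low z) -> posterior (high z) thirds: head, body, tail
  n_tz <- length(tz)
  part_of_z <- rep(c("head", "body", "tail"), c(ceiling(n_tz / 3), ceiling(n_tz / 3),
                                                n_tz - 2 * ceiling(n_tz / 3)))
  # laminar slabs along y: fractions of the tissue thickness per structure
  slab_order <- c("Alveus", "Fimbria", "CA1", "Lacunosum-molecular layer",
                  "CA2/CA3", "Dentate gyrus", "Subicular complex", "Entorhinal cortex")
  slab_width <- c(2, 1, 3, 3, 3, 2, 3, 3)   # in units of ny = 24 tissue rows (20)
  assign_slabs <- function(part) {
    keep <- rep(TRUE, length(slab_order))
    if (part == "head") keep[slab_order == "Fimbria"] <- FALSE
    if (part == "tail") keep[slab_order == "Entorhinal cortex"] <- FALSE
    nm <- slab_order[keep]; w <- slab_width[keep]
    w <- round(w / sum(w) * length(ty)); w[length(w)] <- length(ty) - sum(w[-length(w)])
    rep(nm, w)
  }
  leg_lookup <- function(part, structure) {
    legend$label[legend$part == part & legend$structure == structure]
  }
  for (kz in seq_along(tz)) {
    part <- part_of_z[kz]
    slabs <- assign_slabs(part)
    for (ky in seq_along(ty)) {
      labels[tx, ty[ky], tz[kz]] <- leg_lookup(part, slabs[ky])
    }
  }

  mkp <- function() array(NA_real_, shp)
  f_iso <- mkp(); f_sp <- mkp(); f_is <- mkp(); odi <- mkp()
  t2 <- mkp(); s0 <- mkp()
  mu1 <- array(NA_real_, c(shp, 3)); mu2 <- array(NA_real_, c(shp, 3))
  w1 <- mkp()
  nxyz <- prod(shp)
  set_mu <- function(arr, vox, v) {
    arr[vox] <- v[1]; arr[vox + nxyz] <- v[2]; arr[vox + 2 * nxyz] <- v[3]; arr
  }
  # orientation per structure: white sheets coherent (alveus along x, fimbria
  # along z, the long axis); grey layers along the laminar normal y
  mu_of <- function(structure) {
    switch(structure,
           "Alveus" = c(1, 0, 0),
           "Fimbria" = c(0, 0, 1),
           c(0, 1, 0))
  }
  for (s in seq_len(nrow(tis))) {
    lab_ids <- legend$label[legend$structure == tis$structure[s]]
    vox <- which(labels %in% lab_ids)
    if (length(vox) == 0L) next
    f_iso[vox] <- tis$f_iso[s]; f_sp[vox] <- tis$f_stat_prime[s]
    f_is[vox] <- tis$f_ic_star[s]; odi[vox] <- tis$odi[s]
    t2[vox] <- tis$t2[s]; s0[vox] <- 1000
    mu1 <- set_mu(mu1, vox, mu_of(tis$structure[s]))
    w1[vox] <- 1
  }
  # free-water rim
  vox <- which(rim)
  f_iso[vox] <- 1; f_sp[vox] <- 0; f_is[vox] <- 0; odi[vox] <- 1
  t2[vox] <- 90; s0[vox] <- 1000
  mu1 <- set_mu(mu1, vox, c(0, 0, 1)); w1[vox] <- 1

  # anterior-posterior f*_ic gradient: positive slope raises anterior grey
  # matter and (reversed) posterior white matter
  if (spec$gradient_slope != 0) {
    zmm <- (seq_len(nz) - 1) * spec$grid$voxel_size[3]
    zc <- mean(zmm[tz])
    offs <- spec$gradient_slope * (zc - zmm)   # anterior (low z) positive
    white_ids <- legend$label[legend$structure %in% c("Alveus", "Fimbria")]
    for (kz in tz) {
      sl <- labels[, , kz]
      g <- which(sl > 0 & !(sl %in% white_ids))
      w <- which(sl %in% white_ids)
      off3 <- (kz - 1) * nx * ny
      f_is[g + off3] <- clamp(f_is[g + off3] + offs[kz], 0.02, 0.95)
      f_is[w + off3] <- clamp(f_is[w + off3] - offs[kz], 0.02, 0.95)
    }
  }

  # two-population 90-degree crossing block in the molecular-like layer of
  # the body: populations along x and z, equal weights, low dispersion
  lm_body <- legend$label[legend$part == "body" &
                            legend$structure == "Lacunosum-molecular layer"]
  body_z <- tz[part_of_z == "body"]
  cross_z <- body_z[seq(ceiling(length(body_z) / 3), ceiling(2 * length(body_z) / 3))]
  cross <- array(FALSE, shp)
  cross[tx, ty, cross_z] <- TRUE
  vox <- which(cross & labels == lm_body)
  if (length(vox)) {
    mu1 <- set_mu(mu1, vox, c(1, 0, 0))
    mu2 <- set_mu(mu2, vox, c(0, 0, 1))
    w1[vox] <- 0.5
    odi[vox] <- 0.08
    f_is[vox] <- 0.5
    f_sp[vox] <- 0.05
  }

  structure(list(
    labels = label_map(spec$grid, labels, legend),
    mask = mask, tissue = tissue, rim = rim, crossing = cross & labels == lm_body,
    f_iso = f_iso, f_stat_prime = f_sp, f_ic_star = f_is, odi = odi,
    kappa = array(odi_to_kappa(pmax(odi, 1e-6)), shp),
    mu1 = mu1, mu2 = mu2, w1 = w1, t2 = t2, s0 = s0,
    grid = spec$grid, spec = spec
  ), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d simulated voxels (%d labelled, %d crossing)\n",
              sum(x$mask), sum(x$labels$labels > 0), sum(x$crossing)))
  invisible(x)
}

#' Simulate the diffusion-weighted acquisition of a phantom
#'
#' Noiseless signal per voxel: S0 * (optionally exp(-TE/T2)) * A, with A the
#' weight-averaged four-compartment attenuation over the voxel's fibre
#' populations (each population shares the voxel's fractions but has its own
#' Watson orientation). Rician noise is added per shell with
#' sigma = mean masked b0 signal of the shell / shell SNR, so the SNR
#' definition matches the per-shell b0 measurement.
#'
#' @param truth a [build_phantom()] result.
#' @param scheme a [gradient_scheme()]; default [hydi_scheme()].
#' @param snr_per_shell b0 SNR per shell group (increasing TE order); empty or
#'   NULL for a noiseless simulation.
#' @param use_t2 logical: apply the exp(-TE/T2) echo-time weighting (default TRUE).
#' @param rng_seed integer seed for the noise.
#' @param d_parallel,d_iso fixed diffusivities (mm^2/s).
#' @return a [dwi_dataset()].
#' @export
simulate_dwi <- function(truth, scheme = hydi_scheme(),
                         snr_per_shell = truth$spec$snr_per_shell,
                         use_t2 = TRUE, rng_seed = truth$spec$rng_seed,
                         d_parallel = D_PAR_EXVIVO, d_iso = D_ISO_EXVIVO) {
  stopifnot(inherits(truth, "ground_truth"), inherits(scheme, "gradient_scheme"))
  shp <- truth$grid$shape
  nvol <- length(scheme)
  idx <- which(truth$mask)
  sig <- array(0, c(shp, nvol))
  nxyz <- prod(shp)
  getmu <- function(arr, v) c(arr[v], arr[v + nxyz], arr[v + 2 * nxyz])

  # group voxels sharing identical parameters: the layered phantom has few
  # hundred unique (fractions, kappa, orientations) tuples
  key <- paste(truth$f_iso[idx], truth$f_stat_prime[idx], truth$f_ic_star[idx],
               truth$odi[idx], truth$w1[idx],
               truth$mu1[idx], truth$mu1[idx + nxyz], truth$mu1[idx + 2 * nxyz],
               truth$mu2[idx], truth$mu2[idx + nxyz], truth$mu2[idx + 2 * nxyz])
  groups <- split(idx, key)
  sigm <- matrix(0, nxyz, nvol)
  for (g in groups) {
    v <- g[1]
    if (truth$f_iso[v] >= 1) {
      A <- exp(-scheme$b * d_iso)
    } else {
      p1 <- noddi_params(truth$f_iso[v], truth$f_stat_prime[v], truth$f_ic_star[v],
                         kappa = truth$kappa[v], mu = getmu(truth$mu1, v),
                         d_parallel = d_parallel, d_iso = d_iso)
      A <- truth$w1[v] * noddi_forward(p1, scheme)
      if (truth$w1[v] < 1) {
        p2 <- noddi_params(truth$f_iso[v], truth$f_stat_prime[v], truth$f_ic_star[v],
                           kappa = truth$kappa[v], mu = getmu(truth$mu2, v),
                           d_parallel = d_parallel, d_iso = d_iso)
        A <- A + (1 - truth$w1[v]) * noddi_forward(p2, scheme)
      }
    }
    te_fac <- if (use_t2) exp(-scheme$TE / truth$t2[v]) else rep(1, nvol)
    sigm[g, ] <- rep(truth$s0[g], nvol) * rep(te_fac * A, each = length(g))
  }

  # per-shell Rician noise scaled to the shell's own TE-attenuated b0 mean
  grp <- shell_groups(scheme)
  if (!is.null(snr_per_shell) && length(snr_per_shell) > 0) {
    shells <- levels(grp)
    if (length(snr_per_shell) != length(shells)) {
      stopf("simulate_dwi: %d SNR values for %d shells", length(snr_per_shell), length(shells))
    }
    for (k in seq_along(shells)) {
      cols <- which(grp == shells[k])
      b0cols <- cols[scheme$b[cols] == 0]
      sigma <- mean(sigm[idx, b0cols]) / snr_per_shell[k]
      seed_k <- derive_seed(rng_seed, k)
      sigm[idx, cols] <- add_rician_noise(sigm[idx, cols], sigma, rng_seed = seed_k)
    }
  }
  sig <- array(sigm, c(shp, nvol))
  dwi_dataset(truth$grid, sig, scheme, truth$mask)
}

#' Simulate a multi-echo spin-echo series
#'
#' Echo e signal = S0 * exp(-TE_e / T2(v)) plus Rician noise at
#' sigma = mean masked S0 / snr (noiseless when snr = 0).
#'
#' @param t2 3-D array of T2 (ms), positive inside `mask`.
#' @param s0 3-D array (or scalar) of TE = 0 signal.
#' @param grid a [volume_grid()].
#' @param echo_times strictly increasing echo times (ms); default 12 echoes
#'   linearly spaced 6.4 to 76.8 ms.
#' @param snr b0-style SNR; 0 is the noiseless sentinel.
#' @param rng_seed integer seed.
#' @param mask optional 3-D logical simulation mask.
#' @return an [msme_series()].
#' @export
simulate_msme <- function(t2, s0, grid, echo_times = seq(6.4, 76.8, length.out = 12),
                          snr = 0, rng_seed = 1L, mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  if (is.null(mask)) mask <- array(is.finite(t2) & t2 > 0, dim = grid$shape)
  if (any(mask & !(t2 > 0), na.rm = TRUE)) stopf("simulate_msme: nonpositive T2 in mask")
  if (length(s0) == 1L) s0 <- array(s0, grid$shape)
  ne <- length(echo_times)
  sig <- array(0, c(grid$shape, ne))
  idx <- which(mask)
  for (e in seq_len(ne)) {
    plane <- array(0, grid$shape)
    plane[idx] <- s0[idx] * exp(-echo_times[e] / t2[idx])
    sig[, , , e] <- plane
  }
  if (snr > 0) {
    sigma <- mean(s0[idx]) / snr
    sig <- add_rician_noise(sig, sigma, rng_seed = rng_seed)
  }
  msme_series(grid, sig, echo_times)
}
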