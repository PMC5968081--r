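# Shared synthetic builders for the test suite. Everything is generated in
# code; no fixture files.

# Single-shell scheme: one b0 plus n directions at the given b.
single_shell_scheme <- function(b = 4500, n_dir = 60, TE = 24.2, Delta = 14.4,
                                delta = 4.3) {
  dirs <- uniform_directions(n_dir)
  gradient_scheme(c(0, rep(b, n_dir)), rbind(c(0, 0, 0), dirs),
                  Delta, delta, TE)
}

# Constant-signal 4-D dataset from one attenuation profile.
uniform_dwi <- function(grid, scheme, attenuation, s0 = 1000, mask = NULL) {
  nvol <- length(scheme)
  stopifnot(length(attenuation) == nvol)
  sig <- array(rep(s0 * attenuation, each = prod(grid$shape)),
               c(grid$shape, nvol))
  if (is.null(mask)) mask <- array(TRUE, grid$shape)
  dwi_dataset(grid, sig, scheme, mask)
}

# Pure-stick attenuation profile (optionally two populations).
stick_attenuation <- function(scheme, u1, d = 1.7e-3, u2 = NULL, w1 = 1) {
  a <- exp(-scheme$b * d * as.vector(scheme$directions %*% u1)^2)
  if (!is.null(u2)) {
    a <- w1 * a + (1 - w1) * exp(-scheme$b * d * as.vector(scheme$directions %*% u2)^2)
  }
  a[scheme$b == 0] <- 1
  a
}

# Straight z-fiber ODF field over a slab, from a noiseless Watson-stick
# simulation at the given dispersion.
straight_odf_field <- function(shape = c(10, 10, 40), odi = 0.04, d = 1.7e-3) {
  grid <- volume_grid(shape)
  sch <- single_shell_scheme()
  a <- as.vector(watson_stick_attenuation(sch$b * d,
                                          sch$directions %*% c(0, 0, 1),
                                          odi_to_kappa(odi)))
  a[sch$b == 0] <- 1
  dwi <- uniform_dwi(grid, sch, a)
  list(field = odf_direction_field(fit_aqbi(dwi)), grid = grid, dwi = dwi)
}

# Plus-shaped 90-degree crossing dataset: x-arm sticks along x, y-arm along y,
# centre block mixing both populations (weights 0.55/0.45 so the DTI principal
# direction is deterministic).
crossing_dataset <- function(nx = 21, nz = 7, d = 1.7e-3) {
  grid <- volume_grid(c(nx, nx, nz))
  shp <- grid$shape
  mid <- (nx + 1) %/% 2
  band <- (mid - 2):(mid + 2)
  xarm <- array(FALSE, shp); xarm[, band, 2:(nz - 1)] <- TRUE
  yarm <- array(FALSE, shp); yarm[band, , 2:(nz - 1)] <- TRUE
  crossing <- xarm & yarm
  mask <- xarm | yarm
  sch <- single_shell_scheme()
  sx <- stick_attenuation(sch, c(1, 0, 0), d)
  sy <- stick_attenuation(sch, c(0, 1, 0), d)
  sc <- 0.55 * sx + 0.45 * sy
  m <- matrix(0, prod(shp), length(sch))
  m[which(xarm & !crossing), ] <- rep(1000 * sx, each = sum(xarm & !crossing))
  m[which(yarm & !crossing), ] <- rep(1000 * sy, each = sum(yarm & !crossing))
  m[which(crossing), ] <- rep(1000 * sc, each = sum(crossing))
  dwi <- dwi_dataset(grid, array(m, c(shp, length(sch))), sch, mask)
  list(dwi = dwi, grid = grid, mask = mask, crossing = crossing,
       xarm = xarm, yarm = yarm)
}

# Fraction of streamlines whose extent along `axis` spans [lo, hi].
span_fraction <- function(tg, axis, lo, hi) {
  if (length(tg$streamlines) == 0L) return(0)
  mean(vapply(tg$streamlines, function(p) {
    r <- range(p[, axis]); r[1] < lo && r[2] > hi
  }, TRUE))
}

# Largest angle (degrees) between consecutive segments over a tractogram.
max_step_angle <- function(tg) {
  if (length(tg$streamlines) == 0L) return(0)
  max(vapply(tg$streamlines, function(p) {
    if (nrow(p) < 3) return(0)
    v <- diff(p)
    v <- v / sqrt(rowSums(v^2))
    max(acos(pmin(1, rowSums(v[-1, , drop = FALSE] * v[-nrow(v), , drop = FALSE]))))
  }, 0)) * 180 / pi
}

# Toy straight-line tractogram from explicit endpoints (world mm).
toy_tractogram <- function(point_pairs, n_pts = 20, step = NULL) {
  sl <- lapply(point_pairs, function(pp) {
    t(vapply(seq(0, 1, length.out = n_pts),
             function(t) pp[[1]] + t * (pp[[2]] - pp[[1]]), numeric(3)))
  })
  structure(list(streamlines = sl,
                 step_size = step %||% NA_real_,
                 provenance = list(model = "toy", algorithm = "toy", rng_seed = 0L)),
            class = "tractogram")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
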