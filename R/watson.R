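# Watson orientation-dispersion machinery for the stick compartment.
#
# The Watson-averaged stick attenuation
#   A_ic(g) = < exp(-b d_par (g'u)^2) >_{u ~ Watson(mu, kappa)}
# is the ratio of two spherical integrals of exp(u'Qu) with
#   Q_num = kappa mu mu' - b d_par g g',   Q_den = kappa mu mu'.
# Q_num has rank 2 (eigenvalues l1 >= l2 in span{mu, g}, 0 out of plane), and
#   I(l1, l2, l3) = 2*pi * int_{-1}^{1} exp(l3 t^2 + (1-t^2)(l1+l2)/2)
#                                 * I0((1-t^2)(l1-l2)/2) dt
# (t the cosine of the polar angle about the l3 axis, I0 the modified Bessel
# function from the azimuthal integral). Both integrals are evaluated with
# 64-point Gauss-Legendre quadrature after shifting the eigenvalues so the
# largest is 0, which keeps every exponent nonpositive at any kappa.

WATSON_QUAD_N <- 64L

# log of I(l1, l2, l3) / (2*pi), eigenvalues as n x 3 matrix (vectorised).
log_sphere_integral <- function(lam) {
  gl <- gauss_legendre(WATSON_QUAD_N)
  M <- pmax(lam[, 1], pmax(lam[, 2], lam[, 3]))
  l1 <- lam[, 1] - M; l2 <- lam[, 2] - M; l3 <- lam[, 3] - M
  t2 <- gl$nodes^2                              # length q
  omt <- 1 - t2
  # n x q exponent and scaled-Bessel factor
  s12 <- (l1 + l2) / 2
  a <- abs(outer((l1 - l2) / 2, omt))           # always >= 0
  expo <- outer(l3, t2) + outer(s12, omt) + a
  integrand <- exp(expo) * i0e(a)
  M + log(as.vector(integrand %*% gl$weights))
}

# Exponentially scaled modified Bessel I0(x) * exp(-x), x >= 0, by the
# Abramowitz & Stegun 9.8.1/9.8.2 polynomial approximations (|error| < 2e-7).
# Base R's besselI is ~50x slower here and underflows to zero above ~2e5.
i0e <- function(x) {
  out <- numeric(length(x))
  small <- x < 3.75
  if (any(small)) {
    t2 <- (x[small] / 3.75)^2
    p <- 1 + t2 * (3.5156229 + t2 * (3.0899424 + t2 * (1.2067492 +
         t2 * (0.2659732 + t2 * (0.0360768 + t2 * 0.0045813)))))
    out[small] <- p * exp(-x[small])
  }
  if (any(!small)) {
    xt <- x[!small]
    it <- 3.75 / xt
    p <- 0.39894228 + it * (0.01328592 + it * (0.00225319 + it * (-0.00157565 +
         it * (0.00916281 + it * (-0.02057706 + it * (0.02635537 +
         it * (-0.01647633 + it * 0.00392377)))))))
    out[!small] <- p / sqrt(xt)
  }
  out
}

#' Watson-averaged stick attenuation
#'
#' @param bd nonnegative vector `b * d_par` (dimensionless) per measurement.
#' @param cos_alpha vector of cosines of the angle between each gradient
#'   direction and the Watson mean orientation.
#' @param kappa Watson concentration, >= 0 (kappa = 0 is the uniform sphere).
#' @return attenuation vector in (0, 1].
#' @export
watson_stick_attenuation <- function(bd, cos_alpha, kappa) {
  stopifnot(kappa >= 0)
  kappa <- min(kappa, 1e8)   # numerically indistinguishable from a pure stick
  n <- max(length(bd), length(cos_alpha))
  bd <- rep_len(bd, n); cos_alpha <- rep_len(cos_alpha, n)
  c2 <- clamp(cos_alpha^2, 0, 1)
  s2 <- 1 - c2
  # eigenvalues of the 2x2 restriction of kappa*mu*mu' - bd*g*g'
  tr <- kappa - bd
  dt <- -kappa * bd * s2
  disc <- sqrt(pmax(tr^2 - 4 * dt, 0))
  lam <- cbind((tr + disc) / 2, (tr - disc) / 2, 0)
  log_num <- log_sphere_integral(lam)
  log_den <- log_sphere_integral(matrix(c(kappa, 0, 0), nrow = 1))
  out <- exp(log_num - log_den)
  clamp(out, 0, 1)
}

#' Watson orientation second moment tau1
#'
#' tau1(kappa) = < (mu'u)^2 > over the Watson distribution; 1/3 at kappa = 0,
#' -> 1 as kappa -> Inf. Used by the tortuous extra-cellular tensor.
#'
#' @param kappa Watson concentration, >= 0 (vectorised).
#' @return tau1 in [1/3, 1).
#' @export
watson_tau1 <- function(kappa) {
  gl <- gauss_legendre(WATSON_QUAD_N)
  t2 <- gl$nodes^2
  vapply(pmin(kappa, 1e8), function(k) {
    w <- exp(k * (t2 - 1)) * gl$weights   # shifted by -k: bounded for any k
    s <- sum(w)
    if (s <= 0) return(1)                 # kappa so large all mass is at t = 1
    sum(w * t2) / s
  }, 0)
}

#' Orientation dispersion index conversions
#'
#' ODI = (2/pi) * atan(1/kappa); kappa = 1/tan(pi*ODI/2). ODI 0 is a perfectly
#' coherent stick population, ODI 1 the uniform sphere.
#'
#' @param kappa,odi values to convert.
#' @return the converted value(s).
#' @export
kappa_to_odi <- function(kappa) (2 / pi) * atan2(1, kappa)

#' @rdname kappa_to_odi
#' @export
odi_to_kappa <- function(odi) {
  stopifnot(all(odi > 0 & odi <= 1, na.rm = TRUE))
  1 / tan(pi * odi / 2)
}
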