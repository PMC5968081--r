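# Real symmetric (even-degree) spherical-harmonics basis.
#
# Convention: modified real basis with coefficients ordered by ascending
# degree l (even only), then order m from -l to l:
#   m = 0 :            N_l0 P_l^0(cos theta)
#   m > 0 :  sqrt(2) * N_lm P_l^m(cos theta) * cos(m phi)
#   m < 0 :  sqrt(2) * N_l|m| P_l^|m|(cos theta) * sin(|m| phi)
# with N_lm = sqrt((2l+1)/(4 pi) * (l-m)!/(l+m)!). Antipodally symmetric by
# construction (even l), orthonormal on the sphere.

#' Index table of the even-degree real SH basis
#'
#' @param order maximum (even) degree.
#' @return data.frame with columns `l` and `m`, (order+1)(order+2)/2 rows.
#' @export
sh_index_table <- function(order) {
  if (order %% 2 != 0) stopf("sh_index_table: order must be even")
  ls <- seq(0, order, by = 2)
  data.frame(l = rep(ls, times = 2 * ls + 1),
             m = unlist(lapply(ls, function(l) -l:l)))
}

#' Number of coefficients of the even-degree basis at a given order
#' @param order maximum even degree.
#' @return integer, (order+1)(order+2)/2 (45 at order 8).
#' @export
sh_n_coef <- function(order) as.integer((order + 1) * (order + 2) / 2)

# Associated Legendre P_l^m(x) for all even l <= order, m = 0..l, via the
# standard recurrences; x vector. Returns list plm[[key "l,m"]] of vectors.
assoc_legendre_table <- function(x, order) {
  out <- list()
  somx2 <- sqrt(pmax(0, 1 - x^2))
  for (m in 0:order) {
    # P_m^m
    pmm <- rep(1, length(x))
    if (m > 0) pmm <- (-1)^m * prod(seq(1, 2 * m - 1, by = 2)) * somx2^m
    out[[paste(m, m, sep = ",")]] <- pmm
    if (m < order) {
      pmmp1 <- x * (2 * m + 1) * pmm
      out[[paste(m + 1, m, sep = ",")]] <- pmmp1
      if (m < order - 1) {
        pll_m2 <- pmm; pll_m1 <- pmmp1
        for (l in (m + 2):order) {
          pll <- (x * (2 * l - 1) * pll_m1 - (l + m - 1) * pll_m2) / (l - m)
          out[[paste(l, m, sep = ",")]] <- pll
          pll_m2 <- pll_m1; pll_m1 <- pll
        }
      }
    }
  }
  out
}

#' Evaluate the real symmetric SH basis on unit directions
#'
#' @param dirs n x 3 matrix of unit vectors.
#' @param order maximum even degree (default 8).
#' @return n x sh_n_coef(order) design matrix.
#' @export
sh_basis <- function(dirs, order = 8L) {
  dirs <- matrix(dirs, ncol = 3)
  ct <- clamp(dirs[, 3], -1, 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  tab <- sh_index_table(order)
  plm <- assoc_legendre_table(ct, order)
  B <- matrix(0, nrow(dirs), nrow(tab))
  for (j in seq_len(nrow(tab))) {
    l <- tab$l[j]; m <- tab$m[j]; am <- abs(m)
    nlm <- sqrt((2 * l + 1) / (4 * pi) * exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
    p <- plm[[paste(l, am, sep = ",")]]
    B[, j] <- if (m == 0) nlm * p
      else if (m > 0) sqrt(2) * nlm * p * cos(m * phi)
      else sqrt(2) * nlm * p * sin(am * phi)
  }
  B
}

# Legendre polynomial at zero, even l: P_l(0) = (-1)^(l/2) (l-1)!! / l!!
legendre_p0 <- function(l) {
  vapply(l, function(li) {
    if (li == 0) return(1)
    k <- li / 2
    (-1)^k * prod(seq(1, li - 1, by = 2)) / prod(seq(2, li, by = 2))
  }, 0)
}
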