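# Diffusion gradient schemes: per-volume (b, direction, Delta, delta, TE).
#
# A plain bval/bvec pair cannot carry the pulse separation Delta, pulse width
# delta, and echo time TE that a multi-shell ex vivo protocol varies per
# shell, so the canonical on-disk form is a TSV with columns
# b, gx, gy, gz, Delta_ms, delta_ms, TE_ms.

#' Gyromagnetic ratio of the water proton (rad s^-1 T^-1)
#' @export
GAMMA_WATER <- 2.6752218744e8

#' Diffusion gradient scheme
#'
#' @param b numeric vector of b-values (s/mm^2), one per volume.
#' @param directions n x 3 matrix of diffusion directions; unit-norm for b > 0
#'   entries (checked to 1e-6), ignored (may be zero) for b = 0 entries.
#' @param Delta pulse separation (ms), scalar or per volume.
#' @param delta pulse width (ms), scalar or per volume.
#' @param TE echo time (ms), scalar or per volume.
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1), default [GAMMA_WATER].
#' @return object of class `gradient_scheme`: data.frame-backed table plus `gamma`.
#' @export
gradient_scheme <- function(b, directions, Delta, delta, TE, gamma = GAMMA_WATER) {
  n <- length(b)
  directions <- matrix(as.double(directions), ncol = 3)
  if (nrow(directions) != n) stopf("gradient_scheme: %d b-values but %d directions", n, nrow(directions))
  Delta <- rep_len(as.double(Delta), n)
  delta <- rep_len(as.double(delta), n)
  TE <- rep_len(as.double(TE), n)
  if (any(b < 0)) stopf("gradient_scheme: negative b-value")
  if (any(delta >= Delta)) stopf("gradient_scheme: delta must be < Delta")
  if (any(TE <= 0)) stopf("gradient_scheme: TE must be positive")
  dwi <- b > 0
  if (any(dwi)) {
    nrm <- sqrt(rowSums(directions[dwi, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stopf("gradient_scheme: %d non-unit direction(s) on b > 0 entries",
            sum(abs(nrm - 1) > 1e-6))
    }
  }
  if (!any(b == 0)) stopf("gradient_scheme: at least one b = 0 entry is required")
  sch <- structure(list(
    b = as.double(b), directions = directions,
    Delta = Delta, delta = delta, TE = TE, gamma = gamma
  ), class = "gradient_scheme")
  grp <- shell_groups(sch)
  for (g in levels(grp)) {
    if (!any(sch$b[grp == g] == 0)) {
      warning(sprintf("gradient_scheme: shell group %s has no b = 0 entry", g))
    }
  }
  sch
}

#' @export
length.gradient_scheme <- function(x) length(x$b)

#' @export
print.gradient_scheme <- function(x, ...) {
  tab <- table(round(x$b))
  cat(sprintf("<gradient_scheme> %d volumes; b: %s\n", length(x$b),
              paste(sprintf("%s x%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

subset_scheme <- function(scheme, keep) {
  gradient_scheme(scheme$b[keep], scheme$directions[keep, , drop = FALSE],
                  scheme$Delta[keep], scheme$delta[keep], scheme$TE[keep],
                  gamma = scheme$gamma)
}

#' Shell grouping of a gradient scheme
#'
#' Volumes are grouped by echo time: in the protocol this package emulates
#' each shell is acquired at its own minimum TE and its b = 0 volumes share
#' that TE, so TE identifies the shell grouping including the b0s.
#'
#' @param scheme a [gradient_scheme()].
#' @return factor of length `length(scheme)` naming the shell of each volume.
#' @export
shell_groups <- function(scheme) {
  te <- round(scheme$TE, 6)
  bmax <- vapply(split(scheme$b, te), max, 0)
  lab <- sprintf("b%s", round(bmax[as.character(te)]))
  factor(lab, levels = unique(lab[order(scheme$TE)]))
}

#' Write / read the canonical scheme TSV
#'
#' Columns: b, gx, gy, gz, Delta_ms, delta_ms, TE_ms (full float64 precision).
#'
#' @param scheme a [gradient_scheme()].
#' @param path file path.
#' @return `write_scheme`: invisibly `path`; `read_scheme`: a [gradient_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  df <- data.frame(
    b = scheme$b,
    gx = scheme$directions[, 1], gy = scheme$directions[, 2], gz = scheme$directions[, 3],
    Delta_ms = scheme$Delta, delta_ms = scheme$delta, TE_ms = scheme$TE
  )
  cols <- vapply(df, function(col) format(col, digits = 17, trim = TRUE, scientific = FALSE),
                 character(nrow(df)))
  lines <- c(paste(names(df), collapse = "\t"),
             apply(matrix(cols, nrow = nrow(df)), 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scheme
#' @param gamma gyromagnetic ratio for the reconstructed scheme.
#' @export
read_scheme <- function(path, gamma = GAMMA_WATER) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  need <- c("b", "gx", "gy", "gz", "Delta_ms", "delta_ms", "TE_ms")
  if (!all(need %in% names(df))) {
    stopf("read_scheme: expected columns %s", paste(need, collapse = ", "))
  }
  gradient_scheme(df$b, cbind(df$gx, df$gy, df$gz), df$Delta_ms, df$delta_ms,
                  df$TE_ms, gamma = gamma)
}

#' Import an FSL bval/bvec pair
#'
#' bval/bvec carry no pulse timing, so `Delta`, `delta` and `TE` must be
#' supplied (scalars or per-volume vectors).
#'
#' @param bval_path,bvec_path FSL-format files (one row of b-values; 3 rows of
#'   direction components).
#' @inheritParams gradient_scheme
#' @return a [gradient_scheme()].
#' @export
read_fsl_scheme <- function(bval_path, bvec_path, Delta, delta, TE, gamma = GAMMA_WATER) {
  b <- scan(bval_path, quiet = TRUE)
  vec <- matrix(scan(bvec_path, quiet = TRUE), nrow = 3, byrow = TRUE)
  if (ncol(vec) != length(b)) stopf("read_fsl_scheme: bval/bvec length mismatch")
  gradient_scheme(b, t(vec), Delta, delta, TE, gamma = gamma)
}

#' Near-uniform antipodally spread unit directions
#'
#' Deterministic spherical Fibonacci points on the upper hemisphere; adequate
#' angular uniformity for 60-direction shells.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors with positive z.
#' @export
uniform_directions <- function(n) {
  i <- seq_len(n) - 0.5
  # hemisphere: z in (0, 1), golden-angle azimuth
  z <- i / n
  phi <- 2 * pi * i * (1 - 1 / ((1 + sqrt(5)) / 2))
  s <- sqrt(pmax(0, 1 - z^2))
  cbind(s * cos(phi), s * sin(phi), z)
}

#' Canonical three-shell ex vivo HYDI scheme
#'
#' Emulates the multiple-shell protocol this package targets: shells at
#' b = 4500 / 7500 / 10,000 s/mm^2, 60 directions each, per-shell echo times
#' 24.2 / 39.8 / 54.8 ms, pulse separations 14.4 / 30.0 / 45.0 ms at fixed
#' pulse width 4.3 ms, plus `n_b0` b = 0 volumes per shell at the shell's TE.
#'
#' @param b_shells b-values (s/mm^2).
#' @param n_dir directions per shell.
#' @param TE,Delta,delta per-shell timing (ms).
#' @param n_b0 number of b = 0 volumes per shell.
#' @return a [gradient_scheme()].
#' @export
hydi_scheme <- function(b_shells = c(4500, 7500, 10000), n_dir = 60,
                        TE = c(24.2, 39.8, 54.8), Delta = c(14.4, 30, 45),
                        delta = 4.3, n_b0 = 6) {
  dirs <- uniform_directions(n_dir)
  b <- c(); g <- NULL; DD <- c(); dd <- c(); te <- c()
  for (k in seq_along(b_shells)) {
    b <- c(b, rep(0, n_b0), rep(b_shells[k], n_dir))
    g <- rbind(g, matrix(0, n_b0, 3), dirs)
    DD <- c(DD, rep(Delta[k], n_b0 + n_dir))
    dd <- c(dd, rep(delta, n_b0 + n_dir))
    te <- c(te, rep(TE[k], n_b0 + n_dir))
  }
  gradient_scheme(b, g, DD, dd, te)
}
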