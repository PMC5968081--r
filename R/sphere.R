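# Antipodally symmetric sphere tessellations by icosahedral subdivision.

#' Icosahedral sphere tessellation
#'
#' Recursively subdivides the icosahedron and projects to the unit sphere.
#' The icosahedron is antipodally symmetric and subdivision preserves that,
#' so every vertex's antipode is present. Vertex count is 10 * 4^subdiv + 2
#' (642 at subdiv 3, 2562 -- i.e. 1281 antipodal pairs -- at subdiv 4, the
#' default used for peak extraction).
#'
#' @param subdiv number of subdivision rounds (>= 0).
#' @return object of class `sphere_tessellation`: `vertices` (n x 3 unit
#'   vectors), `neighbors` (list of integer vectors from the triangle edges),
#'   `antipode` (index of each vertex's antipode), `hemi` (logical, one vertex
#'   per antipodal pair).
#' @export
sphere_tessellation <- function(subdiv = 4L) {
  cache_key <- paste0("ico", subdiv)
  cached <- .hdmri_env[[cache_key]]
  if (!is.null(cached)) return(cached)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  vkey <- function(p) paste(round(p[, 1], 9), round(p[, 2], 9), round(p[, 3], 9))
  for (s in seq_len(subdiv)) {
    lookup <- stats::setNames(seq_len(nrow(v)), vkey(v))
    newv <- v
    midpoint <- function(a, b) {
      p <- normalize_rows(matrix((newv[a, ] + newv[b, ]) / 2, 1, 3))
      k <- vkey(p)
      hit <- lookup[k]
      if (!is.na(hit)) return(unname(hit))
      newv <<- rbind(newv, p)
      lookup[k] <<- nrow(newv)
      nrow(newv)
    }
    newf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf[(i - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(c, ca, bc), c(ab, bc, ca))
    }
    v <- newv; f <- newf
  }
  n <- nrow(v)
  # neighbor lists from triangle edges
  edges <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  edges <- rbind(edges, edges[, 2:1])
  nb <- split(edges[, 2], edges[, 1])
  neighbors <- lapply(seq_len(n), function(i) sort(unique(nb[[as.character(i)]])))
  # antipode index
  lookup <- stats::setNames(seq_len(n), vkey(v))
  anti <- unname(lookup[vkey(-v)])
  if (any(is.na(anti))) stopf("sphere_tessellation: antipodal symmetry broken")
  hemi <- seq_len(n) < anti
  out <- structure(list(vertices = v, neighbors = neighbors, antipode = anti,
                        hemi = hemi, faces = f),
                   class = "sphere_tessellation")
  .hdmri_env[[cache_key]] <- out
  out
}

#' @export
print.sphere_tessellation <- function(x, ...) {
  cat(sprintf("<sphere_tessellation> %d vertices (%d antipodal pairs)\n",
              nrow(x$vertices), sum(x$hemi)))
  invisible(x)
}
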