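#' D3Q19 lattice stencil
#'
#' The 19-velocity three-dimensional lattice: one rest velocity, six axis
#' vectors and twelve face diagonals, with weights 1/3, 1/18 and 1/36 and
#' lattice speed of sound squared `cs2 = 1/3`. The `opp` map sends each
#' direction index to the index of its negation and is an involution.
#'
#' @return A list with components `c` (19 x 3 integer matrix of lattice
#'   velocities), `w` (19 weights), `cs2`, and `opp` (integer vector).
#' @export
d3q19 <- function() {
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0),
              c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  dg <- rbind(c(1, 1, 0), c(-1, -1, 0), c(1, -1, 0), c(-1, 1, 0),
              c(1, 0, 1), c(-1, 0, -1), c(1, 0, -1), c(-1, 0, 1),
              c(0, 1, 1), c(0, -1, -1), c(0, 1, -1), c(0, -1, 1))
  cvec <- rbind(c(0, 0, 0), ax, dg)
  w <- c(1 / 3, rep(1 / 18, 6), rep(1 / 36, 12))
  opp <- integer(19)
  for (i in 1:19) {
    for (j in 1:19) {
      if (all(cvec[j, ] == -cvec[i, ])) opp[i] <- j
    }
  }
  list(c = cvec, w = w, cs2 = 1 / 3, opp = opp)
}

# cached stencil; immutable, safe to share across calls
.mdt_cache <- new.env(parent = emptyenv())

stencil <- function() {
  if (is.null(.mdt_cache$stencil)) .mdt_cache$stencil <- d3q19()
  .mdt_cache$stencil
}
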