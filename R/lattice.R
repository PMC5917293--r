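#' Second-order Maxwell-Boltzmann equilibrium populations
#'
#' `f0_i = w_i * rho * (1 + (c_i.u)/cs2 + (c_i.u)^2/(2 cs2^2) - u^2/(2 cs2))`
#' for the D3Q19 stencil. Vectorized over sites: `rho` is a length-n vector
#' and `u` an n x 3 matrix; the result is n x 19.
#'
#' @param rho lattice density (vector, > 0).
#' @param u lattice velocity, n x 3 matrix (or length-3 vector for n = 1).
#' @return n x 19 matrix of equilibrium populations.
#' @export
equilibrium <- function(rho, u) {
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  if (any(rho <= 0)) stop("rho must be > 0")
  st <- stencil()
  cu <- u %*% t(st$c)                  # n x 19, c_i . u
  usq <- rowSums(u * u)
  fac <- 1 + 3 * cu + 4.5 * cu * cu - 1.5 * usq
  (rho %o% st$w) * fac
}

#' Guo second-order forcing populations
#'
#' Discrete forcing term reproducing a hydrodynamic body force to second
#' order: `F_i = w_i (1 - 1/(2 tau)) [ (c_i - u)/cs2 + (c_i.u) c_i/cs2^2 ] . F`.
#' Its moments are `sum F_i = 0` and `sum F_i c_i = (1 - 1/(2 tau)) F`; the
#' half-force deficit is restored by the velocity shift in
#' [macroscopic_moments()].
#'
#' @param Fv lattice body force, n x 3 matrix (or length-3 vector).
#' @param u lattice velocity, n x 3 matrix (or length-3 vector).
#' @param tau relaxation time.
#' @return n x 19 matrix of forcing populations (per unit time step).
#' @export
forcing_term <- function(Fv, u, tau) {
  if (is.null(dim(Fv))) Fv <- matrix(Fv, ncol = 3)
  if (is.null(dim(u))) u <- matrix(u, ncol = 3)
  st <- stencil()
  cF <- Fv %*% t(st$c)                 # n x 19
  cu <- u %*% t(st$c)
  uF <- rowSums(u * Fv)
  pref <- 1 - 1 / (2 * tau)
  n <- nrow(Fv)
  pref * (rep(1, n) %o% st$w) * (3 * cF - 3 * uF + 9 * cu * cF)
}

#' LBGK collision with optional body forcing
#'
#' Single-relaxation-time collision: relax toward the local equilibrium and
#' add the forcing populations, `f* = f - (f - f0)/tau + forcing` (time step
#' 1 in lattice units).
#'
#' @param f n x 19 populations.
#' @param f0 n x 19 equilibrium populations.
#' @param tau relaxation time, must exceed 0.5.
#' @param forcing n x 19 forcing populations, or NULL for unforced flow.
#' @return n x 19 post-collision populations.
#' @export
collide_lbgk <- function(f, f0, tau, forcing = NULL) {
  if (tau <= 0.5) stop("tau must be > 0.5 (inviscid limit)")
  out <- f - (f - f0) / tau
  if (!is.null(forcing)) out <- out + forcing
  out
}

#' Macroscopic moments of a population field
#'
#' Density `rho = sum_i f_i` and force-corrected velocity
#' `u = (sum_i f_i c_i + F/2) / rho`. The half-force shift makes the
#' velocity second-order consistent with the Guo forcing scheme.
#'
#' @param f n x 19 populations.
#' @param Fv n x 3 lattice body force (or NULL for none).
#' @return List with `rho` (length n) and `u` (n x 3).
#' @export
macroscopic_moments <- function(f, Fv = NULL) {
  st <- stencil()
  rho <- rowSums(f)
  mom <- f %*% st$c
  if (!is.null(Fv)) {
    if (is.null(dim(Fv))) Fv <- matrix(Fv, ncol = 3, nrow = nrow(f), byrow = TRUE)
    mom <- mom + Fv / 2
  }
  list(rho = rho, u = mom / rho)
}

#' Lattice equation of state
#'
#' Ideal-gas-like closure `p = rho * cs2` with `cs2 = 1/3`.
#'
#' @param rho lattice density.
#' @return Lattice pressure.
#' @export
equation_of_state <- function(rho) {
  rho / 3
}

# ---------------------------------------------------------------------------
# Streaming plan: precomputed pull/wall index structures for a voxel domain.

#' Build the streaming plan for a domain
#'
#' Precomputes, for each moving direction, the (source, destination) site
#' pairs for fluid-fluid propagation and the wall-cut links handled by the
#' wall scheme. Periodic axes wrap; non-periodic out-of-domain neighbors are
#' treated as solid. Sites of type inlet/outlet carry populations and stream
#' like fluid sites; their populations are overwritten by the boundary
#' conditions after streaming.
#'
#' @param domain a [voxel_domain()].
#' @param wall_scheme `"bfl"` (Bouzidi-Firdaouss-Lallemand linear
#'   interpolation) or `"bounce_back"` (half-way bounce-back, equivalent to
#'   BFL with q = 1/2 everywhere).
#' @return An opaque plan object consumed by [stream()].
#' @export
stream_plan <- function(domain, wall_scheme = c("bfl", "bounce_back")) {
  wall_scheme <- match.arg(wall_scheme)
  st <- stencil()
  dims <- domain$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  n <- nx * ny * nz
  type <- domain$site_type
  active <- type != SITE_SOLID
  idx <- seq_len(n)
  ix <- ((idx - 1L) %% nx) + 1L
  iy <- (((idx - 1L) %/% nx) %% ny) + 1L
  iz <- ((idx - 1L) %/% (nx * ny)) + 1L

  if (wall_scheme == "bfl" && is.null(domain$wall_links))
    domain <- compute_wall_links(domain)

  pulls <- vector("list", 19)
  walls <- vector("list", 19)
  for (i in 2:19) {
    ci <- st$c[i, ]
    jx <- ix + ci[1]; jy <- iy + ci[2]; jz <- iz + ci[3]
    inside <- rep(TRUE, n)
    if (domain$periodic[1]) jx <- ((jx - 1L) %% nx) + 1L else inside <- inside & jx >= 1L & jx <= nx
    if (domain$periodic[2]) jy <- ((jy - 1L) %% ny) + 1L else inside <- inside & jy >= 1L & jy <= ny
    if (domain$periodic[3]) jz <- ((jz - 1L) %% nz) + 1L else inside <- inside & jz >= 1L & jz <= nz
    nbr <- ifelse(inside, jx + (jy - 1L) * nx + (jz - 1L) * nx * ny, NA_integer_)
    src_ok <- active & inside & active[pmax(nbr, 1L)] & !is.na(nbr)
    src <- idx[which(src_ok)]
    pulls[[i]] <- list(src = src, dst = nbr[src])
    # wall links: active site whose neighbor along c_i is solid/outside,
    # handled only for genuine fluid sites (inlet/outlet are overwritten)
    wsite <- idx[which(type == SITE_FLUID & (!inside | (inside & !active[pmax(nbr, 1L)])))]
    if (length(wsite)) {
      if (wall_scheme == "bfl") {
        key <- paste0(wsite, "_", i)
        q <- domain$wall_links$q[match(key, domain$wall_links$key)]
        q[is.na(q)] <- 0.5
      } else {
        q <- rep(0.5, length(wsite))
      }
      # upstream fluid site x - c_i (needed by the q < 1/2 branch)
      ux <- ix[wsite] - ci[1]; uy <- iy[wsite] - ci[2]; uz <- iz[wsite] - ci[3]
      uin <- rep(TRUE, length(wsite))
      if (domain$periodic[1]) ux <- ((ux - 1L) %% nx) + 1L else uin <- uin & ux >= 1L & ux <= nx
      if (domain$periodic[2]) uy <- ((uy - 1L) %% ny) + 1L else uin <- uin & uy >= 1L & uy <= ny
      if (domain$periodic[3]) uz <- ((uz - 1L) %% nz) + 1L else uin <- uin & uz >= 1L & uz <= nz
      up <- ifelse(uin, ux + (uy - 1L) * nx + (uz - 1L) * nx * ny, NA_integer_)
      up_ok <- uin & !is.na(up) & type[pmax(up, 1L)] == SITE_FLUID
      # without an upstream fluid node the q<1/2 interpolation degenerates
      # to half-way bounce-back
      q[!up_ok & q < 0.5] <- 0.5
      walls[[i]] <- list(site = wsite, q = q, up = up, up_ok = up_ok)
    }
  }
  list(domain = domain, scheme = wall_scheme, pulls = pulls, walls = walls,
       active = which(active), fluid = which(type == SITE_FLUID),
       inlet = which(type == SITE_INLET), outlet = which(type == SITE_OUTLET),
       n = n)
}

#' Stream post-collision populations one link
#'
#' Propagates each population along its lattice velocity on fluid-fluid
#' links and applies the wall scheme on wall-cut links. Bouzidi linear
#' interpolation: for cut fraction `q < 1/2`,
#' `f_opp(x) <- 2 q f*_i(x) + (1 - 2 q) f*_i(x - c_i)`; for `q >= 1/2`,
#' `f_opp(x) <- f*_i(x)/(2 q) + (2 q - 1)/(2 q) f*_opp(x)`. At `q = 1/2`
#' both branches reduce to half-way bounce-back.
#'
#' @param f_post n x 19 post-collision populations.
#' @param plan a [stream_plan()].
#' @return n x 19 streamed populations.
#' @export
stream <- function(f_post, plan) {
  st <- stencil()
  f_new <- f_post                       # rest population and stale sites
  for (i in 2:19) {
    p <- plan$pulls[[i]]
    if (length(p$src)) f_new[p$dst, i] <- f_post[p$src, i]
    w <- plan$walls[[i]]
    if (!is.null(w) && length(w$site)) {
      io <- st$opp[i]
      lo <- w$q < 0.5
      if (any(lo)) {
        s <- w$site[lo]; q <- w$q[lo]; up <- w$up[lo]
        f_new[s, io] <- 2 * q * f_post[s, i] + (1 - 2 * q) * f_post[up, i]
      }
      if (any(!lo)) {
        s <- w$site[!lo]; q <- w$q[!lo]
        f_new[s, io] <- f_post[s, i] / (2 * q) +
          (2 * q - 1) / (2 * q) * f_post[s, io]
      }
    }
  }
  f_new
}

#' Initialize a population field
#'
#' Populations set to the equilibrium of the given density and velocity on
#' every active (non-solid) site; solid sites hold zeros and are never read.
#'
#' @param plan a [stream_plan()].
#' @param rho initial lattice density (scalar or per-site vector over all
#'   sites).
#' @param u initial lattice velocity (length-3 vector or n x 3 matrix).
#' @return n x 19 population matrix.
#' @export
init_field <- function(plan, rho = 1, u = c(0, 0, 0)) {
  n <- plan$n
  if (length(rho) == 1L) rho <- rep(rho, n)
  if (is.null(dim(u))) u <- matrix(u, n, 3, byrow = TRUE)
  f <- matrix(0, n, 19)
  a <- plan$active
  f[a, ] <- equilibrium(rho[a], u[a, , drop = FALSE])
  f
}

#' One full lattice update
#'
#' Moments, LBGK collision with optional Guo forcing, then streaming with
#' the plan's wall scheme. Boundary conditions (inlets/outlets) are applied
#' by the caller afterwards.
#'
#' @param f n x 19 population matrix.
#' @param plan a [stream_plan()].
#' @param tau relaxation time.
#' @param force optional n x 3 lattice body-force field.
#' @return The updated population matrix.
#' @export
lb_update <- function(f, plan, tau, force = NULL) {
  a <- plan$active
  fa <- f[a, , drop = FALSE]
  Fa <- if (is.null(force)) NULL else force[a, , drop = FALSE]
  m <- macroscopic_moments(fa, Fa)
  f0 <- equilibrium(m$rho, m$u)
  frc <- if (is.null(Fa)) NULL else forcing_term(Fa, m$u, tau)
  f[a, ] <- collide_lbgk(fa, f0, tau, frc)
  stream(f, plan)
}
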