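#' Physical constants used by the particle model
#'
#' Vacuum permeability `mu0 = 4 pi x 10^-7` H m^-1 and the Boltzmann
#' constant `kB = 1.380649e-23` J K^-1.
#' @export
MU0 <- 4 * pi * 1e-7
#' @rdname MU0
#' @export
KB <- 1.380649e-23

#' Batch of suspended paramagnetic point particles
#'
#' Positions and velocities are continuous physical coordinates (m, m s^-1).
#' Each particle has a magnetic core radius `a`, a non-magnetic coating
#' thickness `a_c` (enters the drag only), a volumetric susceptibility
#' `chi_v` and a material density `rho_p`. The point-particle regime
#' requires `a + a_c` well below the lattice spacing.
#'
#' @param x n x 3 matrix of positions (m).
#' @param a core radius (m), scalar or length n.
#' @param a_c coating thickness (m), default 0.
#' @param chi_v volumetric susceptibility (dimensionless).
#' @param rho_p material density (kg m^-3); magnetite by default.
#' @param u n x 3 matrix of velocities (m s^-1), default rest.
#' @return An object of class `particle_system`.
#' @export
particle_system <- function(x, a, a_c = 0, chi_v = 5.7, rho_p = 5170,
                            u = NULL) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  n <- nrow(x)
  if (any(a <= 0)) stop("core radius a must be > 0")
  if (any(a_c < 0)) stop("coating thickness a_c must be >= 0")
  if (is.null(u)) u <- matrix(0, n, 3)
  structure(list(x = x, u = u,
                 a = rep_len(a, n), a_c = rep_len(a_c, n),
                 chi_v = rep_len(chi_v, n), rho_p = rep_len(rho_p, n),
                 id = seq_len(n), alive = rep(TRUE, n)),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("particle_system:", nrow(x$x), "particles, core radius",
      paste(format(unique(x$a)), collapse = "/"), "m\n")
  invisible(x)
}

#' Permanent point-dipole magnet
#'
#' @param position magnet position (m).
#' @param moment magnetic moment vector (A m^2).
#' @return An object of class `magnet`.
#' @export
magnet <- function(position, moment) {
  stopifnot(length(position) == 3, length(moment) == 3)
  structure(list(position = as.numeric(position),
                 moment = as.numeric(moment)), class = "magnet")
}

#' Force model parameters and toggles
#'
#' Lubrication cutoffs default to the core radius; forces with negligible
#' impact on a given configuration can be toggled off to save work.
#'
#' @param gravity gravitational acceleration vector (m s^-2); the default is
#'   zero (weightless runs); use `c(0, 0, -9.81)` etc. to enable.
#' @param h_e_wall,h_e_pair lubrication cutoff distances (m); `NULL` means
#'   "equal to the particle core radius".
#' @param temperature absolute temperature for Brownian noise (K).
#' @param enable named logical toggles: `gravity`, `magnet`, `dipole_pairs`,
#'   `wall_lubrication`, `pair_lubrication`, `brownian`.
#' @param coupling `"one_way"` or `"two_way"`.
#' @param dipole_cutoff_factor inter-particle dipolar interactions beyond
#'   `factor * a` are skipped (the pair force decays as r^-4).
#' @param h_min_factor contact regularization: the gap entering the
#'   lubrication resistance is floored at `h_min_factor * a`, and positions
#'   are projected back to that gap, so a magnetically pinned particle
#'   settles at a small finite film thickness instead of an ever-shrinking
#'   gap.
#' @return An object of class `force_params`.
#' @export
force_params <- function(gravity = c(0, 0, 0),
                         h_e_wall = NULL, h_e_pair = NULL,
                         temperature = 310.15,
                         enable = list(),
                         coupling = c("one_way", "two_way"),
                         dipole_cutoff_factor = 10,
                         h_min_factor = 0.01) {
  coupling <- match.arg(coupling)
  en <- list(gravity = FALSE, magnet = TRUE, dipole_pairs = TRUE,
             wall_lubrication = TRUE, pair_lubrication = TRUE,
             brownian = FALSE)
  en[names(enable)] <- enable
  if (!is.null(h_e_wall) && h_e_wall <= 0) stop("h_e_wall must be > 0")
  if (!is.null(h_e_pair) && h_e_pair <= 0) stop("h_e_pair must be > 0")
  structure(list(mu0 = MU0, kB = KB, gravity = gravity,
                 h_e_wall = h_e_wall, h_e_pair = h_e_pair,
                 temperature = temperature, enable = en, coupling = coupling,
                 dipole_cutoff_factor = dipole_cutoff_factor,
                 h_min_factor = h_min_factor),
            class = "force_params")
}

#' Magnetic field of a point-dipole magnet
#'
#' `H = (1/4 pi) [ 3 (m0 . r0) r0 / r^5 - m0 / r^3 ]` with `r0` the vector
#' from the magnet to the evaluation point, in A m^-1.
#'
#' @param mg a [magnet()].
#' @param x evaluation points, n x 3 matrix or length-3 vector (m).
#' @return n x 3 matrix of field vectors.
#' @export
dipole_field <- function(mg, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  r0 <- x - matrix(mg$position, nrow(x), 3, byrow = TRUE)
  r2 <- rowSums(r0 * r0)
  if (any(r2 == 0)) stop("field evaluated at the magnet position")
  r <- sqrt(r2)
  mr <- r0 %*% mg$moment                 # (m0 . r0), n x 1
  (3 * as.numeric(mr) / r^5) * r0 / (4 * pi) -
    matrix(mg$moment, nrow(x), 3, byrow = TRUE) / (4 * pi * r^3)
}

#' Induced magnetic moment of a paramagnetic particle
#'
#' `m_i = (4 pi a^3 chi_v / 3) H`: moments align instantaneously with the
#' local field; only the magnetic core radius `a` enters (the coating is
#' non-magnetic).
#'
#' @param a core radius (m), scalar or length n.
#' @param chi_v volumetric susceptibility, scalar or length n.
#' @param H field vectors, n x 3 (A m^-1).
#' @return n x 3 matrix of moments (A m^2).
#' @export
induced_moment <- function(a, chi_v, H) {
  if (is.null(dim(H))) H <- matrix(H, ncol = 3)
  (4 * pi * a^3 * chi_v / 3) * H
}

#' Point-dipole pair force
#'
#' Force on dipole i due to dipole j:
#' `F = 3 mu0 / (4 pi r^5) [ (m_i.r) m_j + (m_j.r) m_i + (m_i.m_j) r
#'   - 5 (m_i.r)(m_j.r) r / r^2 ]` with `r = x_i - x_j`. Antisymmetric under
#' exchange of i and j (Newton's third law).
#'
#' @param m_i,m_j moment vectors, n x 3 or length 3 (A m^2).
#' @param x_i,x_j positions, n x 3 or length 3 (m).
#' @return n x 3 matrix of forces on i (N).
#' @export
pair_dipole_force <- function(m_i, x_i, m_j, x_j) {
  as_m <- function(v) if (is.null(dim(v))) matrix(v, ncol = 3) else v
  m_i <- as_m(m_i); m_j <- as_m(m_j); x_i <- as_m(x_i); x_j <- as_m(x_j)
  n <- max(nrow(m_i), nrow(x_i))
  expand <- function(v) if (nrow(v) == n) v else matrix(v, n, 3, byrow = TRUE)
  m_i <- expand(m_i); m_j <- expand(m_j); x_i <- expand(x_i); x_j <- expand(x_j)
  r <- x_i - x_j
  r2 <- rowSums(r * r)
  if (any(r2 == 0)) stop("coincident dipole positions")
  rn <- sqrt(r2)
  mir <- rowSums(m_i * r)
  mjr <- rowSums(m_j * r)
  mimj <- rowSums(m_i * m_j)
  (3 * MU0 / (4 * pi * rn^5)) *
    (mjr * m_i + mir * m_j + mimj * r - (5 * mir * mjr / r2) * r)
}

#' Force of the permanent magnet on particles
#'
#' Composition of [dipole_field()], [induced_moment()] and
#' [pair_dipole_force()]: the particle's induced moment interacts with the
#' magnet dipole. Scales as distance^-7 and core radius^3.
#'
#' @param mg a [magnet()].
#' @param x particle positions, n x 3 (m).
#' @param a core radii, scalar or length n (m).
#' @param chi_v susceptibilities, scalar or length n.
#' @return n x 3 matrix of forces (N).
#' @export
magnet_particle_force <- function(mg, x, a, chi_v) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  H <- dipole_field(mg, x)
  mi <- induced_moment(a, chi_v, H)
  pair_dipole_force(mi, x, matrix(mg$moment, nrow(x), 3, byrow = TRUE),
                    matrix(mg$position, nrow(x), 3, byrow = TRUE))
}

#' Wall lubrication force
#'
#' Short-range viscous closure satisfying the wall boundary condition:
#' with surface gap `h = |r_w| - a`,
#' `F_L = -6 pi mu a^2 (u_p . rhat_w) (1/h - 1/h_e) rhat_w` for `h < h_e`,
#' zero beyond the cutoff. The force damps wall-normal motion and diverges
#' as the gap closes, preventing penetration.
#'
#' @param u_p particle velocities, n x 3 (m s^-1).
#' @param a core radii (m).
#' @param r_w particle-to-wall vectors, n x 3 (m), e.g. from
#'   [nearest_wall_vector()].
#' @param h_e cutoff distance (m).
#' @param mu dynamic viscosity (Pa s).
#' @return List with `force` (n x 3, N) and `penetrating` (logical, gap
#'   `<= 0`).
#' @export
wall_lubrication <- function(u_p, a, r_w, h_e, mu = 0.004) {
  if (is.null(dim(u_p))) u_p <- matrix(u_p, ncol = 3)
  if (is.null(dim(r_w))) r_w <- matrix(r_w, ncol = 3)
  dw <- sqrt(rowSums(r_w * r_w))
  h <- dw - a
  pen <- h <= 0
  rhat <- r_w / pmax(dw, .Machine$double.xmin)
  un <- rowSums(u_p * rhat)
  gain <- ifelse(!pen & h < h_e, 1 / pmax(h, .Machine$double.xmin) - 1 / h_e, 0)
  Fmag <- -6 * pi * mu * a^2 * un * gain
  list(force = Fmag * rhat, penetrating = pen)
}

#' Pair lubrication force
#'
#' Viscous repulsion between two identical approaching particles:
#' with `h = |r_ij| - 2a` and relative velocity `u_ij = u_i - u_j`,
#' `F_L = -(6 pi / 4) mu a^2 (u_ij . rhat_ij)(1/h - 1/h_e) rhat_ij` on
#' particle i for `h < h_e`, zero beyond; the force on j is its negation.
#'
#' @param x_i,x_j positions (n x 3 or length 3, m).
#' @param u_i,u_j velocities (m s^-1).
#' @param a core radius (m).
#' @param h_e cutoff distance (m).
#' @param mu dynamic viscosity (Pa s).
#' @return List with `force` on i (n x 3, N) and `overlapping` (logical).
#' @export
pair_lubrication <- function(x_i, u_i, x_j, u_j, a, h_e, mu = 0.004) {
  as_m <- function(v) if (is.null(dim(v))) matrix(v, ncol = 3) else v
  x_i <- as_m(x_i); x_j <- as_m(x_j); u_i <- as_m(u_i); u_j <- as_m(u_j)
  r <- x_i - x_j
  d <- sqrt(rowSums(r * r))
  if (any(d == 0)) stop("coincident particle centers")
  h <- d - 2 * a
  over <- h <= 0
  rhat <- r / d
  un <- rowSums((u_i - u_j) * rhat)
  gain <- ifelse(!over & h < h_e, 1 / pmax(h, .Machine$double.xmin) - 1 / h_e, 0)
  Fmag <- -(6 * pi / 4) * mu * a^2 * un * gain
  list(force = Fmag * rhat, overlapping = over)
}

#' Maude's analytic wall-approach force
#'
#' Reference solution for the resistance on a sphere driven toward a plane
#' wall, `F_L = F_0 (9 a / (8 h) + 1)` with `F_0 = 6 pi mu a u`. Used as the
#' validation oracle for the lubrication boundary condition, never inside
#' the model itself.
#'
#' @param a sphere radius (m).
#' @param h surface-to-wall gap (m), > 0.
#' @param u approach speed (m s^-1).
#' @param mu dynamic viscosity (Pa s).
#' @return Force magnitude (N).
#' @export
maude_force <- function(a, h, u, mu = 0.004) {
  if (any(h <= 0)) stop("gap h must be > 0")
  6 * pi * mu * a * u * (9 * a / (8 * h) + 1)
}

#' Gravity and buoyancy force
#'
#' `(rho_p - rho_fluid) * (4/3) pi (a + a_c)^3 * g`; neutral buoyancy gives
#' zero.
#'
#' @param a core radii (m).
#' @param a_c coating thicknesses (m).
#' @param rho_p particle densities (kg m^-3).
#' @param rho_fluid fluid density (kg m^-3).
#' @param g gravitational acceleration vector (m s^-2).
#' @return n x 3 matrix of forces (N).
#' @export
gravity_buoyancy <- function(a, a_c, rho_p, rho_fluid, g = c(0, 0, -9.81)) {
  vol <- (4 / 3) * pi * (a + a_c)^3
  ((rho_p - rho_fluid) * vol) %o% g
}

#' Stokes mobility of a coated particle
#'
#' `beta = 1 / (6 pi mu (a + a_c))`; the coating adds drag but no magnetic
#' response.
#'
#' @param a core radii (m).
#' @param a_c coating thicknesses (m).
#' @param mu dynamic viscosity (Pa s).
#' @return Mobility (m N^-1 s^-1).
#' @export
mobility <- function(a, a_c = 0, mu = 0.004) {
  1 / (6 * pi * mu * (a + a_c))
}

#' Brownian force samples
#'
#' Fluctuation-dissipation closure for the overdamped Euler-Maruyama step:
#' each Cartesian component is an independent Gaussian with zero mean and
#' standard deviation `sqrt(2 kB T / (beta dt))`, which yields displacement
#' variance `2 D dt` per axis with `D = kB T beta` (Stokes-Einstein).
#'
#' @param n number of particles.
#' @param beta mobilities (scalar or length n).
#' @param temperature absolute temperature (K).
#' @param dt time step (s).
#' @param rng a seeded generator from the internal stream tooling, or NULL
#'   to draw from the global RNG.
#' @return n x 3 matrix of forces (N).
#' @export
brownian_force <- function(n, beta, temperature, dt, rng = NULL) {
  if (dt <= 0) stop("dt must be > 0")
  sigma <- sqrt(2 * KB * temperature / (beta * dt))
  z <- if (is.null(rng)) stats::rnorm(3 * n) else rng$rnorm(3 * n)
  matrix(z, n, 3) * sigma
}

#' Interpolate fluid velocity at particle positions
#'
#' Trilinear interpolation over the eight surrounding site centers. Solid
#' corners contribute zero velocity with their weights removed and the
#' remainder renormalized, respecting no-slip walls without extrapolating
#' into them.
#'
#' @param u_lat n_sites x 3 lattice velocity field.
#' @param domain a [voxel_domain()].
#' @param x positions, n x 3 (m).
#' @param units a [unit_system()]; if supplied the result is physical
#'   m s^-1, otherwise lattice units.
#' @param on_empty what to do when every surrounding site is solid:
#'   `"error"` (the default; the position is treated as outside the fluid)
#'   or `"zero"` (return zero velocity; appropriate for positions squeezed
#'   between the outermost fluid-site centers and the vessel surface, where
#'   a no-slip wall is within half a lattice spacing).
#' @return n x 3 matrix of fluid velocities.
#' @export
interpolate_velocity <- function(u_lat, domain, x, units = NULL,
                                 on_empty = c("error", "zero")) {
  on_empty <- match.arg(on_empty)
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  d <- domain$dims
  g <- sweep(x, 2, domain$origin) / domain$spacing - 0.5  # voxel i center -> i-1
  base <- floor(g)
  frac <- g - base
  n <- nrow(x)
  acc <- matrix(0, n, 3)
  wsum <- numeric(n)
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ii <- base[, 1] + cx; jj <- base[, 2] + cy; kk <- base[, 3] + cz
    if (domain$periodic[1]) ii <- ii %% d[1]
    if (domain$periodic[2]) jj <- jj %% d[2]
    if (domain$periodic[3]) kk <- kk %% d[3]
    wx <- if (cx == 1) frac[, 1] else 1 - frac[, 1]
    wy <- if (cy == 1) frac[, 2] else 1 - frac[, 2]
    wz <- if (cz == 1) frac[, 3] else 1 - frac[, 3]
    w <- wx * wy * wz
    okin <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    sid <- ifelse(okin, ii + jj * d[1] + kk * d[1] * d[2] + 1, NA_integer_)
    ok <- okin & !is.na(sid) & domain$site_type[pmax(sid, 1L)] != SITE_SOLID
    w[!ok] <- 0
    has <- which(w > 0)
    if (length(has)) {
      acc[has, ] <- acc[has, , drop = FALSE] +
        w[has] * u_lat[sid[has], , drop = FALSE]
      wsum[has] <- wsum[has] + w[has]
    }
  }
  if (any(wsum == 0) && on_empty == "error")
    stop("position outside the fluid region")
  out <- acc / pmax(wsum, .Machine$double.xmin)
  out[wsum == 0, ] <- 0
  if (!is.null(units)) out <- convert_units(out, "velocity", "to_physical", units)
  out
}

#' Diagnostic ratio of forced to advective particle velocity
#'
#' `|beta (F + F_R)| / |v(x_p)|`: when far below 1 (default threshold 0.01)
#' the particle is drag-dominated and its trajectory is insensitive to
#' mobility changes such as a thicker coating. Reported as `Inf` where the
#' fluid is locally at rest.
#'
#' @param v fluid velocities at the particles, n x 3 (m s^-1).
#' @param Fdet deterministic forces, n x 3 (N).
#' @param F_R Brownian forces, n x 3 (N), zeros if disabled.
#' @param beta mobilities.
#' @return Numeric vector of ratios.
#' @export
drag_dominance <- function(v, Fdet, F_R, beta) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  if (is.null(dim(Fdet))) Fdet <- matrix(Fdet, ncol = 3)
  if (is.null(dim(F_R))) F_R <- matrix(F_R, ncol = 3)
  num <- sqrt(rowSums((beta * (Fdet + F_R))^2))
  den <- sqrt(rowSums(v * v))
  ifelse(den > 0, num / den, Inf)
}

#' Deposit particle reaction forces onto the lattice
#'
#' Two-way coupling: the drag reaction on the fluid — the negation of the
#' Stokes drag the fluid exerts on the particle, i.e.
#' `+6 pi mu (a + a_c) (u_p - v(x_p))` for a particle lagging or leading
#' the flow — is spread onto the eight surrounding sites with trilinear
#' weights (weights sum to 1) after conversion to lattice force units. The
#' caller supplies the force; this function only distributes it.
#'
#' @param force_lat n_sites x 3 lattice body-force accumulator.
#' @param domain a [voxel_domain()].
#' @param x particle positions, n x 3 (m).
#' @param F_phys reaction forces, n x 3 (N).
#' @param units a [unit_system()].
#' @return Updated force accumulator.
#' @export
spread_reaction_force <- function(force_lat, domain, x, F_phys, units) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  if (is.null(dim(F_phys))) F_phys <- matrix(F_phys, ncol = 3)
  F_lat <- convert_units(F_phys, "force", "to_lattice", units)
  d <- domain$dims
  g <- sweep(x, 2, domain$origin) / domain$spacing - 0.5
  base <- floor(g)
  frac <- g - base
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ii <- base[, 1] + cx; jj <- base[, 2] + cy; kk <- base[, 3] + cz
    if (domain$periodic[1]) ii <- ii %% d[1]
    if (domain$periodic[2]) jj <- jj %% d[2]
    if (domain$periodic[3]) kk <- kk %% d[3]
    wx <- if (cx == 1) frac[, 1] else 1 - frac[, 1]
    wy <- if (cy == 1) frac[, 2] else 1 - frac[, 2]
    wz <- if (cz == 1) frac[, 3] else 1 - frac[, 3]
    w <- wx * wy * wz
    okin <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
    sid <- ii + jj * d[1] + kk * d[1] * d[2] + 1
    for (p in which(okin & w > 0)) {
      force_lat[sid[p], ] <- force_lat[sid[p], ] + w[p] * F_lat[p, ]
    }
  }
  force_lat
}

#' Advance particles one overdamped step
#'
#' Per particle, the deterministic force is accumulated from the enabled
#' models (gravity/buoyancy, magnet, inter-particle dipolar with a
#' `10 a` neighbor cutoff), a Brownian force is drawn if enabled, and the
#' non-inertial velocity balance `u_p = v(x_p) + beta (F + F_R)` is solved
#' followed by an explicit Euler position update `x_p <- x_p + u_p dt`.
#'
#' Lubrication forces are velocity-proportional resistances; inside the
#' balance they are treated implicitly (the wall-normal and pair-normal
#' velocity components are solved with the lubrication drag on the
#' new-velocity side). An explicit evaluation would amplify the normal
#' velocity by a factor `-beta*gamma` per step once the gap closes below
#' about one radius, independent of the step size, so the implicit solve is
#' required for the divergence-free gap closure the lubrication closure is
#' meant to guarantee. Pair terms are resolved with one Gauss-Seidel sweep
#' over pairs, which is exact for isolated pairs.
#'
#' @param sys a [particle_system()].
#' @param v_fluid fluid velocities at the particles, n x 3 (m s^-1); zeros
#'   for a quiescent fluid.
#' @param params a [force_params()].
#' @param props a [fluid_properties()].
#' @param dt time step (s).
#' @param domain optional [voxel_domain()] for wall lubrication.
#' @param mg optional [magnet()].
#' @param rng optional seeded generator for the Brownian stream.
#' @param f_ext optional n x 3 external driving force (N), used by the
#'   validation drivers.
#' @return The updated system, with attributes `F_mag` (n x 3 magnetic
#'   forces, N), `F_det` (all deterministic forces incl. lubrication at the
#'   solved velocity), `F_R` and `dominance` from this step.
#' @export
advance_particles <- function(sys, v_fluid, params, props, dt,
                              domain = NULL, mg = NULL, rng = NULL,
                              f_ext = NULL) {
  n <- nrow(sys$x)
  if (is.null(dim(v_fluid))) v_fluid <- matrix(v_fluid, n, 3, byrow = TRUE)
  Fdet <- matrix(0, n, 3)
  Fmag <- matrix(0, n, 3)
  en <- params$enable
  if (!is.null(f_ext)) {
    if (is.null(dim(f_ext))) f_ext <- matrix(f_ext, n, 3, byrow = TRUE)
    Fdet <- Fdet + f_ext
  }
  if (en$gravity)
    Fdet <- Fdet + gravity_buoyancy(sys$a, sys$a_c, sys$rho_p, props$rho,
                                    params$gravity)
  if (en$magnet && !is.null(mg)) {
    Fm <- magnet_particle_force(mg, sys$x, sys$a, sys$chi_v)
    Fmag <- Fmag + Fm
    Fdet <- Fdet + Fm
  }
  pair_info <- NULL
  if ((en$dipole_pairs || en$pair_lubrication) && n > 1) {
    he_pair <- if (is.null(params$h_e_pair)) sys$a else rep_len(params$h_e_pair, n)
    H <- if (!is.null(mg) && en$dipole_pairs) dipole_field(mg, sys$x) else NULL
    mi <- if (!is.null(H)) induced_moment(sys$a, sys$chi_v, H) else NULL
    lub_pairs <- list()
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      rij <- sys$x[rep(i, length(js)), , drop = FALSE] - sys$x[js, , drop = FALSE]
      dij <- sqrt(rowSums(rij * rij))
      if (en$dipole_pairs && !is.null(mi)) {
        nearm <- which(dij <= params$dipole_cutoff_factor * pmax(sys$a[i], sys$a[js]))
        if (length(nearm)) {
          jm <- js[nearm]
          Fp <- pair_dipole_force(mi[rep(i, length(jm)), , drop = FALSE],
                                  sys$x[rep(i, length(jm)), , drop = FALSE],
                                  mi[jm, , drop = FALSE],
                                  sys$x[jm, , drop = FALSE])
          Fdet[i, ] <- Fdet[i, ] + colSums(Fp)
          Fmag[i, ] <- Fmag[i, ] + colSums(Fp)
          Fdet[jm, ] <- Fdet[jm, , drop = FALSE] - Fp
          Fmag[jm, ] <- Fmag[jm, , drop = FALSE] - Fp
        }
      }
      if (en$pair_lubrication) {
        nearl <- which(dij < 2 * sys$a[i] + he_pair[i] & dij > 0)
        for (k in nearl) {
          j <- js[k]
          h <- max(dij[k] - 2 * sys$a[i], params$h_min_factor * sys$a[i])
          if (h < he_pair[i]) {
            gam <- (6 * pi / 4) * props$mu * sys$a[i]^2 * (1 / h - 1 / he_pair[i])
            lub_pairs[[length(lub_pairs) + 1L]] <-
              list(i = i, j = j, rhat = rij[k, ] / dij[k], gamma = gam)
          }
        }
      }
    }
    pair_info <- lub_pairs
  }
  beta <- mobility(sys$a, sys$a_c, props$mu)
  F_R <- if (en$brownian) {
    brownian_force(n, beta, params$temperature, dt, rng)
  } else matrix(0, n, 3)
  if (any(!is.finite(Fdet))) stop("non-finite particle force")

  # provisional velocity without lubrication resistances
  u_new <- v_fluid + beta * (Fdet + F_R)

  # wall lubrication: implicit solve of the normal component,
  # u.n = u0.n / (1 + beta*gamma_w)
  if (en$wall_lubrication && !is.null(domain)) {
    he_wall <- if (is.null(params$h_e_wall)) sys$a else rep_len(params$h_e_wall, n)
    wc <- wall_clearance(domain, sys$x)
    h <- pmax(wc$clearance - sys$a, params$h_min_factor * sys$a)
    act <- which(h < he_wall)
    if (length(act)) {
      rhat <- -wc$inward[act, , drop = FALSE]   # unit vector toward the wall
      gam <- 6 * pi * props$mu * sys$a[act]^2 * (1 / h[act] - 1 / he_wall[act])
      un0 <- rowSums(u_new[act, , drop = FALSE] * rhat)
      un1 <- un0 / (1 + beta[act] * gam)
      u_new[act, ] <- u_new[act, , drop = FALSE] + (un1 - un0) * rhat
      FL <- -(gam * un1) * rhat
      Fdet[act, ] <- Fdet[act, , drop = FALSE] + FL
    }
  }

  # pair lubrication: implicit relative-normal solve, one sweep over pairs
  if (!is.null(pair_info) && length(pair_info)) {
    for (pp in pair_info) {
      i <- pp$i; j <- pp$j; rhat <- pp$rhat
      brel <- beta[i] + beta[j]
      urel0 <- sum((u_new[i, ] - u_new[j, ]) * rhat)
      urel1 <- urel0 / (1 + brel * pp$gamma)
      FL <- -pp$gamma * urel1 * rhat     # on i; -FL on j
      u_new[i, ] <- u_new[i, ] + beta[i] * FL
      u_new[j, ] <- u_new[j, ] - beta[j] * FL
      Fdet[i, ] <- Fdet[i, ] + FL
      Fdet[j, ] <- Fdet[j, ] - FL
    }
  }

  sys$u <- u_new
  sys$x <- sys$x + u_new * dt

  # contact regularization: project any gap that closed below the floor
  # (including a full-step overshoot through the wall) back onto the
  # minimum film thickness, moving along the inward normal
  if (en$wall_lubrication && !is.null(domain)) {
    h_floor <- params$h_min_factor * sys$a
    wc <- wall_clearance(domain, sys$x)
    gap <- wc$clearance - sys$a
    close_w <- which(gap < h_floor)
    if (length(close_w)) {
      sys$x[close_w, ] <- sys$x[close_w, , drop = FALSE] +
        (h_floor[close_w] - gap[close_w]) * wc$inward[close_w, , drop = FALSE]
    }
  }
  if (en$pair_lubrication && n > 1) {
    h_floor <- params$h_min_factor * sys$a
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- sys$x[i, ] - sys$x[j, ]
        d <- sqrt(sum(r * r))
        target <- 2 * sys$a[i] + h_floor[i]
        if (d > 0 && d < target) {
          push <- (target - d) / 2 * (r / d)
          sys$x[i, ] <- sys$x[i, ] + push
          sys$x[j, ] <- sys$x[j, ] - push
        }
      }
    }
  }
  attr(sys, "F_mag") <- Fmag
  attr(sys, "F_det") <- Fdet
  attr(sys, "F_R") <- F_R
  attr(sys, "dominance") <- drag_dominance(v_fluid, Fdet, F_R, beta)
  sys
}
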