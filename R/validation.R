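# Verification and demonstration drivers. All of them run the package's own
# solver end to end and compare against closed-form references computed
# independently.

# identity unit system: lattice units == physical units, handy for
# lattice-scale benchmarks
identity_units <- function() unit_system(delta_x = 1, delta_t = 1, rho = 1)

#' Shear-wave viscosity recovery benchmark
#'
#' A periodic box is initialized with a transverse velocity wave
#' `u_y = A sin(2 pi x / nx)`; its amplitude decays as `exp(-nu k^2 t)`. The
#' measured decay rate recovers the lattice viscosity `nu = (tau - 1/2)/3`.
#'
#' @param tau relaxation time.
#' @param nx wavelength in lattice sites.
#' @param n_steps steps to evolve.
#' @param amplitude initial wave amplitude (lattice units, keep small for
#'   linearity).
#' @return List with `nu_measured`, `nu_theory` and `rel_error`.
#' @export
run_shear_wave <- function(tau = 0.9, nx = 64L, n_steps = 400L,
                           amplitude = 1e-5) {
  nu <- (tau - 0.5) / 3
  dom <- periodic_box(c(nx, 4L, 4L))
  plan <- stream_plan(dom, "bounce_back")  # no walls exist; scheme unused
  n <- plan$n
  ix <- ((seq_len(n) - 1L) %% nx) + 1L
  k <- 2 * pi / nx
  u0 <- cbind(0, amplitude * sin(k * (ix - 1)), 0)
  f <- init_field(plan, rho = 1, u = u0)
  amp <- numeric(n_steps)
  st <- stencil()
  for (s in seq_len(n_steps)) {
    f <- lb_update(f, plan, tau)
    uy <- (f %*% st$c[, 2]) / rowSums(f)
    amp[s] <- (2 / n) * sum(uy * sin(k * (ix - 1)))
  }
  # log-linear fit of the decay over the second half (transients settled)
  win <- seq(floor(n_steps / 2), n_steps)
  fit <- stats::lm(log(amp[win]) ~ win)
  nu_meas <- -stats::coef(fit)[[2]] / k^2
  list(nu_measured = nu_meas, nu_theory = nu,
       rel_error = abs(nu_meas - nu) / nu)
}

#' Cylinder Poiseuille benchmark
#'
#' Body-force-driven flow along a periodic cylinder of (generally
#' non-integer) radius `R_lat` lattice spacings, converged to steady state
#' and compared with the Hagen-Poiseuille profile
#' `u(r) = g (R^2 - r^2) / (4 nu)`.
#'
#' @param R_lat cylinder radius in lattice spacings.
#' @param tau relaxation time.
#' @param wall_scheme `"bfl"` or `"bounce_back"`.
#' @param n_steps steps to converge.
#' @param u_target target centerline lattice velocity (sets the driving
#'   force).
#' @return List with `centerline_error` (relative), `max_error` (relative,
#'   over `r < 0.9 R`), `R_fitted` (from a parabolic fit, lattice units),
#'   `u_centerline`, `u_analytic` and the radial `profile` data frame.
#' @export
run_poiseuille_benchmark <- function(R_lat = 10.3, tau = 0.9,
                                     wall_scheme = "bfl", n_steps = 2500L,
                                     u_target = 0.01) {
  nu <- (tau - 0.5) / 3
  units <- identity_units()
  props <- fluid_properties(mu = nu, rho = 1)
  dom <- voxelize_cylinder(radius = R_lat, length = 4, spacing = 1,
                           periodic = TRUE)
  g <- 4 * nu * u_target / R_lat^2
  cfg <- simulation_config(dom, units, props, wall_scheme = wall_scheme,
                           body_force_phys = c(0, 0, g),
                           n_steps = n_steps, output_every = n_steps)
  run <- run_simulation(cfg)
  act <- run$plan$active
  ctr <- site_centers(dom)[act, , drop = FALSE]
  r <- sqrt((ctr[, 1] - dom$surface$center[1])^2 +
              (ctr[, 2] - dom$surface$center[2])^2)
  uz <- run$u_lat[, 3]
  u_ana <- g * (R_lat^2 - r^2) / (4 * nu)
  on_axis <- r < 1e-9
  u_c <- mean(uz[on_axis])
  core <- r < 0.9 * R_lat
  fit <- stats::lm(uz[core] ~ I(r[core]^2))
  A <- stats::coef(fit)[[1]]; B <- stats::coef(fit)[[2]]
  list(centerline_error = abs(u_c - u_target) / u_target,
       max_error = max(abs(uz[core] - u_ana[core]) / u_target),
       R_fitted = sqrt(-A / B),
       u_centerline = u_c, u_analytic = u_target,
       profile = data.frame(r = r, uz = uz, u_analytic = u_ana))
}

#' Driven wall-approach lubrication validation
#'
#' A particle in quiescent fluid is driven into a plane wall by a constant
#' force and the total hydrodynamic resistance it experiences (Stokes drag
#' plus the lubrication closure) is logged along the trajectory,
#' non-dimensionalized by the instantaneous drag scale `6 pi mu a u_p`, and
#' compared with the analytic approach resistance `9a/(8h) + 1`
#' ([maude_force()]). Snapshot logging pairs each measured resistance with
#' the post-step gap, so the measured curve carries a discretization bias
#' that grows with the step size and vanishes as `dt -> 0`.
#'
#' @param a particle radius (m).
#' @param mu dynamic viscosity (Pa s).
#' @param h_e_factor lubrication cutoff in radii (large, so the closure is
#'   active over the whole measured range).
#' @param step_frac far-field displacement per step in units of `a`
#'   (dimensionless time-step size).
#' @param h_grid gaps (in units of `a`) at which the comparison is made.
#' @return List with `table` (h_over_a, simulated and reference resistance,
#'   relative deviation), `max_rel_dev`, and the raw trajectory log.
#' @export
run_maude_validation <- function(a = 500e-9, mu = 0.004, h_e_factor = 100,
                                 step_frac = 0.02,
                                 h_grid = seq(0.1, 1, by = 0.05)) {
  props <- fluid_properties(mu = mu, rho = 1000)
  beta <- mobility(a, 0, mu)
  u_inf <- 1e-3
  F_d <- u_inf / beta
  dt <- step_frac * a / u_inf
  dom <- channel_domain(4L, 8L, 4L, spacing = 50 * a, q_wall = 0.5)
  y_wall <- dom$surface$y_lo
  params <- force_params(h_e_wall = h_e_factor * a,
                         enable = list(magnet = FALSE, dipole_pairs = FALSE,
                                       pair_lubrication = FALSE,
                                       wall_lubrication = TRUE,
                                       brownian = FALSE),
                         h_min_factor = 1e-4)
  sys <- particle_system(x = c(100 * a, y_wall + a + 3 * a, 100 * a), a = a)
  log_h <- numeric(0); log_ratio <- numeric(0)
  for (s in 1:100000) {
    sys <- advance_particles(sys, c(0, 0, 0), params, props, dt,
                             domain = dom, f_ext = c(0, -F_d, 0))
    gap <- (sys$x[1, 2] - y_wall) - a
    u_now <- abs(sys$u[1, 2])
    log_h <- c(log_h, gap / a)
    log_ratio <- c(log_ratio, F_d / (6 * pi * mu * a * u_now))
    if (gap < 0.05 * a) break
  }
  ord <- order(log_h)
  sim <- stats::approx(log_h[ord], log_ratio[ord], xout = h_grid)$y
  ref <- maude_force(a, h_grid * a, 1, mu) / (6 * pi * mu * a)
  dev <- abs(sim - ref) / ref
  list(table = data.frame(h_over_a = h_grid, resistance_sim = sim,
                          resistance_maude = ref, rel_dev = dev),
       max_rel_dev = max(dev),
       trajectory = data.frame(h_over_a = log_h, resistance = log_ratio))
}

#' Dipolar pair-force validation
#'
#' Two identical particles in a homogeneous external field, oriented
#' parallel and orthogonal to the field. Forces are normalized by the
#' touching-separation (`r = 2a`) parallel force. The implemented point-
#' dipole model is isotropic: the parallel (attractive) and orthogonal
#' (repulsive) magnitudes are in a 2:1 ratio at every separation.
#'
#' @param a particle radius (m).
#' @param chi_v volumetric susceptibility.
#' @param H0 external field magnitude (A m^-1).
#' @param separations center-to-center distances (m), all `> 2a`.
#' @return Data frame with signed radial force components for both
#'   orientations, the normalized parallel force and the magnitude ratio.
#' @export
run_dipole_validation <- function(a = 500e-9, chi_v = 5.7, H0 = 1e5,
                                  separations = 2 * 500e-9 * seq(1, 5, 0.25)) {
  if (any(separations < 2 * a)) stop("separations must be >= 2a (no overlap)")
  m <- induced_moment(a, chi_v, c(H0, 0, 0))   # field along x
  F_par <- F_orth <- numeric(length(separations))
  for (k in seq_along(separations)) {
    r <- separations[k]
    # parallel: pair axis along the field
    Fp <- pair_dipole_force(m, c(r, 0, 0), m, c(0, 0, 0))
    F_par[k] <- Fp[1]
    # orthogonal: pair axis perpendicular to the field
    Fo <- pair_dipole_force(m, c(0, r, 0), m, c(0, 0, 0))
    F_orth[k] <- Fo[2]
  }
  F0 <- abs(F_par[which.min(abs(separations - 2 * a))])
  data.frame(separation = separations, h_over_2a = separations / (2 * a),
             F_parallel = F_par, F_orthogonal = F_orth,
             F_norm_parallel = abs(F_par) / F0,
             ratio_par_orth = abs(F_par) / abs(F_orth))
}

#' Five-particle Poiseuille demonstration
#'
#' Five particles evenly spaced from the centerline toward the wall of a
#' pressure-driven tube (driving force density 103.9 Pa per meter by
#' default) pass a permanent magnet of moment {0, 3000, 0} A m^2 held
#' outside the vessel on the mid-plane. The particle nearest the magnet is
#' deflected to the wall first, loses streamwise speed there and shows the
#' longest near-wall residence; trajectories never merge because the
#' magnet-particle force far exceeds the inter-particle dipolar force.
#'
#' @param tube_radius lumen radius (m).
#' @param R_lat voxels per radius.
#' @param pressure_gradient driving force density (Pa m^-1).
#' @param magnet_moment magnet moment vector (A m^2).
#' @param magnet_offset distance of the magnet from the tube centerline
#'   (m); must put the magnet outside the lumen.
#' @param a,chi_v particle core radius (m) and susceptibility.
#' @param t_total particle-transport time simulated (s).
#' @param warmup lattice steps to settle the flow (started from the
#'   analytic profile).
#' @param particle_dt_factor particle step in lattice steps (flow frozen
#'   after warmup).
#' @param seed master seed.
#' @return List with the `mdt_run`, per-particle `residence` times near the
#'   wall (s), `min_pair_distance` over the run (m), initial radii and key
#'   scales.
#' @export
run_five_particle_demo <- function(tube_radius = 5e-4, R_lat = 8,
                                   pressure_gradient = 103.9,
                                   magnet_moment = c(0, 3000, 0),
                                   magnet_offset = 0.1,
                                   a = 500e-9, chi_v = 5.7,
                                   t_total = 1.2, warmup = 250L,
                                   particle_dt_factor = 10L, seed = 1L) {
  props <- fluid_properties()
  dx <- tube_radius / R_lat
  tau <- 0.9
  nu_lat <- (tau - 0.5) / 3
  dt <- nu_lat * dx^2 / (props$mu / props$rho)
  units <- unit_system(dx, dt, rho = props$rho)
  L <- 64 * dx
  dom <- voxelize_cylinder(tube_radius, L, dx, periodic = TRUE)
  if (magnet_offset <= tube_radius)
    warning("magnet is inside the lumen; the printed-figure offset is not physical")
  cx <- dom$surface$center[1]; cy <- dom$surface$center[2]
  u_max <- pressure_gradient * tube_radius^2 / (4 * props$mu)
  ctr <- site_centers(dom)
  r2 <- (ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2
  u_init <- cbind(0, 0, pmax(0, u_max * (1 - r2 / tube_radius^2)) *
                    units$delta_t / units$delta_x)
  offsets <- c(0, 0.2, 0.4, 0.6, 0.8) * tube_radius
  x0 <- cbind(cx, cy + offsets, 4 * dx)
  sys <- particle_system(x0, a = a, chi_v = chi_v)
  mg <- magnet(c(cx, cy + magnet_offset, L / 2), magnet_moment)
  n_part_steps <- ceiling(t_total / (dt * particle_dt_factor))
  cfg <- simulation_config(
    dom, units, props,
    body_force_phys = c(0, 0, pressure_gradient),
    particles = sys, mg = mg,
    params = force_params(enable = list(magnet = TRUE, dipole_pairs = TRUE,
                                        wall_lubrication = TRUE,
                                        pair_lubrication = TRUE,
                                        brownian = FALSE)),
    n_steps = warmup + n_part_steps * particle_dt_factor,
    output_every = 5L * particle_dt_factor,
    seed = seed, warmup = warmup, freeze_fluid = TRUE,
    particle_dt_factor = particle_dt_factor,
    init_u_lat = u_init)
  run <- run_simulation(cfg)
  tr <- run$trajectories
  tr$r <- sqrt((tr$x - cx)^2 + (tr$y - cy)^2)
  snap_dt <- cfg$output_every * dt
  residence <- vapply(seq_len(5), function(id) {
    sum(tr$r[tr$id == id] > 0.8 * tube_radius) * snap_dt
  }, numeric(1))
  steps <- unique(tr$step)
  minpd <- min(vapply(steps, function(s) {
    p <- tr[tr$step == s, c("x", "y", "z")]
    if (nrow(p) < 2) return(Inf)
    min(stats::dist(p))
  }, numeric(1)))
  list(run = run, residence = residence, initial_offsets = offsets,
       min_pair_distance = minpd, initial_min_pair_distance = min(diff(offsets)),
       u_max = u_max, tube_radius = tube_radius, axis = c(cx, cy))
}

#' Coating-thickness sensitivity study
#'
#' Particles with identical cores but different non-magnetic coating
#' thicknesses are advected together through the demo tube far from the
#' magnet, where the drag-dominance ratio `|beta (F + F_R)| / |v|` stays
#' below a threshold. In that regime the mobility change from the coating
#' leaves trajectories essentially unchanged.
#'
#' @param coatings coating thicknesses (m).
#' @param a core radius (m).
#' @param magnet_offset magnet distance from the centerline (m).
#' @param t_total transport time (s).
#' @param seed master seed.
#' @return List with `max_traj_dev_frac` (largest trajectory deviation of a
#'   coated particle from its uncoated twin, relative to path length),
#'   `max_dominance` (largest Eq-style ratio seen) and the run.
#' @export
run_coating_study <- function(coatings = c(16.25e-9, 32.5e-9, 65e-9),
                              a = 65e-9, magnet_offset = 0.1,
                              t_total = 1.0, seed = 1L) {
  props <- fluid_properties()
  tube_radius <- 5e-4
  dx <- tube_radius / 8
  tau <- 0.9
  dt <- ((tau - 0.5) / 3) * dx^2 / (props$mu / props$rho)
  units <- unit_system(dx, dt, rho = props$rho)
  L <- 64 * dx
  dom <- voxelize_cylinder(tube_radius, L, dx, periodic = TRUE)
  cx <- dom$surface$center[1]; cy <- dom$surface$center[2]
  G <- 103.9
  u_max <- G * tube_radius^2 / (4 * props$mu)
  ctr <- site_centers(dom)
  r2 <- (ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2
  u_init <- cbind(0, 0, pmax(0, u_max * (1 - r2 / tube_radius^2)) *
                    units$delta_t / units$delta_x)
  radial <- c(0, 0.2, 0.4) * tube_radius
  acs <- c(0, coatings)
  x0 <- do.call(rbind, lapply(acs, function(ac) cbind(cx, cy + radial, 4 * dx)))
  sys <- particle_system(x0, a = a, a_c = rep(acs, each = length(radial)),
                         chi_v = 5.7)
  mg <- magnet(c(cx, cy + magnet_offset, L / 2), c(0, 3000, 0))
  pfac <- 10L
  warmup <- 250L
  n_part_steps <- ceiling(t_total / (dt * pfac))
  cfg <- simulation_config(
    dom, units, props, body_force_phys = c(0, 0, G),
    particles = sys, mg = mg,
    params = force_params(enable = list(magnet = TRUE, dipole_pairs = FALSE,
                                        wall_lubrication = TRUE,
                                        pair_lubrication = FALSE,
                                        brownian = FALSE)),
    n_steps = warmup + n_part_steps * pfac,
    output_every = 5L * pfac, seed = seed, warmup = warmup,
    freeze_fluid = TRUE, particle_dt_factor = pfac,
    init_u_lat = u_init)
  run <- run_simulation(cfg)
  tr <- run$trajectories
  nr <- length(radial)
  dev <- 0
  for (k in seq_along(radial)) {
    base <- tr[tr$id == k, c("x", "y", "z")]
    path_len <- sum(sqrt(rowSums(apply(base, 2, diff)^2)))
    for (ci in seq_along(coatings)) {
      twin <- tr[tr$id == k + ci * nr, c("x", "y", "z")]
      m <- min(nrow(base), nrow(twin))
      d <- max(sqrt(rowSums((base[seq_len(m), ] - twin[seq_len(m), ])^2)))
      dev <- max(dev, d / path_len)
    }
  }
  list(max_traj_dev_frac = dev,
       max_dominance = run$dominance_max,
       run = run)
}

#' Targeting-efficiency sweeps
#'
#' Region-of-interest occupancy versus time for the two study designs:
#' varying particle core radius at fixed inflow, and varying inflow peak
#' velocity at fixed radius. The target is a wall-adjacent capture band on
#' the magnet side of a straight vessel; particles are seeded in a sphere
#' at the inlet and removed when they exit.
#'
#' @param sweep `"radius"` or `"velocity"`.
#' @param radii core radii (m) for the radius sweep.
#' @param velocities inlet peak velocities (m s^-1) for the velocity sweep.
#' @param n_particles batch size.
#' @param t_total transport time per case (s).
#' @param magnet_offset magnet distance from the centerline (m).
#' @param seed master seed.
#' @return List of per-case results (`label`, `timeseries`, `peak_fraction`).
#' @export
run_targeting_sweep <- function(sweep = c("radius", "velocity"),
                                radii = c(65e-9, 500e-9),
                                velocities = c(1.62e-3, 3.24e-3),
                                n_particles = 40L, t_total = 4,
                                magnet_offset = 0.07, seed = 1L) {
  sweep <- match.arg(sweep)
  props <- fluid_properties()
  tube_radius <- 5e-4
  dx <- tube_radius / 8
  tau <- 0.9
  dt <- ((tau - 0.5) / 3) * dx^2 / (props$mu / props$rho)
  units <- unit_system(dx, dt, rho = props$rho)
  L <- 64 * dx
  dom <- voxelize_cylinder(tube_radius, L, dx, periodic = FALSE)
  cx <- dom$surface$center[1]; cy <- dom$surface$center[2]
  roi <- region_of_interest("box", bounds = rbind(
    c(cx - tube_radius, cy + 0.7 * tube_radius, 0),
    c(cx + tube_radius, cy + 1.2 * tube_radius, L)))
  mg <- magnet(c(cx, cy + magnet_offset, L / 2), c(0, 3000, 0))
  cases <- if (sweep == "radius") {
    lapply(radii, function(a) list(a = a, u = velocities[1],
                                   label = sprintf("a=%gnm", a * 1e9)))
  } else {
    lapply(velocities, function(u) list(a = radii[1], u = u,
                                        label = sprintf("u=%gm/s", u)))
  }
  pfac <- 10L
  warmup <- 500L
  lapply(cases, function(cs) {
    wf <- make_waveform(0, cs$u, period = 1)   # steady inflow
    inl <- inlet_spec(dom, wf, direction = c(0, 0, 1))
    out <- outlet_spec(dom, normal = c(0, 0, 1))
    ctr <- site_centers(dom)
    r2 <- (ctr[, 1] - cx)^2 + (ctr[, 2] - cy)^2
    u_init <- cbind(0, 0, pmax(0, cs$u * (1 - r2 / tube_radius^2)) *
                      units$delta_t / units$delta_x)
    x0 <- seed_particles_in_sphere(n_particles, c(cx, cy, 8 * dx),
                                   radius = 0.8 * tube_radius,
                                   min_sep = 2e-6,
                                   seed = derive_seed(seed, 1L))
    sys <- particle_system(x0, a = cs$a, chi_v = 5.7)
    n_part_steps <- ceiling(t_total / (dt * pfac))
    cfg <- simulation_config(
      dom, units, props, inlets = list(inl), outlet = out,
      particles = sys, mg = mg,
      params = force_params(enable = list(magnet = TRUE, dipole_pairs = FALSE,
                                          wall_lubrication = TRUE,
                                          pair_lubrication = TRUE,
                                          brownian = FALSE)),
      roi = roi,
      n_steps = warmup + n_part_steps * pfac,
      output_every = 10L * pfac, seed = seed, warmup = warmup,
      freeze_fluid = TRUE, particle_dt_factor = pfac,
      init_u_lat = u_init)
    run <- run_simulation(cfg)
    list(label = cs$label, a = cs$a, u = cs$u,
         timeseries = run$roi_series,
         peak_fraction = max(run$roi_series$fraction),
         exits = nrow(run$exits))
  })
}
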