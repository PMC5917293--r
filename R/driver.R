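#' Full simulation description
#'
#' Aggregates everything a run needs: geometry, unit scaling, fluid
#' properties, boundary conditions, the particle batch, the magnet, force
#' toggles, the region of interest and output cadence. Validation is
#' performed by [run_simulation()] before stepping.
#'
#' For long particle-transport problems in steady or quasi-steady flow the
#' `freeze_fluid` mode first converges the flow for `warmup` lattice steps
#' and then advances only the particles on the frozen field, with a particle
#' time step of `particle_dt_factor` lattice steps. This trades unsteady
#' coupling for a large reduction in cost and is exact for steady flow.
#'
#' @param domain a [voxel_domain()].
#' @param units a [unit_system()].
#' @param props a [fluid_properties()].
#' @param wall_scheme `"bfl"` or `"bounce_back"`.
#' @param inlets list of [inlet_spec()] objects.
#' @param outlet an [outlet_spec()] or NULL.
#' @param body_force_phys constant body-force density (N m^-3), e.g. a
#'   pressure gradient driving the flow.
#' @param particles a [particle_system()] or NULL.
#' @param mg a [magnet()] or NULL.
#' @param params a [force_params()].
#' @param roi a [region_of_interest()] or NULL.
#' @param n_steps total lattice steps.
#' @param output_every snapshot cadence in steps.
#' @param seed master RNG seed; subsystem streams are derived from it.
#' @param warmup lattice steps of pure flow before particles move.
#' @param freeze_fluid freeze the flow field after warmup.
#' @param particle_dt_factor particle step in lattice steps (frozen mode
#'   only).
#' @param init_u_lat optional n_sites x 3 initial lattice velocity field.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(domain, units, props = fluid_properties(),
                              wall_scheme = "bfl",
                              inlets = list(), outlet = NULL,
                              body_force_phys = c(0, 0, 0),
                              particles = NULL, mg = NULL,
                              params = force_params(),
                              roi = NULL,
                              n_steps = 1000L, output_every = 100L,
                              seed = 1L,
                              warmup = 0L, freeze_fluid = FALSE,
                              particle_dt_factor = 1L,
                              init_u_lat = NULL) {
  structure(list(domain = domain, units = units, props = props,
                 wall_scheme = wall_scheme, inlets = inlets, outlet = outlet,
                 body_force_phys = body_force_phys, particles = particles,
                 mg = mg, params = params, roi = roi,
                 n_steps = as.integer(n_steps),
                 output_every = as.integer(output_every),
                 seed = as.integer(seed), warmup = as.integer(warmup),
                 freeze_fluid = freeze_fluid,
                 particle_dt_factor = as.integer(particle_dt_factor),
                 init_u_lat = init_u_lat),
            class = "simulation_config")
}

# lattice per-site body force from a physical force density (N m^-3)
force_density_to_lattice <- function(g_phys, units) {
  # force on one voxel = g * delta_x^3, then scaled to lattice force units
  convert_units(g_phys * units$delta_x^3, "force", "to_lattice", units)
}

#' Run a coupled flow/particle simulation
#'
#' One lattice step performs, in order: LBGK collision with body forcing,
#' streaming with the wall scheme, inlet and outlet conditions; then the
#' particle update: (a no-op communication hook,) force zeroing and
#' accumulation of all enabled forces, fluid-velocity interpolation at the
#' particles, optional spreading of the drag reaction onto the lattice
#' (consumed by the next lattice step), and the overdamped velocity and
#' explicit Euler position update. Particles crossing an outlet plane are
#' removed and logged. The run is reproducible bit-for-bit under a fixed
#' master seed.
#'
#' @param config a [simulation_config()].
#' @return An object of class `mdt_run`: snapshots of particle state,
#'   region-of-interest occupancy time series, the exit ledger, the final
#'   population and velocity fields, and per-snapshot mass totals.
#' @export
run_simulation <- function(config) {
  domain <- config$domain
  units <- config$units
  props <- config$props
  nu_lat <- lattice_viscosity(props, units)
  tau <- relaxation_time(nu_lat)
  u_peak_lat <- 0
  for (inl in config$inlets) {
    pk <- max(abs(eval_waveform(inl$waveform,
                                seq(0, inl$waveform$period, length.out = 200))))
    u_peak_lat <- max(u_peak_lat,
                      abs(convert_units(pk, "velocity", "to_lattice", units)))
  }
  stab <- check_stability(tau, u_peak_lat)
  if (!stab$ok) stop("unstable configuration: ",
                     paste(stab$violations, collapse = "; "))

  plan <- stream_plan(domain, config$wall_scheme)
  domain <- plan$domain                      # wall links may have been added
  n_sites <- plan$n
  f <- init_field(plan)
  if (!is.null(config$init_u_lat)) {
    a <- plan$active
    f[a, ] <- equilibrium(rep(1, length(a)),
                          config$init_u_lat[a, , drop = FALSE])
  }
  base_force <- matrix(0, n_sites, 3)
  g_lat <- force_density_to_lattice(config$body_force_phys, units)
  if (any(g_lat != 0))
    base_force[plan$fluid, ] <- matrix(g_lat, length(plan$fluid), 3, byrow = TRUE)
  force <- base_force

  sys <- config$particles
  n_injected <- if (is.null(sys)) 0L else nrow(sys$x)
  rng <- local_rng(derive_seed(config$seed, 2L))
  two_way <- config$params$coupling == "two_way"

  snaps <- list()
  roi_series <- data.frame(step = integer(), time_s = numeric(),
                           count = integer(), fraction = numeric())
  exits <- data.frame(id = integer(), step = integer(), time_s = numeric())
  mass <- numeric()
  dt <- units$delta_t
  pfac <- max(1L, config$particle_dt_factor)

  take_snapshot <- function(step, sys) {
    t_s <- step * dt
    if (!is.null(sys) && any(sys$alive)) {
      al <- which(sys$alive)
      Fm <- attr(sys, "F_mag")
      if (is.null(Fm)) Fm <- matrix(0, nrow(sys$x), 3)
      snap <- data.frame(step = step, time_s = t_s, id = sys$id[al],
                         x = sys$x[al, 1], y = sys$x[al, 2], z = sys$x[al, 3],
                         ux = sys$u[al, 1], uy = sys$u[al, 2], uz = sys$u[al, 3],
                         Fmag_x = Fm[al, 1], Fmag_y = Fm[al, 2],
                         Fmag_z = Fm[al, 3])
    } else {
      snap <- NULL
    }
    if (!is.null(config$roi) && !is.null(sys)) {
      al <- which(sys$alive)
      cnt <- if (length(al)) {
        count_in_roi(sys$x[al, , drop = FALSE], config$roi)$count
      } else 0L
      roi_series <<- rbind(roi_series,
                           data.frame(step = step, time_s = t_s, count = cnt,
                                      fraction = 100 * cnt / max(1L, n_injected)))
    }
    snap
  }

  step_particles <- function(sys, dt_p, step) {
    # exit ledger: remove particles beyond any outlet plane first
    if (!is.null(domain$exit_planes)) {
      for (ep in domain$exit_planes) {
        gone <- sys$alive &
          ep$dir * (sys$x[, ep$axis] - ep$value) >= 0
        if (any(gone)) {
          exits <<- rbind(exits, data.frame(id = sys$id[gone], step = step,
                                            time_s = step * dt))
          sys$alive[gone] <- FALSE
        }
      }
    }
    al <- which(sys$alive)
    if (!length(al)) return(sys)
    sub <- sys
    sub$x <- sys$x[al, , drop = FALSE]; sub$u <- sys$u[al, , drop = FALSE]
    sub$a <- sys$a[al]; sub$a_c <- sys$a_c[al]
    sub$chi_v <- sys$chi_v[al]; sub$rho_p <- sys$rho_p[al]
    sub$id <- sys$id[al]; sub$alive <- sys$alive[al]
    if (is.null(u_cache)) {
      m <- macroscopic_moments(f[plan$active, , drop = FALSE],
                               force[plan$active, , drop = FALSE])
      u_lat <- matrix(0, n_sites, 3)
      u_lat[plan$active, ] <- m$u
      u_cache <<- u_lat
    }
    u_lat <- u_cache
    # zero-velocity fallback covers positions in the viscous sublayer
    # between the outermost fluid-site centers and the vessel surface;
    # positions outside the domain box are genuine wall-handling faults
    v_fluid <- tryCatch(
      interpolate_velocity(u_lat, domain, sub$x, units, on_empty = "zero"),
      error = function(e) stop("particle escaped the fluid region at step ",
                               step, " (wall-handling fault): ",
                               conditionMessage(e)))
    sub <- advance_particles(sub, v_fluid, config$params, props, dt_p,
                             domain = domain, mg = config$mg, rng = rng)
    if (two_way) {
      # Newton's third law: the fluid receives the negation of the drag it
      # exerts on the particle, i.e. +6 pi mu (a+a_c) (u_p - v)
      beta_tot <- mobility(sub$a, sub$a_c, props$mu)
      reaction <- (sub$u - v_fluid) / beta_tot
      force <<- spread_reaction_force(base_force, domain, sub$x, reaction,
                                      units)
      u_cache <<- NULL
    }
    dom_now <- attr(sub, "dominance")
    dom_now <- dom_now[is.finite(dom_now)]
    if (length(dom_now))
      dominance_max <<- max(dominance_max, dom_now)
    sys$x[al, ] <- sub$x; sys$u[al, ] <- sub$u; sys$alive[al] <- sub$alive
    for (at in c("F_mag", "F_det", "F_R", "dominance")) {
      full <- attr(sys, at)
      if (is.null(full)) {
        full <- if (at == "dominance") rep(0, nrow(sys$x)) else matrix(0, nrow(sys$x), 3)
      }
      if (at == "dominance") full[al] <- attr(sub, at) else full[al, ] <- attr(sub, at)
      attr(sys, at) <- full
    }
    sys
  }

  snaps[[1]] <- take_snapshot(0L, sys)
  frozen <- FALSE
  u_cache <- NULL
  dominance_max <- 0
  step <- 0L
  while (step < config$n_steps) {
    step <- step + 1L
    if (!frozen) {
      u_cache <- NULL
      f <- lb_update(f, plan, tau, force)
      for (inl in config$inlets) f <- apply_velocity_inlet(f, inl, step * dt, units)
      if (!is.null(config$outlet)) f <- apply_pressure_outlet(f, config$outlet)
      if (any(!is.finite(f[plan$active, ])))
        stop("NaN detected in populations at step ", step)
    }
    if (config$freeze_fluid && step >= config$warmup) frozen <- TRUE
    if (!is.null(sys) && step >= config$warmup) {
      if (frozen && pfac > 1L) {
        if ((step - config$warmup) %% pfac == 0L)
          sys <- step_particles(sys, dt * pfac, step)
      } else {
        sys <- step_particles(sys, dt, step)
      }
    }
    if (step %% config$output_every == 0L || step == config$n_steps) {
      snaps[[length(snaps) + 1L]] <- take_snapshot(step, sys)
      mass <- c(mass, sum(f[plan$active, ]))
    }
  }
  m <- macroscopic_moments(f[plan$active, , drop = FALSE],
                           force[plan$active, , drop = FALSE])
  trajectories <- do.call(rbind, snaps[!vapply(snaps, is.null, TRUE)])
  structure(list(trajectories = trajectories, roi_series = roi_series,
                 exits = exits, mass = mass, f = f, plan = plan,
                 rho = m$rho, u_lat = m$u, config = config,
                 n_injected = n_injected, dominance_max = dominance_max,
                 n_alive = if (is.null(sys)) 0L else sum(sys$alive),
                 particles = sys),
            class = "mdt_run")
}

#' @export
print.mdt_run <- function(x, ...) {
  cat("mdt_run:", x$config$n_steps, "steps,", x$n_injected, "particles (",
      x$n_alive, "still in domain,", nrow(x$exits), "exited )\n")
  invisible(x)
}

#' Region-of-interest occupancy time series
#'
#' Percentage of the injected particles found inside the region of interest
#' at each trajectory snapshot.
#'
#' @param trajectories snapshot data frame as produced by
#'   [run_simulation()] (columns `step`, `time_s`, `x`, `y`, `z`).
#' @param roi a [region_of_interest()].
#' @param n_total number of injected particles; defaults to the number of
#'   distinct ids seen.
#' @return Data frame with `step`, `time_s`, `count`, `fraction` (percent).
#' @export
targeting_fraction_timeseries <- function(trajectories, roi, n_total = NULL) {
  if (is.null(trajectories) || !nrow(trajectories))
    stop("empty trajectory set")
  if (is.null(n_total)) n_total <- length(unique(trajectories$id))
  steps <- sort(unique(trajectories$step))
  out <- lapply(steps, function(s) {
    snap <- trajectories[trajectories$step == s, , drop = FALSE]
    cnt <- count_in_roi(cbind(snap$x, snap$y, snap$z), roi)$count
    data.frame(step = s, time_s = snap$time_s[1], count = cnt,
               fraction = 100 * cnt / n_total)
  })
  do.call(rbind, out)
}
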