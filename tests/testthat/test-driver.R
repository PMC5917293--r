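test_that("one-way particle runs leave the fluid bitwise identical", {
  tau <- 0.9; nu <- (tau - 0.5) / 3
  dom <- voxelize_cylinder(5.3, 8, spacing = 1, periodic = TRUE)
  units <- lattice_units(); props <- lattice_fluid(nu)
  base <- simulation_config(dom, units, props,
                            body_force_phys = c(0, 0, 1e-5),
                            n_steps = 80L, output_every = 80L)
  ref <- run_simulation(base)
  sys <- particle_system(c(dom$surface$center[1], dom$surface$center[2], 3),
                         a = 1e-3)
  with_p <- simulation_config(dom, units, props,
                              body_force_phys = c(0, 0, 1e-5),
                              particles = sys,
                              params = force_params(
                                enable = list(magnet = FALSE,
                                              dipole_pairs = FALSE,
                                              wall_lubrication = FALSE,
                                              pair_lubrication = FALSE,
                                              brownian = FALSE)),
                              n_steps = 80L, output_every = 80L)
  out <- run_simulation(with_p)
  expect_identical(out$f, ref$f)
})

test_that("two-way coupling feeds the drag reaction back into the flow", {
  tau <- 0.9; nu <- (tau - 0.5) / 3
  dom <- voxelize_cylinder(5.3, 8, spacing = 1, periodic = TRUE)
  units <- lattice_units(); props <- lattice_fluid(nu)
  cx <- dom$surface$center
  mk <- function(coupling, grav) {
    # a settling particle lags the fluid and exerts a drag reaction on it
    simulation_config(dom, units, props,
                      body_force_phys = c(0, 0, 1e-5),
                      particles = particle_system(c(cx[1], cx[2], 4),
                                                  a = 0.2, rho_p = 100),
                      params = force_params(
                        coupling = coupling, gravity = c(0, 0, -grav),
                        enable = list(gravity = TRUE, magnet = FALSE,
                                      dipole_pairs = FALSE,
                                      wall_lubrication = FALSE,
                                      pair_lubrication = FALSE,
                                      brownian = FALSE)),
                      n_steps = 60L, output_every = 60L)
  }
  one <- run_simulation(mk("one_way", 1e-4))
  two <- run_simulation(mk("two_way", 1e-4))
  # the deposited reaction perturbs the flow and pushes it along -z
  expect_gt(max(abs(one$f - two$f)), 0)
  expect_lt(sum(two$u_lat[, 3]), sum(one$u_lat[, 3]))
  # a force-free tracer exerts no reaction: two-way equals one-way
  tr1 <- run_simulation(mk("one_way", 0))
  tr2 <- run_simulation(mk("two_way", 0))
  expect_lt(max(abs(tr1$f - tr2$f)), 1e-13)
})

test_that("runs are bit-reproducible under a fixed master seed", {
  tau <- 0.9; nu <- (tau - 0.5) / 3
  dom <- voxelize_cylinder(5.3, 10, spacing = 1, periodic = TRUE)
  x0 <- seed_particles_in_sphere(8, c(dom$surface$center[1],
                                      dom$surface$center[2], 3),
                                 radius = 2, min_sep = 0.2, seed = 5)
  mk <- function(seed) {
    simulation_config(dom, lattice_units(), lattice_fluid(nu),
                      body_force_phys = c(0, 0, 1e-5),
                      particles = particle_system(x0, a = 1e-4),
                      params = force_params(
                        enable = list(magnet = FALSE, dipole_pairs = FALSE,
                                      wall_lubrication = FALSE,
                                      pair_lubrication = FALSE,
                                      brownian = TRUE),
                        temperature = 310.15),
                      n_steps = 60L, output_every = 20L, seed = seed)
  }
  r1 <- run_simulation(mk(11L))
  r2 <- run_simulation(mk(11L))
  r3 <- run_simulation(mk(12L))
  expect_identical(r1$trajectories, r2$trajectories)
  expect_false(identical(r1$trajectories, r3$trajectories))
  expect_identical(r1$f, r2$f)
})

test_that("particle ledger balances: injected = alive + exited", {
  tau <- 0.9; nu <- (tau - 0.5) / 3
  dom <- voxelize_cylinder(5.3, 12, spacing = 1)   # flow-through with outlet
  inl <- inlet_spec(dom, make_waveform(0, 0.01, period = 1))
  out <- outlet_spec(dom)
  cx <- dom$surface$center
  x0 <- seed_particles_in_sphere(10, c(cx[1], cx[2], 2.5), radius = 2,
                                 min_sep = 0.3, seed = 3)
  cfg <- simulation_config(dom, lattice_units(), lattice_fluid(nu),
                           inlets = list(inl), outlet = out,
                           particles = particle_system(x0, a = 1e-4),
                           params = force_params(
                             enable = list(magnet = FALSE,
                                           dipole_pairs = FALSE,
                                           wall_lubrication = FALSE,
                                           pair_lubrication = FALSE,
                                           brownian = FALSE)),
                           roi = region_of_interest(
                             "box", bounds = rbind(c(0, 0, 0),
                                                   c(20, 20, 12))),
                           n_steps = 2500L, output_every = 250L)
  run <- run_simulation(cfg)
  expect_gt(nrow(run$exits), 0)           # advected through the outlet
  expect_identical(run$n_injected, 10L)
  expect_identical(run$n_injected, run$n_alive + nrow(run$exits))
  # at every snapshot, alive count + prior exits = injected
  tr <- run$trajectories
  for (s in unique(tr$step)) {
    alive_s <- sum(tr$step == s)
    exited_s <- sum(run$exits$step <= s)
    expect_identical(alive_s + exited_s, 10L)
  }
})

test_that("tracers in steady Poiseuille flow stay on their streamlines", {
  tau <- 0.9; nu <- (tau - 0.5) / 3
  R <- 6.3
  dom <- voxelize_cylinder(R, 16, spacing = 1, periodic = TRUE)
  cx <- dom$surface$center
  u_max <- 0.01
  ctr <- mdtsim:::site_centers(dom)
  r2 <- (ctr[, 1] - cx[1])^2 + (ctr[, 2] - cx[2])^2
  g <- 4 * nu * u_max / R^2
  x0 <- cbind(cx[1], cx[2] + c(0, 2.1, 4.2), 3)
  cfg <- simulation_config(dom, lattice_units(), lattice_fluid(nu),
                           body_force_phys = c(0, 0, g),
                           particles = particle_system(x0, a = 1e-4),
                           params = force_params(
                             enable = list(magnet = FALSE,
                                           dipole_pairs = FALSE,
                                           wall_lubrication = FALSE,
                                           pair_lubrication = FALSE,
                                           brownian = FALSE)),
                           n_steps = 2000L, output_every = 200L,
                           warmup = 800L, freeze_fluid = TRUE,
                           init_u_lat = cbind(0, 0, pmax(0, u_max *
                                                           (1 - r2 / R^2))))
  run <- run_simulation(cfg)
  tr <- run$trajectories
  r <- sqrt((tr$x - cx[1])^2 + (tr$y - cx[2])^2)
  for (id in unique(tr$id)) {
    ri <- r[tr$id == id]
    expect_lt(max(abs(ri - ri[1])), 0.1)  # dx/10
  }
})

test_that("an unstable configuration is rejected before stepping", {
  dom <- voxelize_cylinder(5.3, 8, spacing = 1)
  inl <- inlet_spec(dom, make_waveform(0, 0.2, period = 1))  # over the cap
  cfg <- simulation_config(dom, lattice_units(), lattice_fluid(0.1),
                           inlets = list(inl))
  expect_error(run_simulation(cfg), "Mach")
})

test_that("targeting time series counts fractions of the injected batch", {
  tr <- data.frame(step = rep(c(0L, 10L), each = 3),
                   time_s = rep(c(0, 1), each = 3),
                   id = rep(1:3, 2),
                   x = c(0, 0, 5, 0, 5, 5), y = 0, z = 0)
  roi <- region_of_interest("sphere", center = c(0, 0, 0), radius = 1)
  ts <- targeting_fraction_timeseries(tr, roi)
  expect_equal(ts$fraction, c(100 * 2 / 3, 100 * 1 / 3))
  # an absent particle (exited) lowers the fraction against n_total
  ts2 <- targeting_fraction_timeseries(tr[tr$id != 3, ], roi, n_total = 3)
  expect_equal(ts2$fraction, c(100 * 2 / 3, 100 * 1 / 3))
  expect_error(targeting_fraction_timeseries(tr[0, ], roi), "empty")
})

test_that("targeting efficiency is non-decreasing in the core radius", {
  rs <- run_targeting_sweep("radius", radii = c(65e-9, 500e-9), seed = 1)
  peaks <- vapply(rs, function(x) x$peak_fraction, numeric(1))
  expect_gte(peaks[2], peaks[1])             # a^3 forcing strengthens capture
  expect_gt(peaks[1], 0)
})

test_that("field export and YAML configuration round-trip", {
  dom <- voxelize_cylinder(5.3, 6, spacing = 1)
  plan <- stream_plan(dom, "bounce_back")
  f <- init_field(plan)
  m <- macroscopic_moments(f[plan$active, ])
  path <- file.path(tempdir(), "field.vti")
  write_vti(path, dom, m$rho, m$u, active = plan$active)
  txt <- readLines(path)
  expect_match(txt[2], "ImageData")
  expect_true(any(grepl("Name=\"rho\"", txt)))
  expect_true(any(grepl("Name=\"u\"", txt)))
  unlink(path)

  yml <- file.path(tempdir(), "run.yaml")
  writeLines(c(
    "geometry: {kind: cylinder, radius_m: 5.0e-4, length_m: 3.0e-3, spacing_m: 1.0e-4}",
    "units: {delta_x_m: 1.0e-4, u_phys_max_m_s: 0.01}",
    "fluid: {mu_Pa_s: 0.004, rho_kg_m3: 1000}",
    "inlet: {peak_velocity_m_s: 0.005, bpm: 68}",
    "outlet: {rho_out: 1}",
    "particles: {count: 5, a_m: 6.5e-8, seed_sphere: {center_m: [9.5e-4, 9.5e-4, 5.0e-4], radius_m: 3.0e-4}}",
    "magnet: {position_m: [0.0, 0.07, 1.5e-3], moment_A_m2: [0, 3000, 0]}",
    "roi: {shape: sphere, center_m: [9.5e-4, 9.5e-4, 1.5e-3], radius_m: 4.0e-4}",
    "steps: 10",
    "seed: 7"), yml)
  cfg <- read_config_yaml(yml)
  expect_s3_class(cfg, "simulation_config")
  expect_equal(cfg$units$delta_x, 1e-4)
  expect_equal(nrow(cfg$particles$x), 5)
  expect_equal(cfg$mg$moment, c(0, 3000, 0))
  expect_equal(cfg$roi$radius, 4e-4)
  expect_identical(cfg$n_steps, 10L)
  unlink(yml)
})
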