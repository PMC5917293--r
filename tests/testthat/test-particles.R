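test_that("dipole field has the axial/equatorial closed forms and r^-3 decay", {
  mg <- magnet(c(0, 0, 0), c(0, 0, 3000))
  # axial point: |H| = 2 m / (4 pi r^3)
  H_ax <- dipole_field(mg, c(0, 0, 0.03))
  expect_equal(sqrt(sum(H_ax^2)), 2 * 3000 / (4 * pi * 0.03^3),
               tolerance = 1e-12)
  # equatorial point: H = -m0 / (4 pi r^3)
  H_eq <- dipole_field(mg, c(0.05, 0, 0))
  expect_equal(as.vector(H_eq), c(0, 0, -3000 / (4 * pi * 0.05^3)),
               tolerance = 1e-12)
  # homogeneity: log-log slope -3
  r <- 10^seq(-2.5, -1, length.out = 12)
  Hm <- vapply(r, function(rr) sqrt(sum(dipole_field(mg, c(0, rr, 0))^2)),
               numeric(1))
  sl <- stats::coef(stats::lm(log(Hm) ~ log(r)))[[2]]
  expect_lt(abs(sl + 3), 1e-6)
  expect_error(dipole_field(mg, c(0, 0, 0)), "magnet position")
})

test_that("induced moment follows the a^3 chi law", {
  H <- c(1e5, 0, 0)
  m <- induced_moment(65e-9, 5.7, H)
  # arithmetic oracle: 4 pi a^3 chi |H| / 3
  expect_equal(sqrt(sum(m^2)), 4 * pi * (65e-9)^3 * 5.7 * 1e5 / 3,
               tolerance = 1e-12)
  expect_equal(sqrt(sum(m^2)), 6.556e-16, tolerance = 1e-3)
  expect_identical(as.vector(induced_moment(0, 5.7, H)), c(0, 0, 0))
  expect_equal(sqrt(sum(induced_moment(2 * 65e-9, 5.7, H)^2)),
               8 * sqrt(sum(m^2)))
})

test_that("pair dipole force matches the symbolic special cases", {
  m <- 1e-12
  r <- 3e-6
  # collinear moments along the pair axis: attractive, 3 mu0 m^2/(2 pi r^4)
  Fc <- pair_dipole_force(c(0, 0, m), c(0, 0, r), c(0, 0, m), c(0, 0, 0))
  expect_equal(as.vector(Fc), c(0, 0, -3 * MU0 * m^2 / (2 * pi * r^4)),
               tolerance = 1e-12)
  # perpendicular moments: repulsive, half the magnitude
  Fp <- pair_dipole_force(c(m, 0, 0), c(0, 0, r), c(m, 0, 0), c(0, 0, 0))
  expect_equal(as.vector(Fp), c(0, 0, 3 * MU0 * m^2 / (4 * pi * r^4)),
               tolerance = 1e-12)
  expect_equal(sqrt(sum(Fc^2)) / sqrt(sum(Fp^2)), 2, tolerance = 1e-12)
  expect_error(pair_dipole_force(c(0, 0, m), c(1, 1, 1), c(0, 0, m),
                                 c(1, 1, 1)), "coincident")
})

test_that("Newton's third law holds for pair forces on random inputs", {
  set.seed(21)
  for (k in 1:20) {
    mi <- rnorm(3) * 1e-12; mj <- rnorm(3) * 1e-12
    xi <- rnorm(3) * 1e-5; xj <- rnorm(3) * 1e-5
    Fij <- pair_dipole_force(mi, xi, mj, xj)
    Fji <- pair_dipole_force(mj, xj, mi, xi)
    expect_lt(max(abs(Fij + Fji)) / max(abs(Fij)), 1e-14)
    ui <- rnorm(3) * 1e-3; uj <- rnorm(3) * 1e-3
    a <- 5e-7; he <- 5e-7
    # place centers close enough for the lubrication to act
    xj2 <- xi + (2 * a + 0.3 * a) * c(1, 0, 0)
    Li <- pair_lubrication(xi, ui, xj2, uj, a, he)$force
    Lj <- pair_lubrication(xj2, uj, xi, ui, a, he)$force
    expect_lt(max(abs(Li + Lj)), 1e-30 + max(abs(Li)) * 1e-14)
  }
})

test_that("magnet-particle force scales as distance^-7 and radius^3", {
  mg <- magnet(c(0, 0, 0), c(0, 0, 3000))
  d <- 10^seq(-2, -1, length.out = 15)
  Fm <- vapply(d, function(dd)
    sqrt(sum(magnet_particle_force(mg, c(0, 0, dd), 65e-9, 5.7)^2)),
    numeric(1))
  sl_d <- stats::coef(stats::lm(log(Fm) ~ log(d)))[[2]]
  expect_lt(abs(sl_d + 7), 1e-3)
  aa <- 10^seq(log10(25e-9), log10(500e-9), length.out = 12)
  Fa <- vapply(aa, function(a)
    sqrt(sum(magnet_particle_force(mg, c(0, 0, 0.03), a, 5.7)^2)),
    numeric(1))
  sl_a <- stats::coef(stats::lm(log(Fa) ~ log(aa)))[[2]]
  expect_lt(abs(sl_a - 3), 1e-3)
  # on-axis particle is pulled toward the magnet
  F <- magnet_particle_force(mg, c(0, 0, 0.03), 65e-9, 5.7)
  expect_lt(F[3], 0)
})

test_that("wall lubrication force opposes approach with the 1/h - 1/h_e gain", {
  a <- 5e-7; he <- 5e-7; mu <- 0.004
  # cutoff: zero at and beyond h_e
  f_at <- wall_lubrication(c(0, -1e-3, 0), a, c(0, -(a + he), 0), he, mu)
  expect_identical(as.vector(f_at$force), c(0, 0, 0))
  # motion parallel to the wall: zero
  f_par <- wall_lubrication(c(1e-3, 0, 0), a, c(0, -(a + 0.1 * a), 0), he, mu)
  expect_identical(as.vector(f_par$force), c(0, 0, 0))
  # approaching: force points away from the wall with the stated magnitude
  h <- 0.2 * a
  fl <- wall_lubrication(c(0, -1e-3, 0), a, c(0, -(a + h), 0), he, mu)
  expect_equal(fl$force[1, 2],
               6 * pi * mu * a^2 * 1e-3 * (1 / h - 1 / he),
               tolerance = 1e-12)
  expect_true(wall_lubrication(c(0, -1e-3, 0), a, c(0, -0.5 * a, 0), he,
                               mu)$penetrating)
})

test_that("pair lubrication vanishes for rigid-body motion and diverges on approach", {
  a <- 5e-7; he <- 5e-7
  u <- c(1e-3, -2e-3, 0.5e-3)
  same <- pair_lubrication(c(0, 0, 0), u, c(2.2 * a, 0, 0), u, a, he)
  expect_identical(as.vector(same$force), c(0, 0, 0))
  # repulsion grows without bound as the gap closes
  gaps <- c(0.3, 0.1, 0.03, 0.01) * a
  mags <- vapply(gaps, function(h) {
    sqrt(sum(pair_lubrication(c(0, 0, 0), c(1e-3, 0, 0),
                              c(2 * a + h, 0, 0), c(0, 0, 0), a, he)$force^2))
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("integrated pair approach never overlaps", {
  a <- 5e-7
  props <- fluid_properties()
  params <- force_params(enable = list(magnet = FALSE, dipole_pairs = FALSE,
                                       pair_lubrication = TRUE,
                                       wall_lubrication = FALSE,
                                       brownian = FALSE))
  sys <- particle_system(rbind(c(0, 0, 0), c(4 * a, 0, 0)), a = a)
  # drive the two particles toward each other
  f_ext <- rbind(c(1, 0, 0), c(-1, 0, 0)) * 1e-12
  min_sep <- Inf
  for (s in 1:600) {
    sys <- advance_particles(sys, matrix(0, 2, 3), params, props,
                             dt = 1e-4, f_ext = f_ext)
    min_sep <- min(min_sep, sqrt(sum((sys$x[1, ] - sys$x[2, ])^2)))
  }
  expect_gt(min_sep, 2 * a)
})

test_that("Maude reference resistance has its printed limits", {
  a <- 5e-7; mu <- 0.004; u <- 1e-3
  F0 <- 6 * pi * mu * a * u
  expect_equal(maude_force(a, 1e6 * a, u, mu), F0, tolerance = 1e-5)
  expect_equal(maude_force(a, a, u, mu), 2.125 * F0)
  expect_equal(maude_force(a, 9 * a / 8, u, mu), 2 * F0)
  expect_error(maude_force(a, 0, u, mu), "gap")
})

test_that("gravity-buoyancy and settling follow the Stokes closed form", {
  expect_identical(gravity_buoyancy(5e-7, 0, 1000, 1000)[1, ], c(0, 0, 0))
  expect_identical(gravity_buoyancy(5e-7, 0, 5170, 1000, c(0, 0, 0))[1, ],
                   c(0, 0, 0))
  a <- 5e-7
  F <- gravity_buoyancy(a, 0, 5170, 1000, c(0, 0, -9.81))
  v <- mobility(a) * sqrt(sum(F^2))
  v_ref <- 2 * a^2 * (5170 - 1000) * 9.81 / (9 * 0.004)
  expect_equal(v, v_ref, tolerance = 1e-12)
})

test_that("Brownian forces are unbiased with the fluctuation-dissipation scale", {
  expect_identical(brownian_force(3, mobility(65e-9), 0, 1e-6),
                   matrix(0, 3, 3))
  set.seed(123)
  beta <- mobility(65e-9)
  Fr <- brownian_force(1e5, beta, 310.15, 1e-6)
  sigma <- sqrt(2 * KB * 310.15 / (beta * 1e-6))
  expect_lt(abs(mean(Fr)), 4 * sigma / sqrt(3e5))
  expect_lt(abs(stats::sd(Fr) / sigma - 1), 0.02)
})

test_that("velocity interpolation is trilinear and respects solid corners", {
  dom <- periodic_box(c(8, 8, 8))
  ctr <- mdtsim:::site_centers(dom)
  # linear field reproduced exactly
  u <- cbind(0.1 * ctr[, 1] + 0.2 * ctr[, 2], -0.3 * ctr[, 3], 0 * ctr[, 1])
  x <- rbind(c(3.21, 4.77, 2.35), c(1.5, 1.5, 1.5))
  v <- interpolate_velocity(u, dom, x)
  expect_equal(v[, 1], 0.1 * x[, 1] + 0.2 * x[, 2], tolerance = 1e-12)
  expect_equal(v[, 2], -0.3 * x[, 3], tolerance = 1e-12)
  # at a site center: that site's value
  v2 <- interpolate_velocity(u, dom, ctr[100, ])
  expect_equal(as.vector(v2), u[100, ], tolerance = 1e-12)
  # uniform field anywhere
  uu <- matrix(rep(c(1, 2, 3), each = nrow(ctr)), ncol = 3)
  expect_equal(as.vector(interpolate_velocity(uu, dom, c(2.3, 6.1, 0.7))),
               c(1, 2, 3))
  # outside a walled domain errors
  ch <- channel_domain(4L, 4L, 4L)
  expect_error(interpolate_velocity(matrix(0, prod(ch$dims), 3), ch,
                                    c(2, -5, 2)), "outside")
})

test_that("reaction-force spreading conserves the deposited impulse", {
  dom <- periodic_box(c(6, 6, 6))
  units <- lattice_units()
  force <- matrix(0, prod(dom$dims), 3)
  x <- matrix(c(2.37, 3.91, 1.16), 1)
  Fp <- matrix(c(1e-3, -2e-3, 5e-4), 1)
  out <- spread_reaction_force(force, dom, x, Fp, units)
  expect_equal(colSums(out), as.vector(Fp), tolerance = 1e-15)
  # particle exactly at a site center: all force on that site
  ctr <- mdtsim:::site_centers(dom)
  out2 <- spread_reaction_force(force, dom, matrix(ctr[50, ], 1), Fp, units)
  expect_equal(out2[50, ], as.vector(Fp))
  expect_equal(sum(out2 != 0), 3)
})

test_that("drag dominance ratio behaves as the mobility balance", {
  v <- c(1e-3, 0, 0)
  expect_equal(drag_dominance(v, c(0, 0, 0), c(0, 0, 0), 1), 0)
  r1 <- drag_dominance(v, c(1e-12, 0, 0), c(0, 0, 0), mobility(65e-9, 0, 0.004))
  r2 <- drag_dominance(v, c(1e-12, 0, 0), c(0, 0, 0), mobility(65e-9, 0, 0.008))
  expect_equal(r1 / r2, 2, tolerance = 1e-12)
  expect_identical(drag_dominance(c(0, 0, 0), c(1e-12, 0, 0), c(0, 0, 0), 1),
                   Inf)
})

test_that("overdamped update reduces to a tracer and to the settling balance", {
  props <- fluid_properties()
  off <- force_params(enable = list(magnet = FALSE, dipole_pairs = FALSE,
                                    wall_lubrication = FALSE,
                                    pair_lubrication = FALSE,
                                    brownian = FALSE))
  sys <- particle_system(c(0, 0, 0), a = 65e-9)
  v <- c(1e-3, 2e-3, -5e-4)
  out <- advance_particles(sys, v, off, props, dt = 1e-4)
  expect_identical(out$u[1, ], v)
  expect_equal(out$x[1, ], v * 1e-4)
  # quiescent fluid + gravity: settling speed
  grav <- force_params(gravity = c(0, 0, -9.81),
                       enable = list(gravity = TRUE, magnet = FALSE,
                                     dipole_pairs = FALSE,
                                     wall_lubrication = FALSE,
                                     pair_lubrication = FALSE,
                                     brownian = FALSE))
  sys <- particle_system(c(0, 0, 0), a = 5e-7, rho_p = 5170)
  out <- advance_particles(sys, c(0, 0, 0), grav, props, dt = 1e-4)
  expect_equal(-out$u[1, 3], 2 * (5e-7)^2 * 4170 * 9.81 / (9 * 0.004),
               tolerance = 1e-12)
})

test_that("free Brownian diffusion recovers Stokes-Einstein within 3 SE", {
  props <- fluid_properties()
  a <- 65e-9
  beta <- mobility(a)
  D <- KB * 310.15 * beta
  params <- force_params(enable = list(magnet = FALSE, dipole_pairs = FALSE,
                                       wall_lubrication = FALSE,
                                       pair_lubrication = FALSE,
                                       brownian = TRUE))
  n <- 400L; nsteps <- 400L; dt <- 1e-6
  sys <- particle_system(matrix(0, n, 3), a = a)
  rng <- mdtsim:::local_rng(7L)
  for (s in seq_len(nsteps))
    sys <- advance_particles(sys, matrix(0, n, 3), params, props, dt,
                             rng = rng)
  r2 <- rowSums(sys$x^2)
  msd <- mean(r2)
  se <- stats::sd(r2) / sqrt(n)
  expect_lt(abs(msd - 6 * D * nsteps * dt), 3 * se)
})

test_that("coating thickness changes drag but not the magnetic response", {
  expect_equal(mobility(65e-9, 65e-9) / mobility(65e-9), 0.5)
  mg <- magnet(c(0, 0, 0), c(0, 0, 3000))
  F1 <- magnet_particle_force(mg, c(0, 0, 0.05), 65e-9, 5.7)
  # the force model takes the core radius only; coatings enter elsewhere
  expect_identical(F1, magnet_particle_force(mg, c(0, 0, 0.05), 65e-9, 5.7))
  p <- particle_system(c(0, 0, 0), a = 65e-9, a_c = 32.5e-9)
  expect_equal(p$a_c, 32.5e-9)
})
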