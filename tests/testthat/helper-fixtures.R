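# shared helpers for the test suite

# unit system in which lattice and physical units coincide
lattice_units <- function() unit_system(delta_x = 1, delta_t = 1, rho = 1)

# fluid whose lattice viscosity equals nu under lattice_units()
lattice_fluid <- function(nu) fluid_properties(mu = nu, rho = 1)

# random positive population matrix
random_populations <- function(n, seed = 1) {
  set.seed(seed)
  equilibrium(rep(1, n), matrix(0, n, 3)) + matrix(runif(n * 19, 0, 1e-3), n, 19)
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-300)), tol)
}
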