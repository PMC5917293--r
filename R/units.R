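#' Physical fluid properties
#'
#' Bundle of the physical constants describing the carrier fluid. Defaults
#' correspond to blood plasma at body temperature: dynamic viscosity
#' 0.004 Pa s, density 1000 kg m^-3, temperature 310.15 K (37 C).
#'
#' @param mu dynamic viscosity in Pa s.
#' @param rho mass density in kg m^-3.
#' @param temperature absolute temperature in K (used only by the Brownian
#'   force model; the lattice solver itself is athermal).
#' @return An object of class `fluid_properties`.
#' @export
fluid_properties <- function(mu = 0.004, rho = 1000, temperature = 310.15) {
  if (!is.numeric(mu) || mu <= 0) stop("mu must be > 0")
  if (!is.numeric(rho) || rho <= 0) stop("rho must be > 0")
  if (!is.numeric(temperature) || temperature <= 0) stop("temperature must be > 0")
  structure(list(mu = mu, rho = rho, temperature = temperature),
            class = "fluid_properties")
}

#' Lattice/physical unit system
#'
#' The solver is scaled by a lattice spacing `delta_x` (m), a time step
#' `delta_t` (s) and a lattice mass `delta_m` (kg). All other scales are
#' derived: velocity `delta_x/delta_t`, force `delta_m*delta_x/delta_t^2`,
#' energy `delta_m*delta_x^2/delta_t^2`, pressure
#' `delta_m/(delta_x*delta_t^2)`.
#'
#' `delta_m` defaults to `rho * delta_x^3` so that a lattice density of 1
#' corresponds to the physical fluid density, which makes pressure and force
#' scales unambiguous.
#'
#' @param delta_x lattice spacing, m.
#' @param delta_t time step, s. If `NULL`, computed with [max_timestep()]
#'   from `u_phys_max`.
#' @param rho physical density used for the default lattice mass, kg m^-3.
#' @param delta_m lattice mass, kg; default `rho * delta_x^3`.
#' @param u_phys_max peak physical velocity expected in the run, m s^-1;
#'   required when `delta_t` is omitted.
#' @return An object of class `unit_system` with the three base scales and
#'   the derived scale for every supported quantity kind.
#' @export
unit_system <- function(delta_x, delta_t = NULL, rho = 1000,
                        delta_m = rho * delta_x^3, u_phys_max = NULL) {
  if (delta_x <= 0) stop("delta_x must be > 0")
  if (is.null(delta_t)) {
    if (is.null(u_phys_max)) stop("either delta_t or u_phys_max is required")
    delta_t <- max_timestep(delta_x, u_phys_max)
  }
  if (delta_t <= 0) stop("delta_t must be > 0")
  if (delta_m <= 0) stop("delta_m must be > 0")
  scales <- c(
    length   = delta_x,
    time     = delta_t,
    mass     = delta_m,
    velocity = delta_x / delta_t,
    force    = delta_m * delta_x / delta_t^2,
    energy   = delta_m * delta_x^2 / delta_t^2,
    pressure = delta_m / (delta_x * delta_t^2)
  )
  structure(list(delta_x = delta_x, delta_t = delta_t, delta_m = delta_m,
                 scales = scales),
            class = "unit_system")
}

#' @export
print.unit_system <- function(x, ...) {
  cat("unit_system: delta_x =", format(x$delta_x), "m, delta_t =",
      format(x$delta_t), "s, delta_m =", format(x$delta_m), "kg\n")
  invisible(x)
}

#' Lattice kinematic viscosity
#'
#' Converts the physical kinematic viscosity `mu/rho` into lattice units:
#' `nu_lat = (mu/rho) * delta_t / delta_x^2`.
#'
#' @param props a [fluid_properties()] object.
#' @param units a [unit_system()] object.
#' @return Dimensionless lattice kinematic viscosity.
#' @export
lattice_viscosity <- function(props, units) {
  (props$mu / props$rho) * units$delta_t / units$delta_x^2
}

#' LBGK relaxation time from lattice viscosity
#'
#' In lattice units (c_s^2 = 1/3, step length 1) the kinematic viscosity is
#' `nu = (tau - 1/2)/3`, hence `tau = 3*nu + 1/2`. `tau = 0.5` is the
#' inviscid-flow limit below which the scheme is unstable.
#'
#' @param nu_lat lattice kinematic viscosity (dimensionless, >= 0).
#' @return Relaxation time tau (dimensionless).
#' @export
relaxation_time <- function(nu_lat) {
  if (any(nu_lat < 0)) stop("lattice viscosity must be >= 0")
  3 * nu_lat + 0.5
}

#' Maximum admissible lattice velocity
#'
#' Low-Mach-number cap on the lattice velocity. The Mach limit is read as
#' `u/c_s < 1/30` with `c_s = 1/sqrt(3)`, giving `u_max = 1/(30*sqrt(3))`,
#' about 0.0192 (commonly rounded to 0.02). A literal `u/c_s^2 < 1/30`
#' reading would give 0.011 and is inconsistent with the 0.02 cap used for
#' time-step selection, so it is not used.
#'
#' @return The dimensionless lattice velocity cap.
#' @export
max_lattice_velocity <- function() {
  1 / (30 * sqrt(3))
}

#' Largest stable time step for a target peak velocity
#'
#' The largest `delta_t` keeping the peak lattice velocity at the Mach cap:
#' `delta_t = max_lattice_velocity() * delta_x / u_phys_max`.
#'
#' @param delta_x lattice spacing, m.
#' @param u_phys_max peak physical velocity, m s^-1.
#' @return Time step in seconds.
#' @export
max_timestep <- function(delta_x, u_phys_max) {
  if (delta_x <= 0) stop("delta_x must be > 0")
  if (u_phys_max <= 0) stop("u_phys_max must be > 0")
  max_lattice_velocity() * delta_x / u_phys_max
}

#' Stability report for a lattice configuration
#'
#' Checks the two stability criteria of the LBGK scheme: `tau > 0.5`
#' (viscous stability; 0.5 is the inviscid limit) and
#' `u_lat_peak <= max_lattice_velocity()` (low Mach number).
#'
#' @param tau relaxation time.
#' @param u_lat_peak peak lattice velocity expected in the run.
#' @return A list with elements `ok` (logical) and `violations`
#'   (character vector naming each violated criterion, empty when `ok`).
#' @export
check_stability <- function(tau, u_lat_peak) {
  violations <- character()
  if (tau <= 0.5)
    violations <- c(violations,
                    sprintf("relaxation time tau = %g <= 0.5 (inviscid limit)", tau))
  if (u_lat_peak > max_lattice_velocity())
    violations <- c(violations,
                    sprintf("peak lattice velocity %g exceeds Mach cap %g",
                            u_lat_peak, max_lattice_velocity()))
  list(ok = length(violations) == 0L, violations = violations)
}

#' Convert between physical and lattice units
#'
#' Multiplies (to_lattice divides) by the unit-system scale of the given
#' quantity kind. Round-trip conversion is exact to floating point.
#'
#' @param value numeric value(s) to convert.
#' @param kind one of `"length"`, `"time"`, `"mass"`, `"velocity"`,
#'   `"force"`, `"energy"`, `"pressure"`.
#' @param direction `"to_lattice"` or `"to_physical"`.
#' @param units a [unit_system()].
#' @return Converted numeric value(s).
#' @export
convert_units <- function(value, kind, direction = c("to_lattice", "to_physical"),
                          units) {
  direction <- match.arg(direction)
  if (!kind %in% names(units$scales))
    stop("unknown quantity kind: ", kind)
  s <- units$scales[[kind]]
  if (direction == "to_lattice") value / s else value * s
}

#' Convert pressure from mmHg to Pa
#'
#' Uses the conventional factor 1 mmHg = 133.322 Pa.
#'
#' @param p pressure in mmHg.
#' @return Pressure in Pa.
#' @export
mmHg_to_Pa <- function(p) {
  p * 133.322
}
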