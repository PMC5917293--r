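#' Tabulated pulsatile inlet waveform
#'
#' Peak centerline velocity versus time over one cardiac period. Evaluation
#' is by periodic linear interpolation.
#'
#' @param time_s sample times, s, increasing, starting at 0 and covering one
#'   period.
#' @param peak_velocity_m_s peak velocity samples, m s^-1.
#' @param period period length, s; defaults to the last sample time.
#' @return An object of class `waveform`.
#' @export
make_waveform <- function(time_s, peak_velocity_m_s, period = max(time_s)) {
  stopifnot(length(time_s) == length(peak_velocity_m_s), length(time_s) >= 1,
            period > 0, all(diff(time_s) > 0), min(time_s) >= 0)
  structure(list(time = time_s, value = peak_velocity_m_s, period = period),
            class = "waveform")
}

#' Evaluate a waveform at arbitrary times
#'
#' @param w a [make_waveform()] object.
#' @param t times, s (vectorized); wrapped into the period.
#' @return Peak velocities, m s^-1.
#' @export
eval_waveform <- function(w, t) {
  if (length(w$time) == 1L) return(rep(w$value, length(t)))
  tt <- t %% w$period
  xs <- w$time
  ys <- w$value
  if (xs[length(xs)] < w$period) {   # close the period by wrapping to t0
    xs <- c(xs, w$period)
    ys <- c(ys, ys[1])
  }
  stats::approx(xs, ys, xout = tt, rule = 2)$y
}

#' Synthetic two-harmonic pulse waveform
#'
#' Fixture emulating a physiological pulse: a mean level plus two harmonics
#' of the heart rate, scaled so the maximum equals `peak` and the curve
#' stays positive. Stands in for inlet velocity curves obtained from
#' upstream 1D arterial-network models, which are user inputs here.
#'
#' @param peak peak velocity, m s^-1.
#' @param bpm heart rate, beats per minute.
#' @param n_samples samples per period.
#' @return A [make_waveform()] object with period `60/bpm` s.
#' @export
pulse_waveform <- function(peak, bpm = 68, n_samples = 64) {
  period <- 60 / bpm
  t <- seq(0, period, length.out = n_samples + 1)[-(n_samples + 1)]
  ph <- 2 * pi * t / period
  shape <- 0.55 + 0.35 * sin(ph) + 0.10 * sin(2 * ph + 0.8)
  shape <- shape / max(shape)
  make_waveform(t, peak * shape, period = period)
}

#' Read a waveform from CSV
#'
#' Expects the header `time_s,peak_velocity_m_s`.
#'
#' @param path CSV file path.
#' @return A [make_waveform()] object.
#' @export
read_waveform <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "peak_velocity_m_s") %in% names(df)))
    stop("waveform CSV must have columns time_s, peak_velocity_m_s")
  make_waveform(df$time_s, df$peak_velocity_m_s)
}

#' Write a waveform to CSV
#' @param w a [make_waveform()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_waveform <- function(w, path) {
  utils::write.csv(data.frame(time_s = w$time, peak_velocity_m_s = w$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Parabolic weights for an inlet plane
#'
#' For each inlet lattice site, `w(r) = max(0, 1 - (r/R)^2)` with `r` the
#' in-plane distance from the lumen centroid and `R` the lumen radius on the
#' plane, estimated from the covered area (`sqrt(n dx^2 / pi)`) so the
#' imposed flow rate matches the analytic parabola regardless of how close
#' the outermost site centers fall to the rim. The centroid site gets
#' weight ~1, the rim ~0.
#'
#' @param domain a [voxel_domain()].
#' @param sites inlet site indices.
#' @param normal unit flow direction (defines the plane).
#' @return Numeric weights for `sites`.
#' @export
parabolic_weights <- function(domain, sites, normal) {
  if (!length(sites)) stop("empty inlet")
  ctr <- site_centers(domain)[sites, , drop = FALSE]
  nrm <- normal / sqrt(sum(normal^2))
  proj <- ctr - (ctr %*% nrm) %*% t(nrm)   # in-plane coordinates
  centroid <- colMeans(proj)
  r <- sqrt(rowSums((proj - matrix(centroid, nrow(proj), 3, byrow = TRUE))^2))
  # effective lumen radius from the covered area: robust against how close
  # the outermost site centers happen to fall to the true rim
  R <- max(sqrt(length(sites) / pi) * domain$spacing, max(r) * 1.0000001)
  pmax(0, 1 - (r / R)^2)
}

#' Inlet specification
#'
#' Binds the inlet sites of a domain to a waveform and a flow direction and
#' precomputes the parabolic weights.
#'
#' @param domain a [voxel_domain()].
#' @param waveform a [make_waveform()] object.
#' @param direction unit flow direction (into the domain).
#' @param sites inlet site indices; defaults to all `SITE_INLET` sites.
#' @return An object of class `inlet_spec`.
#' @export
inlet_spec <- function(domain, waveform, direction = c(0, 0, 1),
                       sites = which(domain$site_type == SITE_INLET)) {
  if (!length(sites)) stop("empty inlet")
  direction <- direction / sqrt(sum(direction^2))
  structure(list(sites = sites,
                 weights = parabolic_weights(domain, sites, direction),
                 direction = direction, waveform = waveform),
            class = "inlet_spec")
}

#' Impose a velocity inlet
#'
#' Inlet-site populations are replaced by the equilibrium at the local
#' density and the imposed velocity `weight * peak(t)` along the inlet
#' direction (peak converted to lattice units). Errors out if the requested
#' lattice velocity exceeds the Mach cap.
#'
#' @param f n x 19 population matrix (post-streaming).
#' @param inlet an [inlet_spec()].
#' @param t physical time, s.
#' @param units a [unit_system()].
#' @return Updated population matrix.
#' @export
apply_velocity_inlet <- function(f, inlet, t, units) {
  peak <- eval_waveform(inlet$waveform, t)
  u_lat <- convert_units(peak, "velocity", "to_lattice", units)
  if (abs(u_lat) > max_lattice_velocity())
    stop(sprintf(
      "inlet lattice velocity %g violates the Mach criterion (cap %g)",
      u_lat, max_lattice_velocity()))
  s <- inlet$sites
  rho_loc <- rowSums(f[s, , drop = FALSE])
  uvec <- (inlet$weights * u_lat) %o% inlet$direction
  f[s, ] <- equilibrium(rho_loc, uvec)
  f
}

#' Outlet specification
#'
#' @param domain a [voxel_domain()].
#' @param normal outward unit normal of the outlet plane (axis-aligned).
#' @param sites outlet site indices; defaults to all `SITE_OUTLET` sites.
#' @param rho_out imposed lattice density (Dirichlet pressure
#'   `rho_out * cs2`).
#' @param mode `"dirichlet"` (fixed density, extrapolated velocity) or
#'   `"zero_gradient"` (populations copied from the upstream neighbor).
#' @return An object of class `outlet_spec`.
#' @export
outlet_spec <- function(domain, normal = c(0, 0, 1),
                        sites = which(domain$site_type == SITE_OUTLET),
                        rho_out = 1, mode = c("dirichlet", "zero_gradient")) {
  mode <- match.arg(mode)
  if (!length(sites)) stop("empty outlet")
  if (rho_out <= 0) stop("rho_out must be > 0")
  d <- domain$dims
  ax <- which(abs(normal) > 0.5)
  if (length(ax) != 1) stop("outlet normal must be axis-aligned")
  step <- c(1L, d[1], d[1] * d[2])[ax] * as.integer(-sign(normal[ax]))
  nbr <- sites + step                     # one site inward
  structure(list(sites = sites, nbr = nbr, rho_out = rho_out, mode = mode),
            class = "outlet_spec")
}

#' Impose a pressure (density) outlet
#'
#' Dirichlet closure: outlet populations are set to the equilibrium at the
#' fixed density `rho_out` and the velocity extrapolated from the adjacent
#' interior site. The zero-gradient variant copies the interior neighbor's
#' populations unchanged.
#'
#' @param f n x 19 population matrix (post-streaming).
#' @param outlet an [outlet_spec()].
#' @return Updated population matrix.
#' @export
apply_pressure_outlet <- function(f, outlet) {
  if (outlet$mode == "zero_gradient") {
    f[outlet$sites, ] <- f[outlet$nbr, , drop = FALSE]
    return(f)
  }
  m <- macroscopic_moments(f[outlet$nbr, , drop = FALSE])
  f[outlet$sites, ] <- equilibrium(rep(outlet$rho_out, length(outlet$sites)),
                                   m$u)
  f
}
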