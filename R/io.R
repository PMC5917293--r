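#' Export a field snapshot as VTK ImageData
#'
#' ASCII `.vti` file with per-voxel `rho`, `u` (3-component) and `p` arrays,
#' readable by ParaView and pyvista. Solid sites carry zeros.
#'
#' @param path output path (conventionally ending in `.vti`).
#' @param domain a [voxel_domain()].
#' @param rho lattice density over active sites (in plan order) or all
#'   sites.
#' @param u_lat lattice velocity (matching rows).
#' @param active site indices the field rows correspond to; NULL if the
#'   rows already cover every voxel.
#' @return `path`, invisibly.
#' @export
write_vti <- function(path, domain, rho, u_lat, active = NULL) {
  d <- domain$dims
  n <- prod(d)
  rho_full <- numeric(n); u_full <- matrix(0, n, 3)
  if (is.null(active)) {
    rho_full <- rho; u_full <- u_lat
  } else {
    rho_full[active] <- rho
    u_full[active, ] <- u_lat
  }
  p_full <- ifelse(rho_full > 0, equation_of_state(pmax(rho_full, 0)), 0)
  con <- file(path, "w")
  on.exit(close(con))
  sp <- domain$spacing
  writeLines(c(
    '<?xml version="1.0"?>',
    '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">',
    sprintf('  <ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="%g %g %g" Spacing="%g %g %g">',
            d[1] - 1L, d[2] - 1L, d[3] - 1L,
            domain$origin[1] + sp / 2, domain$origin[2] + sp / 2,
            domain$origin[3] + sp / 2, sp, sp, sp),
    sprintf('    <Piece Extent="0 %d 0 %d 0 %d">', d[1] - 1L, d[2] - 1L, d[3] - 1L),
    '      <PointData Scalars="rho" Vectors="u">',
    '        <DataArray type="Float64" Name="rho" format="ascii">'), con)
  writeLines(paste(format(rho_full, digits = 9), collapse = " "), con)
  writeLines(c('        </DataArray>',
               '        <DataArray type="Float64" Name="u" NumberOfComponents="3" format="ascii">'),
             con)
  writeLines(paste(format(as.vector(t(u_full)), digits = 9), collapse = " "), con)
  writeLines(c('        </DataArray>',
               '        <DataArray type="Float64" Name="p" format="ascii">'),
             con)
  writeLines(paste(format(p_full, digits = 9), collapse = " "), con)
  writeLines(c('        </DataArray>', '      </PointData>', '    </Piece>',
               '  </ImageData>', '</VTKFile>'), con)
  invisible(path)
}

#' Write particle trajectory snapshots to CSV
#'
#' Columns: `step,time_s,id,x,y,z,ux,uy,uz,Fmag_x,Fmag_y,Fmag_z`.
#'
#' @param trajectories the snapshot data frame of an `mdt_run`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE)
  invisible(path)
}

#' Write a region-of-interest occupancy time series to CSV
#'
#' @param roi_series data frame with `step`, `time_s`, `count`, `fraction`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_roi_series <- function(roi_series, path) {
  utils::write.csv(roi_series, path, row.names = FALSE)
  invisible(path)
}

#' Build a simulation configuration from a YAML run description
#'
#' Minimal structured-YAML front end for shell-driven runs. Supported keys:
#' `geometry` (`kind: cylinder|curved_tube|file` plus dimensions or `path`),
#' `units` (`delta_x_m` and either `delta_t_s` or `u_phys_max_m_s`), `fluid`
#' (`mu_Pa_s`, `rho_kg_m3`, `temperature_K`), `wall_scheme`, `inlet`
#' (`waveform_csv` or `peak_velocity_m_s` + `bpm`, `direction`), `outlet`
#' (`rho_out`, `mode`, `normal`), `body_force_Pa_per_m`, `magnet`
#' (`position_m`, `moment_A_m2`), `particles` (`n`, `a_m`, `coating_m`,
#' `chi_v`, `rho_p`, `seed_sphere` with `center_m`/`radius_m`, `min_sep_m`),
#' `forces` (toggle map plus `coupling`), `roi` (`sphere`/`box`), `steps`,
#' `output_every`, `seed`.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_config_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  geo <- y$geometry
  dom <- switch(geo$kind,
    cylinder = voxelize_cylinder(geo$radius_m, geo$length_m, geo$spacing_m,
                                 periodic = isTRUE(geo$periodic)),
    curved_tube = voxelize_curved_tube(geo$radius_m, geo$bend_radius_m,
                                       geo$arc_rad %||% (pi / 2),
                                       geo$spacing_m),
    file = read_voxel_domain(geo$path),
    stop("unknown geometry kind: ", geo$kind))
  props <- fluid_properties(mu = y$fluid$mu_Pa_s %||% 0.004,
                            rho = y$fluid$rho_kg_m3 %||% 1000,
                            temperature = y$fluid$temperature_K %||% 310.15)
  units <- unit_system(delta_x = y$units$delta_x_m,
                       delta_t = y$units$delta_t_s,
                       rho = props$rho,
                       u_phys_max = y$units$u_phys_max_m_s)
  inlets <- list()
  if (!is.null(y$inlet)) {
    wf <- if (!is.null(y$inlet$waveform_csv)) {
      read_waveform(y$inlet$waveform_csv)
    } else {
      pulse_waveform(y$inlet$peak_velocity_m_s, y$inlet$bpm %||% 68)
    }
    inlets <- list(inlet_spec(dom, wf,
                              direction = unlist(y$inlet$direction %||% c(0, 0, 1))))
  }
  outlet <- NULL
  if (!is.null(y$outlet)) {
    outlet <- outlet_spec(dom, normal = unlist(y$outlet$normal %||% c(0, 0, 1)),
                          rho_out = y$outlet$rho_out %||% 1,
                          mode = y$outlet$mode %||% "dirichlet")
  }
  particles <- NULL
  if (!is.null(y$particles)) {
    p <- y$particles
    x0 <- seed_particles_in_sphere(p$count, unlist(p$seed_sphere$center_m),
                                   p$seed_sphere$radius_m,
                                   min_sep = p$min_sep_m %||% 0,
                                   seed = derive_seed(y$seed %||% 1L, 1L))
    particles <- particle_system(x0, a = p$a_m, a_c = p$coating_m %||% 0,
                                 chi_v = p$chi_v %||% 5.7,
                                 rho_p = p$rho_p %||% 5170)
  }
  mg <- if (!is.null(y$magnet)) {
    magnet(unlist(y$magnet$position_m), unlist(y$magnet$moment_A_m2))
  } else NULL
  fp <- force_params(enable = y$forces$enable %||% list(),
                     gravity = unlist(y$forces$gravity %||% c(0, 0, 0)),
                     coupling = y$forces$coupling %||% "one_way",
                     temperature = props$temperature)
  roi <- if (!is.null(y$roi)) {
    if (y$roi$shape == "sphere") {
      region_of_interest("sphere", center = unlist(y$roi$center_m),
                         radius = y$roi$radius_m)
    } else {
      region_of_interest("box", bounds = rbind(unlist(y$roi$lower_m),
                                               unlist(y$roi$upper_m)))
    }
  } else NULL
  simulation_config(dom, units, props,
                    wall_scheme = y$wall_scheme %||% "bfl",
                    inlets = inlets, outlet = outlet,
                    body_force_phys = unlist(y$body_force_Pa_per_m %||% c(0, 0, 0)),
                    particles = particles, mg = mg, params = fp, roi = roi,
                    n_steps = y$steps %||% 1000L,
                    output_every = y$output_every %||% 100L,
                    seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
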