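#' @name site-types
#' @title Voxel site type codes
#' @description Integer codes classifying each voxel: solid wall (0), bulk
#'   fluid (1), inlet (2), outlet (3). Inlet and outlet sites carry
#'   populations like fluid sites but are overwritten by boundary
#'   conditions each step.
#' @export
SITE_SOLID <- 0L
#' @rdname site-types
#' @export
SITE_FLUID <- 1L
#' @rdname site-types
#' @export
SITE_INLET <- 2L
#' @rdname site-types
#' @export
SITE_OUTLET <- 3L

#' Construct a voxelized simulation domain
#'
#' Voxel `(i, j, k)` has its center at `origin + (c(i, j, k) - 0.5) * spacing`
#' (physical meters); all particle positions are continuous physical
#' coordinates. Fixtures carry an analytic surface handle enabling exact
#' wall-distance queries; mask-only domains fall back to half-way wall cuts
#' (`q = 1/2`) and a voxel distance transform.
#'
#' @param dims integer 3-vector of voxel counts.
#' @param spacing lattice spacing (m).
#' @param site_type integer vector of length `prod(dims)` in x-fastest
#'   order, using the `SITE_*` codes.
#' @param origin physical position of the grid corner (m).
#' @param periodic logical 3-vector; periodic axes wrap in streaming.
#' @param surface optional analytic surface handle (see fixtures).
#' @return An object of class `voxel_domain`.
#' @export
voxel_domain <- function(dims, spacing, site_type,
                         origin = c(0, 0, 0), periodic = c(FALSE, FALSE, FALSE),
                         surface = NULL) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), spacing > 0,
            length(site_type) == prod(dims))
  structure(list(dims = dims, spacing = spacing,
                 site_type = as.integer(site_type),
                 origin = as.numeric(origin), periodic = periodic,
                 surface = surface, wall_links = NULL),
            class = "voxel_domain")
}

#' @export
print.voxel_domain <- function(x, ...) {
  tab <- table(factor(x$site_type, levels = 0:3,
                      labels = c("solid", "fluid", "inlet", "outlet")))
  cat("voxel_domain ", paste(x$dims, collapse = " x "),
      " @ ", format(x$spacing), " m\n  ", sep = "")
  cat(paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

# physical centers of all voxels (n x 3), x-fastest order
site_centers <- function(domain) {
  d <- domain$dims
  idx <- seq_len(prod(d))
  ix <- ((idx - 1L) %% d[1]) + 1L
  iy <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  iz <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
  cbind(domain$origin[1] + (ix - 0.5) * domain$spacing,
        domain$origin[2] + (iy - 0.5) * domain$spacing,
        domain$origin[3] + (iz - 0.5) * domain$spacing)
}

# signed distance to the vessel surface: negative inside the lumen.
# Vectorized over rows of p (n x 3).
surface_sdf <- function(surface, p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  switch(surface$type,
    cylinder = {
      r <- sqrt((p[, 1] - surface$center[1])^2 + (p[, 2] - surface$center[2])^2)
      r - surface$radius
    },
    channel = {
      pmax(surface$y_lo - p[, 2], p[, 2] - surface$y_hi)
    },
    torus = {
      rad <- sqrt(p[, 1]^2 + p[, 2]^2)
      sqrt((rad - surface$bend_radius)^2 + p[, 3]^2) - surface$radius
    },
    stop("unknown surface type: ", surface$type)
  )
}

#' Straight cylindrical vessel fixture
#'
#' Axis along z. A voxel is fluid iff its center lies strictly inside the
#' cylinder. In flow-through mode the first and last z-layers of the lumen
#' are marked inlet and outlet; in periodic mode the z-axis wraps (used by
#' the body-force-driven Poiseuille benchmarks).
#'
#' @param radius lumen radius, m (must be at least `2 * spacing`).
#' @param length axial extent, m.
#' @param spacing lattice spacing, m.
#' @param periodic if TRUE the tube is periodic along z with no
#'   inlet/outlet.
#' @return A [voxel_domain()] with an analytic cylinder surface handle.
#' @export
voxelize_cylinder <- function(radius, length, spacing, periodic = FALSE) {
  if (radius < 2 * spacing) stop("radius must be >= 2 * spacing")
  nr <- ceiling(radius / spacing)
  nx <- 2L * nr + 3L
  nz <- max(1L, as.integer(round(length / spacing)))
  cx <- (nx / 2) * spacing               # lumen axis at grid center
  surface <- list(type = "cylinder", center = c(cx, cx), radius = radius,
                  length = nz * spacing)
  dom <- voxel_domain(c(nx, nx, nz), spacing,
                      site_type = integer(nx * nx * nz),
                      periodic = c(FALSE, FALSE, periodic),
                      surface = surface)
  ctr <- site_centers(dom)
  fluid <- surface_sdf(surface, ctr) < 0
  type <- ifelse(fluid, SITE_FLUID, SITE_SOLID)
  if (!periodic) {
    iz <- ((seq_along(type) - 1L) %/% (nx * nx)) + 1L
    type[fluid & iz == 1L] <- SITE_INLET
    type[fluid & iz == nz] <- SITE_OUTLET
    # particles beyond the last site layer have left through the outlet
    dom$exit_planes <- list(list(axis = 3L,
                                 value = dom$origin[3] + (nz - 0.5) * spacing,
                                 dir = 1))
  }
  dom$site_type <- as.integer(type)
  dom
}

#' Curved-tube (torus-section) vessel fixture
#'
#' Lumen of radius `radius` swept along a circular arc of radius
#' `bend_radius` lying in the x-y plane and centered at the grid origin
#' corner; the arc runs from angle 0 (inlet plane y = 0, flow along +y) up
#' to `arc` radians. With `arc = pi/2` the outlet plane is x = 0 with flow
#' along -x, keeping both ports axis-aligned.
#'
#' @param radius lumen radius, m.
#' @param bend_radius radius of the center-line arc, m; must exceed
#'   `radius`.
#' @param arc arc angle in radians, in (0, pi/2].
#' @param spacing lattice spacing, m.
#' @return A [voxel_domain()] with an analytic torus surface handle.
#' @export
voxelize_curved_tube <- function(radius, bend_radius, arc = pi / 2, spacing) {
  if (bend_radius <= radius) stop("bend_radius must exceed radius (self-intersecting tube)")
  if (radius < 2 * spacing) stop("radius must be >= 2 * spacing")
  if (arc <= 0 || arc > pi / 2) stop("arc must be in (0, pi/2]")
  ext <- bend_radius + radius + 2 * spacing
  nx <- as.integer(ceiling(ext / spacing))
  nyv <- nx
  nzv <- as.integer(2 * ceiling(radius / spacing) + 3L)
  surface <- list(type = "torus", bend_radius = bend_radius, radius = radius,
                  arc = arc)
  dom <- voxel_domain(c(nx, nyv, nzv), spacing,
                      site_type = integer(nx * nyv * nzv),
                      origin = c(0, 0, -(nzv / 2) * spacing),
                      surface = surface)
  ctr <- site_centers(dom)
  theta <- atan2(ctr[, 2], ctr[, 1])
  inside <- surface_sdf(surface, ctr) < 0 & theta >= 0 & theta <= arc
  type <- ifelse(inside, SITE_FLUID, SITE_SOLID)
  d <- dom$dims
  idx <- seq_len(prod(d))
  ixv <- ((idx - 1L) %% d[1]) + 1L
  iyv <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
  type[inside & iyv == 1L] <- SITE_INLET
  if (abs(arc - pi / 2) < 1e-12) {
    type[inside & ixv == 1L] <- SITE_OUTLET
    dom$exit_planes <- list(list(axis = 1L,
                                 value = dom$origin[1] + 0.5 * spacing,
                                 dir = -1))
  } else {
    # outlet: last layer of voxels before the arc end plane
    dtheta <- spacing / bend_radius
    type[inside & theta > arc - dtheta] <- SITE_OUTLET
  }
  dom$site_type <- as.integer(type)
  dom
}

#' Fully periodic fluid box
#'
#' Every site fluid, all axes periodic. Used by conservation and shear-wave
#' benchmarks.
#'
#' @param dims integer 3-vector.
#' @param spacing lattice spacing, m.
#' @return A [voxel_domain()].
#' @export
periodic_box <- function(dims, spacing = 1) {
  voxel_domain(dims, spacing, rep(SITE_FLUID, prod(dims)),
               periodic = c(TRUE, TRUE, TRUE))
}

#' Plane channel fixture
#'
#' Fluid slab bounded by two plane walls normal to y, periodic along x and
#' z. The walls sit at a fraction `q_wall` of the link between the last
#' fluid site center and the adjacent solid site center, so non-half-way
#' wall cuts can be exercised.
#'
#' @param nx,ny,nz voxel counts; `ny` counts fluid layers (one solid layer
#'   is added on each side).
#' @param spacing lattice spacing, m.
#' @param q_wall wall-cut fraction in (0, 1].
#' @return A [voxel_domain()] with an analytic channel surface handle.
#' @export
channel_domain <- function(nx, ny, nz, spacing = 1, q_wall = 0.5) {
  ny_tot <- ny + 2L
  d <- c(nx, ny_tot, nz)
  idx <- seq_len(prod(d))
  iy <- (((idx - 1L) %/% nx) %% ny_tot) + 1L
  type <- ifelse(iy >= 2L & iy <= ny + 1L, SITE_FLUID, SITE_SOLID)
  y_lo <- (1.5 - q_wall) * spacing       # wall plane below first fluid layer
  y_hi <- (ny + 0.5 + q_wall) * spacing
  surface <- list(type = "channel", y_lo = y_lo, y_hi = y_hi)
  voxel_domain(d, spacing, type, periodic = c(TRUE, FALSE, TRUE),
               surface = surface)
}

#' Compute wall-link cut fractions
#'
#' For every fluid site and lattice direction crossing into a solid (or
#' out-of-domain) voxel, the fraction `q` in (0, 1] of the link at which the
#' vessel surface is crossed. With an analytic surface handle the crossing
#' is located by bisection of the signed distance along the link (absolute
#' tolerance 1e-12 of the link length); mask-only domains use `q = 1/2`
#' (plain half-way bounce-back accuracy).
#'
#' @param domain a [voxel_domain()].
#' @return The domain with its `wall_links` table populated (`key` =
#'   `"<site>_<dir>"`, `q`).
#' @export
compute_wall_links <- function(domain) {
  st <- stencil()
  d <- domain$dims
  nx <- d[1]; ny <- d[2]; nz <- d[3]
  n <- prod(d)
  type <- domain$site_type
  active <- type != SITE_SOLID
  idx <- seq_len(n)
  ix <- ((idx - 1L) %% nx) + 1L
  iy <- (((idx - 1L) %/% nx) %% ny) + 1L
  iz <- ((idx - 1L) %/% (nx * ny)) + 1L
  keys <- character(0); qs <- numeric(0)
  for (i in 2:19) {
    ci <- st$c[i, ]
    jx <- ix + ci[1]; jy <- iy + ci[2]; jz <- iz + ci[3]
    inside <- rep(TRUE, n)
    if (domain$periodic[1]) jx <- ((jx - 1L) %% nx) + 1L else inside <- inside & jx >= 1L & jx <= nx
    if (domain$periodic[2]) jy <- ((jy - 1L) %% ny) + 1L else inside <- inside & jy >= 1L & jy <= ny
    if (domain$periodic[3]) jz <- ((jz - 1L) %% nz) + 1L else inside <- inside & jz >= 1L & jz <= nz
    nbr <- jx + (jy - 1L) * nx + (jz - 1L) * nx * ny
    is_wall <- type == SITE_FLUID & (!inside | !active[pmin(pmax(nbr, 1L), n)])
    w <- which(is_wall)
    if (!length(w)) next
    if (is.null(domain$surface)) {
      q <- rep(0.5, length(w))
    } else {
      p0 <- cbind(domain$origin[1] + (ix[w] - 0.5) * domain$spacing,
                  domain$origin[2] + (iy[w] - 0.5) * domain$spacing,
                  domain$origin[3] + (iz[w] - 0.5) * domain$spacing)
      dirseg <- matrix(ci, length(w), 3, byrow = TRUE) * domain$spacing
      s0 <- surface_sdf(domain$surface, p0)
      s1 <- surface_sdf(domain$surface, p0 + dirseg)
      q <- bisect_crossing(domain$surface, p0, dirseg, s0, s1)
    }
    keys <- c(keys, paste0(w, "_", i))
    qs <- c(qs, q)
  }
  domain$wall_links <- list(key = keys, q = qs)
  domain
}

# vectorized bisection for the surface crossing fraction along links.
# Links whose endpoints do not bracket a sign change (voxelization corner
# cases) fall back to q = 1/2.
bisect_crossing <- function(surface, p0, dirseg, s0, s1, iters = 45L) {
  m <- length(s0)
  lo <- rep(0, m); hi <- rep(1, m)
  ok <- s0 < 0 & s1 >= 0
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    sm <- surface_sdf(surface, p0 + dirseg * mid)
    below <- sm < 0
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  q <- (lo + hi) / 2
  q[!ok] <- 0.5
  q[q <= 0] <- .Machine$double.eps
  q
}

#' Vector from a point to the nearest vessel wall
#'
#' Exact for fixtures with an analytic surface handle; mask-only domains use
#' the distance to the nearest solid voxel center reduced by half a voxel
#' (documented accuracy downgrade).
#'
#' @param domain a [voxel_domain()].
#' @param x positions, n x 3 matrix (or length-3 vector), physical m.
#' @return n x 3 matrix of particle-to-wall vectors `r_w`.
#' @export
nearest_wall_vector <- function(domain, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  s <- domain$surface
  if (!is.null(s)) {
    switch(s$type,
      cylinder = {
        dx <- x[, 1] - s$center[1]; dy <- x[, 2] - s$center[2]
        r <- sqrt(dx^2 + dy^2)
        ux <- ifelse(r > 0, dx / r, 1)
        uy <- ifelse(r > 0, dy / r, 0)
        cbind(ux * (s$radius - r), uy * (s$radius - r), 0)
      },
      channel = {
        d_lo <- x[, 2] - s$y_lo
        d_hi <- s$y_hi - x[, 2]
        lo_closer <- d_lo <= d_hi
        cbind(0, ifelse(lo_closer, -d_lo, d_hi), 0)
      },
      torus = {
        rad <- sqrt(x[, 1]^2 + x[, 2]^2)
        ex <- ifelse(rad > 0, x[, 1] / rad, 1)
        ey <- ifelse(rad > 0, x[, 2] / rad, 0)
        # closest point on the centre-line circle, then radial to surface
        px <- rad - s$bend_radius
        pr <- sqrt(px^2 + x[, 3]^2)
        ur <- ifelse(pr > 0, px / pr, 1)
        uz <- ifelse(pr > 0, x[, 3] / pr, 0)
        gap <- s$radius - pr
        cbind(ex * ur * gap, ey * ur * gap, uz * gap)
      },
      stop("unknown surface type")
    )
  } else {
    nearest_wall_vector_mask(domain, x)
  }
}

# mask fallback: nearest solid voxel center via brute force against the
# solid shell (solid voxels adjacent to fluid); adequate at desk scale.
nearest_wall_vector_mask <- function(domain, x) {
  shell <- .mdt_cache[[paste0("shell_", substr(digest_key(domain), 1, 16))]]
  if (is.null(shell)) {
    plan_type <- domain$site_type
    d <- domain$dims
    n <- prod(d)
    st <- stencil()
    idx <- seq_len(n)
    ix <- ((idx - 1L) %% d[1]) + 1L
    iy <- (((idx - 1L) %/% d[1]) %% d[2]) + 1L
    iz <- ((idx - 1L) %/% (d[1] * d[2])) + 1L
    is_shell <- rep(FALSE, n)
    solid <- plan_type == SITE_SOLID
    for (i in 2:7) {                    # axis neighbors suffice for a shell
      ci <- st$c[i, ]
      jx <- pmin(pmax(ix + ci[1], 1L), d[1])
      jy <- pmin(pmax(iy + ci[2], 1L), d[2])
      jz <- pmin(pmax(iz + ci[3], 1L), d[3])
      nbr <- jx + (jy - 1L) * d[1] + (jz - 1L) * d[1] * d[2]
      is_shell <- is_shell | (solid & plan_type[nbr] != SITE_SOLID)
    }
    ctr <- site_centers(domain)
    shell <- ctr[is_shell, , drop = FALSE]
    .mdt_cache[[paste0("shell_", substr(digest_key(domain), 1, 16))]] <- shell
  }
  out <- matrix(0, nrow(x), 3)
  for (k in seq_len(nrow(x))) {
    dv <- sweep(shell, 2, x[k, ])
    j <- which.min(rowSums(dv * dv))
    v <- dv[j, ]
    nv <- sqrt(sum(v^2))
    # wall surface approximated half a voxel inside the solid center
    out[k, ] <- v * max(nv - domain$spacing / 2, 0) / nv
  }
  out
}

# signed wall clearance and inward normal at arbitrary points.
# clearance = distance from the point to the vessel surface, measured into
# the fluid (negative if the point lies outside the lumen); inward = unit
# direction of increasing clearance. Used by the lubrication solve and the
# contact projection, which must behave sensibly on both sides of the wall.
wall_clearance <- function(domain, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3)
  s <- domain$surface
  if (!is.null(s)) {
    clear <- -surface_sdf(s, x)
    inward <- switch(s$type,
      cylinder = {
        dx <- x[, 1] - s$center[1]; dy <- x[, 2] - s$center[2]
        r <- sqrt(dx^2 + dy^2)
        cbind(-ifelse(r > 0, dx / r, 1), -ifelse(r > 0, dy / r, 0), 0)
      },
      channel = {
        d_lo <- x[, 2] - s$y_lo
        d_hi <- s$y_hi - x[, 2]
        cbind(0, ifelse(d_lo <= d_hi, 1, -1), 0)
      },
      torus = {
        rad <- sqrt(x[, 1]^2 + x[, 2]^2)
        ex <- ifelse(rad > 0, x[, 1] / rad, 1)
        ey <- ifelse(rad > 0, x[, 2] / rad, 0)
        px <- rad - s$bend_radius
        pr <- sqrt(px^2 + x[, 3]^2)
        ur <- ifelse(pr > 0, px / pr, 1)
        uz <- ifelse(pr > 0, x[, 3] / pr, 0)
        cbind(-ex * ur, -ey * ur, -uz)
      })
    list(clearance = clear, inward = inward)
  } else {
    rw <- nearest_wall_vector_mask(domain, x)
    d <- sqrt(rowSums(rw * rw))
    list(clearance = d, inward = -rw / pmax(d, .Machine$double.xmin))
  }
}

digest_key <- function(domain) {
  paste0(paste(domain$dims, collapse = "x"), "_",
         format(domain$spacing), "_", sum(domain$site_type == SITE_SOLID))
}

# ---------------------------------------------------------------------------
# Voxel-mask file I/O: JSON sidecar header + raw uint8 body (x-fastest).

#' Write a voxel domain to disk
#'
#' Two files are produced: `<path>` holds the site types as raw
#' little-endian uint8 bytes in x-fastest order, and `<path>.json` is a JSON
#' sidecar header with `dims`, `spacing_m`, `origin_m` and the site type
#' code table. Analytic surface handles are not serialized; a re-read domain
#' is mask-only.
#'
#' @param domain a [voxel_domain()].
#' @param path body file path; the header gains a `.json` suffix.
#' @return `path`, invisibly.
#' @export
write_voxel_domain <- function(domain, path) {
  header <- list(dims = domain$dims, spacing_m = domain$spacing,
                 origin_m = domain$origin, periodic = domain$periodic,
                 site_type_codes = list(solid = SITE_SOLID, fluid = SITE_FLUID,
                                        inlet = SITE_INLET, outlet = SITE_OUTLET))
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  writeBin(as.raw(domain$site_type), path)
  invisible(path)
}

#' Read a voxel domain from disk
#'
#' Counterpart of [write_voxel_domain()]. The body must contain exactly
#' `prod(dims)` bytes; anything else is a format error.
#'
#' @param path body file path (with `<path>.json` header alongside).
#' @return A mask-only [voxel_domain()].
#' @export
read_voxel_domain <- function(path) {
  hpath <- paste0(path, ".json")
  if (!file.exists(hpath)) stop("missing voxel-mask header: ", hpath)
  header <- jsonlite::read_json(hpath, simplifyVector = TRUE)
  if (is.null(header$dims) || length(header$dims) != 3)
    stop("malformed voxel-mask header: dims")
  n <- prod(header$dims)
  body <- readBin(path, "raw", n = n + 1L)
  if (length(body) != n)
    stop("voxel-mask body size mismatch: expected ", n, " bytes, found ",
         length(body))
  voxel_domain(header$dims, header$spacing_m, as.integer(body),
               origin = header$origin_m,
               periodic = as.logical(header$periodic))
}

# ---------------------------------------------------------------------------
# Regions of interest and particle seeding.

#' Region of interest
#'
#' Spherical or box-shaped target volume in which the instantaneous particle
#' count defines the targeting efficiency. The boundary is closed: points
#' exactly on the surface count as inside.
#'
#' @param shape `"sphere"` or `"box"`.
#' @param center sphere center (m).
#' @param radius sphere radius (m).
#' @param bounds for boxes, a 2 x 3 matrix `rbind(lower, upper)` (m).
#' @return An object of class `roi`.
#' @export
region_of_interest <- function(shape = c("sphere", "box"), center = NULL,
                               radius = NULL, bounds = NULL) {
  shape <- match.arg(shape)
  if (shape == "sphere") {
    stopifnot(length(center) == 3, is.numeric(radius), radius > 0)
  } else {
    stopifnot(is.matrix(bounds), nrow(bounds) == 2, ncol(bounds) == 3,
              all(bounds[2, ] > bounds[1, ]))
  }
  structure(list(shape = shape, center = center, radius = radius,
                 bounds = bounds), class = "roi")
}

#' Count particles inside a region of interest
#'
#' @param positions n x 3 matrix of particle positions (m).
#' @param roi a [region_of_interest()].
#' @return List with `count` and `fraction` (percentage of the total).
#' @export
count_in_roi <- function(positions, roi) {
  if (is.null(dim(positions))) positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  if (n == 0L) stop("empty particle set")
  inside <- if (roi$shape == "sphere") {
    d2 <- (positions[, 1] - roi$center[1])^2 +
      (positions[, 2] - roi$center[2])^2 +
      (positions[, 3] - roi$center[3])^2
    d2 <= roi$radius^2
  } else {
    positions[, 1] >= roi$bounds[1, 1] & positions[, 1] <= roi$bounds[2, 1] &
      positions[, 2] >= roi$bounds[1, 2] & positions[, 2] <= roi$bounds[2, 2] &
      positions[, 3] >= roi$bounds[1, 3] & positions[, 3] <= roi$bounds[2, 3]
  }
  cnt <- sum(inside)
  list(count = cnt, fraction = 100 * cnt / n)
}

#' Seed non-overlapping particle positions in a sphere
#'
#' Rejection sampling of uniform positions within a sphere subject to a
#' minimum pairwise separation. Reproducible under a fixed seed; errors out
#' if the requested packing cannot be achieved within a bounded number of
#' rejection rounds.
#'
#' @param n number of particles.
#' @param center sphere center (m).
#' @param radius sphere radius (m).
#' @param min_sep minimum center-to-center separation (m).
#' @param seed integer RNG seed.
#' @param max_rounds rejection budget per particle.
#' @return n x 3 matrix of positions.
#' @export
seed_particles_in_sphere <- function(n, center, radius, min_sep = 0,
                                     seed = 1L, max_rounds = 10000L) {
  stopifnot(n >= 1, radius > 0, min_sep >= 0)
  rng <- local_rng(seed)
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > max_rounds * n)
      stop("seed_particles_in_sphere: packing too dense after ",
           tries, " rejections")
    u <- rng$runif(3)
    p <- center + radius * (2 * u - 1)
    if (sum((p - center)^2) > radius^2) next
    if (placed > 0L && min_sep > 0) {
      d2 <- rowSums((pos[seq_len(placed), , drop = FALSE] -
                       matrix(p, placed, 3, byrow = TRUE))^2)
      if (any(d2 < min_sep^2)) next
    }
    placed <- placed + 1L
    pos[placed, ] <- p
  }
  pos
}

# small wrapper giving a private RNG stream without touching the global
# .Random.seed observed by the caller
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed %% .Machine$integer.max))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  with_state <- function(fun) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    fun()
  }
  list(
    runif = function(n) with_state(function() stats::runif(n)),
    rnorm = function(n, sd = 1) with_state(function() stats::rnorm(n, sd = sd))
  )
}

# derive a bounded sub-seed from a master seed and a stream id so that
# subsystems (seeding, Brownian noise) draw from independent streams
derive_seed <- function(master, stream_id) {
  as.integer((as.double(master) * 69069 + stream_id * 104729) %% 2147483647)
}
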