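#' Synthetic surface-patch fixtures
#'
#' Deterministic stand-ins for the anatomical patch the pipeline targets (a
#' roughly 20 mm diameter region cut from a humeral head). Three families are
#' provided: a spherical cap (the demonstration geometry: same footprint scale
#' and smooth convex curvature as the anatomical patch), a wavy plate (an
#' irregular-surface stress fixture) and a flat plate (the planar-limit oracle
#' for the lattice generator). All fixtures are height fields — single-valued
#' z over the build plane — because a 4-DOF arm holding the nozzle vertically
#' can only deposit on upward-facing surfaces.
#'
#' Tessellation is a structured triangulated grid in the (x, y) footprint
#' lifted onto the surface, so face counts are reproducible and every call
#' with the same spec is byte-identical.
#'
#' @name synthetic-fixtures
NULL

#' Spherical-cap fixture
#'
#' A cap of the sphere of radius `sphere_radius`, with rim in the z = 0 plane
#' and circular footprint of diameter `cap_diameter` centred on the origin.
#' Every vertex lies on the sphere (centred at depth `-sqrt(R^2 - (D/2)^2)`)
#' to within floating-point roundoff; the apex height above the rim is the
#' sagitta `R - sqrt(R^2 - (D/2)^2)`.
#'
#' @param cap_diameter footprint diameter (mm).
#' @param sphere_radius sphere radius (mm); must be at least `cap_diameter/2`.
#' @param resolution target edge length of the tessellation (mm).
#' @return A [triangle_mesh()] with all face normals pointing upward.
#' @export
#' @examples
#' cap <- make_spherical_cap(cap_diameter = 20, sphere_radius = 25,
#'                           resolution = 1)
#' mesh_summary(cap)
make_spherical_cap <- function(cap_diameter = 20, sphere_radius = 25,
                               resolution = 0.5) {
  stopifnot(cap_diameter > 0, resolution > 0)
  if (cap_diameter > 2 * sphere_radius) {
    stop("cap_diameter (", cap_diameter, " mm) exceeds the sphere diameter (",
         2 * sphere_radius, " mm): no such cap exists", call. = FALSE)
  }
  rim <- cap_diameter / 2
  zc <- -sqrt(sphere_radius^2 - rim^2)   # sphere centre depth; rim at z = 0
  n_ring <- max(1L, ceiling(rim / resolution))
  n_theta <- max(8L, 4L * ceiling(pi * cap_diameter / (4 * resolution)))
  lift <- function(x, y) {
    r2 <- pmin(x^2 + y^2, sphere_radius^2)
    sqrt(sphere_radius^2 - r2) + zc
  }
  polar_grid_mesh(rim, n_ring, n_theta, lift)
}

#' Wavy-plate fixture
#'
#' Height field `z = amplitude * sin(2*pi*x/wavelength) *
#' sin(2*pi*y/wavelength)` over the square footprint `[0, extent]^2`. With
#' `amplitude = 0` this reduces exactly to [make_flat_plate()]. An optional
#' deterministic in-plane jitter (seeded) perturbs interior grid vertices to
#' exercise irregular tessellations.
#'
#' @param extent footprint side length (mm).
#' @param amplitude wave amplitude (mm).
#' @param wavelength wave period (mm); must be positive.
#' @param resolution target edge length (mm).
#' @param jitter fraction of the grid pitch by which interior vertices are
#'   displaced in-plane (default 0: regular grid).
#' @param seed RNG seed for the jitter (ignored when `jitter = 0`).
#' @return A [triangle_mesh()].
#' @export
make_wavy_patch <- function(extent = 20, amplitude = 1, wavelength = 10,
                            resolution = 0.5, jitter = 0, seed = 0L) {
  stopifnot(extent > 0, resolution > 0, jitter >= 0, jitter < 0.5)
  if (wavelength <= 0) {
    stop("wavelength must be positive (got ", wavelength, ")", call. = FALSE)
  }
  lift <- function(x, y) {
    amplitude * sin(2 * pi * x / wavelength) * sin(2 * pi * y / wavelength)
  }
  square_grid_mesh(extent, resolution, lift, jitter = jitter, seed = seed)
}

#' Flat-plate fixture
#'
#' A planar square plate at z = 0 over `[0, extent]^2`. At `resolution >=
#' extent` this is the minimal two-triangle plate. The planar limit is the
#' oracle for the lattice generator: slicing it must reproduce the classic
#' planar grid infill.
#'
#' @inheritParams make_wavy_patch
#' @return A [triangle_mesh()] whose face normals are all +z.
#' @export
make_flat_plate <- function(extent = 10, resolution = 1) {
  stopifnot(extent > 0, resolution > 0)
  square_grid_mesh(extent, resolution, function(x, y) rep(0, length(x)))
}

# Structured square grid on [0, extent]^2 lifted by z = lift(x, y).
square_grid_mesh <- function(extent, resolution, lift, jitter = 0, seed = 0L) {
  n <- max(1L, ceiling(extent / resolution))
  s <- seq(0, extent, length.out = n + 1L)
  g <- expand.grid(x = s, y = s, KEEP.OUT.ATTRS = FALSE)
  x <- g$x
  y <- g$y
  if (jitter > 0) {
    pitch <- extent / n
    interior <- x > 0 & x < extent & y > 0 & y < extent
    rng <- local({set.seed(seed); matrix(stats::runif(2 * sum(interior), -1, 1),
                                         ncol = 2)})
    x[interior] <- x[interior] + jitter * pitch * rng[, 1]
    y[interior] <- y[interior] + jitter * pitch * rng[, 2]
  }
  v <- cbind(x = x, y = y, z = lift(x, y))
  # cell (i, j): corners in column-major vertex numbering
  idx <- function(i, j) (j - 1L) * (n + 1L) + i
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  a <- idx(i, j); b <- idx(i + 1L, j); cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
  faces <- rbind(cbind(a, b, cc), cbind(a, cc, d))   # CCW from +z
  triangle_mesh(v, faces)
}

# Structured polar grid on the disc of radius rim, lifted by z = lift(x, y).
# n_ring radial rings, n_theta angular sectors; apex fan + ring quads.
polar_grid_mesh <- function(rim, n_ring, n_theta, lift) {
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[seq_len(n_theta)]
  radii <- rim * seq_len(n_ring) / n_ring
  x <- c(0, as.vector(outer(cos(theta), radii)))
  y <- c(0, as.vector(outer(sin(theta), radii)))
  v <- cbind(x = x, y = y, z = lift(x, y))
  ring_start <- function(k) 1L + (k - 1L) * n_theta   # 0-based offset + centre
  nxt <- c(seq_len(n_theta - 1L) + 1L, 1L)
  # fan: centre to ring 1 (CCW from +z)
  r1 <- ring_start(1L) + seq_len(n_theta)
  faces <- matrix(c(rep(1L, n_theta), r1, ring_start(1L) + nxt), ncol = 3)
  if (n_ring > 1L) {
    for (k in seq_len(n_ring - 1L)) {
      inner <- ring_start(k) + seq_len(n_theta)
      outer_ <- ring_start(k + 1L) + seq_len(n_theta)
      inner_n <- ring_start(k) + nxt
      outer_n <- ring_start(k + 1L) + nxt
      faces <- rbind(faces,
                     cbind(inner, outer_, outer_n),
                     cbind(inner, outer_n, inner_n))
    }
  }
  triangle_mesh(v, faces)
}
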