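#' Magnetic flux density of a circular current loop
#'
#' Exact magnetostatic field of a filamentary circular loop of radius
#' `loop_radius` lying in the plane `z = loop_z`, centred on the z axis,
#' evaluated with the standard complete-elliptic-integral closed form
#' (axial plus radial components).  This is the elementary source from
#' which the whole coil field is superposed.
#'
#' @param loop_radius loop radius a, m.
#' @param loop_z axial position of the loop plane, m.
#' @param current loop current, A (peak).
#' @param points n x 3 matrix (or length-3 vector) of field points, m.
#' @return n x 3 matrix of flux-density components (T).
#' @examples
#' # on-axis closed form: Bz = mu0 I / (2 a) at the loop centre
#' loop_field(0.025, 0, 1, c(0, 0, 0))[3]  # ~2.513e-5 T
#' @export
loop_field <- function(loop_radius, loop_z, current, points) {
  a <- loop_radius
  stopifnot(a > 0)
  pts <- rbind(points)
  if (ncol(pts) != 3) stop("points must be n x 3")
  x <- pts[, 1]; y <- pts[, 2]; dz <- pts[, 3] - loop_z
  r <- sqrt(x^2 + y^2)
  d2 <- (a - r)^2 + dz^2                     # squared distance to filament
  if (any(d2 < (1e-9 * a)^2))
    stop("singularity error: field point lies on the wire filament")
  Q <- (a + r)^2 + dz^2
  m <- 4 * a * r / Q                          # elliptic parameter m = k^2
  ek <- pracma::ellipke(pmin(m, 1 - 1e-15))
  K <- ek$k; E <- ek$e
  pref <- MU0 * current / (2 * pi * sqrt(Q))
  Bz <- pref * (K + E * (a^2 - r^2 - dz^2) / d2)
  Br <- numeric(length(r))
  off <- r > 1e-12 * a
  Br[off] <- (pref[off] * dz[off] / r[off]) *
    (-K[off] + E[off] * (a^2 + r[off]^2 + dz[off]^2) / d2[off])
  out <- cbind(
    Bx = ifelse(off, Br * x / pmax(r, .Machine$double.xmin), 0),
    By = ifelse(off, Br * y / pmax(r, .Machine$double.xmin), 0),
    Bz = Bz)
  out
}

#' Flux density of the excitation coil at arbitrary points
#'
#' Superposition of the fields of the coil's turns, each treated as a
#' filamentary circular loop at its axial station.  Linear in current.
#'
#' @param coil a [coil_spec()].
#' @param points n x 3 matrix of field points, m.
#' @param current drive current, A; defaults to the coil's
#'   `current_amplitude`.
#' @return n x 3 matrix of flux-density components (T).
#' @export
field_at_points <- function(coil, points, current = coil$current_amplitude) {
  stopifnot(inherits(coil, "coil_spec"))
  if (is.na(current)) stop("coil current is NA; calibrate or supply `current`")
  pts <- rbind(points)
  B <- matrix(0, nrow(pts), 3)
  for (z0 in turn_positions(coil))
    B <- B + loop_field(coil$inner_radius, z0, current, pts)
  colnames(B) <- c("Bx", "By", "Bz")
  B
}

#' Default evaluation grid for field maps
#'
#' Isotropic grid over a bounding box enclosing the phantom (or scaffold if
#' no phantom) plus a margin.
#'
#' @param scene a `mags_scene`.
#' @param resolution grid step, m (default 1 mm).
#' @param margin margin around the region bounding box, m.
#' @return list of three monotone axis vectors `x`, `y`, `z` (m).
#' @export
default_field_grid <- function(scene, resolution = 1e-3, margin = 5e-3) {
  reg <- if (!is.null(scene$phantom)) scene$phantom else scene$scaffold
  r <- reg$diameter / 2 + margin
  hz <- reg$height / 2 + margin
  cc <- reg$center_offset
  ax <- function(c0, half) {
    n <- ceiling(2 * half / resolution)
    c0 + (seq_len(n) - (n + 1) / 2) * resolution
  }
  list(x = ax(cc[1], r), y = ax(cc[2], r), z = ax(cc[3], hz))
}

#' Gridded flux-density map of the excitation coil
#'
#' Evaluates [field_at_points()] on a regular grid and returns a `FieldMap`
#' holding the three flux-density components per node plus the drive
#' frequency.  The grid must not contain filament positions.
#'
#' @param coil a [coil_spec()].
#' @param grid_axes list of three monotone coordinate vectors (m), e.g.
#'   from [default_field_grid()].
#' @param current drive current, A.
#' @return an object of class `field_map`: `axes`, `B` (array
#'   `nx x ny x nz x 3`, T), `frequency`, plus the source `coil` and
#'   `current` as attributes used by downstream exact-quadrature paths.
#' @export
solenoid_field <- function(coil, grid_axes, current = coil$current_amplitude) {
  gx <- grid_axes$x; gy <- grid_axes$y; gz <- grid_axes$z
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  B <- field_at_points(coil, pts, current)
  arr <- array(B, dim = c(length(gx), length(gy), length(gz), 3))
  structure(list(axes = grid_axes, B = arr, frequency = coil$frequency,
                 coil = coil, current = current),
            class = "field_map")
}

# |B| array of a field_map
field_norm <- function(field) {
  sqrt(field$B[, , , 1]^2 + field$B[, , , 2]^2 + field$B[, , , 3]^2)
}

#' Calibrate the coil current to a target central flux density
#'
#' The field is linear in current, so a single unit-current evaluation at
#' the coil centre fixes the drive amplitude exactly.
#'
#' @param coil a [coil_spec()].
#' @param target_B0 desired |B| at the coil centre, T (peak).
#' @return the current amplitude in A.
#' @examples
#' I <- calibrate_current(coil_spec(), 0.03)
#' @export
calibrate_current <- function(coil, target_B0) {
  stopifnot(target_B0 >= 0)
  B1 <- field_at_points(coil, c(0, 0, 0), current = 1)
  target_B0 / sqrt(sum(B1^2))
}

#' Field homogeneity over a region
#'
#' Ratio xi = m_H / s_H of the mean to the standard deviation of the
#' magnetic field strength H = |B| / mu0 over the grid nodes inside the
#' region.  Higher xi means more uniform exposure of the sample.  The
#' sample (n-1) standard deviation is used.  A perfectly uniform field has
#' s_H = 0; xi is then reported as `Inf` with `uniform = TRUE` rather than
#' raising an error.
#'
#' @param field a `field_map` from [solenoid_field()].
#' @param region a [cylinder_region()]; must contain at least 2 grid nodes.
#' @return an object of class `homogeneity_report`: `mean_field`,
#'   `std_field` (A/m), `xi`, `n_nodes`, `uniform`.
#' @export
homogeneity <- function(field, region) {
  pts <- as.matrix(expand.grid(x = field$axes$x, y = field$axes$y,
                               z = field$axes$z))
  inside <- in_cylinder(region, pts)
  if (sum(inside) < 2L)
    stop("region error: region must contain at least 2 interior grid nodes")
  H <- as.vector(field_norm(field))[inside] / MU0
  homogeneity_from_H(H)
}

# core xi computation from a vector of |H| samples
homogeneity_from_H <- function(H) {
  m <- mean(H); s <- sd(H)
  structure(list(mean_field = m, std_field = s,
                 xi = if (s > 0) m / s else Inf,
                 n_nodes = length(H), uniform = s == 0),
            class = "homogeneity_report")
}

#' @export
print.homogeneity_report <- function(x, ...) {
  cat(sprintf("field homogeneity: m_H = %.4g A/m, s_H = %.4g A/m, xi = %.4g (n = %d)\n",
              x$mean_field, x$std_field, x$xi, x$n_nodes))
  invisible(x)
}

#' Induced azimuthal electric field from a flux-density map
#'
#' For a time-harmonic axisymmetric excitation, the azimuthal electric
#' field amplitude follows from Faraday's law as
#' `|E_phi(r, z)| = omega * |Phi(r, z)| / (2 pi r)`, where `Phi` is the
#' flux of `B_z` through the disc of radius `r` centred on the coil axis
#' at height `z`.  The flux integral is evaluated by trapezoidal
#' quadrature along radial rays (azimuthally averaged from the gridded
#' `B_z`), and `|E_phi| -> 0` as `r -> 0`.
#'
#' @param field a `field_map`.
#' @param n_radial number of radial quadrature nodes per ray.
#' @param n_azimuth number of azimuths averaged when sampling `B_z` off the
#'   grid axes.
#' @return object of class `efield_map`: `axes`, `E` (array nx x ny x nz,
#'   V/m, peak amplitude), `frequency`.
#' @export
induced_efield <- function(field, n_radial = 96L, n_azimuth = 8L) {
  ax <- field$axes
  omega <- 2 * pi * field$frequency
  nx <- length(ax$x); ny <- length(ax$y); nz <- length(ax$z)
  rr <- sqrt(outer(ax$x^2, ax$y^2, `+`))          # nx x ny radii
  rmax <- max(rr)
  rgrid <- seq(0, rmax, length.out = n_radial)
  th <- seq(0, 2 * pi, length.out = n_azimuth + 1L)[-(n_azimuth + 1L)]
  E <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    # azimuthally averaged Bz along the radial ray at this z
    Bz_ray <- vapply(rgrid, function(r) {
      px <- r * cos(th); py <- r * sin(th)
      mean(interp_grid3(ax, field$B[, , , 3], cbind(px, py, ax$z[k])))
    }, numeric(1))
    flux <- 2 * pi * pracma::cumtrapz(rgrid, Bz_ray * rgrid)
    ephi <- c(0, omega * abs(flux[-1]) / (2 * pi * rgrid[-1]))
    E[, , k] <- matrix(approx(rgrid, ephi, xout = as.vector(rr))$y, nx, ny)
  }
  structure(list(axes = ax, E = E, frequency = field$frequency),
            class = "efield_map")
}

#' Induced azimuthal E-field amplitude at arbitrary points (exact source)
#'
#' Same physics as [induced_efield()], but `B_z` along each radial ray is
#' computed directly from the coil's loop-field closed form instead of
#' being interpolated from a grid.  Used internally to build power maps.
#'
#' @param coil a [coil_spec()].
#' @param current drive current, A.
#' @param points n x 3 matrix of points, m.
#' @param n_radial radial quadrature nodes.
#' @return numeric vector of |E_phi| peak amplitudes (V/m).
#' @export
induced_efield_at_points <- function(coil, current, points, n_radial = 96L) {
  pts <- rbind(points)
  omega <- 2 * pi * coil$frequency
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  out <- numeric(nrow(pts))
  zkey <- round(pts[, 3], 9)
  for (z in unique(zkey)) {
    sel <- zkey == z
    rmax <- max(r[sel])
    if (rmax == 0) { out[sel] <- 0; next }
    rgrid <- seq(0, rmax, length.out = n_radial)
    Bz <- field_at_points(coil, cbind(rgrid, 0, z), current)[, 3]
    flux <- 2 * pi * pracma::cumtrapz(rgrid, Bz * rgrid)
    ephi <- c(0, omega * abs(flux[-1]) / (2 * pi * rgrid[-1]))
    out[sel] <- approx(rgrid, ephi, xout = r[sel])$y
  }
  out
}

#' Convert a pickup-coil EMF reading to field strength
#'
#' Faraday's law for a small pickup coil in a uniform sinusoidal field:
#' the peak-to-peak EMF of an `n`-turn coil of diameter `d` is
#' `V_pp = 2 n omega mu0 H pi (d/2)^2`, so
#' `H = V_pp / (2 n omega mu0 pi (d/2)^2)`.
#'
#' @param peak_to_peak_emf measured EMF, V (peak-to-peak).
#' @param frequency field frequency, Hz (> 0).
#' @param probe a [probe_coil_spec()].
#' @return field strength amplitude H in A/m (peak).
#' @seealso [field_to_emf()] for the inverse; their composition is the
#'   identity.
#' @examples
#' # a 30 mT, 400 kHz field through the default probe gives ~15.8 V pk-pk
#' vpp <- field_to_emf(0.03 / (4e-7 * pi), 4e5, probe_coil_spec())
#' emf_to_field(vpp, 4e5, probe_coil_spec())  # ~23.9 kA/m
#' @export
emf_to_field <- function(peak_to_peak_emf, frequency, probe) {
  if (frequency <= 0) stop("domain error: frequency must be positive")
  area <- pi * (probe$diameter / 2)^2
  peak_to_peak_emf / (2 * probe$n_turns * 2 * pi * frequency * MU0 * area)
}

#' @rdname emf_to_field
#' @param H_amplitude field strength amplitude, A/m (peak).
#' @export
field_to_emf <- function(H_amplitude, frequency, probe) {
  if (frequency <= 0) stop("domain error: frequency must be positive")
  area <- pi * (probe$diameter / 2)^2
  2 * probe$n_turns * 2 * pi * frequency * MU0 * H_amplitude * area
}

#' Field-frequency safety product
#'
#' The product H x f (A m^-1 s^-1) commonly quoted against patient-comfort
#' thresholds; computed from the rated peak flux density in free space.
#'
#' @param target_flux_density peak flux density, T.
#' @param frequency Hz.
#' @return H x f in A m^-1 s^-1.
#' @examples
#' hf_product(0.03, 4e5)  # ~9.5e9
#' @export
hf_product <- function(target_flux_density, frequency) {
  (target_flux_density / MU0) * frequency
}

# trilinear interpolation of a 3d array given axes; pts outside the grid are
# clamped to the boundary.
interp_grid3 <- function(axes, arr, pts) {
  pts <- rbind(pts)
  loc <- function(g, v) {
    i <- findInterval(v, g, all.inside = TRUE)
    w <- (v - g[i]) / (g[i + 1] - g[i])
    list(i = i, w = pmin(pmax(w, 0), 1))
  }
  lx <- loc(axes$x, pts[, 1]); ly <- loc(axes$y, pts[, 2]); lz <- loc(axes$z, pts[, 3])
  out <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) lx$w else 1 - lx$w) * (if (dy) ly$w else 1 - ly$w) *
      (if (dz) lz$w else 1 - lz$w)
    out <- out + wt * arr[cbind(lx$i + dx, ly$i + dy, lz$i + dz)]
  }
  out
}
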