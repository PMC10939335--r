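#' Excitation coil specification
#'
#' Geometry and drive of the single-layer induction heating coil.  The
#' coordinate system is right-handed Cartesian with `z` along the coil axis
#' and the origin at the coil's geometric centre (the sample sits at half
#' the coil height).
#'
#' The defaults describe an 8-turn, single-layer water-cooled induction
#' head: 25 mm bore radius, turns evenly spaced over 48 mm (pitch 48/7 mm),
#' 2 mm conductor radius.  The drive current is usually left `NA` and set
#' by [calibrate_current()] so that the central flux density equals the
#' rated exposure (30 mT peak by default).
#'
#' @param n_turns integer number of turns (>= 1).
#' @param inner_radius coil bore radius in m.
#' @param axial_pitch spacing between adjacent turns in m; must exceed the
#'   conductor diameter.
#' @param wire_radius conductor radius in m.
#' @param current_amplitude peak drive current in A (may be `NA` until
#'   calibrated).
#' @param frequency drive frequency in Hz.
#' @return an object of class `coil_spec`.
#' @examples
#' coil <- coil_spec()
#' turn_positions(coil)
#' @export
coil_spec <- function(n_turns = 8L,
                      inner_radius = 0.025,
                      axial_pitch = 0.048 / 7,
                      wire_radius = 0.002,
                      current_amplitude = NA_real_,
                      frequency = 4e5) {
  n_turns <- as.integer(n_turns)
  stopifnot(n_turns >= 1L, inner_radius > 0, frequency > 0, wire_radius > 0)
  if (n_turns > 1L && axial_pitch <= 2 * wire_radius)
    stop("axial_pitch must exceed the conductor diameter (2 * wire_radius)")
  structure(
    list(n_turns = n_turns, inner_radius = inner_radius,
         axial_pitch = axial_pitch, wire_radius = wire_radius,
         current_amplitude = current_amplitude, frequency = frequency),
    class = "coil_spec")
}

#' Axial positions of the coil turns
#'
#' Turns are evenly spaced and centred on the origin, so a symmetric coil
#' is mirror-symmetric under `z -> -z`.
#'
#' @param coil a [coil_spec()].
#' @return numeric vector of turn z-coordinates (m).
#' @export
turn_positions <- function(coil) {
  n <- coil$n_turns
  coil$axial_pitch * (seq_len(n) - (n + 1) / 2)
}

#' Pickup (probe) coil specification
#'
#' A small calibrated coil used to measure the applied field strength from
#' its induced electromotive force via Faraday's law.  Default geometry:
#' 7.3 mm diameter, 2.5 turns (fractional turns allowed).  The winding
#' height is carried as metadata; the single-flux-linkage Faraday formula
#' does not use it.
#'
#' @param diameter coil diameter in m.
#' @param n_turns real number of turns (> 0).
#' @param height winding height in m (metadata).
#' @return an object of class `probe_coil_spec`.
#' @export
probe_coil_spec <- function(diameter = 7.3e-3, n_turns = 2.5, height = 0.03) {
  stopifnot(diameter > 0, n_turns > 0)
  structure(list(diameter = diameter, n_turns = n_turns, height = height),
            class = "probe_coil_spec")
}

#' Cylindrical region (scaffold or phantom)
#'
#' Axis-aligned cylinder with its axis along `z`, described by diameter,
#' height and the offset of its centre from the coil centre.
#'
#' @param diameter cylinder diameter in m.
#' @param height cylinder height in m.
#' @param center_offset length-3 numeric, centre position relative to the
#'   coil centre in m.
#' @param role one of `"scaffold"`, `"phantom"`.
#' @return an object of class `cylinder_region`.
#' @examples
#' scaffold <- cylinder_region(0.02, 0.02, role = "scaffold")
#' phantom  <- cylinder_region(0.025, 0.04, role = "phantom")
#' @export
cylinder_region <- function(diameter, height, center_offset = c(0, 0, 0),
                            role = c("scaffold", "phantom")) {
  role <- match.arg(role)
  stopifnot(diameter > 0, height > 0, length(center_offset) == 3)
  structure(list(diameter = diameter, height = height,
                 center_offset = as.numeric(center_offset), role = role),
            class = "cylinder_region")
}

# is point matrix (n x 3) inside the cylinder?  The small relative
# tolerance keeps the membership of points lying exactly on the boundary
# invariant under rigid floating-point translations of the scene.
in_cylinder <- function(region, pts) {
  d <- sweep(rbind(pts), 2, region$center_offset)
  r2 <- (region$diameter / 2)^2
  hz <- region$height / 2
  (d[, 1]^2 + d[, 2]^2 <= r2 * (1 + 1e-9)) &
    (abs(d[, 3]) <= hz * (1 + 1e-9))
}

#' Material properties
#'
#' Electromagnetic and thermal properties of one material.  Arguments use
#' the units material tables are printed in (J g^-1 K^-1 for specific heat,
#' g cm^-3 for density); they are converted to SI exactly once here and
#' stored as `specific_heat` (J kg^-1 K^-1) and `density` (kg m^-3).
#'
#' @param rel_permittivity relative dielectric permittivity.
#' @param conductivity electrical conductivity, S/m (>= 0).
#' @param thermal_conductivity W m^-1 K^-1.
#' @param specific_heat J g^-1 K^-1 (as tabulated).
#' @param density g cm^-3 (as tabulated).
#' @return an object of class `material_props` with SI fields.
#' @examples
#' agar <- material_props(70, 0.2, 0.48, 4.2, 1)
#' agar$specific_heat  # 4200 J/kg/K
#' @export
material_props <- function(rel_permittivity, conductivity,
                           thermal_conductivity, specific_heat, density) {
  stopifnot(conductivity >= 0)
  if (!is.na(thermal_conductivity)) stopifnot(thermal_conductivity > 0)
  if (!is.na(specific_heat)) stopifnot(specific_heat > 0)
  if (!is.na(density)) stopifnot(density > 0)
  structure(
    list(rel_permittivity = rel_permittivity,
         conductivity = conductivity,
         thermal_conductivity = thermal_conductivity,
         specific_heat = if (is.na(specific_heat)) NA_real_ else specific_heat * 1e3,
         density = if (is.na(density)) NA_real_ else density * 1e3),
    class = "material_props")
}

#' Default material table
#'
#' Properties of the materials in the reference scene: agar tissue-mimicking
#' phantom, iron-loaded PLA composite filament ("PP"), plain PLA, and
#' distilled water (standard handbook values at room temperature; water is
#' needed for the in-water exposure mode).
#'
#' @return named list of [material_props()]: `agar`, `pp`, `pla`, `water`.
#' @export
default_materials <- function() {
  list(
    agar  = material_props(70,  0.2,   0.48, 4.2,  1.0),
    pp    = material_props(3,   1e-5,  0.47, 1.2,  2.7),
    pla   = material_props(2.5, 1e-6,  0.29, 1.8,  0.9),
    water = material_props(78,  5.5e-6, 0.60, 4.18, 1.0)
  )
}

#' Exposure configuration
#'
#' The rated field, timing and ambient conditions of one heating run.
#'
#' @param target_flux_density peak flux density at the coil centre, T.
#' @param frequency drive frequency, Hz.
#' @param duration total simulated/recorded time, s.
#' @param field_off_time instant the field is switched off, s
#'   (0 < field_off_time <= duration).
#' @param ambient_temperature ambient and initial temperature, degC.
#' @param convective_coeff_air convective heat-transfer coefficient h_a at
#'   solid-air interfaces, W m^-2 K^-1 (free convection in air by default).
#' @param medium_mode `"agar"` (scaffold embedded in agar phantom),
#'   `"air"` (bare scaffold), or `"water"` (scaffold in distilled water).
#' @return an object of class `exposure_config`.
#' @export
exposure_config <- function(target_flux_density = 0.03,
                            frequency = 4e5,
                            duration = 900,
                            field_off_time = 600,
                            ambient_temperature = 19,
                            convective_coeff_air = 10,
                            medium_mode = c("agar", "air", "water")) {
  medium_mode <- match.arg(medium_mode)
  stopifnot(target_flux_density > 0, frequency > 0,
            field_off_time > 0, field_off_time <= duration,
            convective_coeff_air >= 0)
  structure(
    list(target_flux_density = target_flux_density, frequency = frequency,
         duration = duration, field_off_time = field_off_time,
         ambient_temperature = ambient_temperature,
         convective_coeff_air = convective_coeff_air,
         medium_mode = medium_mode),
    class = "exposure_config")
}

#' Validate and assemble a physical scene
#'
#' Checks geometric containment (the scaffold must sit fully inside the
#' phantom when one is present) and that every region role has material
#' properties, then returns an immutable scene object.
#'
#' @param coil a [coil_spec()].
#' @param regions list of [cylinder_region()]: exactly one scaffold, at
#'   most one phantom.
#' @param materials named list mapping role (`scaffold`, `phantom`) to
#'   [material_props()].
#' @return an object of class `mags_scene` with elements `coil`,
#'   `scaffold`, `phantom` (or `NULL`) and `materials`.
#' @examples
#' sc <- validate_scene(
#'   coil_spec(),
#'   list(cylinder_region(0.02, 0.02, role = "scaffold"),
#'        cylinder_region(0.025, 0.04, role = "phantom")),
#'   list(scaffold = default_materials()$pp,
#'        phantom = default_materials()$agar))
#' @export
validate_scene <- function(coil, regions, materials) {
  stopifnot(inherits(coil, "coil_spec"))
  roles <- vapply(regions, function(r) r$role, character(1))
  if (sum(roles == "scaffold") != 1L)
    stop("configuration error: regions must include exactly one scaffold")
  if (sum(roles == "phantom") > 1L)
    stop("configuration error: at most one phantom region allowed")
  scaffold <- regions[[which(roles == "scaffold")]]
  phantom <- if (any(roles == "phantom")) regions[[which(roles == "phantom")]] else NULL
  for (role in unique(roles)) {
    if (is.null(materials[[role]]) || !inherits(materials[[role]], "material_props"))
      stop("configuration error: missing material properties for role '", role, "'")
  }
  if (!is.null(phantom)) {
    dc <- scaffold$center_offset - phantom$center_offset
    radial_ok <- sqrt(dc[1]^2 + dc[2]^2) + scaffold$diameter / 2 <=
      phantom$diameter / 2 + 1e-12
    axial_ok <- abs(dc[3]) + scaffold$height / 2 <= phantom$height / 2 + 1e-12
    if (!radial_ok || !axial_ok)
      stop("geometry error: scaffold region not contained in phantom region")
  }
  structure(list(coil = coil, scaffold = scaffold, phantom = phantom,
                 materials = materials),
            class = "mags_scene")
}

#' Rigidly shift the sample (scaffold plus phantom) in the coil
#'
#' The phantom holds the embedded scaffold, so placement sweeps move the
#' pair together; containment is preserved by construction.
#'
#' @param scene a `mags_scene` from [validate_scene()].
#' @param offset length-3 shift in m.
#' @return a new `mags_scene`.
#' @export
shift_scene <- function(scene, offset) {
  stopifnot(inherits(scene, "mags_scene"), length(offset) == 3)
  offset <- as.numeric(offset)
  scene$scaffold$center_offset <- scene$scaffold$center_offset + offset
  if (!is.null(scene$phantom))
    scene$phantom$center_offset <- scene$phantom$center_offset + offset
  scene
}

#' Reference scene: iron-PLA scaffold in an agar phantom
#'
#' The default study geometry: a homogeneous 20 mm x 20 mm cylindrical
#' magnetic scaffold centred in a 25 mm x 40 mm agar phantom, both centred
#' in the default 8-turn coil.
#'
#' @param coil optional [coil_spec()] override.
#' @return a `mags_scene`.
#' @export
default_scene <- function(coil = coil_spec()) {
  mats <- default_materials()
  validate_scene(
    coil,
    list(cylinder_region(0.02, 0.02, role = "scaffold"),
         cylinder_region(0.025, 0.04, role = "phantom")),
    list(scaffold = mats$pp, phantom = mats$agar))
}

#' @export
print.mags_scene <- function(x, ...) {
  cat("<mags_scene>\n")
  cat(sprintf("  coil: %d turns, bore radius %.1f mm, pitch %.2f mm, f = %g kHz\n",
              x$coil$n_turns, x$coil$inner_radius * 1e3,
              x$coil$axial_pitch * 1e3, x$coil$frequency / 1e3))
  fmt <- function(r) sprintf("d = %.1f mm, h = %.1f mm, centre (%g, %g, %g) mm",
                             r$diameter * 1e3, r$height * 1e3,
                             r$center_offset[1] * 1e3, r$center_offset[2] * 1e3,
                             r$center_offset[3] * 1e3)
  cat("  scaffold:", fmt(x$scaffold), "\n")
  if (!is.null(x$phantom)) cat("  phantom: ", fmt(x$phantom), "\n")
  invisible(x)
}
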