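#' Read a scene configuration file
#'
#' One nested YAML file describes a complete run: sections `coil`,
#' `probe_coil`, `scaffold`, `phantom`, `materials`, `exposure`, `solver`
#' and `probes`.  Lengths are given with explicit unit suffixes
#' (`"25 mm"`); bare numbers are SI.  Material properties use the
#' tabulated units (specific heat J g^-1 K^-1, density g cm^-3).
#'
#' @param path YAML file path.
#' @return list with elements `scene` (`mags_scene`), `exposure`
#'   (`exposure_config`), `probe_coil`, `solver` (list: `resolution`,
#'   `dt`, `store_every`), `layout` (`probe_layout`).
#' @seealso [write_scene_config()] for the inverse; a validated scene
#'   round-trips through the config format with identical field values.
#' @export
read_scene_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  len <- function(x, d = NULL) if (is.null(x)) d else parse_quantity(x, "length")
  co <- cfg$coil %||% list()
  coil <- coil_spec(
    n_turns = co$n_turns %||% 8L,
    inner_radius = len(co$inner_radius, 0.025),
    axial_pitch = len(co$axial_pitch, 0.048 / 7),
    wire_radius = len(co$wire_radius, 0.002),
    frequency = parse_quantity(co$frequency %||% 4e5, "frequency"))
  pc <- cfg$probe_coil %||% list()
  probe_coil <- probe_coil_spec(
    diameter = len(pc$diameter, 7.3e-3),
    n_turns = pc$n_turns %||% 2.5,
    height = len(pc$height, 0.03))
  region <- function(x, role) {
    if (is.null(x)) return(NULL)
    cylinder_region(len(x$diameter), len(x$height),
                    center_offset = vapply(x$center_offset %||% list(0, 0, 0),
                                           parse_quantity, numeric(1),
                                           kind = "length"),
                    role = role)
  }
  mats <- default_materials()
  mat <- function(x, d) {
    if (is.null(x)) return(d)
    material_props(x$rel_permittivity, x$conductivity,
                   x$thermal_conductivity, x$specific_heat, x$density)
  }
  mlist <- list(
    scaffold = mat(cfg$materials$scaffold, mats$pp),
    phantom = mat(cfg$materials$phantom, mats$agar))
  regions <- Filter(Negate(is.null),
                    list(region(cfg$scaffold, "scaffold"),
                         region(cfg$phantom, "phantom")))
  scene <- validate_scene(coil, regions, mlist)
  ex <- cfg$exposure %||% list()
  exposure <- exposure_config(
    target_flux_density = parse_quantity(ex$target_flux_density %||% "30 mT",
                                         "flux_density"),
    frequency = parse_quantity(ex$frequency %||% coil$frequency, "frequency"),
    duration = parse_quantity(ex$duration %||% 900, "time"),
    field_off_time = parse_quantity(ex$field_off_time %||% 600, "time"),
    ambient_temperature = ex$ambient_temperature %||% 19,
    convective_coeff_air = ex$convective_coeff_air %||% 10,
    medium_mode = ex$medium_mode %||% "agar")
  sv <- cfg$solver %||% list()
  solver <- list(resolution = len(sv$resolution, 2e-3),
                 dt = parse_quantity(sv$dt %||% 0.1, "time"),
                 store_every = parse_quantity(sv$store_every %||% 60, "time"))
  layout <- if (is.null(cfg$probes)) default_probe_layout() else {
    pos <- lapply(cfg$probes$positions,
                  function(p) vapply(p, parse_quantity, numeric(1),
                                     kind = "length"))
    probe_layout(pos,
                 sampling_rate = cfg$probes$sampling_rate %||% 1,
                 noise_sd = cfg$probes$noise_sd %||% 0.1)
  }
  list(scene = scene, exposure = exposure, probe_coil = probe_coil,
       solver = solver, layout = layout)
}

#' Write a scene configuration file
#'
#' @param scene a `mags_scene`.
#' @param exposure an [exposure_config()].
#' @param path output YAML path.
#' @param probe_coil optional [probe_coil_spec()].
#' @param solver optional solver settings list.
#' @param layout optional [probe_layout()].
#' @export
write_scene_config <- function(scene, exposure, path,
                               probe_coil = probe_coil_spec(),
                               solver = list(resolution = 2e-3, dt = 0.1,
                                             store_every = 60),
                               layout = default_probe_layout()) {
  mat_out <- function(m) list(
    rel_permittivity = m$rel_permittivity, conductivity = m$conductivity,
    thermal_conductivity = m$thermal_conductivity,
    specific_heat = m$specific_heat / 1e3,   # back to J/g/K at the boundary
    density = m$density / 1e3)               # back to g/cm^3
  reg_out <- function(r) if (is.null(r)) NULL else list(
    diameter = format_mm(r$diameter), height = format_mm(r$height),
    center_offset = lapply(r$center_offset, format_mm))
  cfg <- list(
    coil = list(n_turns = scene$coil$n_turns,
                inner_radius = format_mm(scene$coil$inner_radius),
                axial_pitch = format_mm(scene$coil$axial_pitch),
                wire_radius = format_mm(scene$coil$wire_radius),
                frequency = scene$coil$frequency),
    probe_coil = list(diameter = format_mm(probe_coil$diameter),
                      n_turns = probe_coil$n_turns,
                      height = format_mm(probe_coil$height)),
    scaffold = reg_out(scene$scaffold),
    phantom = reg_out(scene$phantom),
    materials = list(scaffold = mat_out(scene$materials$scaffold),
                     phantom = if (!is.null(scene$materials$phantom))
                       mat_out(scene$materials$phantom)),
    exposure = list(target_flux_density = paste(exposure$target_flux_density * 1e3, "mT"),
                    frequency = exposure$frequency,
                    duration = exposure$duration,
                    field_off_time = exposure$field_off_time,
                    ambient_temperature = exposure$ambient_temperature,
                    convective_coeff_air = exposure$convective_coeff_air,
                    medium_mode = exposure$medium_mode),
    solver = list(resolution = format_mm(solver$resolution), dt = solver$dt,
                  store_every = solver$store_every),
    probes = list(positions = setNames(
      lapply(seq_len(nrow(layout$positions)),
             function(i) lapply(layout$positions[i, ], format_mm)),
      rownames(layout$positions)),
      sampling_rate = layout$sampling_rate,
      noise_sd = layout$noise_sd))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Export / import a gridded field map
#'
#' Self-describing long-format CSV: comment header with the frequency,
#' then columns `x_mm, y_mm, z_mm, Bx_T, By_T, Bz_T`.  The importer
#' reconstructs the grid axes from the coordinates.
#'
#' @param field a `field_map`.
#' @param path file path.
#' @return `read_field_map` returns a `field_map` (without the source
#'   coil attribute).
#' @export
write_field_map <- function(field, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# freq_hz=%.10g", field$frequency), con)
  pts <- expand.grid(x = field$axes$x, y = field$axes$y, z = field$axes$z)
  df <- data.frame(x_mm = pts$x * 1e3, y_mm = pts$y * 1e3, z_mm = pts$z * 1e3,
                   Bx_T = as.vector(field$B[, , , 1]),
                   By_T = as.vector(field$B[, , , 2]),
                   Bz_T = as.vector(field$B[, , , 3]))
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_map
#' @export
read_field_map <- function(path) {
  hdr <- grep("^#", readLines(path, n = 3L), value = TRUE)
  freq <- as.numeric(sub("^#\\s*freq_hz=", "",
                         grep("freq_hz=", hdr, value = TRUE)[1]))
  df <- read.csv(path, comment.char = "#")
  axes <- list(x = sort(unique(df$x_mm)) / 1e3,
               y = sort(unique(df$y_mm)) / 1e3,
               z = sort(unique(df$z_mm)) / 1e3)
  n <- lengths(axes)
  ord <- order(df$z_mm, df$y_mm, df$x_mm)
  B <- array(c(df$Bx_T[ord], df$By_T[ord], df$Bz_T[ord]), dim = c(n, 3))
  structure(list(axes = axes, B = B, frequency = freq,
                 coil = NULL, current = NULL),
            class = "field_map")
}
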