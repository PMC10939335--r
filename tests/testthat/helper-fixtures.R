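# shared fixtures for the test suite; everything is generated in code

MU0_T <- 4e-7 * pi

# reference geometry: 20 x 20 mm scaffold in a 25 x 40 mm agar phantom
ref_scene <- function(coil = coil_spec()) default_scene(coil)

# short exposure used by transient property tests
quick_exposure <- function(duration = 120, field_off_time = 100, ...) {
  exposure_config(duration = duration, field_off_time = field_off_time, ...)
}

# a hand-built uniform field map (used by homogeneity / E-field oracles)
uniform_field_map <- function(B0 = 0.03, axes = list(x = seq(-0.012, 0.012, 1e-3),
                                                     y = seq(-0.012, 0.012, 1e-3),
                                                     z = seq(-0.02, 0.02, 2e-3)),
                              frequency = 4e5) {
  n <- lengths(axes)
  B <- array(0, dim = c(n, 3))
  B[, , , 3] <- B0
  structure(list(axes = axes, B = B, frequency = frequency,
                 coil = NULL, current = NULL), class = "field_map")
}

# uniform volumetric power map over the active voxels of a scene
uniform_power_map <- function(voxels, P_v) {
  dims <- dim(voxels$label)
  act <- as.vector(voxels$label) != "ambient"
  arr <- array(0, dims); arr[act] <- P_v
  structure(list(volumetric = arr, mass = arr, hysteresis = arr,
                 dielectric_eddy = array(0, dims), frequency = 4e5),
            class = "power_map")
}

# direct Biot-Savart quadrature oracle for a circular loop (independent of
# the elliptic-integral closed form in the package)
loop_field_quadrature <- function(a, z0, current, pt, rel.tol = 1e-12) {
  integrand <- function(phi, comp) {
    sapply(phi, function(p) {
      dl <- c(-sin(p), cos(p), 0) * a
      rv <- pt - c(a * cos(p), a * sin(p), z0)
      cr <- c(dl[2] * rv[3] - dl[3] * rv[2],
              dl[3] * rv[1] - dl[1] * rv[3],
              dl[1] * rv[2] - dl[2] * rv[1])
      cr[comp] / sum(rv^2)^1.5
    })
  }
  sapply(1:3, function(c0)
    MU0_T * current / (4 * pi) *
      integrate(integrand, 0, 2 * pi, comp = c0, rel.tol = rel.tol)$value)
}

# closed-form area of the amplitude-truncated tanh loop (oracle)
tanh_loop_area_closed <- function(Bs, Hc, w, A) {
  2 * Bs * w * (log(cosh((A + Hc) / w)) - log(cosh((A - Hc) / w)))
}
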