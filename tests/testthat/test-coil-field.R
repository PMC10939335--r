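test_that("single-loop field matches closed forms and the quadrature oracle", {
  a <- 0.025
  # on-axis closed form at the loop centre
  B <- loop_field(a, 0, 1, c(0, 0, 0))
  expect_equal(unname(B[3]), MU0_T / (2 * a), tolerance = 1e-12)
  expect_equal(unname(B[1:2]), c(0, 0))

  # far field decays as a dipole, 1/r^3
  z1 <- 1; z2 <- 2
  B1 <- loop_field(a, 0, 1, c(0, 0, z1))[3]
  B2 <- loop_field(a, 0, 1, c(0, 0, z2))[3]
  expect_equal(B1 / B2, (z2 / z1)^3, tolerance = 1e-3)

  # off-axis point against direct Biot-Savart quadrature
  pt <- c(0.010, 0, 0.005)
  Bq <- loop_field_quadrature(a, 0, 1, pt)
  Bl <- loop_field(a, 0, 1, pt)
  expect_lt(max(abs(Bl - Bq)) / sqrt(sum(Bq^2)), 1e-8)
  # and at a rotated azimuth (exercises the x/y decomposition)
  pt2 <- c(0.006, 0.008, -0.004)
  Bq2 <- loop_field_quadrature(a, 0.003, 2.5, pt2)
  Bl2 <- loop_field(a, 0.003, 2.5, pt2)
  expect_lt(max(abs(Bl2 - Bq2)) / sqrt(sum(Bq2^2)), 1e-8)

  expect_error(loop_field(a, 0, 1, c(a, 0, 0)), "singularity")
})

test_that("solenoid field is linear in current and has the right limits", {
  coil <- coil_spec()
  pts <- rbind(c(0, 0, 0), c(0.005, 0.002, 0.01))
  expect_equal(field_at_points(coil, pts, current = 2),
               2 * field_at_points(coil, pts, current = 1))

  # long dense solenoid approaches mu0 * n * I
  long <- coil_spec(n_turns = 200, inner_radius = 0.01, axial_pitch = 1e-3,
                    wire_radius = 4e-4)
  Bc <- field_at_points(long, c(0, 0, 0), current = 1)
  expect_equal(unname(Bc[3]), MU0_T * (1 / 1e-3) * 1, tolerance = 1e-2)

  # field is stronger at the centre than 2 cm up the axis
  B0 <- sqrt(sum(field_at_points(coil, c(0, 0, 0), 1)^2))
  B2 <- sqrt(sum(field_at_points(coil, c(0, 0, 0.02), 1)^2))
  expect_gt(B0, B2)
})

test_that("mirror symmetry of the symmetric coil holds on a field map", {
  coil <- coil_spec()
  axes <- list(x = seq(-0.01, 0.01, 5e-3), y = c(-0.002, 0.002),
               z = seq(-0.016, 0.016, 4e-3))
  fm <- solenoid_field(coil, axes, current = 100)
  nB <- sqrt(fm$B[, , , 1]^2 + fm$B[, , , 2]^2 + fm$B[, , , 3]^2)
  expect_equal(nB, nB[, , rev(seq_along(axes$z))], tolerance = 1e-10)
})

test_that("current calibration is exact by linearity", {
  coil <- coil_spec()
  expect_equal(calibrate_current(coil, 0), 0)
  I <- calibrate_current(coil, 0.03)
  B <- field_at_points(coil, c(0, 0, 0), I)
  expect_equal(sqrt(sum(B^2)), 0.03, tolerance = 1e-12)
  # agrees with an independent on-axis superposition of per-loop closed forms
  a <- coil$inner_radius
  B_unit <- sum(sapply(turn_positions(coil), function(z0)
    MU0_T * a^2 / (2 * (a^2 + z0^2)^1.5)))
  expect_equal(I, 0.03 / B_unit, tolerance = 1e-12)
})

test_that("homogeneity xi = mean/sd of |H| with the degenerate case flagged", {
  # hand-built map whose |H| samples inside the region are {1, 1, 3} kA/m
  axes <- list(x = c(-1e-3, 0, 1e-3), y = 0, z = 0)
  B <- array(0, dim = c(3, 1, 1, 3))
  B[, 1, 1, 3] <- MU0_T * c(1e3, 1e3, 3e3)
  fm <- structure(list(axes = axes, B = B, frequency = 4e5),
                  class = "field_map")
  region <- cylinder_region(0.01, 0.01, role = "scaffold")
  rep <- homogeneity(fm, region)
  expect_equal(rep$mean_field, 5e3 / 3)
  expect_equal(rep$std_field, sd(c(1e3, 1e3, 3e3)))
  expect_equal(rep$xi, (5e3 / 3) / sd(c(1e3, 1e3, 3e3)), tolerance = 1e-12)
  expect_false(rep$uniform)

  uf <- uniform_field_map(0.03)
  urep <- homogeneity(uf, region)
  expect_true(urep$uniform)
  expect_identical(urep$xi, Inf)
})

test_that("xi over the scaffold strictly decreases with axial offset", {
  coil <- coil_spec()
  I <- calibrate_current(coil, 0.03)
  xi_at <- function(z0) {
    region <- cylinder_region(0.02, 0.02, center_offset = c(0, 0, z0),
                              role = "scaffold")
    sc <- shift_scene(ref_scene(), c(0, 0, z0))
    ax <- default_field_grid(sc, resolution = 2e-3, margin = 0)
    homogeneity(solenoid_field(coil, ax, I), region)$xi
  }
  xis <- sapply(c(0, 0.01, 0.02), xi_at)
  expect_true(all(diff(xis) < 0))
})

test_that("induced E-field obeys Faraday's law for a uniform B_z", {
  fm <- uniform_field_map(0.02)
  em <- induced_efield(fm)
  omega <- 2 * pi * fm$frequency
  pts <- as.matrix(expand.grid(x = fm$axes$x, y = fm$axes$y, z = fm$axes$z))
  r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
  expect_equal(as.vector(em$E), 0.5 * omega * 0.02 * r, tolerance = 1e-3)
  # zero field gives zero E
  fm0 <- uniform_field_map(0)
  expect_true(all(induced_efield(fm0)$E == 0))
})

test_that("gridded E-field matches the refined exact-quadrature path", {
  coil <- coil_spec()
  I <- calibrate_current(coil, 0.03)
  sc <- ref_scene()
  fm <- solenoid_field(coil, default_field_grid(sc, resolution = 1e-3), I)
  em <- induced_efield(fm)
  # phantom wall, coil mid-plane
  pt <- c(0.0125, 0, 0)
  ix <- which.min(abs(fm$axes$x - pt[1]))
  iy <- which.min(abs(fm$axes$y - 0))
  iz <- which.min(abs(fm$axes$z - 0))
  E_grid <- em$E[ix, iy, iz]
  pt_grid <- c(fm$axes$x[ix], fm$axes$y[iy], fm$axes$z[iz])
  E_exact <- induced_efield_at_points(coil, I, pt_grid, n_radial = 192L)
  expect_equal(E_grid, E_exact, tolerance = 1e-2)
})

test_that("Faraday pickup-coil conversion round-trips and scales correctly", {
  probe <- probe_coil_spec()
  H <- 0.03 / MU0_T
  vpp <- field_to_emf(H, 4e5, probe)
  expect_equal(vpp, 15.8, tolerance = 2e-3)            # ~15.8 V pk-pk
  expect_equal(emf_to_field(vpp, 4e5, probe), H, tolerance = 1e-12)
  expect_equal(emf_to_field(vpp, 4e5, probe) / 1e3, 23.9, tolerance = 2e-3)
  expect_equal(emf_to_field(0, 4e5, probe), 0)
  # same reading at doubled frequency implies half the field
  expect_equal(emf_to_field(vpp, 8e5, probe), H / 2, tolerance = 1e-12)
  expect_error(emf_to_field(1, 0, probe), "domain error")
})
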