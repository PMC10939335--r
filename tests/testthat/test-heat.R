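test_that("voxelization recovers cylinder volumes and shifts equivariantly", {
  sc <- ref_scene()
  v_true <- pi * 0.01^2 * 0.02
  v1 <- build_voxel_scene(sc, 1e-3)
  expect_lt(abs(voxel_volume(v1, "scaffold") - v_true) / v_true, 0.05)
  # refinement strictly reduces the labelled-volume error
  errs <- sapply(c(4e-3, 2e-3, 1e-3), function(r)
    abs(voxel_volume(build_voxel_scene(sc, r), "scaffold") - v_true) / v_true)
  expect_true(all(diff(errs) < 0))
  # translation equivariance of the labelled centroid
  v_shift <- build_voxel_scene(shift_scene(sc, c(3e-3, 0, 0)), 1e-3)
  cen <- function(v) {
    av <- v$axes
    pts <- as.matrix(expand.grid(av$x, av$y, av$z))
    colMeans(pts[as.vector(v$label) == "scaffold", ])
  }
  expect_equal(unname(cen(v_shift) - cen(v1)), c(3e-3, 0, 0),
               tolerance = 5e-4)                 # within half a voxel
  expect_error(build_voxel_scene(sc, 8e-3), "resolution error")
})

test_that("zero sources keep the system in equilibrium at ambient", {
  sc <- ref_scene()
  vox <- build_voxel_scene(sc, 4e-3)
  hist <- solve_transient(vox, NULL, quick_exposure(duration = 30,
                                                    field_off_time = 20))
  expect_equal(volume_average(hist, "scaffold")$temp,
               rep(19, length(hist$times)), tolerance = 1e-12)
  expect_equal(surface_average(hist, "phantom")$temp,
               rep(19, length(hist$times)), tolerance = 1e-12)
})

test_that("insulated uniform source gives the exact adiabatic ramp", {
  sc <- ref_scene()
  ex <- quick_exposure(duration = 60, field_off_time = 60,
                       convective_coeff_air = 0, medium_mode = "air")
  vox <- build_voxel_scene(sc, 2e-3, medium_mode = "air")
  P_v <- 1e5
  hist <- solve_transient(vox, uniform_power_map(vox, P_v), ex)
  pp <- default_materials()$pp
  ramp <- 19 + P_v / (pp$density * pp$specific_heat) * hist$times
  expect_equal(volume_average(hist, "scaffold")$temp, ramp,
               tolerance = 1e-6)
  # spatially uniform: surface average equals volume average
  expect_equal(surface_average(hist, "scaffold")$temp,
               volume_average(hist, "scaffold")$temp, tolerance = 1e-9)
})

test_that("adiabatic energy balance is conserved with a nonuniform source", {
  sc <- ref_scene()
  coil <- coil_spec()
  I <- calibrate_current(coil, 0.03)
  vox <- build_voxel_scene(sc, 2e-3)
  pm <- power_map(vox, coil, I, default_bh_loop())
  ex <- quick_exposure(duration = 60, field_off_time = 60,
                       convective_coeff_air = 0)
  hist <- solve_transient(vox, pm, ex)
  # enthalpy increase = integrated deposited power
  mats <- default_materials()
  rhoCp <- c(scaffold = mats$pp$density * mats$pp$specific_heat,
             phantom = mats$agar$density * mats$agar$specific_heat)
  Vv <- vox$resolution^3
  n_s <- sum(vox$label == "scaffold"); n_p <- sum(vox$label == "phantom")
  dH <- (volume_average(hist, "scaffold")$temp[length(hist$times)] - 19) *
    rhoCp["scaffold"] * n_s * Vv +
    (volume_average(hist, "phantom")$temp[length(hist$times)] - 19) *
    rhoCp["phantom"] * n_p * Vv
  E_in <- total_power(pm, vox) * max(hist$times)
  expect_equal(unname(dH), E_in, tolerance = 1e-2)
})

test_that("post-switch-off cooling follows the lumped-capacitance constant", {
  # small Biot number: bare scaffold, weak convection
  sc <- ref_scene()
  ex <- exposure_config(duration = 400, field_off_time = 100,
                        convective_coeff_air = 5, medium_mode = "air")
  vox <- build_voxel_scene(sc, 2e-3, medium_mode = "air")
  hist <- solve_transient(vox, uniform_power_map(vox, 2e5), ex)
  va <- volume_average(hist, "scaffold")
  sel <- va$time > 150 & va$time < 400
  fit <- lm(log(va$temp[sel] - 19) ~ va$time[sel])
  tau_fit <- -1 / coef(fit)[2]
  # lumped model of the same discrete system: C_tot / sum(U_faces)
  pp <- default_materials()$pp
  C_tot <- pp$density * pp$specific_heat * voxel_volume(vox, "scaffold")
  U <- 1 / (1 / 5 + (vox$resolution / 2) / pp$thermal_conductivity)
  tau_lump <- C_tot / (U * voxel_surface_area(vox, "scaffold"))
  expect_equal(unname(tau_fit), tau_lump, tolerance = 0.05)
})

test_that("maximum principle holds after switch-off", {
  sc <- ref_scene()
  coil <- coil_spec()
  I <- calibrate_current(coil, 0.03)
  vox <- build_voxel_scene(sc, 2e-3)
  pm <- power_map(vox, coil, I, default_bh_loop())
  hist <- solve_transient(vox, pm, quick_exposure(duration = 200,
                                                  field_off_time = 60),
                          store_every = 20)
  i_off <- which(hist$snapshot_times == 60)
  m_off <- max(hist$snapshots[[i_off]], na.rm = TRUE)
  for (i in seq_along(hist$snapshot_times)) {
    if (hist$snapshot_times[i] > 60)
      expect_lte(max(hist$snapshots[[i]], na.rm = TRUE), m_off + 1e-9)
  }
  # heating-then-cooling: the scaffold average peaks at field-off
  va <- volume_average(hist, "scaffold")
  expect_equal(va$time[which.max(va$temp)], 60)
  # mean bounded by extremes at every stored time
  for (i in seq_along(hist$snapshot_times)) {
    arr <- hist$snapshots[[i]]
    sca <- arr[vox$label == "scaffold"]
    tavg <- va$temp[va$time == hist$snapshot_times[i]]
    expect_gte(tavg, min(sca) - 1e-9)
    expect_lte(tavg, max(sca) + 1e-9)
  }
})

test_that("implicit and explicit integrators agree", {
  sc <- ref_scene()
  coil <- coil_spec()
  I <- calibrate_current(coil, 0.03)
  vox <- build_voxel_scene(sc, 4e-3)
  pm <- power_map(vox, coil, I, default_bh_loop())
  ex <- quick_exposure(duration = 40, field_off_time = 30)
  hi <- solve_transient(vox, pm, ex, method = "implicit")
  he <- solve_transient(vox, pm, ex, method = "explicit")
  Ti <- volume_average(hi, "scaffold")$temp
  Te <- volume_average(he, "scaffold")$temp
  expect_equal(Ti, Te, tolerance = 5e-3)
})

test_that("peak volume average is grid-converged at the working resolution", {
  sc <- ref_scene()
  ex <- quick_exposure()
  p2 <- simulate_heating(sc, ex, resolution = 2e-3)$peak_temp
  p1 <- simulate_heating(sc, ex, resolution = 1e-3)$peak_temp
  expect_lt(abs(p2 - p1) / (p1 - 19), 0.03)
})

test_that("in-air heating shows surface cooler than volume at the peak", {
  sc <- ref_scene()
  ex <- quick_exposure(medium_mode = "air")
  r <- simulate_heating(sc, ex, resolution = 2e-3)
  sa <- surface_average(r$history, "scaffold")
  va <- volume_average(r$history, "scaffold")
  expect_lt(max(sa$temp), max(va$temp))
})

test_that("water convection surrogate reduces the scaffold peak", {
  sc <- ref_scene()
  ex <- quick_exposure(duration = 150, field_off_time = 120,
                       medium_mode = "water")
  # enhancement forced to 1 must equal the conduction-only run
  vox <- build_voxel_scene(sc, 4e-3, medium_mode = "water")
  coil <- coil_spec()
  I <- calibrate_current(coil, 0.03)
  pm <- power_map(vox, coil, I, default_bh_loop())
  h_ref <- solve_transient(vox, pm, ex)
  h_fix <- solve_transient(apply_water_convection(vox, list(type = "fixed",
                                                            factor = 1)),
                           pm, ex)
  expect_equal(volume_average(h_fix, "scaffold")$temp,
               volume_average(h_ref, "scaffold")$temp, tolerance = 1e-12)
  # active Nusselt enhancement strictly lowers the peak
  h_nu <- solve_transient(apply_water_convection(vox), pm, ex)
  expect_lt(max(volume_average(h_nu, "scaffold")$temp),
            max(volume_average(h_ref, "scaffold")$temp))
  # fixed enhancement > 1 also lowers the peak
  h_f2 <- solve_transient(apply_water_convection(vox, list(type = "fixed",
                                                           factor = 3)),
                          pm, ex)
  expect_lt(max(volume_average(h_f2, "scaffold")$temp),
            max(volume_average(h_ref, "scaffold")$temp))
  expect_error(apply_water_convection(build_voxel_scene(sc, 4e-3)),
               "medium_mode")
})
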