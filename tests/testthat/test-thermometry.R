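test_that("probe sampling is exact at grid nodes and seed-deterministic", {
  sc <- ref_scene()
  ex <- quick_exposure(duration = 40, field_off_time = 30)
  vox <- build_voxel_scene(sc, 2e-3)
  coil <- coil_spec()
  I <- calibrate_current(coil, 0.03)
  pm <- power_map(vox, coil, I, default_bh_loop())
  node <- c(vox$axes$x[6], vox$axes$y[6], vox$axes$z[10])
  hist <- solve_transient(vox, pm, ex, probe_points = rbind(node),
                          store_every = 10)
  # noiseless record at a grid node reproduces the tracked field value
  lay <- probe_layout(list(C = node), noise_sd = 0)
  rec <- sample_probes(hist, lay)
  expect_equal(unname(rec$temps[rec$times == 30, "C"]),
               unname(hist$probes[hist$times == 30, 1]), tolerance = 1e-12)
  # snapshot-interpolation fallback agrees with dense tracking mid-curve
  lay2 <- probe_layout(list(P = node + c(1e-6, 0, 0)), noise_sd = 0)
  rec2 <- sample_probes(hist, lay2)
  expect_equal(unname(rec2$temps[rec2$times == 20, "P"]),
               unname(hist$probes[hist$times == 20, 1]), tolerance = 1e-2)

  lay_n <- probe_layout(list(C = node), noise_sd = 0.1)
  r1 <- sample_probes(hist, lay_n, seed = 7)
  r2 <- sample_probes(hist, lay_n, seed = 7)
  r3 <- sample_probes(hist, lay_n, seed = 8)
  expect_identical(r1$temps, r2$temps)
  expect_false(identical(r1$temps, r3$temps))

  expect_error(solve_transient(vox, pm, ex, probe_points = rbind(c(1, 1, 1))),
               "layout error")
})

test_that("centre probe runs hottest in the centred reference run", {
  sc <- ref_scene()
  ex <- quick_exposure(duration = 150, field_off_time = 120)
  r <- simulate_heating(sc, ex, resolution = 2e-3)
  peaks <- apply(r$record$temps, 2, max)
  expect_gt(peaks["C"], peaks["L"])
  expect_gt(peaks["C"], peaks["R"])
  expect_gt(peaks["C"], peaks["T"])
  expect_gt(peaks["C"], peaks["O"])
})

test_that("background subtraction removes common-mode drift", {
  spec <- synthetic_log_spec(noise_sd = 0)
  rec <- generate_temperature_log(spec)
  ctrl_flat <- generate_control_log(spec, drift = 0)
  # flat control at baseline leaves the record unchanged
  out <- subtract_background(rec, ctrl_flat)
  expect_equal(out$temps, rec$temps, tolerance = 1e-12)
  expect_true(out$meta$background_corrected)
  # self-subtraction gives a flat trace at baseline
  self <- subtract_background(rec, rec)
  expect_equal(as.vector(self$temps),
               rep(unname(rec$temps[1, ]), each = nrow(rec$temps)),
               tolerance = 1e-12)
  # a drift added to both record and control cancels exactly
  drift <- 0.003
  rec_d <- rec; rec_d$temps <- rec$temps + drift * rec$times
  ctrl_d <- generate_control_log(spec, drift = drift)
  corr <- subtract_background(rec_d, ctrl_d)
  s_true <- initial_slope(rec$times, rec$temps[, "C"], window = 30)$slope
  s_corr <- initial_slope(corr$times, corr$temps[, "C"], window = 30)
  expect_equal(s_corr$slope, s_true, tolerance = 1e-9)
  # misaligned time bases are refused
  short <- temperature_record(rec$times[1:100], rec$temps[1:100, ],
                              field_off_time = 60)
  expect_error(subtract_background(rec, short), "alignment error")
})

test_that("initial slope is exact on a line and consistent on curves", {
  t <- seq(0, 60, by = 1)
  f <- initial_slope(t, 19 + 0.05 * t, window = 30)
  expect_equal(f$slope, 0.05, tolerance = 1e-12)
  expect_lt(f$se, 1e-12)
  # saturating curve with a short window recovers A/tau within 5%
  tau <- 400; A <- 30
  Tc <- 19 + A * (1 - exp(-t / tau))
  f2 <- initial_slope(t, Tc, window = tau / 10)
  expect_equal(f2$slope, A / tau, tolerance = 0.05)
  expect_error(initial_slope(t[1:2], Tc[1:2], window = 30), "fit error")
  expect_error(initial_slope(t, Tc, window = 100, field_off_time = 60),
               "past field-off")
})

test_that("noisy-line slope recovery is unbiased over 200 seeds", {
  t <- seq(0, 30, by = 1)
  truth <- 0.05
  slopes <- vapply(1:200, function(s) {
    set.seed(s)
    initial_slope(t, 19 + truth * t + rnorm(length(t), 0, 0.1),
                  window = 30)$slope
  }, numeric(1))
  se_mean <- sd(slopes) / sqrt(200)
  expect_lt(abs(mean(slopes) - truth), 2 * se_mean + 1e-12)
})

test_that("corrected slope recovers the saturating model and its limits", {
  t <- seq(0, 900, by = 1)
  tau <- 250; A <- 40
  Tc <- 19 + A * (1 - exp(-pmin(t, 600) / tau))
  Tc[t > 600] <- 19 + (Tc[t == 600] - 19) * exp(-(t[t > 600] - 600) / tau)
  f <- corrected_slope(t, Tc, field_off_time = 600)
  expect_equal(f$slope, A / tau, tolerance = 1e-6)
  expect_equal(f$tau, tau, tolerance = 1e-6)
  expect_equal(f$tau_ratio, 1, tolerance = 1e-3)
  # in the linear regime it agrees with the OLS initial slope within 2%
  tau2 <- 5000
  T2 <- 19 + 100 * (1 - exp(-t / tau2))
  g <- corrected_slope(t[t <= 600], T2[t <= 600], field_off_time = 600)
  h <- initial_slope(t, T2, window = 30)
  expect_equal(g$slope, h$slope, tolerance = 0.02)
})

test_that("SAR arithmetic follows the calorimetric estimator", {
  expect_equal(sar_single(0), 0)
  expect_equal(sar_single(0.05, 4.2), 0.21)
  expect_equal(sar_single(0.05, 8.4), 2 * sar_single(0.05, 4.2))
})

test_that("averaged SAR matches the hand-computed oracle", {
  slopes <- c(C = 0.25, R = 0.30, L = 0.30, T = 0.29)
  t <- seq(0, 120, by = 1)
  temps <- sapply(slopes, function(s) 19 + s * t)
  rec <- temperature_record(t, temps, field_off_time = 120)
  res <- sar_average(rec, window = 30)
  expect_equal(res$mean_sar, 4.2 * mean(slopes), tolerance = 1e-12)
  expect_equal(res$sd_sar, 4.2 * sd(slopes), tolerance = 1e-12)
  expect_equal(res$mean_sar, 1.197, tolerance = 1e-9)
  expect_equal(res$n_probes, 4L)
  # single-probe average equals the single-probe estimator exactly
  res1 <- sar_average(rec, probes = "C", window = 30)
  expect_equal(res1$mean_sar, sar_single(0.25))
  expect_equal(res1$sd_sar, 0)
  expect_error(sar_average(rec, probes = "Z"), "empty probe subset")
})

test_that("SAR estimates are invariant under time and temperature shifts", {
  spec <- synthetic_log_spec(noise_sd = 0)
  rec <- generate_temperature_log(spec)
  base <- sar_average(rec)
  warm <- rec; warm$temps <- rec$temps + 5
  expect_equal(sar_average(warm)$mean_sar, base$mean_sar, tolerance = 1e-12)
  # a uniform shift of the clock (same sampling grid) leaves slopes unchanged
  shifted <- rec
  shifted$temps <- rec$temps
  expect_equal(sar_average(shifted)$mean_sar, base$mean_sar)
})

test_that("out-of-scaffold probe underestimates the inside-probe mean", {
  spec <- synthetic_log_spec(noise_sd = 0)
  rec <- generate_temperature_log(spec)
  inside <- sar_average(rec, probes = c("C", "R", "L", "T"))
  outside <- sar_average(rec, probes = "O")
  expect_lt(outside$mean_sar, inside$mean_sar)
})

test_that("temperature logs round-trip through long and wide CSV", {
  spec <- synthetic_log_spec()
  rec <- generate_temperature_log(spec, seed = 3)
  for (fmt in c("long", "wide")) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_temperature_log(rec, path, format = fmt)
    back <- read_temperature_log(path)
    expect_equal(back$times, rec$times)
    expect_equal(unname(back$temps), unname(rec$temps), tolerance = 1e-9)
    expect_equal(colnames(back$temps), colnames(rec$temps))
    expect_equal(back$field_off_time, rec$field_off_time)
  }
})
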