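test_that("loop area reproduces exact areas of simple shapes", {
  # rectangle spanning H in [-Hc, Hc], B in [-Bs, Bs]: area 4 Hc Bs
  Hc <- 1000; Bs <- 0.2; Hmax <- 2000
  H <- seq(-Hmax, Hmax, length.out = 4001)
  B_asc <- ifelse(H < Hc, -Bs, Bs)
  B_desc <- ifelse(H > -Hc, Bs, -Bs)
  rect <- bh_loop(H, B_asc, B_desc, mass_density = 2700)
  expect_equal(loop_area(rect)$area, 4 * Hc * Bs, tolerance = 1e-3)
  expect_equal(loop_area(rect)$specific_area, 4 * Hc * Bs / 2700,
               tolerance = 1e-3)

  # ellipse with semi-axes (Hc, Bs): area pi Hc Bs within 0.1% at 1e3 samples
  H <- seq(-Hc, Hc, length.out = 1001)
  Bup <- Bs * sqrt(pmax(1 - (H / Hc)^2, 0))
  ell <- bh_loop(H, -Bup, Bup, mass_density = 2700)
  expect_equal(loop_area(ell)$area, pi * Hc * Bs, tolerance = 1e-3)
})

test_that("synthetic tanh loop is odd-symmetric and matches its closed form", {
  Bs <- 0.1; Hc <- 500; w <- 2000; Hmax <- 2e4
  loop <- synth_bh_loop(Bs, Hc, w, Hmax)
  # odd symmetry across branches: B_desc(-H) = -B_asc(H)
  expect_equal(rev(loop$B_desc), -loop$B_asc, tolerance = 1e-12)
  # area against the independent closed-form quadrature oracle
  expect_equal(loop_area(loop)$area,
               tanh_loop_area_closed(Bs, Hc, w, Hmax), tolerance = 1e-3)
  # anhysteretic limit: zero coercivity means zero enclosed area
  loop0 <- synth_bh_loop(Bs, 1e-9, w, Hmax)
  expect_lt(loop_area(loop0)$area, 1e-6 * loop_area(loop)$area)
  expect_error(synth_bh_loop(Bs, 500, w, H_max = 400), "parameter error")
})

test_that("loop area grows with coercivity and survives resampling/reversal", {
  Bs <- 0.1; w <- 2000; Hmax <- 2e4
  areas <- sapply(c(100, 300, 900, 2700),
                  function(hc) loop_area(synth_bh_loop(Bs, hc, w, Hmax))$area)
  expect_true(all(diff(areas) > 0))

  loop <- synth_bh_loop(Bs, 500, w, Hmax, n_samples = 801L)
  a_ref <- loop_area(loop)$area
  # uniform resampling
  H2 <- seq(-Hmax, Hmax, length.out = 1601)
  l2 <- bh_loop(H2, approx(loop$H, loop$B_asc, H2)$y,
                approx(loop$H, loop$B_desc, H2)$y)
  expect_equal(loop_area(l2)$area, a_ref, tolerance = 1e-4)
  # branch sample order reversal
  l3 <- bh_loop(rev(loop$H), rev(loop$B_asc), rev(loop$B_desc))
  expect_equal(loop_area(l3)$area, a_ref, tolerance = 1e-12)
})

test_that("minor-loop area is anchored, monotone and matches the oracle", {
  Bs <- 0.1; Hc <- 500; w <- 2000; Hmax <- 2e4
  loop <- synth_bh_loop(Bs, Hc, w, Hmax)
  expect_equal(minor_loop_area(loop, 0), 0)
  expect_equal(minor_loop_area(loop, Hmax), loop_area(loop)$area,
               tolerance = 1e-4)
  # at the coercive field: strictly inside (0, full area), polygon oracle
  a_hc <- minor_loop_area(loop, Hc)
  expect_gt(a_hc, 0)
  expect_lt(a_hc, loop_area(loop)$area)
  expect_equal(a_hc, tanh_loop_area_closed(Bs, Hc, w, Hc), tolerance = 1e-3)
  expect_warning(minor_loop_area(loop, 2 * Hmax), "clamped")

  # property: monotone non-decreasing in amplitude over random tanh loops
  set.seed(42)
  for (i in 1:20) {
    p <- c(Bs = runif(1, 0.01, 0.3), Hc = runif(1, 50, 5000),
           w = runif(1, 500, 5e4))
    l <- synth_bh_loop(p["Bs"], p["Hc"], p["w"], H_max = 1e5)
    amps <- sort(runif(8, 0, 1e5))
    expect_true(all(diff(minor_loop_area(l, amps)) >= -1e-12))
  }
})

test_that("malformed loops are rejected", {
  H <- seq(-1000, 1000, length.out = 101)
  expect_error(bh_loop(H, H * 1e-4, H * 1e-4 + c(rep(0.01, 100), 0.2)),
               "malformed-loop")
  expect_error(bh_loop(H, H * 1e-4 + 0.01, H * 1e-4), "malformed-loop")
})

test_that("BH loop CSV round-trips and the reader validates", {
  loop <- synth_bh_loop(0.1, 500, 2000, 2e4, n_samples = 201L,
                        mass_density = 2500)
  path <- withr::local_tempfile(fileext = ".csv")
  write_bh_loop(loop, path)
  l2 <- read_bh_loop(path)
  expect_equal(l2$H, loop$H)
  expect_equal(l2$B_asc, loop$B_asc, tolerance = 1e-9)
  expect_equal(l2$mass_density, 2500)
  expect_equal(loop_area(l2)$area, loop_area(loop)$area, tolerance = 1e-9)
})

test_that("default loop is calibrated to the rated exposure", {
  loop <- default_bh_loop()
  H0 <- 0.03 / MU0_T
  # per-cycle area at the rated amplitude gives 1 W/g adiabatic SAR
  area <- minor_loop_area(loop, H0)
  pp <- default_materials()$pp
  sar <- 4.2e3 * (4e5 * area / (pp$density * pp$specific_heat)) / 1e3
  expect_equal(sar, 1.0, tolerance = 1e-3)
})
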