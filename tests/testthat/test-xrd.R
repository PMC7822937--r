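# renderer-independent split pseudo-Voigt used to generate fixtures
spv_fixture <- function(x, x0, wl, wr, eta) {
  w <- ifelse(x < x0, wl, wr)
  u <- (x - x0) / w
  eta / (1 + u^2) + (1 - eta) * exp(-log(2) * u^2)
}

test_that("split pseudo-Voigt fits recover known peak shapes", {
  tt <- seq(24, 28, by = 0.01)
  # noiseless symmetric pseudo-Voigt of FWHM 0.4
  y <- 80 * spv_fixture(tt, 25.9, 0.2, 0.2, 0.5) + 10 + 0.1 * tt
  f <- fit_peak(data.frame(two_theta = tt, intensity = y), c(24.5, 27.5), "002")
  expect_rel_error(f$fwhm_obs, 0.4, 0.005)
  expect_rel_error(f$position, 25.9, 1e-4)
  expect_true(f$converged)

  # pure Gaussian input: mixing goes to the Gaussian limit
  sig <- 0.25
  yg <- 100 * exp(-(tt - 25.9)^2 / (2 * sig^2)) + 5
  fg <- fit_peak(data.frame(two_theta = tt, intensity = yg), c(24.5, 27.5))
  expect_lt(fg$eta, 0.05)
  expect_rel_error(fg$fwhm_obs, 2 * sqrt(2 * log(2)) * sig, 0.01)
})

test_that("stepped scans yield Bragg-consistent 002 and 004 positions", {
  sc <- render_diffraction(15.4, 11.9, 9.5, 8.5, 9.418, 6.884, seed = 8)
  f2 <- fit_peak(sc$stepped_002, c(23, 27), "002")
  f4 <- fit_peak(sc$stepped_004, c(50, 55), "004")
  d <- function(p) 1.5406 / (2 * sin(p / 2 * pi / 180))
  expect_rel_error(d(f4$position), d(f2$position) / 2, 0.002)
})

test_that("instrument broadening is removed in quadrature", {
  cag <- c(U = 0, V = 0, W = 0.01)  # constant 0.1 degree instrument width
  beta_inst <- 0.1
  expect_equal(correct_instrument(sqrt(2) * beta_inst, 15, cag),
               beta_inst * pi / 180, tolerance = 1e-12)
  # no instrument broadening leaves the observed width
  expect_equal(correct_instrument(0.5, 15, c(U = 0, V = 0, W = 0)),
               0.5 * pi / 180, tolerance = 1e-12)
  expect_error(correct_instrument(0.05, 15, cag), class = "rib_fit_error")
})

test_that("Scherrer equation inverts algebraically", {
  th <- 13 * pi / 180
  beta <- 0.9 * 0.15406 / (10 * cos(th))
  expect_equal(scherrer_cl(beta, th), 10, tolerance = 1e-12)
  expect_equal(scherrer_cl(2 * beta, th), 5, tolerance = 1e-12)
})

test_that("instrument-corrected Scherrer round-trips a known size", {
  cfg <- rib_config()
  th <- 12.95 * pi / 180
  L <- 18
  beta_s <- 0.9 * cfg$xrd$wavelength_nm / (L * cos(th))
  t <- tan(th)
  inst2 <- cfg$xrd$caglioti[["U"]] * t^2 + cfg$xrd$caglioti[["V"]] * t +
    cfg$xrd$caglioti[["W"]]
  beta_obs_deg <- sqrt((beta_s * 180 / pi)^2 + inst2)
  rec <- scherrer_cl(correct_instrument(beta_obs_deg, 12.95, cfg$xrd$caglioti),
                     th)
  expect_rel_error(rec, L, 0.01)
})

test_that("two-point Williamson-Hall separation is exact", {
  k <- 0.9; lam <- 0.15406
  th <- c(12.93, 26.62) * pi / 180
  L <- 25; eps <- 0.003
  beta <- (4 * eps * sin(th) + k * lam / L) / cos(th)
  wh <- williamson_hall(beta, th)
  expect_equal(wh$size_nm, L, tolerance = 1e-9)
  expect_equal(wh$strain, eps, tolerance = 1e-9)

  # strain-free: slope zero, L equals the Scherrer value from either point
  beta0 <- (k * lam / L) / cos(th)
  wh0 <- williamson_hall(beta0, th)
  expect_equal(wh0$strain, 0, tolerance = 1e-10)
  expect_equal(wh0$size_nm, scherrer_cl(beta0[1], th[1]), tolerance = 1e-9)

  # strain widens the higher-order reflection more
  expect_gt((beta - beta0)[2], (beta - beta0)[1])

  expect_error(williamson_hall(beta, rep(th[1], 2)), class = "rib_fit_error")
})

test_that("lattice parameters invert the hexagonal Bragg relation", {
  a <- 9.418; c <- 6.884; lam <- 1.5406
  pos <- function(h, k, l) {
    2 * asin(lam / (2 * hex_d_spacing(h, k, l, a, c))) * 180 / pi
  }
  lat <- lattice_parameters(pos(0, 0, 2), pos(0, 0, 4), pos(0, 3, 0))
  expect_rel_error(lat$a_axis, a, 5e-4)
  expect_rel_error(lat$c_axis, c, 5e-4)
  expect_equal(lat$c_from_002, lat$c_from_004, tolerance = 1e-9)

  # larger 030 angle means smaller a
  lat2 <- lattice_parameters(pos(0, 0, 2), pos(0, 0, 4), pos(0, 3, 0) + 0.1)
  expect_lt(lat2$a_axis, lat$a_axis)
})

test_that("full diffraction analysis is invariant to intensity scaling", {
  sc <- render_diffraction(15.4, 11.9, 9.5, 8.5, 9.418, 6.884, seed = 9)
  r1 <- analyze_xrd(sc$wide, sc$stepped_002, sc$stepped_004)
  scale2 <- function(d) dplyr::mutate(d, intensity = 5 * intensity)
  r2 <- analyze_xrd(scale2(sc$wide), scale2(sc$stepped_002),
                    scale2(sc$stepped_004))
  expect_equal(as.numeric(r2), as.numeric(r1), tolerance = 1e-6)
})

test_that("diffraction round trip recovers sizes and lattice constants", {
  tab <- toy_table(3, seed = 31)
  for (i in 1:3) {
    rec <- tab[i, ]
    sc <- render_diffraction(rec$CL002, rec$CL004, rec$CL030, rec$CL210,
                             rec$a_axis, rec$c_axis, seed = 40 + i)
    r <- analyze_xrd(sc$wide, sc$stepped_002, sc$stepped_004)
    expect_rel_error(r$CL002, rec$CL002, 0.02)
    expect_rel_error(r$CL004, rec$CL004, 0.02)
    expect_rel_error(r$CL030, rec$CL030, 0.02)
    expect_rel_error(r$a_axis, rec$a_axis, 0.001)
    expect_rel_error(r$c_axis, rec$c_axis, 0.001)
  }
})
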