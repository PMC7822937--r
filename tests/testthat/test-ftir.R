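make_spectrum <- function(f, from = 400, to = 4000, by = 2) {
  wn <- seq(from, to, by = by)
  tibble::tibble(wavenumber_cm1 = wn, absorbance = f(wn))
}

test_that("band areas integrate above the chord baseline", {
  # triangle of height 1 over a 100 cm^-1 band on zero background
  tri <- make_spectrum(function(x) pmax(0, 1 - abs(x - 1000) / 50))
  expect_equal(band_area(tri, 950, 1050), 50, tolerance = 1e-9)

  # a spectrum equal to its own chord nets zero area
  lin <- make_spectrum(function(x) 0.1 + 2e-4 * x)
  expect_equal(band_area(lin, 900, 1200), 0, tolerance = 1e-9)

  # Gaussian of known analytic area at 4 cm^-1 sampling
  g <- make_spectrum(function(x) exp(-(x - 1000)^2 / (2 * 20^2)), by = 4)
  expect_rel_error(band_area(g, 880, 1120), 20 * sqrt(2 * pi), 0.01)

  expect_error(band_area(tri, 100, 300), class = "rib_extract_error")
  dip <- make_spectrum(function(x) -exp(-(x - 1000)^2 / 800))
  expect_warning(res <- band_area(dip, 950, 1050))
  expect_equal(res, 0)
})

test_that("indices follow constructed band areas", {
  # two clean Gaussians: phosphate area 3x amide area
  f <- function(x) {
    3 / (30 * sqrt(2 * pi)) * exp(-(x - 1050)^2 / (2 * 30^2)) +
      1 / (15 * sqrt(2 * pi)) * exp(-(x - 1675)^2 / (2 * 15^2)) +
      0.02 / (4 * sqrt(2 * pi)) * exp(-(x - 870)^2 / (2 * 4^2)) +
      0.05 * exp(-(x - 603)^2 / (2 * 8^2)) +
      0.05 * exp(-(x - 566)^2 / (2 * 8^2))
  }
  sp <- make_spectrum(f)
  r <- ftir_indices(sp)
  expect_rel_error(r$MM, 3, 0.02)
  expect_rel_error(r$CC, 1 / 3, 0.02)
  expect_equal(r$MM * r$CC, 1, tolerance = 1e-9)
})

test_that("equal nu4 intensities give a crystallinity index of 2", {
  # flat-topped nu4 feature: identical corrected intensity at 605, 565, 595
  sp <- make_spectrum(function(x) {
    0.5 +
      0.2 * (x > 540 & x < 620) +
      0.3 * exp(-(x - 1035)^2 / 3200) +
      0.1 * exp(-(x - 1660)^2 / 450) +
      0.01 * exp(-(x - 872)^2 / 40)
  })
  expect_equal(ftir_indices(sp)$CI, 2, tolerance = 1e-9)
})

test_that("indices are invariant to spectrum scaling and grid direction", {
  sp <- render_ftir_spectrum(3.6, 0.0072, 3.85)
  r <- ftir_indices(sp)
  r_scaled <- ftir_indices(dplyr::mutate(sp, absorbance = 7.3 * absorbance))
  expect_equal(as.numeric(r_scaled), as.numeric(r), tolerance = 1e-9)
  r_rev <- ftir_indices(sp[rev(seq_len(nrow(sp))), ])
  expect_equal(as.numeric(r_rev), as.numeric(r), tolerance = 1e-9)
})

test_that("forward-rendered spectra round-trip all four indices", {
  cases <- tibble::tribble(
    ~mm,  ~cp,     ~ci,
    3.0,  0.0060,  3.4,
    3.6,  0.0072,  3.85,
    4.2,  0.0085,  4.4
  )
  for (i in seq_len(nrow(cases))) {
    sp <- render_ftir_spectrum(cases$mm[i], cases$cp[i], cases$ci[i],
                               noise_au = 5e-5, seed = i)
    r <- ftir_indices(sp)
    expect_rel_error(r$MM, cases$mm[i], 0.02)
    expect_rel_error(r$CP, cases$cp[i], 0.02)
    expect_rel_error(r$CI, cases$ci[i], 0.02)
    expect_rel_error(r$CC, 1 / cases$mm[i], 0.02)
  }
})
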