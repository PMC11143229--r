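wn <- seq(1400, 1800, by = 2)

test_that("extinction formula and round trip back to transmittance", {
  t0 <- spectrum(wn, rep(1, length(wn)), "transmittance")
  tv <- spectrum(wn, rep(0.95, length(wn)), "transmittance")
  e <- extinction_from_transmittance(tv, t0)
  expect_equal(unique(e$values), 0.05)
  expect_identical(e$kind, "extinction")

  # identical spectra give zero extinction
  e0 <- extinction_from_transmittance(t0, t0)
  expect_true(all(e0$values == 0))

  # one deviating point
  v <- rep(1, length(wn)); v[100] <- 0.8
  e1 <- extinction_from_transmittance(spectrum(wn, v, "transmittance"), t0)
  expect_equal(e1$values[100], 0.2)
  expect_true(all(e1$values[-100] == 0))

  # algebraic inverse: T_vg = T_0 * (1 - extinction), machine precision
  tv2 <- spectrum(wn, runif(length(wn), 0.3, 0.99), "transmittance")
  t02 <- spectrum(wn, runif(length(wn), 0.5, 1.0), "transmittance")
  ex <- extinction_from_transmittance(tv2, t02)
  expect_equal(t02$values * (1 - ex$values), tv2$values, tolerance = 1e-14)

  # errors
  expect_error(extinction_from_transmittance(
    spectrum(wn + 1, rep(0.9, length(wn)), "transmittance"), t0),
    class = "snf_error_grid_mismatch")
})

test_that("spectrum invariants are enforced", {
  expect_error(spectrum(rev(wn), rep(0.5, length(wn))), class = "snf_error_grid_order")
  expect_error(spectrum(wn, rep(1.2, length(wn)), "transmittance"),
               class = "snf_error_domain")
  expect_error(spectrum(wn, rep(NA_real_, length(wn))), class = "snf_error_nonfinite")
})

test_that("baseline reproduces a dip-free plasmon envelope to < 1% of peak", {
  lor <- 0.3 / (1 + ((wn - 1600) / 75)^2)
  b <- fit_baseline(spectrum(wn, lor, "extinction"))
  expect_lt(max(abs(b$values - lor)), 0.01 * 0.3)

  flat <- fit_baseline(spectrum(wn, rep(0.2, length(wn)), "extinction"))
  expect_lt(max(abs(flat$values - 0.2)), 1e-9)
})

test_that("baseline ignores an injected dip to < 2% of dip depth", {
  lor <- 0.3 / (1 + ((wn - 1600) / 75)^2)
  dip <- 0.06 * exp(-(wn - 1626)^2 / (2 * 8^2))
  b <- fit_baseline(spectrum(wn, lor - dip, "extinction"))
  win <- wn >= 1600 & wn <= 1700
  expect_lt(max(abs(b$values - lor)[win]), 0.02 * 0.06)
})

test_that("delta extinction turns dips into positive peaks of the right size", {
  lor <- 0.3 / (1 + ((wn - 1600) / 75)^2)
  sp <- spectrum(wn, lor, "extinction")
  b <- fit_baseline(sp)
  d0 <- delta_extinction(sp, b)
  expect_lt(max(abs(d0$values)), 0.01 * 0.3)   # own baseline -> ~zero

  dip1 <- 0.06 * exp(-(wn - 1626)^2 / (2 * 8^2))
  dip2 <- 0.04 * exp(-(wn - 1538)^2 / (2 * 8^2))
  sp2 <- spectrum(wn, lor - dip1 - dip2, "extinction")
  d <- delta_extinction(sp2, fit_baseline(sp2))
  win <- wn >= 1600 & wn <= 1700
  expect_equal(max(d$values[win]), 0.06, tolerance = 0.02)
  # the two notch positions recover as local peaks
  expect_equal(wn[win][which.max(d$values[win])], 1626, tolerance = 2)
  lo <- wn >= 1500 & wn < 1600
  expect_equal(wn[lo][which.max(d$values[lo])], 1538, tolerance = 2)
  # integrated dip area within 5% of the injected area
  expect_equal(sum(d$values[win]) * 2, sum(dip1[win]) * 2,
               tolerance = 0.05 * sum(dip1[win]) * 2)
})

test_that("amide window slicing is inclusive, idempotent and guarded", {
  g <- seq(1400, 1800, by = 1)
  d <- spectrum(g, rexp(length(g)) * 1e-3, "delta_extinction")
  w <- window_amide_I(d)
  expect_equal(length(w$wavenumbers), 101)
  expect_equal(range(w$wavenumbers), c(1600, 1700))
  expect_identical(window_amide_I(w), w)   # idempotent

  exact <- spectrum(seq(1600, 1700), rep(1e-3, 101), "delta_extinction")
  expect_identical(window_amide_I(exact)$wavenumbers, exact$wavenumbers)

  short <- spectrum(seq(1650, 1800), rep(1e-3, 151), "delta_extinction")
  expect_error(window_amide_I(short), class = "snf_error_range")
})

test_that("baseline requires enough anchor points", {
  g <- seq(1496, 1704, by = 2)
  sp <- spectrum(g, rep(0.1, length(g)), "extinction")
  expect_error(fit_baseline(sp), class = "snf_error_insufficient_anchor")
})

test_that("spectrum CSV round trip preserves grid, values and kind", {
  sp <- spectrum(wn, 0.3 / (1 + ((wn - 1600) / 75)^2), "extinction")
  path <- tempfile(fileext = ".csv")
  write_spectrum_csv(sp, path, provenance = list(source = "synthetic"))
  back <- read_spectrum_csv(path)
  expect_equal(back$wavenumbers, sp$wavenumbers)
  expect_equal(back$values, sp$values, tolerance = 1e-12)
  expect_identical(back$kind, "extinction")
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(side$kind, "extinction")
})

test_that("grid alignment utility interpolates linearly", {
  sp <- spectrum(c(1400, 1500, 1600), c(0, 0.1, 0.3), "extinction")
  al <- align_spectrum(sp, c(1450, 1550))
  expect_equal(al$values, c(0.05, 0.2))
  expect_error(align_spectrum(sp, c(1300, 1500)), class = "snf_error_range")
})
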