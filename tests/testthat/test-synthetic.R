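test_that("uncoupled plasmon peaks at its resonance and ignores g = 0 modes", {
  pm <- plasmon_model()     # 100 V overdrive -> 1600 cm-1
  expect_equal(pm$omega_p, 1600, tolerance = 1e-9)
  sp <- simulate_extinction(pm)
  expect_equal(sp$wavenumbers[which.max(sp$values)], 1600, tolerance = 2)
  expect_equal(max(sp$values), pm$amplitude, tolerance = 1e-6)

  off <- simulate_extinction(pm, list(vibrational_mode(1626, g = 0),
                                      vibrational_mode(1538, g = 0)))
  expect_equal(off$values, sp$values, tolerance = 1e-12)
})

test_that("a coupled mode carves a dip at its own frequency", {
  pm <- plasmon_model()
  sp <- simulate_extinction(pm, list(vibrational_mode(1626, g = 25)))
  win <- sp$wavenumbers >= 1610 & sp$wavenumbers <= 1645
  dip_at <- sp$wavenumbers[win][which.min(sp$values[win])]
  expect_equal(dip_at, 1626, tolerance = 3)

  # both notches of the amide bands appear
  sp2 <- simulate_extinction(pm, list(vibrational_mode(1626),
                                      vibrational_mode(1538)))
  base <- simulate_extinction(pm)
  d <- base$values - sp2$values
  for (target in c(1538, 1626)) {
    nb <- abs(sp2$wavenumbers - target) <= 10
    expect_equal(sp2$wavenumbers[nb][which.max(d[nb])], target, tolerance = 3)
  }
})

test_that("dip depth increases strictly with coupling strength", {
  pm <- plasmon_model()
  base <- simulate_extinction(pm)
  depth <- vapply(c(10, 25, 40), function(g) {
    sp <- simulate_extinction(pm, list(vibrational_mode(1626, g = g)))
    max(base$values - sp$values)
  }, numeric(1))
  expect_true(all(diff(depth) > 0))
  # and the spectrum approaches the uncoupled limit continuously
  tiny <- simulate_extinction(pm, list(vibrational_mode(1626, g = 0.5)))
  expect_lt(max(abs(tiny$values - base$values)), 1e-3 * max(base$values))
})

test_that("doping shifts follow the quarter-power gate law", {
  pm <- plasmon_model(v_g = 100, v_cnp = 0)
  expect_identical(apply_doping_shift(pm, 0)$omega_p, pm$omega_p)
  red <- apply_doping_shift(pm, -20)
  expect_lt(red$omega_p, pm$omega_p)
  expect_error(apply_doping_shift(pm, 5), class = "snf_error_domain")

  # scaling the overdrive by 16 doubles the resonance
  lo <- plasmon_model(v_g = 10)
  hi <- plasmon_model(v_g = 160)
  expect_equal(hi$omega_p / lo$omega_p, 2, tolerance = 1e-12)
})

test_that("stage presets carry the tabulated compositions and morphologies", {
  tab <- stage_preset()
  expect_equal(nrow(tab), 9)
  p <- stage_preset("279K-15min")
  expect_equal(c(p$f_beta, p$f_coil, p$f_turn), c(79, 14, 7))
  expect_equal(sum(p$f_beta, p$f_coil, p$f_turn), 100)
  expect_identical(p$morphology, "oligomer")
  expect_equal(stage_preset("348K-300min")$mean_length_nm, 95)
  expect_error(stage_preset("400K-1min"), class = "snf_error_unknown_preset")
})

test_that("amide bands round-trip their preset composition when noise-free", {
  for (nm in c("279K-15min", "279K-60min", "279K-300min", "299K-15min")) {
    p <- stage_preset(nm)
    band <- window_amide_I(make_amide_band(nm, noise_frac = 0, seed = 1))
    ct <- content_from_components(suppressWarnings(deconvolve_amide_I(band)))
    expect_equal(ct$content$percent, c(p$f_beta, p$f_coil, p$f_turn),
                 tolerance = 0.5)
  }
})

test_that("generators are bit-reproducible under a fixed seed", {
  b1 <- make_amide_band("279K-60min", 0.02, seed = 5)
  b2 <- make_amide_band("279K-60min", 0.02, seed = 5)
  expect_identical(b1, b2)
  expect_false(identical(b1, make_amide_band("279K-60min", 0.02, seed = 6)))

  i1 <- make_afm_image("348K-300min", "height", seed = 3, size = 256)
  i2 <- make_afm_image("348K-300min", "height", seed = 3, size = 256)
  expect_identical(i1$map, i2$map)

  c1 <- make_chain_config("aggregate", 3, 8, seed = 3)
  c2 <- make_chain_config("aggregate", 3, 8, seed = 3)
  expect_identical(c1, c2)
})

test_that("chain arrangements produce the intended contact structure", {
  disp <- make_chain_config("dispersed", 5, 10, seed = 2)
  expect_equal(contact_number(disp)$mean, 0)

  fib2 <- make_chain_config("fibril", 2, 10, seed = 2)
  expect_identical(contact_number(fib2)$per_replica[1],
                   brute_force_contacts(fib2))
  expect_gt(contact_number(fib2)$mean, 0)

  fib <- make_chain_config("fibril", 6, 12, seed = 4)
  al <- strand_axis_alignment(fib)
  expect_gt(al$p2, 0.95)
})

test_that("generator rejects impossible AFM densities and sizes", {
  expect_error(make_afm_image("348K-300min", "length", seed = 1, size = 256,
                              n_objects = 400), class = "snf_error_density")
  expect_error(make_afm_image("348K-300min", "height", seed = 1, size = 128),
               class = "snf_error_domain")
  expect_error(make_amide_band("348K-300min"), class = "snf_error_unknown_preset")
})
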