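test_that("ribbon stripes are detected with width, period and reference level", {
  img <- make_afm_image("348K-300min", "height", seed = 3, size = 512,
                        n_objects = 0, noise_sd = 0.05)
  rb <- detect_ribbons(img)
  expect_equal(rb$width_nm, 60, tolerance = 4 / 60)
  expect_equal(rb$period_nm, 120, tolerance = 8 / 120)
  expect_equal(rb$graphene_level, 2.0, tolerance = 0.1)
})

test_that("ribbon detection survives a 30-degree rotation", {
  img <- make_afm_image("348K-300min", "height", seed = 3, size = 512,
                        n_objects = 0, ribbon_angle_deg = 30, noise_sd = 0.05)
  rb <- detect_ribbons(img)
  expect_equal(rb$width_nm, 60, tolerance = 4 / 60)
  expect_equal(rb$period_nm, 120, tolerance = 8 / 120)
  expect_equal(abs(rb$orientation_deg) %% 180, 30, tolerance = 2)
})

test_that("a flat image raises a no-ribbon error", {
  set.seed(7)
  flat <- afm_image(matrix(rnorm(256 * 256, sd = 0.1), 256), pixel_nm = 2)
  expect_error(detect_ribbons(flat), class = "snf_error_no_ribbon")
})

test_that("a single drawn rod is measured to its drawn length", {
  img <- make_afm_image("348K-300min", "length", seed = 201, size = 512,
                        n_objects = 1, ribbon_height_nm = 0,
                        blur_sigma_px = 0, noise_sd = 0)
  seg <- segment_rods(img, NULL, min_height = 1, smooth_px = 0)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$length_nm, img$metadata$objects$length_nm,
               tolerance = 4 / seg$length_nm)   # +/- 2 px at 2 nm/px
})

test_that("skeleton length matches drawn length within 2 px over random rods", {
  errs_px <- vapply(1:10, function(k) {
    img <- make_afm_image("348K-300min", "length", seed = 300 + k,
                          size = 512, n_objects = 1, ribbon_height_nm = 0,
                          blur_sigma_px = 0, noise_sd = 0)
    seg <- segment_rods(img, NULL, min_height = 1, smooth_px = 0)
    (seg$length_nm - img$metadata$objects$length_nm) / img$pixel_nm
  }, numeric(1))
  expect_lt(max(abs(errs_px)), 2)
})

test_that("two parallel rods give exactly two segments; blank ribbons none", {
  m <- matrix(0, 256, 256)
  m[100:104, 60:160] <- 4
  m[120:124, 60:160] <- 4
  img <- afm_image(m, pixel_nm = 2)
  seg <- segment_rods(img, NULL, min_height = 1, smooth_px = 0)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$length_nm[1], 200, tolerance = 0.03 * 200)

  blank <- make_afm_image("348K-300min", "height", seed = 5, size = 256,
                          n_objects = 0)
  expect_equal(nrow(segment_rods(blank, detect_ribbons(blank), 1)), 0)
})

test_that("raising the detection threshold never increases segment count", {
  img <- make_afm_image("348K-300min", "height", seed = 9, size = 512)
  rb <- detect_ribbons(img)
  counts <- vapply(c(0.5, 1, 2, 3, 5),
                   function(mh) nrow(segment_rods(img, rb, mh)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("height recovery is unbiased across drawn heights", {
  img <- make_afm_image("348K-300min", "height", seed = 7, size = 512)
  rb <- detect_ribbons(img)
  seg <- segment_rods(img, rb, min_height = 1)
  expect_equal(mean(seg$peak_height_nm), 6.2, tolerance = 0.3 / 6.2)

  olig <- make_afm_image("279K-15min", "height", seed = 7, size = 512)
  oseg <- segment_rods(olig, detect_ribbons(olig), min_height = 0.4)
  expect_equal(mean(oseg$peak_height_nm), 0.8, tolerance = 0.3 / 0.8)
})

test_that("per-position statistics and SEM behave", {
  img <- make_afm_image("348K-300min", "height", seed = 7, size = 512)
  seg <- segment_rods(img, detect_ribbons(img), min_height = 1)
  thirds <- list(c(1, 170, 1, 512), c(171, 341, 1, 512), c(342, 512, 1, 512))
  st <- measure_heights(seg, thirds)
  expect_equal(st$n_positions, 3)
  expect_equal(st$mean_nm, 6.2, tolerance = 0.3 / 6.2)
  expect_true(st$sem_nm >= 0)

  # identical positions -> SEM exactly zero
  same <- measure_heights(seg, list(c(1, 512, 1, 512), c(1, 512, 1, 512)))
  expect_equal(same$sem_nm, 0)

  expect_warning(measure_heights(seg, list(c(1, 512, 1, 512), c(1, 2, 1, 2))),
                 class = "snf_warning_empty_position")
  expect_error(measure_heights(seg, list(c(1, 2, 1, 2))),
               class = "snf_error_degenerate_input")
})

test_that("band filter partitions segments and ignores ordering", {
  img <- make_afm_image("348K-300min", "length", seed = 21, size = 512)
  seg <- segment_rods(img, detect_ribbons(img), min_height = 1)
  band <- c(3, 4)
  inb <- sum(seg$peak_height_nm >= band[1] & seg$peak_height_nm <= band[2])
  ld <- length_distribution(seg, band)
  expect_equal(length(ld$lengths_nm), inb)
  expect_equal(inb + sum(seg$peak_height_nm < band[1] |
                           seg$peak_height_nm > band[2]), nrow(seg))

  perm <- seg[sample(nrow(seg)), ]
  ld2 <- length_distribution(perm, band)
  expect_equal(sort(ld2$lengths_nm), sort(ld$lengths_nm))

  # a band excluding everything flags an empty distribution
  tall <- make_afm_image("348K-300min", "height", seed = 7, size = 512)
  tseg <- segment_rods(tall, detect_ribbons(tall), min_height = 1)
  empty <- length_distribution(tseg, c(3, 4))
  expect_true(empty$empty)
  expect_true(is.nan(empty$mean_length_nm))
})

test_that("AFM image text and TIFF round trips preserve heights", {
  img <- make_afm_image("279K-60min", "height", seed = 2, size = 256)
  for (ext in c(".txt", ".tif")) {
    path <- tempfile(fileext = ext)
    write_afm_image(img, path)
    back <- read_afm_image(path)
    expect_equal(back$pixel_nm, img$pixel_nm)
    expect_lt(max(abs(back$map - img$map)), 1e-5)
  }
})
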