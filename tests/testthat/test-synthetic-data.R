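test_that("analytic buildup PDD has the constructed surface value and flat limit", {
  pdd <- make_buildup_pdd(dmax_cm = 1.5, surface_fraction = 0.15)
  expect_equal(pdd$values[1], 15)
  expect_equal(max(pdd$values), 100)

  # surface_fraction -> 1 limit: flat at 100 over the buildup region
  flat <- make_buildup_pdd(dmax_cm = 1.5, surface_fraction = 1 - 1e-9)
  in_buildup <- flat$depths <= 1.5
  expect_true(all(abs(flat$values[in_buildup] - 100) < 1e-5))

  expect_error(make_buildup_pdd(surface_fraction = 1.2), "surface_fraction")
  expect_error(make_buildup_pdd(dmax_cm = -1), "dmax")
})

test_that("default buildup curve's slab ratio matches the closed-form oracle", {
  # closed form for the parabolic buildup: mean over [0, t] divided by the
  # value at t, with U = t / dmax
  sf <- 0.30; U <- 0.5 / 1.5
  oracle <- (sf + (1 - sf) * (U - U^2 / 3)) / (sf + (1 - sf) * (2 * U - U^2))
  r <- predict_bolus_surface_ratio(make_buildup_pdd(), 0.5)
  expect_lt(abs(r - oracle), 1e-3)
  expect_gt(r, 0.70)
  expect_lt(r, 0.78)
})

test_that("pdd_curve validates its invariants", {
  expect_error(pdd_curve(c(0.5, 1), c(50, 100)), "start at 0")
  expect_error(pdd_curve(c(0, 1, 1), c(50, 100, 90)), "strictly increasing")
  expect_error(pdd_curve(c(0, 1, 2), c(50, -1, 90)), "non-negative")
  # two disjoint maximum regions rejected
  expect_error(pdd_curve(c(0, 1, 2, 3), c(100, 50, 100, 40)), "single global maximum")
})

test_that("degenerate penumbra gives an exact top-hat at the stated doses", {
  fs <- field_spec(3, 0, central_dose_cGy = 1000, penumbra_sigma_mm = 0,
                   bolus_film_ratio_truth = 0.749)
  sim <- simulate_field_dose(fs, coarse_grid())
  co <- map_coords(sim$film_dose)
  inside <- abs(co$y) <= 14.9
  expect_true(all(sim$film_dose$values[inside, inside] == 1000))
  outside <- abs(co$x) > 15.1
  expect_true(all(sim$film_dose$values[, outside] == 0))
  # bolus map is the truth ratio times the film map, pointwise
  expect_equal(sim$bolus_avg_dose$values, 0.749 * sim$film_dose$values)
  ic <- which.min(abs(co$y))
  expect_equal(sim$bolus_avg_dose$values[ic, ic], 749)
})

test_that("film-plane integral matches the analytic error-function integral", {
  fs <- field_spec(3, 0, central_dose_cGy = 1000, penumbra_sigma_mm = 3)
  gs <- coarse_grid(80, 0.25)
  sim <- simulate_field_dose(fs, gs)
  # blurring a top-hat with a (normalized) Gaussian preserves its integral:
  # D0 * w * h, up to the hard 3-sigma truncation
  num <- sum(sim$film_dose$values) * 0.25^2
  expect_lt(abs(num - 1000 * 30 * 30) / (1000 * 30 * 30), 0.001)
})

test_that("grids that cannot hold the field plus margin are rejected", {
  expect_error(
    simulate_field_dose(field_spec(4), coarse_grid(70)),
    "margin"
  )
})

test_that("bolus render follows Beer-Lambert and flags dynamic-range overflow", {
  tr <- test_truth()
  gs <- coarse_grid(70, 1)
  sim <- simulate_field_dose(field_spec(3, 0, central_dose_cGy = 1000,
                                        bolus_film_ratio_truth = 1.0), gs)
  imgs <- render_bolus_images(sim$bolus_avg_dose, tr, noiseless = TRUE)

  # zero dose: post equals pre exactly (no noise, same quantization)
  zero <- dose_map(matrix(0, 32, 32), 1, "bolus")
  z <- render_bolus_images(zero, tr, noiseless = TRUE)
  expect_identical(z$post$counts, z$pre$counts)

  # at 1000 cGy, slope 3e-4 and t = 5 mm: post/pre = exp(-1.5)
  co <- map_coords(sim$film_dose)
  ctr <- which.min(abs(co$y))
  expect_lt(abs(imgs$post$counts[ctr, ctr] / imgs$pre$counts[ctr, ctr] -
                exp(-1.5)), 1e-3)

  # transmission below one count is a hard error
  hot <- dose_map(matrix(40000, 16, 16), 1, "bolus")
  expect_error(render_bolus_images(hot, tr, noiseless = TRUE), "dynamic-range")
})

test_that("dose monotonically darkens the noiseless bolus image", {
  tr <- test_truth()
  doses <- seq(0, 3000, by = 500)
  counts <- vapply(doses, function(d) {
    img <- render_bolus_images(dose_map(matrix(d, 8, 8), 1, "bolus"), tr,
                               noiseless = TRUE)
    img$post$counts[4, 4]
  }, numeric(1))
  expect_true(all(diff(counts) < 0))
})

test_that("film render applies the configured netOD and errors out of range", {
  tr <- test_truth()
  zero <- dose_map(matrix(0, 16, 16), 0.4, "film")
  z <- render_film_scan(zero, tr, noiseless = TRUE)
  expect_identical(z$irradiated$counts, z$background$counts)

  # a netOD of 0.3 attenuates by 10^-0.3 ~ 0.5012; invert the default
  # response for the dose giving netOD 0.3: 0.55 D / (D + 800) = 0.3
  d03 <- 0.3 * 800 / (0.55 - 0.3)
  m <- render_film_scan(dose_map(matrix(d03, 16, 16), 0.4, "film"), tr,
                        noiseless = TRUE)
  expect_lt(abs(m$irradiated$counts[8, 8] / m$background$counts[8, 8] -
                10^(-0.3)), 1e-3)

  over <- dose_map(matrix(2000, 8, 8), 0.4, "film")
  expect_error(render_film_scan(over, tr), "extrapolation")
})

test_that("study bundles are byte-identical under a fixed seed", {
  cfg <- reduced_config(seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_study(cfg, d1, overwrite = TRUE)
  generate_study(cfg, d2, overwrite = TRUE)
  files <- sort(dir(d1))
  expect_identical(files, sort(dir(d2)))
  md5_1 <- tools::md5sum(file.path(d1, files))
  md5_2 <- tools::md5sum(file.path(d2, files))
  expect_identical(unname(md5_1), unname(md5_2))

  # refusing to clobber an existing bundle
  expect_error(generate_study(cfg, d1), "overwrite")
})

test_that("the default study manifest records the published protocol", {
  cfg <- default_study_config(seed = 1)
  expect_identical(cfg$angles, c(0, 22.5, 45, 67.5, 90))
  expect_identical(range(cfg$calibration$bolus_doses), c(100, 4000))
  expect_identical(max(cfg$calibration$film_doses), 1500)
  expect_identical(cfg$correction_angle_subset, c(0, 22.5, 45, 67.5))
  expect_equal(unname(cfg$ratio_truths[c("0", "67.5")]), c(0.749, 0.890))

  d <- withr::local_tempdir()
  generate_study(reduced_config(seed = 3), d, overwrite = TRUE)
  man <- jsonlite::read_json(file.path(d, "manifest.json"), simplifyVector = TRUE)
  expect_identical(man$seed, 3L)
  expect_identical(man$camera_spacing_mm, 0.4)
  expect_true(all(c("bolus_cal_doses_cGy", "angles_deg", "truth") %in% names(man)))
})
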