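table1_stats <- function() {
  tibble::tibble(
    gantry_angle_deg = c(0, 22.5, 45, 67.5, 90),
    mean_ratio = c(0.749, 0.760, 0.802, 0.890, 0.930)
  )
}

test_that("the published per-angle means give k = 0.800 +/- 0.064 (and 0.826 with 90 deg)", {
  k <- derive_correction_factor(table1_stats(), c(0, 22.5, 45, 67.5))
  expect_equal(round(k$k, 3), 0.800)
  expect_equal(round(k$k_sd, 3), 0.064)
  expect_identical(k$direction, "bolus_over_film")

  k_all <- derive_correction_factor(table1_stats(), c(0, 22.5, 45, 67.5, 90))
  expect_equal(round(k_all$k, 3), 0.826)

  k_same <- derive_correction_factor(
    tibble::tibble(gantry_angle_deg = 1:3, mean_ratio = c(0.8, 0.8, 0.8)), 1:3)
  expect_equal(k_same$k, 0.8)
  expect_equal(k_same$k_sd, 0)

  expect_error(derive_correction_factor(table1_stats(), numeric(0)), "empty")
  expect_error(derive_correction_factor(table1_stats(), c(0, 30)), "not present")
})

test_that("ratio maps and per-angle statistics behave on constructed fields", {
  film <- dose_map(matrix(500, 20, 20), 0.5, "film")
  bolus <- dose_map(0.8 * film$values, 0.5, "bolus")
  mask <- matrix(TRUE, 20, 20)
  r <- ratio_map(bolus, film, mask)
  expect_true(all(abs(r - 0.8) < 1e-12))
  st <- per_angle_stats(r, mask, 0)
  expect_equal(st$mean_ratio, 0.8)
  expect_equal(st$ratio_sd, 0)
  expect_identical(st$n_pixels, 400L)

  r2 <- matrix(rep(c(0.7, 0.9), each = 200), 20, 20)
  st2 <- per_angle_stats(r2, mask, 45)
  expect_equal(st2$mean_ratio, 0.8)

  expect_error(ratio_map(bolus, film, matrix(FALSE, 20, 20)), "empty")
  zero_film <- dose_map(matrix(0, 20, 20), 0.5, "film")
  expect_error(ratio_map(bolus, zero_film, mask), "positive")
})

test_that("ratio statistics are invariant to a common dose rescaling", {
  gs <- coarse_grid()
  sim <- simulate_field_dose(field_spec(3, 45, central_dose_cGy = 700), gs)
  mask <- field_roi(sim$film_dose)
  st1 <- per_angle_stats(ratio_map(sim$bolus_avg_dose, sim$film_dose, mask), mask, 45)
  for (c_scale in c(0.25, 3)) {
    b2 <- dose_map(sim$bolus_avg_dose$values * c_scale, 0.5, "bolus")
    f2 <- dose_map(sim$film_dose$values * c_scale, 0.5, "film")
    st2 <- per_angle_stats(ratio_map(b2, f2, mask), mask, 45)
    expect_equal(st2$mean_ratio, st1$mean_ratio, tolerance = 1e-12)
    expect_equal(st2$ratio_sd, st1$ratio_sd, tolerance = 1e-10)
  }
})

test_that("the field ROI is the half-maximum region eroded by 2 mm", {
  # top hat: mask should be the interior minus a 2 mm rim
  fs <- field_spec(3, 0, central_dose_cGy = 1000, penumbra_sigma_mm = 0)
  sim <- simulate_field_dose(fs, coarse_grid(70, 0.5))
  mask <- field_roi(sim$film_dose)
  co <- map_coords(sim$film_dose)
  inside <- outer(abs(co$y) <= 12.5, abs(co$x) <= 12.5, "&")
  beyond <- outer(abs(co$y) > 15, abs(co$x) > 15, "|")
  expect_true(all(mask[inside]))
  expect_true(!any(mask[beyond]))

  # blurred 3 x 3 field: mask area between 4 and 9 cm^2
  simb <- simulate_field_dose(field_spec(3, 0, central_dose_cGy = 1000,
                                         penumbra_sigma_mm = 3),
                              coarse_grid(70, 0.5))
  area_cm2 <- sum(field_roi(simb$film_dose)) * 0.5^2 / 100
  expect_gt(area_cm2, 4)
  expect_lt(area_cm2, 9)

  expect_error(field_roi(dose_map(matrix(0, 10, 10), 0.5, "film")), "positive")
})

test_that("apply_correction divides by k and keeps provenance", {
  bm <- dose_map(matrix(800, 4, 4), 0.5, "bolus")
  corr <- apply_correction(bm, 0.800)
  expect_equal(corr$values[1, 1], 1000)
  expect_identical(corr$provenance, "corrected")
  expect_identical(apply_correction(bm, 1)$values, bm$values)
  expect_error(apply_correction(bm, -2), "positive")

  # normal-incidence case: correcting with the pooled k leaves the known
  # residual mismatch between 0.749 and 0.800 (about 6.4%)
  gs <- coarse_grid()
  sim <- simulate_field_dose(field_spec(3, 0, central_dose_cGy = 700,
                                        bolus_film_ratio_truth = 0.749), gs)
  mask <- field_roi(sim$film_dose)
  corr0 <- apply_correction(sim$bolus_avg_dose, 0.800)
  rel <- abs(corr0$values[mask] - sim$film_dose$values[mask]) /
    sim$film_dose$values[mask]
  expect_lt(mean(rel), 0.07)
})

test_that("profile differences report mean absolute percent deviations", {
  gs <- coarse_grid()
  sim <- simulate_field_dose(field_spec(3, 0, central_dose_cGy = 700), gs)
  mask <- field_roi(sim$film_dose)
  expect_equal(profile_difference(sim$film_dose, sim$film_dose, "y", mask), 0)
  scaled <- dose_map(sim$film_dose$values * 1.02, 0.5, "film")
  expect_equal(profile_difference(scaled, sim$film_dose, "x", mask), 2,
               tolerance = 1e-9)
})

test_that("registration recovers identity, known shifts and known rotations", {
  gs <- coarse_grid(70, 0.5)
  ref <- simulate_field_dose(field_spec(c(2, 3), 0, central_dose_cGy = 700), gs)$film_dose

  regI <- register_maps(ref, ref)
  expect_lt(abs(regI$transform$rotation_deg), 0.05)
  expect_lt(max(abs(regI$transform$translation_mm)), 0.05)
  expect_gt(regI$transform$score, 0.9999)

  mov <- simulate_field_dose(field_spec(c(2, 3), 0, central_dose_cGy = 700,
                                        center_mm = c(2.0, -1.4)), gs)$film_dose
  reg <- register_maps(ref, mov)
  expect_lt(abs(reg$transform$translation_mm[1] - 2.0), 0.2)
  expect_lt(abs(reg$transform$translation_mm[2] + 1.4), 0.2)

  # moving map evaluated on rotated coordinates: expected recovery -phi
  phi <- -3
  th <- phi * pi / 180
  co <- map_coords(ref)
  Y <- rep(co$y, times = length(co$x)); X <- rep(co$x, each = length(co$y))
  ym <- cos(th) * Y - sin(th) * X
  xm <- sin(th) * Y + cos(th) * X
  ey <- 0.5 * (pracma::erf((15 - ym) / (sqrt(2) * 3)) + pracma::erf((15 + ym) / (sqrt(2) * 3)))
  ex <- 0.5 * (pracma::erf((10 - xm) / (sqrt(2) * 3)) + pracma::erf((10 + xm) / (sqrt(2) * 3)))
  rot <- dose_map(matrix(700 * ey * ex, length(co$y), length(co$x)), 0.5, "film")
  reg_rot <- register_maps(ref, rot)
  expect_lt(abs(reg_rot$transform$rotation_deg - 3), 0.25)

  flat <- dose_map(matrix(5, 40, 40), 0.5, "film")
  expect_error(register_maps(flat, flat), "featureless")
})

test_that("random rigid perturbations are recovered within one search step", {
  # 100 seeded trials on a rectangular field; moving map built analytically
  # on transformed coordinates (independent of the package's resampler)
  n_trial <- 100
  spacing <- 1
  nn <- 60
  y <- (seq_len(nn) - (nn + 1) / 2) * spacing
  Y <- rep(y, times = nn); X <- rep(y, each = nn)
  ref <- dose_map(analytic_field(y, y, 15, 10, 3, 700), spacing, "film")
  set.seed(123)
  ok <- 0L
  for (i in seq_len(n_trial)) {
    phi <- runif(1, -3, 3)
    t0 <- runif(2, -4, 4)
    th <- phi * pi / 180
    ym <- cos(th) * Y - sin(th) * X + t0[1]
    xm <- sin(th) * Y + cos(th) * X + t0[2]
    ey <- 0.5 * (pracma::erf((15 - ym) / (sqrt(2) * 3)) + pracma::erf((15 + ym) / (sqrt(2) * 3)))
    ex <- 0.5 * (pracma::erf((10 - xm) / (sqrt(2) * 3)) + pracma::erf((10 + xm) / (sqrt(2) * 3)))
    mov <- dose_map(matrix(700 * ey * ex, nn, nn), spacing, "film")
    # moving(p) = ref(A p) with A = (R_phi, t0); registration should find
    # T = A^{-1}: rotation -phi, translation -R_{-phi} t0
    reg <- register_maps(ref, mov)$transform
    exp_rot <- -phi
    thm <- -th
    exp_t <- -c(cos(thm) * t0[1] - sin(thm) * t0[2],
                sin(thm) * t0[1] + cos(thm) * t0[2])
    hit <- abs(reg$rotation_deg - exp_rot) <= 0.25 &&
      all(abs(reg$translation_mm - exp_t) <= 0.2)
    ok <- ok + hit
  }
  expect_gte(ok, 95)
})
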