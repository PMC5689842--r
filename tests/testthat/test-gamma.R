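test_that("identical distributions give gamma 0 and a 100% pass rate", {
  p <- gamma_pair(1)
  g <- gamma_map(p$ref, p$ref)
  expect_lt(max(g$gamma, na.rm = TRUE), 1e-12)
  expect_equal(g$pass_rate_pct, 100)
  expect_equal(pass_rate(g), 100)
  # below-threshold pixels are excluded
  expect_true(all(is.na(g$gamma[p$ref$values < 10])))
})

test_that("a uniform +3% discrepancy peaks at gamma 1 under global normalization", {
  # wide plateau so no cheaper off-position exists within the search radius
  fs <- field_spec(4, 0, central_dose_cGy = 1000, penumbra_sigma_mm = 2)
  sim <- simulate_field_dose(fs, coarse_grid(85, 0.5))
  ref <- sim$film_dose
  ev <- dose_map(ref$values * 1.03, 0.5, "film")
  g <- gamma_map(ref, ev)
  expect_equal(max(g$gamma, na.rm = TRUE), 1, tolerance = 1e-6)
  expect_equal(g$pass_rate_pct, 100)
})

test_that("a pure shift by exactly the DTA passes everywhere on a gradient", {
  n <- 48; sp <- 1
  x <- (seq_len(n) - (n + 1) / 2) * sp
  grad <- matrix(rep(100 + 2 * x, each = n), n, n)
  ref <- dose_map(grad, sp, "bolus")
  shifted <- dose_map(matrix(rep(100 + 2 * (x - 3), each = n), n, n), sp, "film")
  g <- gamma_map(ref, shifted)
  inner <- g$gamma[5:(n - 4), 5:(n - 4)]
  expect_true(all(inner[is.finite(inner)] <= 1 + 1e-6))
})

test_that("pass_rate counts the gamma <= 1 fraction", {
  fake <- structure(
    list(gamma = matrix(c(0.5, 0.5, 1.5, 1.5), 2, 2),
         n_evaluated = 4L,
         pass_rate_pct = 50,
         params = gamma_params(), pixel_spacing_mm = c(1, 1)),
    class = "gamma_result"
  )
  expect_equal(pass_rate(fake), 50)
})

test_that("gamma agrees with the brute-force oracle on seeded random pairs", {
  params <- gamma_params(search_step_fraction = 1 / 50)
  for (seed in 1:5) {
    p <- gamma_pair(seed)
    gf <- gamma_map(p$ref, p$ev, params)
    go <- gamma_brute_oracle(p$ref, p$ev)
    expect_lt(max(abs(gf$gamma - go$gamma), na.rm = TRUE), 1e-3)
  }
})

test_that("a single hot pixel fails identically in both implementations", {
  p <- gamma_pair(99, noise = 0)
  ev <- p$ev$values
  ctr <- which(p$ref$values == max(p$ref$values), arr.ind = TRUE)[1, ]
  ev[ctr[1], ctr[2]] <- ev[ctr[1], ctr[2]] * 1.05
  evm <- dose_map(ev, p$ev$pixel_spacing_mm, "film")
  params <- gamma_params(search_step_fraction = 1 / 50)
  gf <- gamma_map(p$ref, evm, params)
  go <- gamma_brute_oracle(p$ref, evm)
  expect_identical(which(gf$gamma > 1), which(go$gamma > 1))
})

test_that("gamma grows with dose discrepancy and shrinks with looser criteria", {
  # On a gradient-free plateau a uniform discrepancy scaling is provably
  # monotone in gamma (with spatial gradients the DTA search can offset a
  # larger dose error, so monotonicity is only guaranteed pointwise here)
  sim <- simulate_field_dose(field_spec(3, 0, central_dose_cGy = 1000,
                                        penumbra_sigma_mm = 0),
                             coarse_grid(70, 0.5))
  ref <- sim$film_dose
  gprev <- NULL
  for (c_scale in c(1, 2, 3)) {
    ev <- dose_map(ref$values * (1 + 0.01 * c_scale), 0.5, "film")
    g <- gamma_map(ref, ev)
    if (!is.null(gprev)) {
      ok <- is.finite(g$gamma)
      expect_true(all(g$gamma[ok] >= gprev$gamma[ok] - 1e-9))
    }
    gprev <- g
  }

  # loosening either criterion never lowers the pass rate
  p <- gamma_pair(7, noise = 0.03)
  ref <- p$ref
  ev2 <- dose_map(pmax(ref$values + 2 * (p$ev$values - ref$values), 0),
                  p$ev$pixel_spacing_mm, "film")
  base <- gamma_map(ref, ev2, gamma_params(2, 2))
  expect_gte(gamma_map(ref, ev2, gamma_params(4, 2))$pass_rate_pct,
             base$pass_rate_pct)
  expect_gte(gamma_map(ref, ev2, gamma_params(2, 4))$pass_rate_pct,
             base$pass_rate_pct)
})

test_that("local normalization tightens high-dose scoring relative to global", {
  p <- gamma_pair(13, noise = 0.05)
  g_global <- gamma_map(p$ref, p$ev)
  g_local <- gamma_map(p$ref, p$ev, gamma_params(local_normalization = TRUE))
  ok <- is.finite(g_global$gamma)
  # local dd is never larger than global dd, so gamma never decreases
  expect_true(all(g_local$gamma[ok] >= g_global$gamma[ok] - 1e-9))
})

test_that("degenerate inputs are rejected", {
  zero <- dose_map(matrix(0, 8, 8), 1, "bolus")
  one <- dose_map(matrix(1, 8, 8), 1, "film")
  expect_error(gamma_map(zero, one), "positive")
  expect_error(gamma_params(dose_criterion_pct = -3), "positive")
  expect_error(gamma_params(low_dose_threshold_pct = 100), "threshold")
  big <- dose_map(matrix(1, 128, 128), 1, "bolus")
  expect_error(gamma_brute_oracle(big, big), "too large")
})
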