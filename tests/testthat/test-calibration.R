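test_that("an exact linear series is fitted exactly", {
  cal <- fit_bolus_calibration(c(0, 1000, 2000), c(0, 0.30, 0.60))
  expect_equal(cal$slope, 3.0e-4, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-12)
  expect_length(cal$flagged, 0)

  expect_error(fit_bolus_calibration(c(0, 1000), c(0, 0.3)), ">= 3")
  expect_error(fit_bolus_calibration(c(0, 0, 0), c(0, 0.1, 0.2)), "distinct")
})

test_that("a noiseless synthetic calibration series returns the generator slope", {
  tr <- test_truth()
  doses <- c(100, 500, 1000, 2000, 3000, 4000)
  mu <- vapply(doses, function(d) {
    p <- render_bolus_images(dose_map(matrix(d, 48, 48), 0.2, "bolus"), tr,
                             noiseless = TRUE)
    mean_absorption(p$pre, p$post, tr$bolus_thickness_mm)
  }, numeric(1))
  cal <- fit_bolus_calibration(doses, mu)
  expect_lt(abs(cal$slope / tr$bolus_slope - 1), 1e-3)
  expect_lt(abs(cal$intercept), 1e-4)
})

test_that("tidy and glance summarize the bolus fit", {
  cal <- fit_bolus_calibration(c(100, 1000, 2000, 4000),
                               c(0.031, 0.301, 0.599, 1.2005))
  td <- tidy(cal)
  expect_identical(td$term, c("intercept", "slope"))
  expect_true(all(td$conf.low < td$estimate & td$estimate < td$conf.high))
  gl <- glance(cal)
  expect_identical(gl$n, 4L)
  expect_gt(gl$r.squared, 0.999)
})

test_that("film calibration interpolates monotonically and inverts exactly at knots", {
  doses <- c(0, 250, 500, 1000, 1500)
  ods <- c(0, 0.13, 0.21, 0.31, 0.36)
  fc <- fit_film_calibration(doses, ods)
  # linear segments stay linear under the monotone interpolant
  lin <- fit_film_calibration(c(0, 500, 1000), c(0, 0.1, 0.2))
  expect_equal(lin$netod_of_dose(250), 0.05, tolerance = 1e-9)
  # round trip at every knot, to the bisection tolerance
  expect_equal(fc$dose_of_netod(fc$netod_of_dose(doses)), doses, tolerance = 0.02)
  expect_error(fit_film_calibration(c(0, 100, 200), c(0, 0.2, 0.1)),
               "strictly increasing")
})

test_that("film dose recovery is within 0.5% mid-range for the generator truth", {
  tr <- test_truth()
  pts <- tr$film_netod_points
  fc <- fit_film_calibration(pts$dose_cGy, pts$net_od)
  mid <- c(300, 600, 700, 900, 1200)
  rec <- fc$dose_of_netod(0.55 * mid / (mid + 800))
  expect_true(all(abs(rec / mid - 1) < 0.005))
})

test_that("map_to_dose applies the linear and interpolated inverses", {
  cal <- fit_bolus_calibration(c(0, 1000, 2000), c(0, 0.30, 0.60),
                               dose_range = c(0, 4000))
  m <- absorption_map(matrix(c(0.300, 0, 0.15, 0.6), 2, 2), 0.2, 5)
  # the exactly-zero signal sits on the range boundary and clips (warned)
  dm <- suppressWarnings(map_to_dose(m, cal))
  expect_equal(dm$values, matrix(c(1000, 0, 500, 2000), 2, 2), tolerance = 1e-9)
  expect_identical(dm$provenance, "bolus")

  # out-of-range pixels clip to the range ends with a warning
  m_hot <- absorption_map(matrix(c(0.3, 1.5), 1, 2), 0.2, 5)
  expect_warning(dm_hot <- map_to_dose(m_hot, cal), "clipped")
  expect_equal(dm_hot$values[1, 2], 4000)

  fc <- fit_film_calibration(c(0, 500, 1000, 1500), c(0, 0.21, 0.31, 0.36))
  odm <- od_map(matrix(0.21, 3, 3), 0.1693)
  fdm <- map_to_dose(odm, fc)
  expect_equal(fdm$values[1, 1], 500, tolerance = 0.5)
  expect_identical(fdm$provenance, "film")
})

test_that("dose conversion is monotone in the signal", {
  cal <- fit_bolus_calibration(c(0, 1000, 2000), c(0.001, 0.301, 0.601))
  sig <- seq(0.001, 0.601, length.out = 40)
  d <- suppressWarnings(map_to_dose(absorption_map(matrix(sig, 1), 0.2, 5), cal))$values
  expect_true(all(diff(as.vector(d)) > 0))

  fc <- fit_film_calibration(c(0, 500, 1000, 1500), c(0, 0.21, 0.31, 0.36))
  od <- seq(0, 0.36, length.out = 40)
  fd <- map_to_dose(od_map(matrix(od, 1), 0.2), fc)$values
  expect_true(all(diff(as.vector(fd)) >= 0))
})

test_that("simulated series recover the slope without bias (small batch)", {
  # high-dose renders legitimately clip a few near-zero counts
  rec <- suppressWarnings(simulate_calibration_recovery(n_sim = 40, seed = 7))
  expect_lt(abs(mean(rec$slope) / 3.00e-4 - 1), 0.005)
  # coverage at n = 40 is noisy; just require a sane band
  expect_gt(mean(rec$covered), 0.75)
})
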