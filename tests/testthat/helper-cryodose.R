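# Shared fixtures, all built in code.

# default generator truth used throughout the tests
test_truth <- function(...) generator_truth(...)

# a coarse grid spec for fast field simulations
coarse_grid <- function(extent_mm = 70, spacing_mm = 0.5) {
  list(extent_mm = extent_mm, pixel_spacing_mm = spacing_mm)
}

# analytic separable open-field dose (duplicates the physics, not the code:
# used as an independent surface for registration / gamma fixtures)
analytic_field <- function(y, x, half_y, half_x, sigma, d0) {
  ey <- 0.5 * (pracma::erf((half_y - y) / (sqrt(2) * sigma)) +
               pracma::erf((half_y + y) / (sqrt(2) * sigma)))
  ex <- 0.5 * (pracma::erf((half_x - x) / (sqrt(2) * sigma)) +
               pracma::erf((half_x + x) / (sqrt(2) * sigma)))
  d0 * (ey %o% ex)
}

# a compact smooth reference/evaluated dose-map pair for gamma testing;
# the evaluated map is the reference with small multiplicative noise
gamma_pair <- function(seed, n = 32, spacing = 2, noise = 0.04) {
  set.seed(seed)
  y <- (seq_len(n) - (n + 1) / 2) * spacing
  f <- 100 * exp(-(y / 12)^2) %o% exp(-(y / 12)^2)
  ev <- f * (1 + noise * matrix(rnorm(n * n), n, n))
  list(
    ref = dose_map(f, spacing, "bolus"),
    ev = dose_map(pmax(ev, 0), spacing, "film")
  )
}

# fast reduced study configuration (coarser grids, fewer cases) for
# pipeline-contract tests where full resolution is unnecessary
reduced_config <- function(seed = 1) {
  default_study_config(
    seed = seed,
    film_spacing_mm = 0.4,
    camera_spacing_mm = 0.4,
    calibration = list(
      bolus_doses = c(100, 500, 1000, 2000, 3000, 4000),
      film_doses = c(0, 100, 500, 1000, 1500),
      roi_px = 48L
    ),
    angles = c(0, 45),
    ratio_truths = c(`0` = 0.749, `45` = 0.802),
    correction_angle_subset = c(0, 45),
    arrangements = default_validation_arrangements()["pop_0_180"]
  )
}
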