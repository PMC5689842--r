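#' Fit the cryogel bolus dose-response calibration
#'
#' Ordinary least squares of mean absorption coefficient on delivered dose,
#' over the response's linear range. The point estimates (slope alpha in
#' mm^-1 cGy^-1 and intercept in mm^-1) are OLS; the slope standard error
#' is heteroscedasticity-consistent (HC3 sandwich), because optical signal
#' variance grows steeply with dose (transmission falls as
#' `exp(-alpha t D)`, so high-dose points are read from far fewer counts)
#' and the classical OLS standard error badly understates the slope
#' uncertainty under that noise structure. Points with absolute studentized
#' residual above 3 are flagged as potentially outside the linear range
#' (flagged, not dropped).
#'
#' @param doses Delivered doses in cGy (>= 3 distinct values).
#' @param signals Mean absorption coefficients (mm^-1), e.g. from
#'   [mean_absorption()].
#' @param dose_range Validity range (cGy) for later dose conversion;
#'   defaults to `(0, max(doses))` — the fitted line is anchored near zero
#'   by its intercept.
#' @return A `bolus_calibration` with `slope`, `intercept`, `slope_se`,
#'   `dose_range`, `flagged` (indices), and the underlying `lm` fit.
#' @export
#' @examples
#' cal <- fit_bolus_calibration(c(0, 1000, 2000), c(0, 0.30, 0.60))
#' tidy(cal)
fit_bolus_calibration <- function(doses, signals, dose_range = NULL) {
  doses <- as.numeric(doses); signals <- as.numeric(signals)
  if (length(doses) != length(signals) || length(doses) < 3) {
    stop("need >= 3 (dose, signal) points", call. = FALSE)
  }
  if (length(unique(doses)) < 3) stop("doses must include >= 3 distinct levels", call. = FALSE)
  fit <- lm(signals ~ doses)
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("degenerate calibration: fitted slope is not positive", call. = FALSE)
  }
  # suppressWarnings: summary.lm inside vcovHC warns on exact (noise-free) fits
  slope_se <- suppressWarnings(sqrt(sandwich::vcovHC(fit, type = "HC3")[2, 2]))
  # suppressed: rstudent warns about "essentially perfect" fits on exact lines
  stud <- suppressWarnings(stats::rstudent(fit))
  flagged <- which(is.finite(stud) & abs(stud) > 3)
  if (is.null(dose_range)) dose_range <- c(0, max(doses))
  if (dose_range[1] >= dose_range[2]) stop("dose_range min must be < max", call. = FALSE)
  structure(
    list(
      slope = slope,
      intercept = unname(coef(fit)[1]),
      slope_se = slope_se,
      dose_range = as.numeric(dose_range),
      flagged = flagged,
      fit = fit,
      n = length(doses)
    ),
    class = "bolus_calibration"
  )
}

#' @export
print.bolus_calibration <- function(x, ...) {
  cat(sprintf(
    "<bolus_calibration> slope %.4g +/- %.2g mm^-1 cGy^-1, intercept %.3g mm^-1, range [%g, %g] cGy, n = %d\n",
    x$slope, x$slope_se, x$intercept, x$dose_range[1], x$dose_range[2], x$n
  ))
  if (length(x$flagged)) {
    cat("  flagged (|studentized residual| > 3):", paste(x$flagged, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.bolus_calibration <- function(x, conf.level = 0.95, ...) {
  tcrit <- qt(1 - (1 - conf.level) / 2, df = x$n - 2)
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(suppressWarnings(sqrt(sandwich::vcovHC(x$fit, type = "HC3")[1, 1])),
                  x$slope_se),
    conf.low = estimate - tcrit * std.error,
    conf.high = estimate + tcrit * std.error
  )
}

#' @export
glance.bolus_calibration <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, slope_se = x$slope_se, intercept = x$intercept,
    r.squared = suppressWarnings(summary(x$fit)$r.squared), n = x$n,
    n_flagged = length(x$flagged),
    dose_min = x$dose_range[1], dose_max = x$dose_range[2]
  )
}

#' Confidence interval for the calibration slope
#'
#' Two-sided t interval using the HC3 slope standard error.
#'
#' @param cal A `bolus_calibration`.
#' @param level Confidence level.
#' @return Length-2 numeric `(lower, upper)`.
#' @export
slope_confint <- function(cal, level = 0.95) {
  stopifnot(inherits(cal, "bolus_calibration"))
  tcrit <- qt(1 - (1 - level) / 2, df = cal$n - 2)
  cal$slope + c(-1, 1) * tcrit * cal$slope_se
}

#' Simulate repeated bolus calibration series and summarize slope recovery
#'
#' Monte Carlo check of the calibration chain: for each replicate, renders
#' a noisy pre/post image pair (uniform dose, default generator truth) at
#' every dose level, extracts the mean absorption signal, fits the
#' calibration, and records the slope estimate and whether the true slope
#' falls inside the 95% confidence interval.
#'
#' @param n_sim Number of simulated calibration series.
#' @param doses Dose levels per series (cGy).
#' @param truth A [generator_truth()].
#' @param roi_px Side length of the uniform calibration image (pixels).
#' @param pixel_spacing_mm Camera pixel spacing (mm).
#' @param seed Integer seed.
#' @return A tibble with one row per replicate: `slope`, `slope_se`,
#'   `covered` (logical).
#' @export
simulate_calibration_recovery <- function(n_sim = 500,
                                          doses = c(100, 250, 500, 750, 1000, 1500,
                                                    2000, 2500, 3000, 3500, 4000),
                                          truth = generator_truth(),
                                          roi_px = 64L,
                                          pixel_spacing_mm = 0.2,
                                          seed = 1) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_sim), function(i) {
      mu <- vapply(doses, function(d) {
        dm <- dose_map(matrix(d, roi_px, roi_px), pixel_spacing_mm, "bolus")
        p <- render_bolus_images(dm, truth)
        mean_absorption(p$pre, p$post, truth$bolus_thickness_mm)
      }, numeric(1))
      cal <- fit_bolus_calibration(doses, mu)
      ci <- slope_confint(cal)
      tibble::tibble(
        sim = i, slope = cal$slope, slope_se = cal$slope_se,
        covered = ci[1] <= truth$bolus_slope && truth$bolus_slope <= ci[2]
      )
    })
    do.call(rbind, rows)
  })
}

#' Fit the film net-optical-density calibration
#'
#' Stores the strictly monotone (dose, netOD) points and exposes a monotone
#' shape-preserving cubic interpolant plus its numeric inverse (bisection
#' to 0.01 cGy). No parametric model is imposed on the film response.
#'
#' @param doses Doses in cGy, >= 3 distinct values.
#' @param net_ods Net optical densities, strictly increasing with dose.
#' @return A `film_calibration` with `points` (tibble), `dose_range`, and
#'   interpolant closures `netod_of_dose` / `dose_of_netod`.
#' @export
#' @examples
#' fc <- fit_film_calibration(c(0, 500, 1000, 1500), c(0, 0.21, 0.31, 0.36))
#' fc$dose_of_netod(fc$netod_of_dose(700))
fit_film_calibration <- function(doses, net_ods) {
  ord <- order(doses)
  doses <- as.numeric(doses)[ord]; net_ods <- as.numeric(net_ods)[ord]
  if (length(doses) < 3) stop("need >= 3 calibration points", call. = FALSE)
  if (any(diff(doses) <= 0)) stop("doses must be distinct", call. = FALSE)
  if (any(diff(net_ods) <= 0)) {
    stop("netOD must be strictly increasing with dose", call. = FALSE)
  }
  fwd <- splinefun(doses, net_ods, method = "monoH.FC")
  dose_range <- range(doses)
  inv <- function(od) {
    vapply(od, function(o) {
      if (o <= net_ods[1]) return(dose_range[1])
      if (o >= net_ods[length(net_ods)]) return(dose_range[2])
      uniroot(function(d) fwd(d) - o, interval = dose_range, tol = 0.01)$root
    }, numeric(1))
  }
  structure(
    list(
      points = tibble::tibble(dose_cGy = doses, net_od = net_ods),
      dose_range = dose_range,
      netod_of_dose = fwd,
      dose_of_netod = inv
    ),
    class = "film_calibration"
  )
}

#' @export
print.film_calibration <- function(x, ...) {
  cat(sprintf("<film_calibration> %d points, dose range [%g, %g] cGy, netOD range [%.3g, %.3g]\n",
              nrow(x$points), x$dose_range[1], x$dose_range[2],
              min(x$points$net_od), max(x$points$net_od)))
  invisible(x)
}

#' @export
tidy.film_calibration <- function(x, ...) x$points

#' @export
glance.film_calibration <- function(x, ...) {
  tibble::tibble(
    n = nrow(x$points),
    dose_min = x$dose_range[1], dose_max = x$dose_range[2],
    net_od_max = max(x$points$net_od)
  )
}

#' Convert a signal map to a dose map
#'
#' Applies the relevant calibration: for an [absorption_map()],
#' `D = (mu - intercept) / slope`; for an [od_map()], the numeric inverse of
#' the monotone film interpolant. Pixels whose converted dose falls outside
#' the calibration's validity range are clipped to the range ends, and the
#' clipped count is reported as a warning.
#'
#' @param map An [absorption_map()] or [od_map()].
#' @param cal The matching `bolus_calibration` or `film_calibration`.
#' @return A [dose_map()] with provenance `"bolus"` or `"film"`.
#' @export
map_to_dose <- function(map, cal) {
  if (inherits(map, "absorption_map")) {
    stopifnot(inherits(cal, "bolus_calibration"))
    dose <- (map$values - cal$intercept) / cal$slope
    rng <- cal$dose_range
    prov <- "bolus"
  } else if (inherits(map, "od_map")) {
    stopifnot(inherits(cal, "film_calibration"))
    od <- map$values
    rng <- cal$dose_range
    # fast path: interpolate dose on a dense netOD grid (the inverse is
    # monotone), then clip; bisection accuracy is kept by the grid density
    d_knots <- seq(rng[1], rng[2], length.out = 2048L)
    od_knots <- cal$netod_of_dose(d_knots)
    keep <- c(TRUE, diff(od_knots) > 0)
    od_knots <- od_knots[keep]; d_knots <- d_knots[keep]
    inv_fast <- splinefun(od_knots, d_knots, method = "monoH.FC")
    dose <- matrix(inv_fast(pmin(pmax(od, min(od_knots)), max(od_knots))),
                   nrow(od), ncol(od))
    prov <- "film"
  } else {
    stop("map must be an absorption_map or od_map", call. = FALSE)
  }
  n_out <- sum(dose < rng[1] | dose > rng[2])
  if (n_out > 0) {
    warning(sprintf("%d pixel(s) outside the calibration dose range were clipped", n_out),
            call. = FALSE)
  }
  dose <- pmin(pmax(dose, rng[1]), rng[2])
  dose <- pmax(dose, 0)
  dose_map(matrix(dose, nrow(map$values), ncol(map$values)),
           map$pixel_spacing_mm, provenance = prov)
}
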