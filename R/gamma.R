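#' Gamma-index evaluation criteria
#'
#' Parameters of the 2D gamma analysis: dose-difference criterion (percent
#' of the reference maximum under global normalization),
#' distance-to-agreement (mm), low-dose threshold (percent of the reference
#' maximum below which reference pixels are excluded), and the search
#' geometry (radius as a multiple of the DTA, sampling step as a fraction
#' of the DTA). The defaults are the 3%/3 mm, 10%-threshold protocol.
#'
#' @param dose_criterion_pct Dose-difference criterion (% of reference max).
#' @param dta_mm Distance-to-agreement criterion (mm).
#' @param low_dose_threshold_pct Exclusion threshold (% of reference max).
#' @param search_radius_factor Search radius, in multiples of `dta_mm`.
#' @param search_step_fraction Search lattice step, as a fraction of `dta_mm`.
#' @param local_normalization If `TRUE`, normalize the dose difference to
#'   the local reference dose instead of the global maximum.
#' @return A `gamma_params` object.
#' @export
#' @examples
#' gamma_params()
gamma_params <- function(dose_criterion_pct = 3, dta_mm = 3,
                         low_dose_threshold_pct = 10,
                         search_radius_factor = 3,
                         search_step_fraction = 0.1,
                         local_normalization = FALSE) {
  vals <- c(dose_criterion_pct, dta_mm, low_dose_threshold_pct,
            search_radius_factor, search_step_fraction)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all gamma parameters must be positive", call. = FALSE)
  }
  if (low_dose_threshold_pct >= 100) {
    stop("low-dose threshold must be below 100%", call. = FALSE)
  }
  structure(
    list(
      dose_criterion_pct = dose_criterion_pct,
      dta_mm = dta_mm,
      low_dose_threshold_pct = low_dose_threshold_pct,
      search_radius_factor = search_radius_factor,
      search_step_fraction = search_step_fraction,
      local_normalization = isTRUE(local_normalization)
    ),
    class = "gamma_params"
  )
}

# offsets (mm) on a polar-bounded lattice, sorted by distance
.gamma_offsets <- function(radius_mm, step_mm) {
  g <- seq(-radius_mm, radius_mm, by = step_mm)
  off <- expand.grid(dy = g, dx = g)
  d2 <- off$dy^2 + off$dx^2
  keep <- d2 <= radius_mm^2 + 1e-12
  off <- off[keep, ]
  d2 <- d2[keep]
  ord <- order(d2)
  list(dy = off$dy[ord], dx = off$dx[ord], d2 = d2[ord])
}

#' 2D gamma-index map
#'
#' For every reference pixel at or above the low-dose threshold, the gamma
#' index is the minimum over nearby evaluated-map positions `r` of
#' \deqn{\sqrt{\frac{|r - r_0|^2}{\Delta d^2} +
#'       \frac{(D_e(r) - D_r(r_0))^2}{\Delta D^2}},}
#' with the evaluated map sampled bilinearly on a lattice of step
#' `search_step_fraction * dta_mm` out to `search_radius_factor * dta_mm`.
#' Under global normalization `\Delta D` is `dose_criterion_pct`% of the
#' reference maximum. Reference pixels below threshold are `NA` and excluded
#' from the pass-rate denominator; the reference map is never interpolated.
#' A pixel passes when gamma <= 1 (with a 1e-9 absolute tolerance so that
#' exact boundary cases are not lost to floating-point rounding).
#'
#' @param reference The reference [dose_map()] (for this pipeline: the
#'   corrected bolus distribution).
#' @param evaluated The evaluated [dose_map()] (film). May be on a
#'   different grid; physical coordinates are shared (centred).
#' @param params A [gamma_params()].
#' @return A `gamma_result`: `gamma` matrix (`NA` below threshold),
#'   `pass_rate_pct`, `n_evaluated`, `params`.
#' @export
gamma_map <- function(reference, evaluated, params = gamma_params()) {
  stopifnot(inherits(reference, "dose_map"), inherits(evaluated, "dose_map"),
            inherits(params, "gamma_params"))
  ref <- reference$values
  dmax <- max(ref)
  if (dmax <= 0) stop("reference maximum must be positive", call. = FALSE)
  mask <- ref >= params$low_dose_threshold_pct / 100 * dmax
  if (!any(mask)) stop("no reference pixels above the low-dose threshold", call. = FALSE)

  dta <- params$dta_mm
  step <- params$search_step_fraction * dta
  off <- .gamma_offsets(params$search_radius_factor * dta, step)
  dd_abs <- if (params$local_normalization) {
    params$dose_criterion_pct / 100 * ref[mask]
  } else {
    params$dose_criterion_pct / 100 * dmax
  }

  co <- map_coords(reference)
  nr_e <- nrow(evaluated$values); nc_e <- ncol(evaluated$values)
  sp_e <- evaluated$pixel_spacing_mm
  refv <- ref[mask]
  midx <- which(mask)
  iy <- ((midx - 1L) %% nrow(ref)) + 1L
  jx <- ((midx - 1L) %/% nrow(ref)) + 1L
  Y <- co$y[iy]; X <- co$x[jx]

  g2 <- rep(Inf, length(refv))
  active <- seq_along(refv)
  n_off <- length(off$dy)
  for (k in seq_len(n_off)) {
    dist2 <- off$d2[k] / dta^2
    cur_max <- max(g2[active])
    if (dist2 >= cur_max) break
    ypx <- .phys_to_px(Y[active] + off$dy[k], nr_e, sp_e[1])
    xpx <- .phys_to_px(X[active] + off$dx[k], nc_e, sp_e[2])
    de <- .point_sample(evaluated$values, ypx, xpx)
    dd <- if (params$local_normalization) dd_abs[active] else dd_abs
    cand <- dist2 + ((de - refv[active]) / dd)^2
    g2[active] <- pmin(g2[active], cand, na.rm = TRUE)
    if (k %% 64L == 0L) {
      # drop pixels that no further (more distant) offset can improve
      active <- active[g2[active] > dist2]
      if (length(active) == 0) break
    }
  }

  gam <- matrix(NA_real_, nrow(ref), ncol(ref))
  gvals <- sqrt(g2)
  gvals[!is.finite(gvals)] <- NA_real_ # no valid evaluated sample at all
  gam[midx] <- gvals
  n_eval <- sum(is.finite(gam))
  if (n_eval == 0) stop("no evaluable pixels (evaluated map does not overlap)", call. = FALSE)
  structure(
    list(
      gamma = gam,
      pass_rate_pct = 100 * sum(gam[is.finite(gam)] <= 1 + 1e-9) / n_eval,
      n_evaluated = n_eval,
      params = params,
      pixel_spacing_mm = reference$pixel_spacing_mm
    ),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf(
    "<gamma_result> %.1f%%/%g mm, %g%% threshold: pass rate %.1f%% (n = %d), max gamma %.2f\n",
    x$params$dose_criterion_pct, x$params$dta_mm, x$params$low_dose_threshold_pct,
    x$pass_rate_pct, x$n_evaluated, max(x$gamma, na.rm = TRUE)
  ))
  invisible(x)
}

#' @export
glance.gamma_result <- function(x, ...) {
  tibble::tibble(
    pass_rate_pct = x$pass_rate_pct,
    n_evaluated = x$n_evaluated,
    max_gamma = max(x$gamma, na.rm = TRUE),
    mean_gamma = mean(x$gamma[is.finite(x$gamma)]),
    dose_criterion_pct = x$params$dose_criterion_pct,
    dta_mm = x$params$dta_mm,
    low_dose_threshold_pct = x$params$low_dose_threshold_pct
  )
}

#' Gamma pass rate
#'
#' Percentage of evaluated pixels with gamma <= 1.
#'
#' @param result A `gamma_result`.
#' @return Pass rate in percent.
#' @export
pass_rate <- function(result) {
  stopifnot(inherits(result, "gamma_result"))
  if (result$n_evaluated == 0) stop("empty evaluation set", call. = FALSE)
  g <- result$gamma[is.finite(result$gamma)]
  100 * sum(g <= 1 + 1e-9) / length(g)
}

#' Brute-force gamma oracle
#'
#' Independent reference implementation for testing: an exhaustive
#' per-pixel search over a dense evaluated-position lattice (default step
#' `dta/50`), written without the vectorized offset sweep or early
#' termination of [gamma_map()]. Guarded to small grids.
#'
#' @inheritParams gamma_map
#' @param step_fraction Dense lattice step as a fraction of the DTA.
#' @param max_dim Guard: largest allowed reference dimension.
#' @return A `gamma_result`.
#' @export
gamma_brute_oracle <- function(reference, evaluated, params = gamma_params(),
                               step_fraction = 1 / 50, max_dim = 64L) {
  stopifnot(inherits(reference, "dose_map"), inherits(evaluated, "dose_map"))
  if (max(dim(reference$values)) > max_dim) {
    stop("reference grid too large for the brute-force oracle", call. = FALSE)
  }
  ref <- reference$values
  dmax <- max(ref)
  if (dmax <= 0) stop("reference maximum must be positive", call. = FALSE)
  thr <- params$low_dose_threshold_pct / 100 * dmax
  dta <- params$dta_mm
  radius <- params$search_radius_factor * dta
  g <- seq(-radius, radius, by = step_fraction * dta)
  lat <- expand.grid(dy = g, dx = g)
  keep <- lat$dy^2 + lat$dx^2 <= radius^2 + 1e-12
  lat <- lat[keep, ]
  dist2 <- (lat$dy^2 + lat$dx^2) / dta^2

  co <- map_coords(reference)
  ev <- evaluated$values
  nr_e <- nrow(ev); nc_e <- ncol(ev); sp_e <- evaluated$pixel_spacing_mm
  gam <- matrix(NA_real_, nrow(ref), ncol(ref))
  for (i in seq_len(nrow(ref))) {
    for (j in seq_len(ncol(ref))) {
      if (ref[i, j] < thr) next
      dd_abs <- params$dose_criterion_pct / 100 *
        (if (params$local_normalization) ref[i, j] else dmax)
      # self-contained bilinear interpolation (kept independent of the
      # helpers used by gamma_map)
      ypx <- (co$y[i] + lat$dy) / sp_e[1] + (nr_e + 1) / 2
      xpx <- (co$x[j] + lat$dx) / sp_e[2] + (nc_e + 1) / 2
      ok <- ypx >= 1 & ypx <= nr_e & xpx >= 1 & xpx <= nc_e
      y0 <- floor(ypx); x0 <- floor(xpx)
      fy <- ypx - y0; fx <- xpx - x0
      fy[y0 >= nr_e] <- 0; fx[x0 >= nc_e] <- 0
      y0 <- pmin(pmax(y0, 1L), nr_e); x0 <- pmin(pmax(x0, 1L), nc_e)
      y1 <- pmin(y0 + 1L, nr_e); x1 <- pmin(x0 + 1L, nc_e)
      de <- ev[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
        ev[cbind(y1, x0)] * fy * (1 - fx) +
        ev[cbind(y0, x1)] * (1 - fy) * fx +
        ev[cbind(y1, x1)] * fy * fx
      de[!ok] <- NA_real_
      g2 <- dist2 + ((de - ref[i, j]) / dd_abs)^2
      m <- suppressWarnings(min(g2, na.rm = TRUE))
      gam[i, j] <- if (is.finite(m)) sqrt(m) else NA_real_
    }
  }
  n_eval <- sum(is.finite(gam))
  if (n_eval == 0) stop("no evaluable pixels", call. = FALSE)
  structure(
    list(
      gamma = gam,
      pass_rate_pct = 100 * sum(gam[is.finite(gam)] <= 1 + 1e-9) / n_eval,
      n_evaluated = n_eval,
      params = params,
      pixel_spacing_mm = reference$pixel_spacing_mm
    ),
    class = "gamma_result"
  )
}
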