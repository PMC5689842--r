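#' Percent-depth-dose curves
#'
#' A `pdd_curve` tabulates relative dose versus depth along the beam axis,
#' normalized to 100 at the depth of maximum dose. Megavoltage photon beams
#' show a steep buildup over the first centimetres (lack of electronic
#' equilibrium) followed by a quasi-exponential falloff; the buildup region
#' is what makes the average dose inside a 0.5 cm bolus slab differ from the
#' dose at its deep surface.
#'
#' @param depths Strictly increasing depths in cm, starting at 0.
#' @param values Relative dose in percent; positive, normalized so the
#'   maximum is 100.
#' @param field_size Field size label in cm (metadata).
#' @param energy_label Beam-quality label, e.g. `"6 MV"` (metadata).
#'
#' @return A `pdd_curve` object (also a tibble-friendly list).
#' @export
#' @examples
#' pdd_curve(c(0, 0.5, 1.5, 5), c(40, 75, 100, 87))
pdd_curve <- function(depths, values, field_size = NA_real_, energy_label = "6 MV") {
  depths <- as.numeric(depths); values <- as.numeric(values)
  if (length(depths) != length(values) || length(depths) < 2) {
    stop("depths and values must be equal-length vectors (>= 2 points)", call. = FALSE)
  }
  if (depths[1] != 0) stop("depths must start at 0", call. = FALSE)
  if (any(diff(depths) <= 0)) stop("depths must be strictly increasing", call. = FALSE)
  if (any(values < 0) || any(!is.finite(values))) {
    stop("PDD values must be finite and non-negative", call. = FALSE)
  }
  # exactly one global maximum region: the indices attaining the maximum
  # (to within rounding) must be contiguous
  at_max <- which(values >= max(values) * (1 - 1e-9))
  if (any(diff(at_max) != 1L)) {
    stop("PDD must have a single global maximum region", call. = FALSE)
  }
  structure(
    list(depths = depths, values = values,
         field_size = field_size, energy_label = energy_label),
    class = "pdd_curve"
  )
}

#' @export
print.pdd_curve <- function(x, ...) {
  cat(sprintf("<pdd_curve> %s, %d depths over [0, %.3g] cm, dmax at %.3g cm\n",
              x$energy_label, length(x$depths), max(x$depths),
              x$depths[which.max(x$values)]))
  invisible(x)
}

#' @export
as_tibble.pdd_curve <- function(x, ...) {
  tibble::tibble(depth_cm = x$depths, pdd_percent = x$values)
}

#' Analytic buildup percent-depth-dose curve
#'
#' Parametric stand-in for commissioning beam data: a smooth parabolic rise
#' from `surface_fraction * 100` at the surface to 100 at `dmax_cm` (zero
#' slope at the maximum, so the curve is continuously differentiable),
#' followed by exponential falloff at `decay_per_cm`. The defaults emulate a
#' 6 MV photon beam: surface dose about 30% of maximum, depth of maximum
#' dose 1.5 cm, and ~4.6%/cm falloff (so roughly 67% of maximum at 10 cm).
#'
#' @param dmax_cm Depth of maximum dose in cm; must be positive.
#' @param surface_fraction Surface dose as a fraction of maximum, strictly
#'   between 0 and 1.
#' @param decay_per_cm Exponential falloff rate beyond `dmax_cm` (per cm).
#' @param max_depth_cm Last tabulated depth in cm.
#' @param step_cm Tabulation step in cm.
#'
#' @return A [pdd_curve()].
#' @export
#' @examples
#' pdd <- make_buildup_pdd()
#' head(as_tibble(pdd))
make_buildup_pdd <- function(dmax_cm = 1.5, surface_fraction = 0.30,
                             decay_per_cm = 0.046, max_depth_cm = 30,
                             step_cm = 0.05) {
  if (!is.finite(dmax_cm) || dmax_cm <= 0) stop("dmax_cm must be positive", call. = FALSE)
  if (!is.finite(surface_fraction) || surface_fraction <= 0 || surface_fraction >= 1) {
    stop("surface_fraction must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (decay_per_cm < 0) stop("decay_per_cm must be non-negative", call. = FALSE)
  depths <- sort(unique(c(seq(0, min(dmax_cm, max_depth_cm), by = step_cm),
                          dmax_cm,
                          seq(dmax_cm, max_depth_cm, by = 5 * step_cm),
                          max_depth_cm)))
  u <- pmin(depths / dmax_cm, 1)
  buildup <- surface_fraction + (1 - surface_fraction) * (2 * u - u^2)
  falloff <- exp(-decay_per_cm * pmax(depths - dmax_cm, 0))
  values <- 100 * buildup * falloff
  pdd_curve(depths, values, energy_label = "6 MV (analytic)")
}

#' Read a percent-depth-dose curve from CSV
#'
#' Expects a two-column plain-text CSV with headers `depth_cm` and
#' `pdd_percent` (commissioning-style tabulation).
#'
#' @param path CSV file path.
#' @param ... Passed to [pdd_curve()] (e.g. `energy_label`).
#' @return A [pdd_curve()].
#' @export
read_pdd_csv <- function(path, ...) {
  df <- utils::read.csv(path)
  need <- c("depth_cm", "pdd_percent")
  if (!all(need %in% names(df))) {
    stop("PDD CSV must have columns depth_cm and pdd_percent", call. = FALSE)
  }
  pdd_curve(df$depth_cm, df$pdd_percent, ...)
}

# monotone-in-shape interpolant of a PDD (monotone cubic is shape-preserving
# between knots; buildup curves are sparse near the surface and linear
# interpolation biases the integral low)
.pdd_fun <- function(pdd) {
  splinefun(pdd$depths, pdd$values, method = "monoH.FC")
}
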