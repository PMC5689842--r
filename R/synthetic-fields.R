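#' Published per-angle bolus/film dose ratios
#'
#' The oblique-irradiation study's mean ratio between the dose recorded in
#' the 0.5 cm radiochromic bolus and the skin-surface dose measured with
#' film, by gantry angle. These are the default ground-truth ratios of the
#' synthetic generator's oblique-incidence cases.
#'
#' @return A named numeric vector (names are gantry angles in degrees).
#' @export
#' @examples
#' reference_angle_ratios()
reference_angle_ratios <- function() {
  c(`0` = 0.749, `22.5` = 0.760, `45` = 0.802, `67.5` = 0.890, `90` = 0.930)
}

#' Specify a rectangular open field
#'
#' Describes one jaw-collimated field (or one step-and-shoot segment) as
#' delivered onto the bolus + film stack: field size, gantry angle, monitor
#' units, penumbra width, the film-plane central dose, and the ground-truth
#' bolus/film dose ratio used by the simulator. Obliquity is emulated
#' through `bolus_film_ratio_truth` alone (the statistical structure the
#' analysis needs), not through radiation transport.
#'
#' @param field_size_cm Length-2 `(w, h)` field size in cm (scalar recycled).
#' @param gantry_angle_deg Gantry angle in degrees, in `[0, 90]`.
#' @param monitor_units Delivered monitor units.
#' @param penumbra_sigma_mm Gaussian penumbra width (mm); the field edge is
#'   an error-function falloff with this sigma.
#' @param central_dose_cGy Film-plane dose on the central axis (cGy).
#' @param bolus_film_ratio_truth True bolus/film dose ratio, in (0, 1.2].
#'   Defaults to the published value for `gantry_angle_deg` when tabulated.
#' @param center_mm Length-2 `(y, x)` field-centre offset in mm (for
#'   multi-segment arrangements).
#'
#' @return A `field_spec` object.
#' @export
#' @examples
#' field_spec(3, 0, central_dose_cGy = 700)
field_spec <- function(field_size_cm = 3, gantry_angle_deg = 0,
                       monitor_units = 1000, penumbra_sigma_mm = 3,
                       central_dose_cGy = 700,
                       bolus_film_ratio_truth = NULL,
                       center_mm = c(0, 0)) {
  size <- rep_len(as.numeric(field_size_cm), 2L)
  if (any(size <= 0)) stop("field size must be positive", call. = FALSE)
  if (gantry_angle_deg < 0 || gantry_angle_deg > 90) {
    stop("gantry angle must lie in [0, 90] degrees", call. = FALSE)
  }
  if (is.null(bolus_film_ratio_truth)) {
    tab <- reference_angle_ratios()
    key <- as.character(gantry_angle_deg)
    bolus_film_ratio_truth <- if (key %in% names(tab)) unname(tab[key]) else 0.8
  }
  if (bolus_film_ratio_truth <= 0 || bolus_film_ratio_truth > 1.2) {
    stop("bolus_film_ratio_truth must lie in (0, 1.2]", call. = FALSE)
  }
  if (penumbra_sigma_mm < 0) stop("penumbra sigma must be >= 0", call. = FALSE)
  structure(
    list(
      field_size_cm = size,
      gantry_angle_deg = gantry_angle_deg,
      monitor_units = monitor_units,
      penumbra_sigma_mm = penumbra_sigma_mm,
      central_dose_cGy = central_dose_cGy,
      bolus_film_ratio_truth = bolus_film_ratio_truth,
      center_mm = rep_len(as.numeric(center_mm), 2L)
    ),
    class = "field_spec"
  )
}

# 1D error-function edge profile: fraction of the open field seen at
# position x (mm) for half-width a (mm) and penumbra sigma (mm)
.edge_profile <- function(x, a, sigma) {
  if (sigma <= 0) return(as.numeric(abs(x) <= a))
  0.5 * (pracma::erf((a - x) / (sqrt(2) * sigma)) +
         pracma::erf((a + x) / (sqrt(2) * sigma)))
}

#' Simulate the film-plane and bolus-average dose of an open field
#'
#' The film-plane dose is the separable product of error-function edge
#' profiles (Gaussian-blurred top-hat) scaled to `central_dose_cGy`; the
#' bolus-average dose is `bolus_film_ratio_truth` times the film dose,
#' pointwise. Dose beyond 3 penumbra sigma outside the field edge is set to
#' zero. The grid must cover the field with at least 2 cm margin.
#'
#' @param field A [field_spec()].
#' @param grid_spec List with `extent_mm` (length-2 `(height, width)` of the
#'   grid, mm) and `pixel_spacing_mm` (`(dy, dx)`, mm).
#' @return List with `film_dose` and `bolus_avg_dose`, both [dose_map()]s on
#'   the same grid.
#' @export
#' @examples
#' gs <- list(extent_mm = 70, pixel_spacing_mm = 0.5)
#' sim <- simulate_field_dose(field_spec(3, 0, central_dose_cGy = 700), gs)
#' sim$film_dose
simulate_field_dose <- function(field, grid_spec) {
  stopifnot(inherits(field, "field_spec"))
  extent <- rep_len(as.numeric(grid_spec$extent_mm), 2L)
  spacing <- rep_len(as.numeric(grid_spec$pixel_spacing_mm), 2L)
  half_w <- field$field_size_cm * 10 / 2 # (w, h) -> mm half-sizes
  if (any(extent < 10 * rev(field$field_size_cm) + 2 * 20)) {
    stop("grid must cover the field plus >= 2 cm margin", call. = FALSE)
  }
  nr <- round(extent[1] / spacing[1])
  nc <- round(extent[2] / spacing[2])
  y <- .axis_coords(nr, spacing[1]) - field$center_mm[1]
  x <- .axis_coords(nc, spacing[2]) - field$center_mm[2]
  s <- field$penumbra_sigma_mm
  py <- .edge_profile(y, half_w[2], s) # h along y
  px <- .edge_profile(x, half_w[1], s) # w along x
  film <- field$central_dose_cGy * (py %o% px)
  # hard zero outside 3 sigma of the penumbra
  out_y <- abs(y) > half_w[2] + 3 * s
  out_x <- abs(x) > half_w[1] + 3 * s
  film[out_y, ] <- 0
  film[, out_x] <- 0
  list(
    film_dose = dose_map(film, spacing, provenance = "film"),
    bolus_avg_dose = dose_map(field$bolus_film_ratio_truth * film, spacing,
                              provenance = "bolus")
  )
}

#' Simulate a multi-segment (IMRT-like) arrangement
#'
#' Sums the film and bolus dose of several [field_spec()] segments on a
#' common grid, emulating step-and-shoot deliveries where each segment
#' carries its own effective bolus/film ratio.
#'
#' @param segments List of [field_spec()]s.
#' @param grid_spec As in [simulate_field_dose()].
#' @return List with `film_dose` and `bolus_avg_dose` [dose_map()]s.
#' @export
simulate_arrangement_dose <- function(segments, grid_spec) {
  stopifnot(length(segments) >= 1)
  acc <- NULL
  for (seg in segments) {
    sim <- simulate_field_dose(seg, grid_spec)
    if (is.null(acc)) {
      acc <- list(film = sim$film_dose$values, bolus = sim$bolus_avg_dose$values,
                  spacing = sim$film_dose$pixel_spacing_mm)
    } else {
      acc$film <- acc$film + sim$film_dose$values
      acc$bolus <- acc$bolus + sim$bolus_avg_dose$values
    }
  }
  list(
    film_dose = dose_map(acc$film, acc$spacing, provenance = "film"),
    bolus_avg_dose = dose_map(acc$bolus, acc$spacing, provenance = "bolus")
  )
}
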