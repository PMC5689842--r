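#' Irradiated-area region of interest of a film dose map
#'
#' The "irradiated area" over which bolus/film ratios are averaged: pixels
#' receiving at least `threshold` (default 50%) of the map maximum,
#' morphologically eroded by `erode_mm` (default 2 mm) to exclude the
#' penumbra, where ratios are noise- and registration-dominated.
#'
#' @param film A [dose_map()] with positive maximum.
#' @param threshold Fraction of the maximum dose defining the field.
#' @param erode_mm Erosion radius in mm.
#' @return A logical matrix mask on the film grid.
#' @export
field_roi <- function(film, threshold = 0.5, erode_mm = 2) {
  stopifnot(inherits(film, "dose_map"))
  dmax <- max(film$values)
  if (dmax <= 0) stop("film map has no positive dose", call. = FALSE)
  mask <- film$values >= threshold * dmax
  r_px <- erode_mm / mean(film$pixel_spacing_mm)
  if (r_px >= 1) {
    brush <- EBImage::makeBrush(2L * floor(r_px) + 1L, shape = "disc")
    mask <- EBImage::erode(mask * 1, brush) > 0.5
  }
  if (!any(mask)) stop("ROI is empty after erosion", call. = FALSE)
  mask
}

#' Point-by-point bolus/film dose-ratio map
#'
#' Computes `bolus / film` inside the mask; pixels outside the mask are
#' `NA`. Maps must share a grid (register or resample first).
#'
#' @param bolus,film [dose_map()]s on the same grid.
#' @param mask Logical matrix, e.g. from [field_roi()].
#' @return A numeric matrix of ratios (`NA` outside the mask).
#' @export
ratio_map <- function(bolus, film, mask) {
  stopifnot(inherits(bolus, "dose_map"), inherits(film, "dose_map"))
  if (!identical(dim(bolus$values), dim(film$values))) {
    stop("bolus and film maps must share the same grid", call. = FALSE)
  }
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  if (any(film$values[mask] <= 0)) {
    stop("film dose must be positive inside the mask", call. = FALSE)
  }
  out <- matrix(NA_real_, nrow(film$values), ncol(film$values))
  out[mask] <- bolus$values[mask] / film$values[mask]
  out
}

#' Per-angle ratio statistics
#'
#' Mean and (pixel-wise) standard deviation of the bolus/film ratio over the
#' irradiated-area mask for one gantry angle.
#'
#' @param ratios Ratio matrix from [ratio_map()].
#' @param mask Logical matrix used to compute it.
#' @param angle Gantry angle in degrees (metadata).
#' @return A one-row tibble: `gantry_angle_deg`, `mean_ratio`, `ratio_sd`,
#'   `n_pixels`.
#' @export
per_angle_stats <- function(ratios, mask, angle) {
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  v <- ratios[mask]
  v <- v[is.finite(v)]
  tibble::tibble(
    gantry_angle_deg = angle,
    mean_ratio = mean(v),
    ratio_sd = if (length(v) > 1) sd(v) else 0,
    n_pixels = length(v)
  )
}

#' Derive the single bolus-to-skin correction factor
#'
#' The correction factor k is the unweighted mean of the per-angle mean
#' bolus/film ratios over the chosen angle subset (default 0--67.5 degrees,
#' excluding the tangential 90-degree case), and its SD is the sample
#' standard deviation (n - 1) of those means. Restricting to 0--67.5
#' degrees reflects typical beam incidences; the derived k converts a
#' bolus-average dose reading into a skin-surface dose estimate.
#'
#' @param stats Tibble of per-angle rows, as from [per_angle_stats()]
#'   (columns `gantry_angle_deg`, `mean_ratio`).
#' @param angle_subset Angles (degrees) to average over; all must be present.
#' @return A `correction_factor` with `k`, `k_sd`, `angle_subset`, and
#'   `direction = "bolus_over_film"`.
#' @export
#' @examples
#' st <- tibble::tibble(
#'   gantry_angle_deg = c(0, 22.5, 45, 67.5, 90),
#'   mean_ratio = c(0.749, 0.760, 0.802, 0.890, 0.930)
#' )
#' derive_correction_factor(st)
derive_correction_factor <- function(stats, angle_subset = c(0, 22.5, 45, 67.5)) {
  stats <- tibble::as_tibble(stats)
  if (length(angle_subset) == 0) stop("angle subset is empty", call. = FALSE)
  idx <- vapply(angle_subset, function(a) {
    j <- which(abs(stats$gantry_angle_deg - a) < 1e-6)
    if (length(j) != 1) stop(sprintf("angle %g not present exactly once in stats", a),
                             call. = FALSE)
    j
  }, integer(1))
  means <- stats$mean_ratio[idx]
  k <- mean(means)
  if (k <= 0) stop("derived correction factor must be positive", call. = FALSE)
  structure(
    list(
      k = k,
      k_sd = if (length(means) > 1) sd(means) else 0,
      angle_subset = as.numeric(angle_subset),
      direction = "bolus_over_film",
      per_angle_means = means
    ),
    class = "correction_factor"
  )
}

#' @export
print.correction_factor <- function(x, ...) {
  cat(sprintf("<correction_factor> k = %.3f +/- %.3f (bolus/film, angles %s)\n",
              x$k, x$k_sd, paste(x$angle_subset, collapse = ", ")))
  invisible(x)
}

#' @export
tidy.correction_factor <- function(x, ...) {
  tibble::tibble(
    gantry_angle_deg = x$angle_subset,
    mean_ratio = x$per_angle_means
  )
}

#' @export
glance.correction_factor <- function(x, ...) {
  tibble::tibble(
    k = x$k, k_sd = x$k_sd,
    n_angles = length(x$angle_subset),
    direction = x$direction
  )
}

#' Apply the correction factor to a bolus dose map
#'
#' Because k is the bolus-average over skin-surface dose ratio (below 1 in
#' the buildup region), the skin-surface dose estimate is the bolus dose
#' divided by k. Provenance is set to `"corrected"`.
#'
#' @param bolus A [dose_map()] (provenance `"bolus"`).
#' @param k A `correction_factor`, or a bare positive number.
#' @return A corrected [dose_map()].
#' @export
#' @examples
#' bm <- dose_map(matrix(800, 4, 4), 0.5, "bolus")
#' apply_correction(bm, 0.8)$values[1, 1] # 1000
apply_correction <- function(bolus, k) {
  stopifnot(inherits(bolus, "dose_map"))
  kval <- if (inherits(k, "correction_factor")) k$k else as.numeric(k)
  if (!is.finite(kval) || kval <= 0) stop("k must be positive", call. = FALSE)
  dose_map(bolus$values / kval, bolus$pixel_spacing_mm, provenance = "corrected")
}

#' Mean absolute percent difference along a central profile
#'
#' Extracts the central inline (`axis = "y"`) or crossline (`axis = "x"`)
#' profile through the mask centroid and returns the mean of
#' `|a - b| / b * 100` over the masked portion of that line.
#'
#' @param a,b [dose_map()]s on the same grid (`b` is the denominator, i.e.
#'   the reference, typically film).
#' @param axis `"y"` (inline) or `"x"` (crossline).
#' @param mask Logical matrix restricting the comparison.
#' @return Mean absolute percent difference (a single number, in %).
#' @export
profile_difference <- function(a, b, axis = c("y", "x"), mask) {
  stopifnot(inherits(a, "dose_map"), inherits(b, "dose_map"))
  axis <- match.arg(axis)
  if (!identical(dim(a$values), dim(b$values))) {
    stop("maps must share the same grid", call. = FALSE)
  }
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("mask is empty", call. = FALSE)
  ci <- round(mean(idx[, 1])); cj <- round(mean(idx[, 2]))
  if (axis == "y") {
    sel <- mask[, cj]
    if (!any(sel)) stop("central profile misses the mask", call. = FALSE)
    av <- a$values[sel, cj]; bv <- b$values[sel, cj]
  } else {
    sel <- mask[ci, ]
    if (!any(sel)) stop("central profile misses the mask", call. = FALSE)
    av <- a$values[ci, sel]; bv <- b$values[ci, sel]
  }
  mean(abs(av - bv) / bv) * 100
}
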