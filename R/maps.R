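#' Planar physical maps: absorption, optical density, dose
#'
#' All intermediate and final signals of the pipeline live on 2D physical
#' grids sharing the `image_plane` geometry: linear absorption coefficient
#' maps (mm^-1) for the cryogel bolus, net optical density maps
#' (dimensionless) for film, and absorbed dose maps (cGy). Constructors
#' validate the respective invariants.
#'
#' @param values Numeric matrix of per-pixel values.
#' @param pixel_spacing_mm `(dy, dx)` spacing in mm (scalar recycled).
#' @param thickness_mm Bolus slab thickness in mm (absorption maps).
#' @param provenance For dose maps: one of `"bolus"`, `"film"`, `"corrected"`.
#'
#' @return An object of class `absorption_map`, `od_map` or `dose_map`, all
#'   inheriting from `planar_map`.
#' @name planar-maps
NULL

.new_planar_map <- function(values, pixel_spacing_mm, class, extra = list()) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (any(!is.finite(values))) stop("map values must be finite", call. = FALSE)
  spacing <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (any(spacing <= 0)) stop("pixel spacing must be positive", call. = FALSE)
  structure(
    c(list(values = values, pixel_spacing_mm = spacing), extra),
    class = c(class, "planar_map")
  )
}

#' @rdname planar-maps
#' @export
absorption_map <- function(values, pixel_spacing_mm, thickness_mm) {
  if (thickness_mm <= 0) stop("thickness must be positive", call. = FALSE)
  .new_planar_map(values, pixel_spacing_mm, "absorption_map",
                  list(thickness_mm = thickness_mm))
}

#' @rdname planar-maps
#' @export
od_map <- function(values, pixel_spacing_mm) {
  .new_planar_map(values, pixel_spacing_mm, "od_map")
}

#' @rdname planar-maps
#' @export
dose_map <- function(values, pixel_spacing_mm, provenance = c("film", "bolus", "corrected")) {
  provenance <- match.arg(provenance)
  if (any(values < 0)) stop("dose must be non-negative", call. = FALSE)
  .new_planar_map(values, pixel_spacing_mm, "dose_map",
                  list(provenance = provenance))
}

#' @export
print.planar_map <- function(x, ...) {
  kind <- class(x)[1]
  cat(sprintf(
    "<%s> %d x %d px, %.4g x %.4g mm/px, range [%.4g, %.4g]%s\n",
    kind, nrow(x$values), ncol(x$values),
    x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
    min(x$values), max(x$values),
    if (kind == "dose_map") paste0(", provenance: ", x$provenance) else ""
  ))
  invisible(x)
}

#' @export
dim.planar_map <- function(x) dim(x$values)

#' Physical coordinates of a planar map or image
#'
#' Returns the centred physical axis coordinates (mm) of the rows (`y`) and
#' columns (`x`) of a grid.
#'
#' @param x A `planar_map` or `image_plane`.
#' @return A list with numeric vectors `y` and `x` (mm).
#' @export
map_coords <- function(x) {
  m <- if (inherits(x, "image_plane")) x$counts else x$values
  list(
    y = .axis_coords(nrow(m), x$pixel_spacing_mm[1]),
    x = .axis_coords(ncol(m), x$pixel_spacing_mm[2])
  )
}

#' Convert a planar map to a tidy tibble
#'
#' One row per pixel with physical coordinates, suitable for dplyr/ggplot2
#' work.
#'
#' @param x A `planar_map`.
#' @param ... Unused.
#' @return A tibble with columns `y_mm`, `x_mm`, `value`.
#' @export
as_tibble.planar_map <- function(x, ...) {
  co <- map_coords(x)
  tibble::tibble(
    y_mm = rep(co$y, times = length(co$x)),
    x_mm = rep(co$x, each = length(co$y)),
    value = as.vector(x$values)
  )
}

# --- interpolation helpers (bilinear), shared by registration and gamma ---

# Sample matrix at fractional pixel coordinates given by the separable grid
# ry x rx (1-based pixel units). Returns length(ry) x length(rx) matrix with
# NA outside the grid.
.grid_sample <- function(mat, ry, rx) {
  nr <- nrow(mat); nc <- ncol(mat)
  i0 <- floor(ry); j0 <- floor(rx)
  wi <- ry - i0; wj <- rx - j0
  # clamp index pairs; validity handled by mask
  ok_i <- ry >= 1 & ry <= nr
  ok_j <- rx >= 1 & rx <= nc
  i0c <- pmin(pmax(i0, 1L), nr); i1c <- pmin(i0c + 1L, nr)
  j0c <- pmin(pmax(j0, 1L), nc); j1c <- pmin(j0c + 1L, nc)
  # where ry lands exactly on nr, use weight 0 on the (clamped) upper row
  wi[i0 >= nr] <- 0; wj[j0 >= nc] <- 0
  out <- mat[i0c, j0c, drop = FALSE] * ((1 - wi) %o% (1 - wj)) +
    mat[i1c, j0c, drop = FALSE] * (wi %o% (1 - wj)) +
    mat[i0c, j1c, drop = FALSE] * ((1 - wi) %o% wj) +
    mat[i1c, j1c, drop = FALSE] * (wi %o% wj)
  out[!ok_i, ] <- NA_real_
  out[, !ok_j] <- NA_real_
  out
}

# Sample matrix at arbitrary fractional pixel coordinate pairs (vectors).
.point_sample <- function(mat, ypx, xpx) {
  nr <- nrow(mat); nc <- ncol(mat)
  ok <- ypx >= 1 & ypx <= nr & xpx >= 1 & xpx <= nc
  i0 <- floor(ypx); j0 <- floor(xpx)
  wi <- ypx - i0; wj <- xpx - j0
  wi[i0 >= nr] <- 0; wj[j0 >= nc] <- 0
  i0 <- pmin(pmax(i0, 1L), nr); j0 <- pmin(pmax(j0, 1L), nc)
  i1 <- pmin(i0 + 1L, nr); j1 <- pmin(j0 + 1L, nc)
  v <- mat[cbind(i0, j0)] * (1 - wi) * (1 - wj) +
    mat[cbind(i1, j0)] * wi * (1 - wj) +
    mat[cbind(i0, j1)] * (1 - wi) * wj +
    mat[cbind(i1, j1)] * wi * wj
  v[!ok] <- NA_real_
  v
}
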