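#' Compute a linear absorption-coefficient map from a pre/post image pair
#'
#' Beer--Lambert inversion of the optical readout: for each pixel,
#' \deqn{\mu(x, y) = \ln(\mathrm{pre} / \mathrm{post}) / t \quad [\mathrm{mm}^{-1}],}
#' where t is the slab thickness in mm. Because the same illumination field
#' multiplies both images (fixed light-box geometry), it cancels exactly in
#' the ratio. Zero or saturated counts are clipped to `[1, 2^bit_depth - 1]`
#' before the logarithm; the number of clipped pixels is reported as a
#' warning when non-zero.
#'
#' @param pre,post [image_plane()]s on identical grids.
#' @param thickness_mm Slab thickness t in mm (> 0).
#' @return An [absorption_map()] (mm^-1).
#' @export
#' @examples
#' pre <- image_plane(matrix(40000, 4, 4), 0.2)
#' post <- image_plane(matrix(20000, 4, 4), 0.2)
#' compute_absorption_map(pre, post, 5)$values[1, 1] # ln(2)/5
compute_absorption_map <- function(pre, post, thickness_mm) {
  .check_pair(pre, post)
  if (!is.finite(thickness_mm) || thickness_mm <= 0) {
    stop("thickness must be positive", call. = FALSE)
  }
  mu <- log(.clip_counts(pre) / .clip_counts(post)) / thickness_mm
  absorption_map(mu, pre$pixel_spacing_mm, thickness_mm)
}

#' Compute a net-optical-density map from film scans
#'
#' Net optical density subtracts the film's background optical density:
#' \deqn{\mathrm{netOD}(x, y) = \log_{10}(\mathrm{background} / \mathrm{irradiated}),}
#' with counts clipped to at least 1 before the logarithm.
#'
#' @param background,irradiated [image_plane()]s on identical grids.
#' @return An [od_map()] (dimensionless).
#' @export
compute_net_od <- function(background, irradiated) {
  .check_pair(background, irradiated)
  netod <- log10(.clip_counts(background) / .clip_counts(irradiated))
  od_map(netod, background$pixel_spacing_mm)
}

.check_pair <- function(a, b) {
  stopifnot(inherits(a, "image_plane"), inherits(b, "image_plane"))
  if (!identical(dim(a$counts), dim(b$counts))) {
    stop("image pair must share the same grid", call. = FALSE)
  }
  if (!isTRUE(all.equal(a$pixel_spacing_mm, b$pixel_spacing_mm))) {
    stop("image pair must share the same pixel spacing", call. = FALSE)
  }
  invisible(TRUE)
}

.clip_counts <- function(img) {
  cmax <- 2^img$bit_depth - 1
  x <- img$counts
  n_clip <- sum(x < 1 | x > cmax)
  if (n_clip > 0) {
    warning(sprintf("%d count(s) clipped to [1, %d] before the logarithm",
                    n_clip, cmax), call. = FALSE)
  }
  pmin(pmax(x, 1), cmax)
}

#' Mean absorption coefficient of a region, from count means
#'
#' Per-dose-level calibration signal: the region-mean absorption estimated
#' as `ln(mean(pre) / mean(post)) / t` over an ROI. Taking the log of mean
#' counts (rather than the mean of per-pixel logs) avoids the Jensen bias
#' that noisy low-count (high-dose) pixels induce in log-domain averages.
#'
#' @inheritParams compute_absorption_map
#' @param roi Optional logical matrix selecting pixels (default: all).
#' @return Mean absorption coefficient (mm^-1), a single number.
#' @export
mean_absorption <- function(pre, post, thickness_mm, roi = NULL) {
  .check_pair(pre, post)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(pre$counts), ncol(pre$counts))
  log(mean(.clip_counts(pre)[roi]) / mean(.clip_counts(post)[roi])) / thickness_mm
}

#' Mean net optical density of a region, from count means
#'
#' Film analogue of [mean_absorption()]:
#' `log10(mean(background) / mean(irradiated))` over an ROI.
#'
#' @inheritParams compute_net_od
#' @param roi Optional logical matrix selecting pixels (default: all).
#' @return Mean net optical density, a single number.
#' @export
mean_net_od <- function(background, irradiated, roi = NULL) {
  .check_pair(background, irradiated)
  if (is.null(roi)) roi <- matrix(TRUE, nrow(background$counts), ncol(background$counts))
  log10(mean(.clip_counts(background)[roi]) / mean(.clip_counts(irradiated)[roi]))
}

#' Denoise an absorption or optical-density map
#'
#' Default method is wavelet soft-thresholding (symlet-4 analysis, 3
#' decomposition levels, universal threshold estimated from the finest
#' diagonal subband), which suppresses pixel noise while preserving local
#' means; `strength` scales the threshold (0 is the identity). A simple
#' `"median"` filter (3x3) is offered as an alternative.
#'
#' @param map An [absorption_map()] or [od_map()].
#' @param method `"wavelet"` (default) or `"median"`.
#' @param strength Non-negative multiplier on the universal threshold.
#' @return A map of the same class and grid.
#' @export
denoise_map <- function(map, method = c("wavelet", "median"), strength = 1) {
  stopifnot(inherits(map, "planar_map"))
  method <- match.arg(method)
  if (strength < 0) stop("strength must be >= 0", call. = FALSE)
  vals <- switch(method,
    wavelet = if (strength == 0) map$values else
      .wavelet_denoise(map$values, levels = 3L, strength = strength),
    median = if (strength == 0) map$values else .median3(map$values)
  )
  out <- map
  out$values <- vals
  out
}

# 3x3 median filter via EBImage (values rescaled to [0, 1] and back)
.median3 <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(x)
  z <- (x - rng[1]) / (rng[2] - rng[1])
  zf <- EBImage::medianFilter(z, size = 1L)
  zf * (rng[2] - rng[1]) + rng[1]
}
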