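#' Ground truth of the synthetic measurement chain
#'
#' Collects every physical parameter the simulator needs to turn a dose map
#' into detector images: the cryogel dose-response slope (linear absorption
#' coefficient per unit dose), its baseline intercept, slab thickness, the
#' film net-optical-density response (tabulated, strictly monotone in dose),
#' the light-box illumination nonuniformity, CCD background level and read
#' noise, and the digitizer depth.
#'
#' Defaults: slope 3.00e-4 mm^-1 cGy^-1 (the measured cryogel response),
#' zero intercept, 5 mm slab, a saturating film response
#' netOD(D) = 0.55 D / (D + 800) tabulated over 0--1500 cGy, a radial
#' vignette with 10% corner falloff (identical in pre and post images, as
#' for a fixed light-box geometry, so it cancels in the ratio), Gaussian
#' read noise of SD 50 counts on a 40,000-count background, 16-bit
#' quantization.
#'
#' @param bolus_slope Absorption per dose, mm^-1 cGy^-1 (> 0).
#' @param bolus_intercept Baseline absorption, mm^-1.
#' @param bolus_thickness_mm Slab thickness t in mm (> 0).
#' @param film_netod_points Data frame / tibble with columns `dose_cGy` and
#'   `net_od`, strictly increasing in both.
#' @param vignette_strength Fractional illumination falloff at the image
#'   corner (radial, multiplicative).
#' @param read_noise_sd Gaussian read noise SD in counts.
#' @param background_counts Unattenuated illumination level in counts.
#' @param bit_depth Digitizer bit depth.
#'
#' @return A `generator_truth` object.
#' @export
#' @examples
#' tr <- generator_truth()
#' tr$bolus_slope
generator_truth <- function(bolus_slope = 3.00e-4,
                            bolus_intercept = 0,
                            bolus_thickness_mm = 5,
                            film_netod_points = default_film_response(),
                            vignette_strength = 0.10,
                            read_noise_sd = 50,
                            background_counts = 40000,
                            bit_depth = 16L) {
  if (bolus_slope <= 0) stop("bolus slope must be positive", call. = FALSE)
  if (bolus_thickness_mm <= 0) stop("bolus thickness must be positive", call. = FALSE)
  pts <- as.data.frame(film_netod_points)
  if (!all(c("dose_cGy", "net_od") %in% names(pts))) {
    stop("film_netod_points needs columns dose_cGy and net_od", call. = FALSE)
  }
  pts <- pts[order(pts$dose_cGy), ]
  if (any(diff(pts$net_od) <= 0)) {
    stop("film netOD points must be strictly monotone in dose", call. = FALSE)
  }
  structure(
    list(
      bolus_slope = bolus_slope,
      bolus_intercept = bolus_intercept,
      bolus_thickness_mm = bolus_thickness_mm,
      film_netod_points = tibble::as_tibble(pts),
      vignette_strength = vignette_strength,
      read_noise_sd = read_noise_sd,
      background_counts = background_counts,
      bit_depth = as.integer(bit_depth)
    ),
    class = "generator_truth"
  )
}

#' Default synthetic film response table
#'
#' Saturating net-optical-density response netOD(D) = 0.55 D / (D + 800),
#' tabulated at 0 and the applied calibration levels spanning 100--1500 cGy.
#' The shape (monotone, sublinear at high dose) mimics radiochromic film's
#' red-channel response.
#'
#' @return A tibble with columns `dose_cGy`, `net_od`.
#' @export
default_film_response <- function() {
  d <- c(0, 100, 250, 500, 750, 1000, 1250, 1500)
  tibble::tibble(dose_cGy = d, net_od = 0.55 * d / (d + 800))
}

# multiplicative illumination field: radial vignette, 1 at centre,
# (1 - strength) at the grid corner
.illumination_field <- function(nr, nc, spacing, strength) {
  y <- .axis_coords(nr, spacing[1])
  x <- .axis_coords(nc, spacing[2])
  r2 <- outer(y^2, x^2, "+")
  1 - strength * r2 / max(r2)
}

# shared tail of both renderers: illumination, noise, quantization
.digitize <- function(clean, truth, noiseless) {
  if (!noiseless) {
    clean <- clean + rnorm(length(clean), sd = truth$read_noise_sd)
  }
  cmax <- 2^truth$bit_depth - 1
  matrix(pmin(pmax(round(clean), 0), cmax), nrow(clean), ncol(clean))
}

#' Render pre/post-irradiation bolus images
#'
#' Applies the Beer--Lambert signal chain of the optical readout in the
#' forward direction: the pre-irradiation image is the illumination field
#' times the background level (times any baseline attenuation); the
#' post-irradiation image is the pre image further attenuated by
#' `exp(-slope * D * t)` pixel by pixel. Read noise and 16-bit quantization
#' are applied last; both images share the same illumination field, so it
#' cancels in the log ratio.
#'
#' @param bolus_avg_dose A [dose_map()] of slab-average dose (cGy).
#' @param truth A [generator_truth()].
#' @param noiseless If `TRUE`, skip read noise (quantization still applies).
#' @param placement_offset_mm Length-2 `(y, x)` mm offset of the bolus slab
#'   relative to its nominal position (emulates manual placement); the dose
#'   pattern is shifted by this amount in the rendered images.
#' @return List with `pre` and `post` [image_plane()]s.
#' @export
render_bolus_images <- function(bolus_avg_dose, truth = generator_truth(),
                                noiseless = FALSE,
                                placement_offset_mm = c(0, 0)) {
  stopifnot(inherits(bolus_avg_dose, "dose_map"))
  D <- .shift_dose(bolus_avg_dose, placement_offset_mm)
  spacing <- bolus_avg_dose$pixel_spacing_mm
  nr <- nrow(D); nc <- ncol(D)
  illum <- .illumination_field(nr, nc, spacing, truth$vignette_strength)
  base_att <- exp(-truth$bolus_intercept * truth$bolus_thickness_mm)
  pre_clean <- truth$background_counts * illum * base_att
  trans <- exp(-truth$bolus_slope * D * truth$bolus_thickness_mm)
  post_clean <- pre_clean * trans
  if (min(post_clean) < 1) {
    stop("dose drives transmission below 1 count: dynamic-range overflow",
         call. = FALSE)
  }
  list(
    pre = image_plane(.digitize(pre_clean, truth, noiseless), spacing, truth$bit_depth),
    post = image_plane(.digitize(post_clean, truth, noiseless), spacing, truth$bit_depth)
  )
}

#' Render background and irradiated film scans
#'
#' The irradiated film scan is the background scan attenuated by
#' `10^(-netOD(D))`, with netOD interpolated (monotone cubic) from the
#' truth's tabulated response. Doses outside the tabulated range raise an
#' extrapolation error. Noise and quantization as in
#' [render_bolus_images()].
#'
#' @param film_dose A [dose_map()] of film-plane dose (cGy).
#' @inheritParams render_bolus_images
#' @return List with `background` and `irradiated` [image_plane()]s.
#' @export
render_film_scan <- function(film_dose, truth = generator_truth(),
                             noiseless = FALSE) {
  stopifnot(inherits(film_dose, "dose_map"))
  pts <- truth$film_netod_points
  D <- film_dose$values
  if (min(D) < min(pts$dose_cGy) - 1e-9 || max(D) > max(pts$dose_cGy) + 1e-9) {
    stop("film dose outside the tabulated netOD range (extrapolation)", call. = FALSE)
  }
  netod_fun <- splinefun(pts$dose_cGy, pts$net_od, method = "monoH.FC")
  spacing <- film_dose$pixel_spacing_mm
  illum <- .illumination_field(nrow(D), ncol(D), spacing, truth$vignette_strength)
  bg_clean <- truth$background_counts * illum
  irr_clean <- bg_clean * 10^(-netod_fun(D))
  list(
    background = image_plane(.digitize(bg_clean, truth, noiseless), spacing, truth$bit_depth),
    irradiated = image_plane(.digitize(irr_clean, truth, noiseless), spacing, truth$bit_depth)
  )
}

# shift a dose map's pattern by (dy, dx) mm via bilinear resampling
# (zero outside); identity when the offset is zero
.shift_dose <- function(dmap, offset_mm) {
  offset_mm <- rep_len(as.numeric(offset_mm), 2L)
  if (all(offset_mm == 0)) return(dmap$values)
  nr <- nrow(dmap$values); nc <- ncol(dmap$values)
  ry <- seq_len(nr) - offset_mm[1] / dmap$pixel_spacing_mm[1]
  rx <- seq_len(nc) - offset_mm[2] / dmap$pixel_spacing_mm[2]
  out <- .grid_sample(dmap$values, ry, rx)
  out[is.na(out)] <- 0
  out
}
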