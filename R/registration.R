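#' Rigidly register one dose map onto another
#'
#' Automates the visual bolus-to-film alignment step: finds the rigid
#' transform (rotation + translation) maximizing the normalized
#' cross-correlation (NCC) between the reference map and the moving map
#' resampled onto the reference grid. The search is a coarse grid over
#' rotation (default +/-5 degrees in 0.25-degree steps; translation over
#' +/-10 mm is evaluated for every integer-pixel shift at once by FFT
#' cross-correlation), followed by local continuous refinement
#' (Nelder--Mead on the NCC). Ties favour the smallest transform.
#'
#' The returned transform maps reference physical coordinates `p` (mm,
#' centred) to moving-map coordinates via `R(theta) p + t`.
#'
#' @param reference,moving [dose_map()]s with overlapping physical extents
#'   and in-field signal in both.
#' @param translation_range_mm Half-range of the translation search (mm).
#' @param rotation_range_deg Half-range of the rotation search (degrees).
#' @param rotation_step_deg Coarse rotation step (degrees).
#' @return A list with `transform` (class `rigid_transform2d`: `rotation_deg`,
#'   `translation_mm` `(dy, dx)`, `score`) and `resampled` (the moving map
#'   bilinearly resampled onto the reference grid; out-of-support pixels 0).
#' @export
register_maps <- function(reference, moving,
                          translation_range_mm = 10,
                          rotation_range_deg = 5,
                          rotation_step_deg = 0.25) {
  stopifnot(inherits(reference, "dose_map"), inherits(moving, "dose_map"))
  if (sd(reference$values) == 0 || sd(moving$values) == 0) {
    stop("featureless (flat) map: registration is unresolvable", call. = FALSE)
  }
  ref <- reference$values
  co <- map_coords(reference)

  # coarse: for each rotation, resample the rotated moving map on the
  # reference grid, then FFT cross-correlation over integer-pixel shifts
  angles <- seq(-rotation_range_deg, rotation_range_deg, by = rotation_step_deg)
  ref0 <- ref - mean(ref)
  Fr <- fft(ref0)
  nr <- nrow(ref); nc <- ncol(ref)
  max_sy <- floor(translation_range_mm / reference$pixel_spacing_mm[1])
  max_sx <- floor(translation_range_mm / reference$pixel_spacing_mm[2])
  best <- list(score = -Inf)
  for (th in angles) {
    rot <- .resample_on(moving, co, theta_deg = th, t_mm = c(0, 0))
    rot[is.na(rot)] <- 0
    rot0 <- rot - mean(rot)
    # C[t] = sum_p ref0[p] rot0[p + t] = IFFT(Conj(F(ref0)) F(rot0))[t]:
    # the score of sampling the rotated moving map at p + t
    cc <- Re(fft(Conj(Fr) * fft(rot0), inverse = TRUE)) / length(ref0)
    sy <- c(0:max_sy, -(max_sy:1))
    sx <- c(0:max_sx, -(max_sx:1))
    iy <- ((sy) %% nr) + 1L
    ix <- ((sx) %% nc) + 1L
    sub <- cc[iy, ix, drop = FALSE]
    # tie-break toward the smallest transform
    pen <- 1e-9 * (outer(abs(sy), abs(sx), "+") + abs(th))
    sub <- sub - pen * max(abs(sub))
    k <- arrayInd(which.max(sub), dim(sub))
    sc <- sub[k]
    if (sc > best$score) {
      best <- list(
        score = sc, theta = th,
        t_mm = c(sy[k[1]] * reference$pixel_spacing_mm[1],
                 sx[k[2]] * reference$pixel_spacing_mm[2])
      )
    }
  }

  # local refinement on true NCC
  ncc_of <- function(par) {
    m <- .resample_on(moving, co, theta_deg = par[1], t_mm = par[2:3])
    ok <- !is.na(m)
    if (sum(ok) < 16) return(1) # degenerate overlap
    a <- ref[ok]; b <- m[ok]
    if (sd(b) == 0) return(1)
    -sum((a - mean(a)) * (b - mean(b))) / ((length(a) - 1) * sd(a) * sd(b))
  }
  opt <- optim(c(best$theta, best$t_mm), ncc_of, method = "Nelder-Mead",
               control = list(reltol = 1e-8, maxit = 300))
  theta <- opt$par[1]; t_mm <- opt$par[2:3]; score <- -opt$value
  res <- .resample_on(moving, co, theta_deg = theta, t_mm = t_mm)
  res[is.na(res)] <- 0
  res <- pmax(res, 0)
  transform <- structure(
    list(rotation_deg = theta, translation_mm = t_mm, score = score),
    class = "rigid_transform2d"
  )
  resampled <- dose_map(res, reference$pixel_spacing_mm,
                        provenance = moving$provenance)
  list(transform = transform, resampled = resampled)
}

#' @export
print.rigid_transform2d <- function(x, ...) {
  cat(sprintf("<rigid_transform2d> rotation %.3f deg, translation (%.3f, %.3f) mm, NCC %.4f\n",
              x$rotation_deg, x$translation_mm[1], x$translation_mm[2], x$score))
  invisible(x)
}

# sample `moving` at R(theta) p + t for every reference-grid point p;
# returns matrix on the reference grid with NA outside the moving support
.resample_on <- function(moving, ref_coords, theta_deg, t_mm) {
  th <- theta_deg * pi / 180
  Y <- rep(ref_coords$y, times = length(ref_coords$x))
  X <- rep(ref_coords$x, each = length(ref_coords$y))
  ym <- cos(th) * Y - sin(th) * X + t_mm[1]
  xm <- sin(th) * Y + cos(th) * X + t_mm[2]
  nr <- nrow(moving$values); nc <- ncol(moving$values)
  ypx <- .phys_to_px(ym, nr, moving$pixel_spacing_mm[1])
  xpx <- .phys_to_px(xm, nc, moving$pixel_spacing_mm[2])
  matrix(.point_sample(moving$values, ypx, xpx),
         length(ref_coords$y), length(ref_coords$x))
}

#' Resample a dose map onto another map's grid
#'
#' Identity-transform resampling (bilinear), used when two maps share
#' physical coordinates but not pixel grids.
#'
#' @param moving A [dose_map()].
#' @param reference A `planar_map` providing the target grid.
#' @return A [dose_map()] on the reference grid (0 outside support).
#' @export
resample_dose_map <- function(moving, reference) {
  out <- .resample_on(moving, map_coords(reference), theta_deg = 0, t_mm = c(0, 0))
  out[is.na(out)] <- 0
  dose_map(pmax(out, 0), reference$pixel_spacing_mm, provenance = moving$provenance)
}
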