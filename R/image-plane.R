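#' Detector image with physical pixel spacing
#'
#' An `image_plane` is the raw currency of the optical readout: a 2D grid of
#' non-negative integer detector counts (CCD camera for the cryogel bolus,
#' flatbed scanner for film) together with the physical pixel spacing in mm
#' and the digitizer bit depth. Row-major `(y, x)` indexing; physical
#' coordinates are in mm with the origin at the image centre.
#'
#' @param counts Integer-valued matrix of detector counts.
#' @param pixel_spacing_mm Numeric length-2 `(dy, dx)` spacing in mm, or a
#'   single number used for both axes.
#' @param bit_depth Digitizer depth; counts must fit in `[0, 2^bit_depth - 1]`.
#'
#' @return An `image_plane` object.
#' @export
#' @examples
#' img <- image_plane(matrix(40000L, 8, 8), pixel_spacing_mm = 0.2)
#' img
image_plane <- function(counts, pixel_spacing_mm, bit_depth = 16L) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix", call. = FALSE)
  spacing <- rep_len(as.numeric(pixel_spacing_mm), 2L)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("pixel spacing must be positive and finite", call. = FALSE)
  }
  cmax <- 2^bit_depth - 1
  if (any(counts < 0) || any(counts > cmax)) {
    stop("counts must lie in [0, 2^bit_depth - 1]", call. = FALSE)
  }
  structure(
    list(
      counts = matrix(as.numeric(counts), nrow(counts), ncol(counts)),
      pixel_spacing_mm = spacing,
      bit_depth = as.integer(bit_depth)
    ),
    class = "image_plane"
  )
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf(
    "<image_plane> %d x %d px, %.4g x %.4g mm/px, %d-bit, counts [%d, %d]\n",
    nrow(x$counts), ncol(x$counts), x$pixel_spacing_mm[1], x$pixel_spacing_mm[2],
    x$bit_depth, min(x$counts), max(x$counts)
  ))
  invisible(x)
}

#' @export
dim.image_plane <- function(x) dim(x$counts)

#' Read / write 16-bit grayscale TIFF images
#'
#' Thin wrappers around the \pkg{tiff} package that attach and honour the
#' physical pixel spacing. Images are stored as single-channel 16-bit
#' grayscale TIFF, the readout apparatus's native format.
#'
#' @param path File path.
#' @param pixel_spacing_mm Pixel spacing `(dy, dx)` in mm. Spacing is carried
#'   in the study manifest, never inferred from image content.
#' @param image An [image_plane()].
#' @return `read_image_tiff()` returns an [image_plane()]; `write_image_tiff()`
#'   returns `path` invisibly.
#' @export
read_image_tiff <- function(path, pixel_spacing_mm) {
  raw <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  image_plane(raw, pixel_spacing_mm = pixel_spacing_mm, bit_depth = 16L)
}

#' @rdname read_image_tiff
#' @export
write_image_tiff <- function(image, path) {
  stopifnot(inherits(image, "image_plane"))
  cmax <- 2^image$bit_depth - 1
  tiff::writeTIFF(image$counts / cmax, path, bits.per.sample = 16L)
  invisible(path)
}

# physical axis coordinates (mm, centred) of a planar grid
.axis_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

# pixel coordinates (1-based, fractional) of physical positions on an axis
.phys_to_px <- function(pos_mm, n, spacing) pos_mm / spacing + (n + 1) / 2
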