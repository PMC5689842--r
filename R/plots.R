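#' Plot methods
#'
#' `autoplot()` methods render the pipeline's objects with ggplot2: planar
#' maps as physical-coordinate rasters, calibrations as signal-vs-dose
#' curves, gamma results as gamma-value rasters, PDD curves as depth-dose
#' lines.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name cryodose-autoplot
NULL

#' @rdname cryodose-autoplot
#' @export
autoplot.planar_map <- function(object, ...) {
  df <- as_tibble(object)
  lab <- switch(class(object)[1],
    absorption_map = expression(mu ~ (mm^-1)),
    od_map = "netOD",
    dose_map = "dose (cGy)",
    "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = lab) +
    ggplot2::labs(x = "x (mm)", y = "y (mm)")
}

#' @rdname cryodose-autoplot
#' @export
autoplot.gamma_result <- function(object, ...) {
  sp <- object$pixel_spacing_mm
  nr <- nrow(object$gamma); nc <- ncol(object$gamma)
  df <- tibble::tibble(
    y_mm = rep(.axis_coords(nr, sp[1]), times = nc),
    x_mm = rep(.axis_coords(nc, sp[2]), each = nr),
    gamma = as.vector(object$gamma)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_mm, y = .data$y_mm,
                                   fill = .data$gamma)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = expression(gamma), na.value = "grey85") +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)",
      title = sprintf("Gamma %.0f%%/%g mm, pass rate %.1f%%",
                      object$params$dose_criterion_pct, object$params$dta_mm,
                      object$pass_rate_pct)
    )
}

#' @rdname cryodose-autoplot
#' @export
autoplot.bolus_calibration <- function(object, ...) {
  df <- tibble::tibble(
    dose_cGy = object$fit$model$doses,
    mu = object$fit$model$signals
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose_cGy, y = .data$mu)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "dose (cGy)", y = expression(mu ~ (mm^-1)))
}

#' @rdname cryodose-autoplot
#' @export
autoplot.film_calibration <- function(object, ...) {
  grid <- seq(object$dose_range[1], object$dose_range[2], length.out = 200)
  line <- tibble::tibble(dose_cGy = grid, net_od = object$netod_of_dose(grid))
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$dose_cGy, y = .data$net_od)) +
    ggplot2::geom_line(data = line, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "dose (cGy)", y = "net optical density")
}

#' @rdname cryodose-autoplot
#' @export
autoplot.pdd_curve <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$depth_cm, y = .data$pdd_percent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(x = "depth (cm)", y = "PDD (%)", title = object$energy_label)
}

#' @importFrom rlang .data
NULL
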