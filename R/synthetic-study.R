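#' Default validation field arrangements
#'
#' Four synthetic multi-segment arrangements standing in for the validation
#' deliveries: two parallel-opposed-pair (POP) static-beam cases and two
#' step-and-shoot IMRT-like cases (3-segment "larynx", 9-segment "neck").
#' Each segment carries its own effective bolus/film ratio truth; the
#' values are fixed within about +/-3% of the derived correction factor
#' 0.800, emulating the published observation that corrected-bolus and film
#' dose distributions agree to within about 2% for clinical head-and-neck
#' arrangements (mixed, mostly non-tangential incidence).
#'
#' @return Named list of arrangements; each has `name` and `segments`
#'   (a list of [field_spec()]s).
#' @export
default_validation_arrangements <- function() {
  seg <- function(size, dose, ratio, center = c(0, 0)) {
    field_spec(size, gantry_angle_deg = 0, central_dose_cGy = dose,
               bolus_film_ratio_truth = ratio, center_mm = center,
               penumbra_sigma_mm = 3)
  }
  neck_offsets <- expand.grid(y = c(-15, 0, 15), x = c(-15, 0, 15))
  neck_ratios <- c(0.78, 0.81, 0.79, 0.82, 0.80, 0.78, 0.81, 0.79, 0.82)
  list(
    pop_0_180 = list(
      name = "0/180 POP static",
      segments = list(seg(3, 350, 0.780), seg(3, 350, 0.820))
    ),
    pop_90_270 = list(
      name = "90/270 POP static",
      segments = list(seg(3, 300, 0.790, center = c(0, -2)),
                      seg(3, 300, 0.815, center = c(0, 2)))
    ),
    imrt_larynx_3field = list(
      name = "3-field larynx IMRT",
      segments = list(
        seg(3, 400, 0.800),
        seg(c(1.5, 3), 200, 0.770, center = c(0, -7.5)),
        seg(c(1.5, 3), 200, 0.830, center = c(0, 7.5))
      )
    ),
    imrt_neck_9field = list(
      name = "9-field neck IMRT",
      segments = lapply(seq_len(9), function(i) {
        seg(2, 120, neck_ratios[i],
            center = c(neck_offsets$y[i], neck_offsets$x[i]))
      })
    )
  )
}

#' Default study configuration
#'
#' The full synthetic study mirrors the physical protocol: a bolus
#' calibration series spanning 100--4000 cGy and a film series spanning
#' 100--1500 cGy (plus the zero-dose background point), open-field
#' oblique-incidence cases at gantry angles 0, 22.5, 45, 67.5 and 90
#' degrees (3 x 3 cm, 1000 MU, 700 cGy film-plane central dose) with the
#' published per-angle bolus/film ratios as ground truth, a correction
#' factor derived over 0--67.5 degrees, and four validation arrangements
#' evaluated with 3%/3 mm, 10%-threshold gamma. Film grids use 0.1693 mm
#' pixels (150 DPI), camera grids 0.2 mm.
#'
#' @param seed Integer seed driving all simulated noise.
#' @param ... Named overrides of top-level config entries.
#' @return A `study_config` list.
#' @export
#' @examples
#' cfg <- default_study_config(seed = 7)
#' names(cfg)
default_study_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    truth = generator_truth(),
    film_spacing_mm = 0.1693,
    camera_spacing_mm = 0.2,
    extent_mm = 70,
    calibration = list(
      bolus_doses = c(100, 250, 500, 750, 1000, 1500, 2000, 2500, 3000, 3500, 4000),
      film_doses = c(0, 100, 250, 500, 750, 1000, 1250, 1500),
      roi_px = 64L
    ),
    angles = c(0, 22.5, 45, 67.5, 90),
    angle_field = list(field_size_cm = 3, central_dose_cGy = 700,
                       penumbra_sigma_mm = 3, monitor_units = 1000),
    ratio_truths = reference_angle_ratios(),
    bolus_placement_offset_mm = c(1.0, -0.6),
    correction_angle_subset = c(0, 22.5, 45, 67.5),
    gamma = gamma_params(),
    denoise = TRUE,
    arrangements = default_validation_arrangements()
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config entries: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    # replacement, not recursive merge: an override supplies the whole entry
    cfg[names(over)] <- over
  }
  structure(cfg, class = "study_config")
}

# simulate every raw image of the study; returns nested image_planes +
# metadata. All randomness flows from config$seed.
.simulate_study_raw <- function(config) {
  withr::with_seed(config$seed, {
    truth <- config$truth
    cam_sp <- config$camera_spacing_mm
    film_sp <- config$film_spacing_mm
    roi <- config$calibration$roi_px

    bolus_cal <- lapply(config$calibration$bolus_doses, function(d) {
      dm <- dose_map(matrix(d, roi, roi), cam_sp, "bolus")
      render_bolus_images(dm, truth)
    })
    names(bolus_cal) <- as.character(config$calibration$bolus_doses)

    film_cal <- lapply(config$calibration$film_doses, function(d) {
      dm <- dose_map(matrix(d, roi, roi), film_sp, "film")
      render_film_scan(dm, truth)
    })
    names(film_cal) <- as.character(config$calibration$film_doses)

    grid_cam <- list(extent_mm = config$extent_mm, pixel_spacing_mm = cam_sp)
    grid_film <- list(extent_mm = config$extent_mm, pixel_spacing_mm = film_sp)

    angle_cases <- lapply(config$angles, function(a) {
      fs <- do.call(field_spec, c(
        list(gantry_angle_deg = a,
             bolus_film_ratio_truth = unname(config$ratio_truths[as.character(a)])),
        config$angle_field
      ))
      sim_f <- simulate_field_dose(fs, grid_film)
      sim_b <- simulate_field_dose(fs, grid_cam)
      list(
        angle = a, field = fs,
        bolus = render_bolus_images(sim_b$bolus_avg_dose, truth,
                                    placement_offset_mm = config$bolus_placement_offset_mm),
        film = render_film_scan(sim_f$film_dose, truth),
        truth_film = sim_f$film_dose
      )
    })
    names(angle_cases) <- as.character(config$angles)

    arrangement_cases <- lapply(config$arrangements, function(arr) {
      sim_f <- simulate_arrangement_dose(arr$segments, grid_film)
      sim_b <- simulate_arrangement_dose(arr$segments, grid_cam)
      list(
        name = arr$name,
        bolus = render_bolus_images(sim_b$bolus_avg_dose, truth,
                                    placement_offset_mm = config$bolus_placement_offset_mm),
        film = render_film_scan(sim_f$film_dose, truth)
      )
    })

    list(bolus_cal = bolus_cal, film_cal = film_cal,
         angle_cases = angle_cases, arrangement_cases = arrangement_cases)
  })
}

#' Generate a study fixture bundle on disk
#'
#' Runs the full synthetic study simulation and writes every image as a
#' 16-bit grayscale TIFF, together with a JSON manifest recording doses,
#' angles, pixel spacings, the seed and the generator truth parameters
#' (spacing is carried by the manifest, never inferred from image
#' content). Deterministic: the same config and seed produce a
#' byte-identical bundle.
#'
#' @param config A [default_study_config()] (its `seed` drives the noise).
#' @param out_dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
generate_study <- function(config = default_study_config(), out_dir,
                           overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite) {
    stop("output directory exists and is not empty; use overwrite = TRUE",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  raw <- .simulate_study_raw(config)
  wr <- function(img, name) write_image_tiff(img, file.path(out_dir, name))

  for (d in names(raw$bolus_cal)) {
    wr(raw$bolus_cal[[d]]$pre, sprintf("bolus_cal_%s_pre.tif", d))
    wr(raw$bolus_cal[[d]]$post, sprintf("bolus_cal_%s_post.tif", d))
  }
  for (d in names(raw$film_cal)) {
    wr(raw$film_cal[[d]]$background, sprintf("film_cal_%s_background.tif", d))
    wr(raw$film_cal[[d]]$irradiated, sprintf("film_cal_%s_irradiated.tif", d))
  }
  for (a in names(raw$angle_cases)) {
    cs <- raw$angle_cases[[a]]
    wr(cs$bolus$pre, sprintf("angle_%s_bolus_pre.tif", a))
    wr(cs$bolus$post, sprintf("angle_%s_bolus_post.tif", a))
    wr(cs$film$background, sprintf("angle_%s_film_background.tif", a))
    wr(cs$film$irradiated, sprintf("angle_%s_film_irradiated.tif", a))
  }
  for (key in names(raw$arrangement_cases)) {
    cs <- raw$arrangement_cases[[key]]
    wr(cs$bolus$pre, sprintf("arr_%s_bolus_pre.tif", key))
    wr(cs$bolus$post, sprintf("arr_%s_bolus_post.tif", key))
    wr(cs$film$background, sprintf("arr_%s_film_background.tif", key))
    wr(cs$film$irradiated, sprintf("arr_%s_film_irradiated.tif", key))
  }

  truth <- config$truth
  manifest <- list(
    seed = config$seed,
    camera_spacing_mm = config$camera_spacing_mm,
    film_spacing_mm = config$film_spacing_mm,
    extent_mm = config$extent_mm,
    bolus_cal_doses_cGy = config$calibration$bolus_doses,
    film_cal_doses_cGy = config$calibration$film_doses,
    angles_deg = config$angles,
    ratio_truths = as.list(config$ratio_truths),
    arrangements = names(config$arrangements),
    bolus_placement_offset_mm = config$bolus_placement_offset_mm,
    truth = list(
      bolus_slope = truth$bolus_slope,
      bolus_intercept = truth$bolus_intercept,
      bolus_thickness_mm = truth$bolus_thickness_mm,
      film_netod_points = truth$film_netod_points,
      vignette_strength = truth$vignette_strength,
      read_noise_sd = truth$read_noise_sd,
      background_counts = truth$background_counts,
      bit_depth = truth$bit_depth
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
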