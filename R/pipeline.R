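#' Run the full skin-dose measurement study
#'
#' Orchestrates the complete analysis on simulated (or previously
#' generated) data: fit the bolus and film calibrations, convert the
#' oblique-incidence image pairs to dose maps, register bolus onto film,
#' compute per-angle bolus/film ratio statistics, derive and apply the
#' bolus-to-skin correction factor, and evaluate every validation
#' arrangement with gamma analysis and central-profile differences.
#'
#' @param config A [default_study_config()].
#' @param input_dir Optional directory produced by [generate_study()]; when
#'   omitted the study is simulated in memory from `config` (same code
#'   path, same seed semantics).
#' @param out_json Optional path; when given, the report is written there
#'   as JSON (schema in `system.file("schema/report.schema.json",
#'   package = "cryodose")`).
#' @param verbose Log stage progress to stderr.
#' @return A `study_report` list: `seed`, `calibration`, `per_angle`
#'   (tibble), `correction_factor`, `validation` (tibble), `gamma_params`,
#'   `n_clip_warnings`.
#' @export
run_study <- function(config = default_study_config(), input_dir = NULL,
                      out_json = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  n_warn <- 0L
  count_warnings <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("clipped", conditionMessage(w))) {
        n_warn <<- n_warn + 1L
        invokeRestart("muffleWarning")
      }
    })
  }

  say("simulating / loading raw study data (seed %d)", config$seed)
  raw <- if (is.null(input_dir)) .simulate_study_raw(config) else
    .load_study_raw(input_dir, config)
  truth <- config$truth
  t_mm <- truth$bolus_thickness_mm

  say("fitting calibrations")
  bolus_doses <- as.numeric(names(raw$bolus_cal))
  mu_means <- vapply(raw$bolus_cal, function(p) {
    count_warnings(mean_absorption(p$pre, p$post, t_mm))
  }, numeric(1))
  bolus_cal <- fit_bolus_calibration(bolus_doses, mu_means)

  film_doses <- as.numeric(names(raw$film_cal))
  od_means <- vapply(raw$film_cal, function(p) {
    count_warnings(mean_net_od(p$background, p$irradiated))
  }, numeric(1))
  # anchor at exactly zero netOD for the unirradiated point
  od_means[film_doses == 0] <- 0
  film_cal <- fit_film_calibration(film_doses, od_means)

  analyze_case <- function(cs) {
    mu <- count_warnings(compute_absorption_map(cs$bolus$pre, cs$bolus$post, t_mm))
    od <- count_warnings(compute_net_od(cs$film$background, cs$film$irradiated))
    if (isTRUE(config$denoise)) {
      mu <- denoise_map(mu)
      od <- denoise_map(od)
    }
    bolus_dose <- count_warnings(map_to_dose(mu, bolus_cal))
    film_dose <- count_warnings(map_to_dose(od, film_cal))
    reg <- register_maps(film_dose, bolus_dose)
    mask <- field_roi(film_dose)
    list(film = film_dose, bolus = reg$resampled, reg = reg$transform, mask = mask)
  }

  say("analysing %d oblique-incidence cases", length(raw$angle_cases))
  angle_results <- lapply(raw$angle_cases, function(cs) {
    res <- analyze_case(cs)
    rm <- ratio_map(res$bolus, res$film, res$mask)
    st <- per_angle_stats(rm, res$mask, cs$angle)
    c(res, list(stats = st))
  })
  per_angle <- do.call(rbind, lapply(angle_results, `[[`, "stats"))

  say("deriving correction factor")
  k <- derive_correction_factor(per_angle, config$correction_angle_subset)

  per_angle$registration_dy_mm <- vapply(angle_results, function(r) r$reg$translation_mm[1], numeric(1))
  per_angle$registration_dx_mm <- vapply(angle_results, function(r) r$reg$translation_mm[2], numeric(1))
  per_angle$registration_rot_deg <- vapply(angle_results, function(r) r$reg$rotation_deg, numeric(1))
  per_angle$profile_diff_inline_pct <- vapply(angle_results, function(r) {
    profile_difference(apply_correction(r$bolus, k), r$film, "y", r$mask)
  }, numeric(1))
  per_angle$profile_diff_crossline_pct <- vapply(angle_results, function(r) {
    profile_difference(apply_correction(r$bolus, k), r$film, "x", r$mask)
  }, numeric(1))

  say("evaluating %d validation arrangements", length(raw$arrangement_cases))
  validation <- do.call(rbind, lapply(names(raw$arrangement_cases), function(key) {
    cs <- raw$arrangement_cases[[key]]
    res <- analyze_case(cs)
    corrected <- apply_correction(res$bolus, k)
    gr <- gamma_map(corrected, res$film, config$gamma)
    tibble::tibble(
      arrangement = key,
      label = cs$name,
      pass_rate_pct = gr$pass_rate_pct,
      n_evaluated = gr$n_evaluated,
      max_gamma = max(gr$gamma, na.rm = TRUE),
      profile_diff_inline_pct = profile_difference(corrected, res$film, "y", res$mask),
      profile_diff_crossline_pct = profile_difference(corrected, res$film, "x", res$mask)
    )
  }))

  report <- structure(
    list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("cryodose")),
      calibration = list(
        bolus = as.list(glance(bolus_cal)),
        film = list(points = film_cal$points,
                    dose_range = film_cal$dose_range)
      ),
      per_angle = per_angle,
      correction_factor = list(k = k$k, k_sd = k$k_sd,
                               angle_subset = k$angle_subset,
                               direction = k$direction),
      validation = validation,
      gamma_params = unclass(config$gamma),
      n_clip_warnings = n_warn
    ),
    class = "study_report"
  )
  if (!is.null(out_json)) {
    jsonlite::write_json(.report_as_json(report), out_json,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

.report_as_json <- function(report) {
  r <- unclass(report)
  r$per_angle <- as.data.frame(r$per_angle)
  r$validation <- as.data.frame(r$validation)
  r$calibration$film$points <- as.data.frame(r$calibration$film$points)
  r
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> seed %d\n", x$seed))
  cat(sprintf("  bolus calibration: slope %.4g +/- %.2g mm^-1 cGy^-1\n",
              x$calibration$bolus$slope, x$calibration$bolus$slope_se))
  cat(sprintf("  correction factor: k = %.3f +/- %.3f over angles {%s}\n",
              x$correction_factor$k, x$correction_factor$k_sd,
              paste(x$correction_factor$angle_subset, collapse = ", ")))
  cat("  per-angle mean ratios:",
      paste(sprintf("%.3f", x$per_angle$mean_ratio), collapse = ", "), "\n")
  cat("  validation pass rates (%):",
      paste(sprintf("%.1f", x$validation$pass_rate_pct), collapse = ", "), "\n")
  invisible(x)
}

# reload a generate_study() bundle into the raw-structure layout
.load_study_raw <- function(input_dir, config) {
  man <- jsonlite::read_json(file.path(input_dir, "manifest.json"),
                             simplifyVector = TRUE)
  cam_sp <- man$camera_spacing_mm
  film_sp <- man$film_spacing_mm
  rd <- function(name, sp) read_image_tiff(file.path(input_dir, name), sp)

  bolus_cal <- lapply(as.character(man$bolus_cal_doses_cGy), function(d) {
    list(pre = rd(sprintf("bolus_cal_%s_pre.tif", d), cam_sp),
         post = rd(sprintf("bolus_cal_%s_post.tif", d), cam_sp))
  })
  names(bolus_cal) <- as.character(man$bolus_cal_doses_cGy)
  film_cal <- lapply(as.character(man$film_cal_doses_cGy), function(d) {
    list(background = rd(sprintf("film_cal_%s_background.tif", d), film_sp),
         irradiated = rd(sprintf("film_cal_%s_irradiated.tif", d), film_sp))
  })
  names(film_cal) <- as.character(man$film_cal_doses_cGy)
  angle_cases <- lapply(man$angles_deg, function(a) {
    key <- as.character(a)
    list(
      angle = a,
      bolus = list(pre = rd(sprintf("angle_%s_bolus_pre.tif", key), cam_sp),
                   post = rd(sprintf("angle_%s_bolus_post.tif", key), cam_sp)),
      film = list(background = rd(sprintf("angle_%s_film_background.tif", key), film_sp),
                  irradiated = rd(sprintf("angle_%s_film_irradiated.tif", key), film_sp))
    )
  })
  names(angle_cases) <- as.character(man$angles_deg)
  arrangement_cases <- lapply(man$arrangements, function(key) {
    list(
      name = key,
      bolus = list(pre = rd(sprintf("arr_%s_bolus_pre.tif", key), cam_sp),
                   post = rd(sprintf("arr_%s_bolus_post.tif", key), cam_sp)),
      film = list(background = rd(sprintf("arr_%s_film_background.tif", key), film_sp),
                  irradiated = rd(sprintf("arr_%s_film_irradiated.tif", key), film_sp))
    )
  })
  names(arrangement_cases) <- man$arrangements
  list(bolus_cal = bolus_cal, film_cal = film_cal,
       angle_cases = angle_cases, arrangement_cases = arrangement_cases)
}
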