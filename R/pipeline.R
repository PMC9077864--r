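# End-to-end simulated calibration study: render scans per material and
# mode, read them back through the ROI/netOD chain, fit the response and
# calibration curves, and assemble accuracy, uncertainty and uniformity
# tables.

#' Study configuration
#'
#' Describes a full compensating-material comparison study. Defaults mirror
#' the standard CLOD protocol: calibration doses spanning 0-100 cGy with
#' three replicate irradiations per dose, accuracy checks at 25 and 70 cGy,
#' a 3.5 mm read-out ROI, 300 dpi 16-bit scans, and the four study
#' materials in both scan modes.
#'
#' @param materials Character vector of built-in material names (see
#'   [clod_materials()]) or a named list of [material_spec()] objects (the
#'   same specs are then used in both modes).
#' @param modes Scan modes to include.
#' @param calibration_doses_cgy Calibration dose levels, cGy (must include
#'   0, the unexposed reference).
#' @param replicates Replicate irradiations per dose level.
#' @param accuracy_doses_cgy Dose levels for the accuracy check, cGy.
#' @param roi_side_mm Read-out ROI side, mm.
#' @param dpi,bit_depth,wavelength Scanner settings (see [scan_config()]).
#' @param seed Master seed; every rendered scan derives its own seed from
#'   it, so a rerun with the same seed reproduces the report exactly.
#' @param geometry A [lens_geometry()].
#' @param truth A [ground_truth_response()].
#' @param M_unexp,M_bkg Unexposed and background count levels of the
#'   renders.
#' @param n_glass,n_lens Refractive indices of glass and dosimeter surface.
#' @param jitter_gap Randomise per-footprint contact-gap phase (see
#'   [render_scan()]).
#' @param output_dir Optional directory; when set,
#'   [run_calibration_study()] writes the rendered TIFFs, CSV tables and
#'   the JSON report there.
#' @return An object of class `study_config`.
#' @export
study_config <- function(materials = c("air", "DS", "SC", "OG"),
                         modes = c("transmission", "reflective"),
                         calibration_doses_cgy = c(0, 10, 25, 50, 70, 100),
                         replicates = 3,
                         accuracy_doses_cgy = c(25, 70),
                         roi_side_mm = 3.5,
                         dpi = 300, bit_depth = 16, wavelength = 630,
                         seed = 1L,
                         geometry = lens_geometry(),
                         truth = ground_truth_response(),
                         M_unexp = 40000, M_bkg = 2000,
                         n_glass = 1.52, n_lens = 1.50,
                         jitter_gap = TRUE,
                         output_dir = NULL) {
  modes <- match.arg(modes, c("transmission", "reflective"),
                     several.ok = TRUE)
  if (any(calibration_doses_cgy < 0)) stop("doses must be >= 0")
  if (!0 %in% calibration_doses_cgy)
    stop("calibration doses must include 0 (the unexposed reference)")
  if (replicates < 1) stop("replicates must be >= 1")
  structure(list(materials = materials, modes = modes,
                 calibration_doses_cgy = sort(calibration_doses_cgy),
                 replicates = as.integer(replicates),
                 accuracy_doses_cgy = accuracy_doses_cgy,
                 roi_side_mm = roi_side_mm, dpi = dpi,
                 bit_depth = bit_depth, wavelength = wavelength,
                 seed = as.integer(seed), geometry = geometry,
                 truth = truth, M_unexp = M_unexp, M_bkg = M_bkg,
                 n_glass = n_glass, n_lens = n_lens,
                 jitter_gap = jitter_gap, output_dir = output_dir),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Accepts the scalar fields of [study_config()] directly, plus nested
#' `geometry` and `truth` blocks with the argument names of
#' [lens_geometry()] and [ground_truth_response()].
#'
#' @param path YAML file path.
#' @param ... Overrides applied on top of the file's values.
#' @return A [study_config()].
#' @export
read_study_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$geometry)) cfg$geometry <- do.call(lens_geometry, cfg$geometry)
  if (!is.null(cfg$truth)) cfg$truth <- do.call(ground_truth_response, cfg$truth)
  if (!is.null(cfg$materials)) cfg$materials <- unlist(cfg$materials)
  if (!is.null(cfg$modes)) cfg$modes <- unlist(cfg$modes)
  for (f in c("calibration_doses_cgy", "accuracy_doses_cgy"))
    if (!is.null(cfg[[f]])) cfg[[f]] <- unlist(cfg[[f]])
  over <- list(...)
  cfg[names(over)] <- over
  do.call(study_config, cfg)
}

#' ROI read-out of a rendered scan
#'
#' Places the read-out ROI at each footprint centre of a generated scan
#' (and at the background position), extracts the red channel and computes
#' the ROI statistics.
#'
#' @param scan A `clod_scan` from [render_scan()].
#' @param roi_side_mm ROI side, mm.
#' @return Data frame of per-footprint statistics (`footprint`, `dose_gy`,
#'   `mean`, `sd`, `n_pixels`, `cv`), with the background [roi_stats()] as
#'   attribute `"background"`.
#' @export
analyze_scan <- function(scan, roi_side_mm = 3.5) {
  stopifnot(inherits(scan, "clod_scan"))
  red <- extract_channel(scan$image, "red")
  man <- scan$manifest
  dims <- dim(red$pixels)
  one <- function(x, y) {
    win <- roi_window(roi_spec(x, y, roi_side_mm), red$dpi, dim = dims)
    roi_stats(red, win)
  }
  st <- lapply(seq_len(nrow(man)), function(i) one(man$x_mm[i], man$y_mm[i]))
  out <- data.frame(footprint = man$footprint, dose_gy = man$dose_gy,
                    mean = vapply(st, `[[`, 0, "mean"),
                    sd = vapply(st, `[[`, 0, "sd"),
                    n_pixels = vapply(st, `[[`, 0L, "n_pixels"),
                    cv = vapply(st, `[[`, 0, "cv"))
  bg <- attr(man, "background_mm")
  attr(out, "background") <- one(bg[["x"]], bg[["y"]])
  out
}

# pool replicate ROI statistics for one dose level: mean of means, rms of
# SDs (the replicate footprints are identically distributed)
pool_stats <- function(df) {
  list(mean = mean(df$mean), sd = sqrt(mean(df$sd^2)))
}

# netOD table (replicate means) from an analysed calibration scan
netod_from_stats <- function(st, bg) {
  unexp <- pool_stats(st[st$dose_gy == 0, ])
  doses <- sort(unique(st$dose_gy))
  rows <- lapply(doses, function(d) {
    if (d == 0)  # the unexposed scans define the reference: netOD(0) = 0
      return(data.frame(dose_gy = 0, netod = 0,
                        sigma_netod = netod_uncertainty(
                          unexp$mean, unexp$mean, bg$mean,
                          unexp$sd, unexp$sd, bg$sd),
                        M_exp = unexp$mean, sd_exp = unexp$sd))
    ex <- pool_stats(st[st$dose_gy == d, ])
    data.frame(dose_gy = d,
               netod = compute_netod(unexp$mean, ex$mean, bg$mean),
               sigma_netod = netod_uncertainty(unexp$mean, ex$mean, bg$mean,
                                               unexp$sd, ex$sd, bg$sd),
               M_exp = ex$mean, sd_exp = ex$sd)
  })
  out <- do.call(rbind, rows)
  attr(out, "M_unexp") <- unexp$mean
  attr(out, "sd_unexp") <- unexp$sd
  attr(out, "M_bkg") <- bg$mean
  attr(out, "sd_bkg") <- bg$sd
  out
}

fit_summary <- function(fit) {
  list(lin_coeff = unname(coef(fit)[["lin_coeff"]]),
       pow_coeff = unname(coef(fit)[["pow_coeff"]]),
       exponent = unname(coef(fit)[["exponent"]]),
       param_sds = as.list(fit$param_sds),
       adj_r2 = fit$adj_r2, n_points = fit$n_points)
}

analyze_material_mode <- function(mat, mode, cfg, scan_seed, scan_writer) {
  reps <- cfg$replicates
  cal_gy <- rep(cfg$calibration_doses_cgy, each = reps) / 100

  render1 <- function(doses_gy, seed, tag) {
    sc <- render_scan(doses_gy, geometry = cfg$geometry, material = mat,
                      config = scan_config(mode, cfg$dpi, cfg$bit_depth,
                                           cfg$wavelength, seed),
                      truth = cfg$truth, M_unexp = cfg$M_unexp,
                      M_bkg = cfg$M_bkg, n_glass = cfg$n_glass,
                      n_lens = cfg$n_lens, jitter_gap = cfg$jitter_gap)
    scan_writer(sc, sprintf("%s_%s_%s.tiff", tag, mat$name, mode))
    sc
  }

  cal_scan <- render1(cal_gy, scan_seed, "calibration")
  cal_st <- analyze_scan(cal_scan, cfg$roi_side_mm)
  nod <- netod_from_stats(cal_st, attr(cal_st, "background"))

  dr_fit <- fit_dose_response(nod$dose_gy, nod$netod, nod$sigma_netod)
  cal_fit <- fit_calibration(nod$netod, nod$dose_gy, nod$sigma_netod)

  pos <- nod$dose_gy > 0
  budget <- total_uncertainty(cal_fit, nod$netod[pos], nod$sigma_netod[pos])
  budget <- cbind(material = mat$name, mode = mode,
                  dose_cgy = nod$dose_gy[pos] * 100, budget)

  sens <- data.frame(material = mat$name, mode = mode,
                     dose_cgy = nod$dose_gy[pos] * 100,
                     sensitivity = sensitivity(dr_fit, nod$dose_gy[pos]))

  # accuracy check on an independently rendered scan
  acc_gy <- rep(c(0, cfg$accuracy_doses_cgy), each = reps) / 100
  acc_scan <- render1(acc_gy, scan_seed + 1L, "accuracy")
  acc_st <- analyze_scan(acc_scan, cfg$roi_side_mm)
  acc_nod <- netod_from_stats(acc_st, attr(acc_st, "background"))
  acc_pos <- acc_nod[acc_nod$dose_gy > 0, ]
  accuracy <- data.frame(
    material = mat$name, mode = mode,
    delivered_cgy = acc_pos$dose_gy * 100,
    measured_cgy = apply_calibration(cal_fit, acc_pos$netod) * 100)
  accuracy$dose_diff_pct <- dose_difference_pct(accuracy$measured_cgy,
                                                accuracy$delivered_cgy)

  uniformity <- data.frame(material = mat$name, mode = mode,
                           cv = mean(cal_st$cv[cal_st$dose_gy > 0]))

  list(material = mat$name, mode = mode,
       netod_table = cbind(material = mat$name, mode = mode, nod),
       dose_response = dr_fit, calibration = cal_fit,
       sensitivity_table = sens, uncertainty = budget,
       accuracy = accuracy, uniformity = uniformity)
}

#' Run a full simulated calibration study
#'
#' For every material and scan mode of the configuration: renders a
#' calibration scan (all dose levels, replicated) and an independent
#' accuracy scan, reads both back through the ROI, netOD and fitting
#' chain, and assembles dose-response and calibration fits, sensitivity
#' values, an uncertainty budget per dose, the accuracy table and the
#' scan-uniformity table. Cross-material summaries (average dose
#' difference, sensitivity increase over air at 50 cGy, and the
#' reflective/transmission sensitivity ratio) are added when the
#' configuration supports them. Reruns with the same seed reproduce the
#' report exactly.
#'
#' @param config A [study_config()].
#' @return An object of class `clod_study`: a list of per-combination
#'   results (`runs`) plus summary tables `accuracy`, `avg_dose_diff`,
#'   `uniformity`, `sensitivity_increase` and `mode_ratio`.
#' @export
run_calibration_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$output_dir
  scan_writer <- if (is.null(out_dir)) function(sc, name) invisible(NULL)
  else {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    function(sc, name) write_scan(sc, file.path(out_dir, name))
  }

  mats <- config$materials
  runs <- list()
  k <- 0L
  for (mode in config$modes) {
    mat_list <- if (is.character(mats)) clod_materials(mode)[mats] else mats
    if (any(vapply(mat_list, is.null, TRUE)))
      stop("unknown material name among: ", paste(mats, collapse = ", "))
    for (m in mat_list) {
      runs[[paste(m$name, mode, sep = ".")]] <-
        analyze_material_mode(m, mode, config,
                              scan_seed = config$seed + 2L * k, scan_writer)
      k <- k + 1L
    }
  }

  accuracy <- do.call(rbind, lapply(runs, `[[`, "accuracy"))
  rownames(accuracy) <- NULL
  mat_names <- unique(accuracy$material)
  avg <- data.frame(material = mat_names,
                    avg_dose_diff_pct = vapply(
                      mat_names,
                      function(m) average_dose_difference(accuracy, m), 0))
  rownames(avg) <- NULL
  uniformity <- do.call(rbind, lapply(runs, `[[`, "uniformity"))
  rownames(uniformity) <- NULL

  sens_inc <- NULL
  if ("air" %in% mat_names) {
    rows <- list()
    for (mode in config$modes) {
      air_fit <- runs[[paste("air", mode, sep = ".")]]$dose_response
      for (m in setdiff(mat_names, "air")) {
        rows[[paste(m, mode)]] <- data.frame(
          material = m, mode = mode, dose_cgy = 50,
          sensitivity_increase_pct = sensitivity_increase_pct(
            runs[[paste(m, mode, sep = ".")]]$dose_response, air_fit, 0.5))
      }
    }
    if (length(rows)) sens_inc <- do.call(rbind, rows)
    if (!is.null(sens_inc)) rownames(sens_inc) <- NULL
  }

  mode_ratio <- NULL
  if (all(c("transmission", "reflective") %in% config$modes)) {
    grid <- config$calibration_doses_cgy[config$calibration_doses_cgy > 0] / 100
    mode_ratio <- data.frame(
      material = mat_names,
      sensitivity_ratio = vapply(mat_names, function(m)
        mode_sensitivity_ratio(
          runs[[paste(m, "reflective", sep = ".")]]$dose_response,
          runs[[paste(m, "transmission", sep = ".")]]$dose_response,
          grid), 0))
    rownames(mode_ratio) <- NULL
  }

  study <- structure(list(seed = config$seed, runs = runs,
                          accuracy = accuracy, avg_dose_diff = avg,
                          uniformity = uniformity,
                          sensitivity_increase = sens_inc,
                          mode_ratio = mode_ratio),
                     class = "clod_study")
  if (!is.null(out_dir)) write_study_report(study, out_dir)
  study
}

#' Write a study report to disk
#'
#' Emits the machine-readable JSON report plus CSV tables (accuracy,
#' uniformity, per-point netOD, uncertainty budgets, fit parameters).
#'
#' @param study A `clod_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(study, dir) {
  stopifnot(inherits(study, "clod_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(study$accuracy, file.path(dir, "accuracy.csv"),
            row.names = FALSE)
  write.csv(study$uniformity, file.path(dir, "uniformity.csv"),
            row.names = FALSE)
  netod_all <- do.call(rbind, lapply(study$runs, `[[`, "netod_table"))
  write.csv(netod_all, file.path(dir, "netod.csv"), row.names = FALSE)
  budget_all <- do.call(rbind, lapply(study$runs, `[[`, "uncertainty"))
  write.csv(budget_all, file.path(dir, "uncertainty.csv"),
            row.names = FALSE)
  fits <- do.call(rbind, lapply(study$runs, function(r)
    data.frame(material = r$material, mode = r$mode,
               curve = c("dose_response", "calibration"),
               rbind(coef(r$dose_response), coef(r$calibration)),
               adj_r2 = c(r$dose_response$adj_r2, r$calibration$adj_r2))))
  write.csv(fits, file.path(dir, "fits.csv"), row.names = FALSE)

  report <- list(
    seed = study$seed,
    accuracy = study$accuracy,
    avg_dose_diff = study$avg_dose_diff,
    uniformity = study$uniformity,
    sensitivity_increase = study$sensitivity_increase,
    mode_ratio = study$mode_ratio,
    fits = lapply(study$runs, function(r)
      list(dose_response = fit_summary(r$dose_response),
           calibration = fit_summary(r$calibration))),
    uncertainty = lapply(study$runs, `[[`, "uncertainty"))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.clod_study <- function(x, ...) {
  cat("CLOD simulated calibration study (seed", x$seed, ")\n\n")
  cat("Average dose difference by material (%):\n")
  print(x$avg_dose_diff, row.names = FALSE)
  cat("\nScan uniformity (CV):\n")
  print(x$uniformity, row.names = FALSE)
  if (!is.null(x$mode_ratio)) {
    cat("\nReflective/transmission sensitivity ratio:\n")
    print(x$mode_ratio, row.names = FALSE)
  }
  invisible(x)
}
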