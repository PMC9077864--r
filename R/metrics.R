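# Comparison metrics between scan modes and compensating materials:
# dose-difference accuracy, sensitivity ratios, and scan-uniformity CV,
# plus the published accuracy and uniformity tables as bundled fixtures.

#' Absolute percent dose difference
#'
#' `|measured - delivered| / delivered x 100`, the accuracy figure of merit
#' for a calibrated read-out.
#'
#' @param measured,delivered Doses in the same unit (vectorised);
#'   `delivered` must be positive.
#' @return Percent difference (>= 0).
#' @examples
#' dose_difference_pct(26.7, 25) # 6.8
#' @export
dose_difference_pct <- function(measured, delivered) {
  if (any(delivered <= 0)) stop("delivered dose must be > 0")
  abs(measured - delivered) / delivered * 100
}

#' Per-material average dose difference
#'
#' Arithmetic mean of the percent dose differences over all doses and scan
#' modes recorded for one material.
#'
#' @param records Data frame with at least columns `material` and
#'   `dose_diff_pct` (e.g. the accuracy table of a study report or
#'   [clod_table1()]).
#' @param material Material label to average over; `NULL` averages all
#'   rows.
#' @return Mean percent dose difference.
#' @export
average_dose_difference <- function(records, material = NULL) {
  stopifnot(is.data.frame(records), "dose_diff_pct" %in% names(records))
  if (!is.null(material)) {
    records <- records[records$material == material, , drop = FALSE]
    if (nrow(records) == 0L) stop("no records for material ", material)
  }
  mean(records$dose_diff_pct)
}

#' Sensitivity increase of a compensating material over air
#'
#' `(S_material(D) - S_air(D)) / S_air(D) x 100` using the analytic
#' sensitivities of the two fitted dose-response curves; negative when the
#' material lowers the sensitivity.
#'
#' @param fit_material,fit_air `dose_response_fit` objects.
#' @param dose_gy Dose at which to compare, Gy.
#' @return Percent increase (may be negative).
#' @export
sensitivity_increase_pct <- function(fit_material, fit_air, dose_gy) {
  s_air <- sensitivity(fit_air, dose_gy)
  if (any(s_air == 0)) stop("air sensitivity is zero; increase undefined")
  (sensitivity(fit_material, dose_gy) - s_air) / s_air * 100
}

#' Reflective/transmission sensitivity ratio
#'
#' Mean over a dose grid of `S_reflective(D) / S_transmission(D)`. When the
#' two responses share their shape up to a common gain the ratio is
#' constant and equals the gain.
#'
#' @param fit_reflective,fit_transmission `dose_response_fit` objects.
#' @param doses_gy Dose grid, Gy (> 0).
#' @return Mean sensitivity ratio (dimensionless).
#' @export
mode_sensitivity_ratio <- function(fit_reflective, fit_transmission,
                                   doses_gy) {
  if (any(doses_gy <= 0)) stop("dose grid must be > 0")
  s_t <- sensitivity(fit_transmission, doses_gy)
  bad <- s_t == 0
  if (any(bad)) {
    warning("transmission sensitivity is zero at some grid points; excluded")
    doses_gy <- doses_gy[!bad]
    s_t <- s_t[!bad]
  }
  mean(sensitivity(fit_reflective, doses_gy) / s_t)
}

#' Scan-uniformity record from ROI statistics
#'
#' Scan uniformity is quantified by the coefficient of variation of the ROI
#' pixel values, `cv = sd / mean`.
#'
#' @param stats An [roi_stats()] object.
#' @param material,mode Labels carried into the record.
#' @return A one-row data frame `material`, `mode`, `cv`.
#' @export
scan_uniformity <- function(stats, material = NA_character_,
                            mode = NA_character_) {
  stopifnot(inherits(stats, "roi_stats"))
  if (stats$mean <= 0) stop("ROI mean must be > 0")
  data.frame(material = material, mode = mode,
             cv = stats$sd / stats$mean)
}

#' Published CLOD accuracy table (bundled fixture)
#'
#' The printed accuracy results of the CLOD compensating-material study:
#' measured dose (cGy) and percent dose difference for each material
#' (air, DS, SC, OG), scan mode, and delivered dose (25 and 70 cGy), as
#' published. Used by [reproduce_table1()] to verify the dose-difference
#' arithmetic against the printed cells.
#'
#' @return Data frame with columns `material`, `mode`, `delivered_cgy`,
#'   `measured_cgy`, `printed_diff_pct`.
#' @export
clod_table1 <- function() {
  data.frame(
    material = rep(c("air", "DS", "SC", "OG"), each = 4),
    mode = rep(c("transmission", "reflective"), times = 8),
    delivered_cgy = rep(rep(c(25, 70), each = 2), times = 4),
    measured_cgy = c(26.7, 26.3, 74.6, 74.1,
                     26.4, 23.8, 74.5, 73.9,
                     23.7, 26.2, 73.6, 73.4,
                     25.6, 25.3, 70.2, 70.1),
    printed_diff_pct = c(6.8, 5.2, 6.6, 5.9,
                         5.4, 4.8, 6.4, 5.5,
                         5.4, 4.7, 5.2, 4.9,
                         2.2, 1.3, 0.3, 0.2)
  )
}

#' Published CLOD scan-uniformity table (bundled fixture)
#'
#' The printed scan-uniformity coefficients of variation per material and
#' scan mode.
#'
#' @return Data frame with columns `material`, `mode`, `cv`.
#' @export
clod_table2 <- function() {
  data.frame(
    material = rep(c("air", "DS", "SC", "OG"), times = 2),
    mode = rep(c("transmission", "reflective"), each = 4),
    cv = c(0.0166, 0.0161, 0.0162, 0.0146,
           0.0134, 0.0110, 0.0115, 0.0097)
  )
}

#' Recompute the published accuracy table from its measured doses
#'
#' Re-derives every percent dose difference of [clod_table1()] from the
#' printed measured doses, compares cell by cell against the printed
#' differences (the measured doses are printed to 1 decimal place, so a
#' rounding slack applies), and recomputes the per-material averages over
#' both doses and both modes.
#'
#' @param tolerance_pp Per-cell agreement slack in percentage points
#'   (default 0.25, the worst case consistent with 1-dp rounding of the
#'   measured doses).
#' @return List with `cells` (the table plus `recomputed_diff_pct`,
#'   `delta_pp`, `consistent`) and `averages` (per-material means of the
#'   printed and recomputed differences).
#' @export
reproduce_table1 <- function(tolerance_pp = 0.25) {
  tab <- clod_table1()
  tab$recomputed_diff_pct <- dose_difference_pct(tab$measured_cgy,
                                                 tab$delivered_cgy)
  tab$delta_pp <- abs(tab$recomputed_diff_pct - tab$printed_diff_pct)
  tab$consistent <- tab$delta_pp <= tolerance_pp
  avg <- do.call(rbind, lapply(split(tab, tab$material), function(d)
    data.frame(material = d$material[1],
               printed_avg_pct = mean(d$printed_diff_pct),
               recomputed_avg_pct = mean(d$recomputed_diff_pct))))
  rownames(avg) <- NULL
  list(cells = tab, averages = avg)
}
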