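# Net optical density from pixel-value triplets, with first-order
# uncertainty propagation in the Devic radiochromic-film tradition.

#' Net optical density from a pixel-value triplet
#'
#' `netOD = log10((M_unexp - M_bkg) / (M_exp - M_bkg))`, where `M_unexp` is
#' the pixel value before irradiation, `M_exp` after, and `M_bkg` the value
#' with nothing on the scanner bed. A darkening dosimeter (`M_exp <
#' M_unexp`) then has positive netOD -- the conventional orientation used
#' throughout radiochromic dosimetry and throughout this package.
#'
#' `convention = "literal"` flips the ratio, i.e. computes
#' `log10((M_exp - M_bkg) / (M_unexp - M_bkg))`, which yields negative
#' values for a darkening dosimeter. Some published write-ups print the
#' defining equation in this orientation even though their reported netOD
#' values are positive; the flag exists so both readings can be audited.
#'
#' @param M_unexp,M_exp,M_bkg Pixel values (counts); vectorised over the
#'   first two. `M_bkg` defaults to 0 when no empty-bed scan is available.
#' @param convention `"positive"` (default) or `"literal"` (see above).
#' @param strict If `TRUE`, brightening (`M_exp > M_unexp`, negative netOD
#'   under the positive convention) is an error instead of a warning.
#' @return netOD, dimensionless.
#' @examples
#' compute_netod(40000, 30000, 1000) # log10(39000/29000) = 0.1288
#' @export
compute_netod <- function(M_unexp, M_exp, M_bkg = 0,
                          convention = c("positive", "literal"),
                          strict = FALSE) {
  convention <- match.arg(convention)
  if (missing(M_bkg))
    message("compute_netod: no background value supplied; assuming M_bkg = 0")
  if (any(M_unexp <= M_bkg) || any(M_exp <= M_bkg))
    stop("signal at or below background: need M_unexp > M_bkg and M_exp > M_bkg")
  if (any(M_exp > M_unexp)) {
    if (strict) stop("M_exp > M_unexp: dosimeter brightened under strict mode")
    warning("M_exp > M_unexp: negative netOD (brightening)")
  }
  out <- log10((M_unexp - M_bkg) / (M_exp - M_bkg))
  if (convention == "literal") -out else out
}

#' First-order netOD uncertainty
#'
#' Propagates the three pixel-value SDs through the netOD logarithm:
#' `sigma_netOD = (1/ln 10) sqrt((sd_exp^2 + sd_bkg^2) / (M_exp - M_bkg)^2
#' + (sd_unexp^2 + sd_bkg^2) / (M_unexp - M_bkg)^2)`.
#' This is the standard scan-noise ("uncertainty of film scanning") term of
#' the radiochromic read-out protocol; for pixel SDs of a few percent of the
#' signal it agrees with full Monte-Carlo propagation to well within 5%.
#'
#' @param M_unexp,M_exp,M_bkg Pixel values, counts.
#' @param sd_unexp,sd_exp,sd_bkg Their SDs, counts.
#' @return `sigma_netOD`, dimensionless.
#' @export
netod_uncertainty <- function(M_unexp, M_exp, M_bkg = 0,
                              sd_unexp = 0, sd_exp = 0, sd_bkg = 0) {
  if (any(M_unexp <= M_bkg) || any(M_exp <= M_bkg))
    stop("signal at or below background")
  if (any(c(sd_unexp, sd_exp, sd_bkg) < 0)) stop("SDs must be >= 0")
  (1 / log(10)) * sqrt((sd_exp^2 + sd_bkg^2) / (M_exp - M_bkg)^2 +
                       (sd_unexp^2 + sd_bkg^2) / (M_unexp - M_bkg)^2)
}

#' Bundle a netOD measurement with its propagated uncertainty
#'
#' @inheritParams compute_netod
#' @inheritParams netod_uncertainty
#' @return An object of class `od_measurement` carrying the inputs plus
#'   `netOD` and `sigma_netOD`.
#' @export
od_measurement <- function(M_unexp, M_exp, M_bkg = 0,
                           sd_unexp = 0, sd_exp = 0, sd_bkg = 0,
                           convention = c("positive", "literal")) {
  convention <- match.arg(convention)
  netod <- compute_netod(M_unexp, M_exp, M_bkg, convention = convention)
  structure(list(M_unexp = M_unexp, M_exp = M_exp, M_bkg = M_bkg,
                 sd_unexp = sd_unexp, sd_exp = sd_exp, sd_bkg = sd_bkg,
                 netOD = netod,
                 sigma_netOD = netod_uncertainty(M_unexp, M_exp, M_bkg,
                                                 sd_unexp, sd_exp, sd_bkg)),
            class = "od_measurement")
}

#' @export
print.od_measurement <- function(x, ...) {
  cat(sprintf("netOD = %.5f +/- %.5f  (M_unexp %.0f, M_exp %.0f, M_bkg %.0f)\n",
              x$netOD, x$sigma_netOD, x$M_unexp, x$M_exp, x$M_bkg))
  invisible(x)
}
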