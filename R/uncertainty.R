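# Decomposition of the relative uncertainty of a calibrated dose into the
# experimental (scan-noise) and fit-parameter components, combined in
# quadrature.

cal_params <- function(fit) {
  stopifnot(inherits(fit, "calibration_fit"))
  list(lin = unname(coef(fit)[["lin_coeff"]]),
       pow = unname(coef(fit)[["pow_coeff"]]),
       n = unname(coef(fit)[["exponent"]]),
       sd_lin = unname(fit$param_sds[["lin_coeff"]]),
       sd_pow = unname(fit$param_sds[["pow_coeff"]]),
       sd_n = unname(fit$param_sds[["exponent"]]),
       cov_lp = unname(fit$covariance["lin_coeff", "pow_coeff"]))
}

#' Experimental (scan-noise) component of the relative dose uncertainty
#'
#' Propagates the netOD measurement uncertainty through the calibration
#' curve `D = a netOD + b netOD^n`:
#' `sigma_Dexp(%) = |a + n b netOD^(n-1)| sigma_netOD / D_fit x 100`.
#'
#' @param fit A `calibration_fit`.
#' @param netod Measured netOD (vectorised, > 0: at netOD = 0 the fitted
#'   dose is 0 and the relative uncertainty is undefined).
#' @param sigma_netod netOD SD(s) from [netod_uncertainty()].
#' @return Relative uncertainty in percent.
#' @export
experimental_uncertainty <- function(fit, netod, sigma_netod) {
  p <- cal_params(fit)
  if (any(netod <= 0))
    stop("relative uncertainty undefined at netOD = 0 (D_fit = 0)")
  if (any(sigma_netod < 0)) stop("sigma_netod must be >= 0")
  d_fit <- apply_calibration(fit, netod)
  abs(p$lin + p$n * p$pow * netod^(p$n - 1)) * sigma_netod / d_fit * 100
}

#' Fit-parameter component of the relative dose uncertainty
#'
#' `sigma_Dfit(%) = sqrt(netOD^2 sigma_a^2 + netOD^(2n) sigma_b^2) / D_fit
#' x 100`, using the SDs of the two calibration coefficients. The default
#' deliberately omits the coefficient covariance and the exponent's
#' uncertainty, matching the conventional two-term bookkeeping of the
#' radiochromic protocol; `extended = TRUE` adds the
#' `2 netOD^(n+1) cov(a, b)` cross term and the first-order exponent term
#' `(b netOD^n ln netOD)^2 sigma_n^2` for comparison.
#'
#' @param fit A `calibration_fit`.
#' @param netod Measured netOD (vectorised, > 0).
#' @param extended Include covariance and exponent terms.
#' @return Relative uncertainty in percent.
#' @export
fit_uncertainty <- function(fit, netod, extended = FALSE) {
  p <- cal_params(fit)
  if (any(netod <= 0))
    stop("relative uncertainty undefined at netOD = 0 (D_fit = 0)")
  d_fit <- apply_calibration(fit, netod)
  v <- netod^2 * p$sd_lin^2 + netod^(2 * p$n) * p$sd_pow^2
  if (extended) {
    v <- v + 2 * netod^(p$n + 1) * p$cov_lp +
      (p$pow * netod^p$n * log(netod))^2 * p$sd_n^2
    v <- pmax(v, 0)
  }
  sqrt(v) / d_fit * 100
}

#' Total relative dose uncertainty budget
#'
#' Combines the experimental and fit components:
#' `sigma_Dtot(%) = sqrt(netOD^2 sigma_a^2 + netOD^(2n) sigma_b^2 +
#' (a + n b netOD^(n-1))^2 sigma_netOD^2) / D_fit x 100`,
#' which is algebraically the quadrature sum of
#' [experimental_uncertainty()] and [fit_uncertainty()].
#'
#' @param fit A `calibration_fit`.
#' @param netod Measured netOD (vectorised, > 0).
#' @param sigma_netod netOD SD(s).
#' @param extended Use the extended fit-component propagation (see
#'   [fit_uncertainty()]).
#' @return An `uncertainty_budget` data frame with columns `at_netOD`,
#'   `at_D_fit` (Gy), `sigma_exp_pct`, `sigma_fit_pct`, `sigma_tot_pct`.
#' @examples
#' # a 3-4-5 quadrature: components of 3% and 4% combine to 5%
#' @export
total_uncertainty <- function(fit, netod, sigma_netod, extended = FALSE) {
  s_exp <- experimental_uncertainty(fit, netod, sigma_netod)
  s_fit <- fit_uncertainty(fit, netod, extended = extended)
  out <- data.frame(at_netOD = netod,
                    at_D_fit = apply_calibration(fit, netod),
                    sigma_exp_pct = s_exp,
                    sigma_fit_pct = s_fit,
                    sigma_tot_pct = sqrt(s_exp^2 + s_fit^2))
  class(out) <- c("uncertainty_budget", "data.frame")
  out
}
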