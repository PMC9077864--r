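# Power-law dose-response and inverse calibration fits, and the analytic
# sensitivity of the fitted response.

# Multi-start Levenberg-Marquardt fit of y = a x + b x^n. The through-origin
# power law is weakly identified when a x and b x^n are nearly collinear, so
# a single start can land in a poor local minimum; restarting over a small
# grid of exponents and keeping the lowest SSR is cheap insurance.
power_law_fit <- function(x, y, weights = NULL,
                          n_bounds = c(0.2, 5),
                          n_starts = c(0.5, 1, 1.5, 2.5, 4)) {
  stopifnot(length(x) == length(y), length(x) >= 4L)
  if (length(unique(x)) < 3L) stop("need at least 3 distinct x values")
  pos <- x > 0
  lo <- pos & x <= sort(unique(x[pos]))[min(2L, length(unique(x[pos])))]
  a0 <- sum(y[lo] * x[lo]) / sum(x[lo]^2)          # through-origin slope
  if (!is.finite(a0)) a0 <- 0
  df <- data.frame(x = x, y = y)
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  best <- NULL
  best_ssr <- Inf
  for (n0 in n_starts) {
    b0 <- (mean(y[x == max(x)]) - a0 * max(x)) / max(x)^n0
    if (!is.finite(b0) || b0 == 0) b0 <- 1e-3
    ft <- tryCatch(
      minpack.lm::nlsLM(y ~ a * x + b * x^n, data = df,
                        start = list(a = a0, b = b0, n = n0),
                        lower = c(-Inf, -Inf, n_bounds[1]),
                        upper = c(Inf, Inf, n_bounds[2]),
                        weights = w,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(ft)) next
    ssr <- sum(w * residuals(ft)^2)
    if (ssr < best_ssr) {
      best_ssr <- ssr
      best <- ft
    }
  }
  if (is.null(best)) stop("power-law fit failed to converge from any start")
  cf <- coef(best)
  vc <- tryCatch(vcov(best), error = function(e) matrix(NA_real_, 3, 3))
  sds <- sqrt(pmax(diag(vc), 0))
  nn <- length(y)
  r2 <- 1 - best_ssr / sum(w * (y - sum(w * y) / sum(w))^2)
  adj_r2 <- 1 - (1 - r2) * (nn - 1) / (nn - 3 - 1)
  at_bound <- cf[["n"]] <= n_bounds[1] + 1e-8 || cf[["n"]] >= n_bounds[2] - 1e-8
  if (at_bound)
    warning("fitted exponent sits at its bound (", signif(cf[["n"]], 4), ")")
  list(coefficients = cf, sds = sds, covariance = vc,
       adj_r2 = adj_r2, ssr = best_ssr, n_points = nn,
       exponent_at_bound = at_bound, range = range(x))
}

new_power_fit <- function(raw, class, names3) {
  cf <- setNames(as.numeric(raw$coefficients), names3)
  structure(list(coefficients = cf,
                 param_sds = setNames(as.numeric(raw$sds), names3),
                 covariance = structure(raw$covariance,
                                        dimnames = list(names3, names3)),
                 adj_r2 = raw$adj_r2, ssr = raw$ssr,
                 n_points = raw$n_points,
                 exponent_at_bound = raw$exponent_at_bound,
                 range = raw$range),
            class = class)
}

#' Fit the power-law dose-response curve
#'
#' Least-squares fit of `netOD = a D + b D^n` to calibration points. The
#' fit is unweighted by default (pass `weighted = TRUE` to weight by
#' `1 / sigma_netod^2`); both curve forms pass through the origin, so
#' `(0, 0)` points may be included. Goodness of fit is the adjusted R
#' squared `1 - (1 - R^2)(N - 1)/(N - p - 1)` with `p = 3`.
#'
#' @param dose_gy Delivered doses, Gy.
#' @param netod Measured netOD values.
#' @param sigma_netod Optional per-point netOD SDs (needed for
#'   `weighted = TRUE`).
#' @param weighted Weight the fit by `1 / sigma_netod^2`.
#' @return An object of class `dose_response_fit` with elements
#'   `coefficients` (`lin_coeff`, `pow_coeff`, `exponent`), `param_sds`,
#'   `covariance`, `adj_r2`, `n_points`, `range`.
#' @examples
#' D <- rep(c(0.1, 0.25, 0.5, 1), each = 2)
#' fit <- fit_dose_response(D, 0.3 * D + 0.1 * D^1.8)
#' coef(fit)
#' @export
fit_dose_response <- function(dose_gy, netod, sigma_netod = NULL,
                              weighted = FALSE) {
  if (any(dose_gy < 0)) stop("doses must be >= 0")
  w <- fit_weights(weighted, sigma_netod)
  raw <- power_law_fit(dose_gy, netod, weights = w)
  new_power_fit(raw, c("dose_response_fit", "power_fit"),
                c("lin_coeff", "pow_coeff", "exponent"))
}

#' Fit the inverse calibration curve
#'
#' Least-squares fit of `D = a netOD + b netOD^n`, the curve used to turn a
#' measured netOD of an unknown exposure into a dose. Parameter naming
#' follows the dose-response fit: `lin_coeff` (Gy/netOD) and `pow_coeff`
#' (Gy/netOD^n) are the linear and power-term coefficients -- the pair that
#' uncertainty decompositions often label *b* and *c*.
#'
#' @param netod Measured netOD values.
#' @param dose_gy Delivered doses, Gy.
#' @param sigma_netod Optional per-point netOD SDs.
#' @param weighted Weight the fit by `1 / sigma_netod^2`.
#' @return An object of class `calibration_fit` (same structure as
#'   [fit_dose_response()]).
#' @export
fit_calibration <- function(netod, dose_gy, sigma_netod = NULL,
                            weighted = FALSE) {
  if (any(netod < 0)) stop("netOD must be >= 0")
  w <- fit_weights(weighted, sigma_netod)
  raw <- power_law_fit(netod, dose_gy, weights = w)
  new_power_fit(raw, c("calibration_fit", "power_fit"),
                c("lin_coeff", "pow_coeff", "exponent"))
}

fit_weights <- function(weighted, sigma) {
  if (!weighted) return(NULL)
  if (is.null(sigma)) stop("weighted fit requires sigma_netod")
  if (any(sigma <= 0)) stop("weights need strictly positive sigma_netod")
  1 / sigma^2
}

#' @export
coef.power_fit <- function(object, ...) object$coefficients

#' @export
print.power_fit <- function(x, ...) {
  cf <- x$coefficients
  lab <- if (inherits(x, "calibration_fit")) "D = a netOD + b netOD^n"
         else "netOD = a D + b D^n"
  cat(sprintf("%s\n  a = %.6g (sd %.3g)\n  b = %.6g (sd %.3g)\n  n = %.6g (sd %.3g)\n  adj R^2 = %.6f on %d points\n",
              lab, cf[1], x$param_sds[1], cf[2], x$param_sds[2],
              cf[3], x$param_sds[3], x$adj_r2, x$n_points))
  invisible(x)
}

#' Analytic sensitivity of a fitted dose-response
#'
#' The sensitivity is the slope of the dose-response curve,
#' `S(D) = d netOD / d D = a + n b D^(n-1)`. For exponents below 1 the
#' power term's derivative diverges at zero dose, so `D = 0` returns `Inf`
#' with a warning in that case.
#'
#' @param fit A `dose_response_fit` (or any object whose `coef()` returns
#'   `lin_coeff`, `pow_coeff`, `exponent`).
#' @param dose_gy Doses at which to evaluate, Gy (vectorised, >= 0).
#' @return Sensitivity in netOD/Gy.
#' @export
sensitivity <- function(fit, dose_gy) {
  cf <- coef(fit)
  if (any(dose_gy < 0)) stop("dose must be >= 0")
  n <- cf[["exponent"]]
  if (n < 1 && any(dose_gy == 0))
    warning("sensitivity diverges at D = 0 for exponent < 1")
  unname(cf[["lin_coeff"]] + n * cf[["pow_coeff"]] * dose_gy^(n - 1))
}

#' Convert netOD to dose through a fitted calibration curve
#'
#' `D_fit = a netOD + b netOD^n` with the fitted calibration parameters.
#' netOD values beyond the fitted range trigger an extrapolation warning.
#'
#' @param fit A `calibration_fit`.
#' @param netod Measured netOD (vectorised, >= 0).
#' @return Dose in Gy.
#' @export
apply_calibration <- function(fit, netod) {
  stopifnot(inherits(fit, "calibration_fit"))
  if (any(netod < 0)) stop("netOD must be >= 0")
  if (any(netod > fit$range[2] * (1 + 1e-9)))
    warning("netOD above the calibrated range; extrapolating")
  cf <- coef(fit)
  unname(cf[["lin_coeff"]] * netod + cf[["pow_coeff"]] * netod^cf[["exponent"]])
}

#' @rdname apply_calibration
#' @param object A `calibration_fit`.
#' @param ... Unused.
#' @export
predict.calibration_fit <- function(object, netod, ...) {
  apply_calibration(object, netod)
}

#' @export
predict.dose_response_fit <- function(object, dose_gy, ...) {
  cf <- coef(object)
  unname(cf[["lin_coeff"]] * dose_gy +
           cf[["pow_coeff"]] * dose_gy^cf[["exponent"]])
}

#' Build a fit object from known parameters
#'
#' Wraps externally known power-law parameters (e.g. a published
#' calibration, or ground truth in simulations) in the fit classes used by
#' [sensitivity()], [apply_calibration()] and the uncertainty
#' decomposition, without performing a fit.
#'
#' @param lin_coeff,pow_coeff,exponent Power-law parameters.
#' @param sd_lin,sd_pow,sd_n Parameter SDs (default 0).
#' @param cov_lin_pow Covariance of the linear and power coefficients.
#' @param range Applicable range of the predictor (netOD for a calibration
#'   curve, Gy for a dose-response curve).
#' @return A `calibration_fit` / `dose_response_fit` object.
#' @export
as_calibration_fit <- function(lin_coeff, pow_coeff, exponent,
                               sd_lin = 0, sd_pow = 0, sd_n = 0,
                               cov_lin_pow = 0, range = c(0, 1)) {
  nm <- c("lin_coeff", "pow_coeff", "exponent")
  vc <- diag(c(sd_lin, sd_pow, sd_n)^2)
  vc[1, 2] <- vc[2, 1] <- cov_lin_pow
  dimnames(vc) <- list(nm, nm)
  structure(list(coefficients = setNames(c(lin_coeff, pow_coeff, exponent), nm),
                 param_sds = setNames(c(sd_lin, sd_pow, sd_n), nm),
                 covariance = vc, adj_r2 = NA_real_, ssr = NA_real_,
                 n_points = NA_integer_, exponent_at_bound = FALSE,
                 range = range),
            class = c("calibration_fit", "power_fit"))
}

#' @rdname as_calibration_fit
#' @export
as_dose_response_fit <- function(lin_coeff, pow_coeff, exponent,
                                 sd_lin = 0, sd_pow = 0, sd_n = 0,
                                 cov_lin_pow = 0, range = c(0, 1)) {
  out <- as_calibration_fit(lin_coeff, pow_coeff, exponent, sd_lin, sd_pow,
                            sd_n, cov_lin_pow, range)
  class(out) <- c("dose_response_fit", "power_fit")
  out
}
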