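doses6 <- c(0.05, 0.1, 0.25, 0.5, 0.7, 1.0)

test_that("exact power-law data are recovered to machine-level precision", {
  y <- power_points(doses6, 0.3, 0.1, 1.8)
  fit <- fit_dose_response(doses6, y)
  expect_equal(unname(coef(fit)), c(0.3, 0.1, 1.8), tolerance = 1e-6)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-9)
  # point order must not matter
  perm <- c(4, 1, 6, 2, 5, 3)
  fit2 <- fit_dose_response(doses6[perm], y[perm])
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-10)
})

test_that("a linear truth is fitted as an effectively linear curve", {
  # with b = 0 the model family is non-identifiable (any n with b ~ 0, or
  # n = 1 with an a/b split, gives the same curve), so assert the fitted
  # curve rather than the raw coefficients
  y <- 0.25 * doses6
  fit <- fit_dose_response(doses6, y)
  expect_equal(predict(fit, doses6), y, tolerance = 1e-8)
  grid <- seq(0.05, 1, by = 0.05)
  expect_equal(sensitivity(fit, grid), rep(0.25, length(grid)),
               tolerance = 1e-6)
})

test_that("weighted fitting accepts uncertainties and degrades gracefully", {
  y <- power_points(doses6, 0.3, 0.1, 1.8)
  fitw <- fit_dose_response(doses6, y, sigma_netod = rep(0.005, 6),
                            weighted = TRUE)
  expect_equal(unname(coef(fitw)), c(0.3, 0.1, 1.8), tolerance = 1e-6)
  expect_error(fit_dose_response(doses6, y, weighted = TRUE), "sigma")
  expect_error(fit_dose_response(doses6[1:3], y[1:3]), "length")
})

test_that("sensitivity equals the analytic derivative of the fitted curve", {
  # closed form: a = 0.5, b = 0.2, n = 2 at 1 Gy gives 0.5 + 2*0.2 = 0.9
  fit <- as_dose_response_fit(0.5, 0.2, 2)
  expect_equal(sensitivity(fit, 1), 0.9)
  # linear response: S is the constant slope
  expect_equal(sensitivity(as_dose_response_fit(0.4, 0, 3), c(0.1, 1)),
               c(0.4, 0.4))
  # central finite-difference oracle on a genuinely fitted curve
  y <- power_points(doses6, 0.3, 0.1, 1.8)
  ft <- fit_dose_response(doses6, y)
  grid <- seq(0.05, 1, by = 0.05)
  h <- 1e-6
  fd <- (predict(ft, grid + h) - predict(ft, grid - h)) / (2 * h)
  expect_equal(sensitivity(ft, grid), fd, tolerance = 1e-6)
  # saturating response (n < 1): sensitivity strictly decreases with dose
  sat <- as_dose_response_fit(0.12, 0.18, 0.65)
  expect_true(all(diff(sensitivity(sat, grid)) < 0))
  expect_warning(s0 <- sensitivity(sat, 0), "diverges")
  expect_identical(s0, Inf)
  expect_error(sensitivity(sat, -1), ">= 0")
})

test_that("calibration fit recovers exact inverse-curve parameters", {
  nod <- c(0.02, 0.05, 0.1, 0.2, 0.3, 0.4)
  D <- power_points(nod, 0.9, 0.5, 2)
  fit <- fit_calibration(nod, D)
  expect_equal(unname(coef(fit)), c(0.9, 0.5, 2), tolerance = 1e-6)
  expect_equal(apply_calibration(fit, 0), 0)
  expect_equal(apply_calibration(fit, 0.2), 0.9 * 0.2 + 0.5 * 0.04,
               tolerance = 1e-6)
  # monotone for positive parameters
  expect_true(all(diff(apply_calibration(fit, seq(0, 0.4, 0.01))) > 0))
  expect_warning(apply_calibration(fit, 0.9), "extrapolating")
  expect_error(apply_calibration(fit, -0.1), ">= 0")
})

test_that("forward and inverse fits are mutually consistent", {
  # simulate the calibration protocol: forward curve generates netOD,
  # inverse curve converts it back; disagreement is bounded by the inverse
  # fit's own residuals
  truth <- c(a = 0.12, b = 0.18, n = 0.65)
  D <- c(0, 0.1, 0.25, 0.5, 0.7, 1.0)
  nod <- power_points(D, truth["a"], truth["b"], truth["n"])
  inv <- fit_calibration(nod, D)
  D_hat <- apply_calibration(inv, nod)
  max_resid <- max(abs(D_hat - D))
  grid_nod <- seq(min(nod[nod > 0]), max(nod), length.out = 50)
  grid_D <- vapply(grid_nod, function(y)
    uniroot(function(d) power_points(d, truth["a"], truth["b"], truth["n"]) - y,
            c(0, 2))$root, 0)
  expect_lt(max(abs(apply_calibration(inv, grid_nod) - grid_D)),
            2 * max_resid + 1e-12)
})
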