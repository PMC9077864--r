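test_that("air gap follows the sphere-on-flat closed form and is monotone", {
  geom <- lens_geometry(base_curve_radius = 8, contact_radius = 6)
  expect_identical(air_gap_profile(0, geom), 0)
  # r^2 / (2R) = 1/16 mm = 62.5 um at r = 1 mm, R = 8 mm
  expect_equal(air_gap_profile(1, geom), 62.5)
  r <- seq(0, 6, length.out = 1000)
  expect_true(all(diff(air_gap_profile(r, geom)) >= 0))
  expect_error(air_gap_profile(-0.1, geom), "contact_radius")
  expect_error(air_gap_profile(6.5, geom), "contact_radius")
  expect_error(lens_geometry(base_curve_radius = 5, contact_radius = 6),
               "exceed")
})

test_that("fringe visibility vanishes at index match and ranks materials", {
  # perfect match at both interfaces kills both reflections
  expect_identical(fringe_visibility(1.5, n_glass = 1.5, n_lens = 1.5), 0)
  # independent Fresnel oracle for the air vs optical-grease comparison
  fresnel <- function(n_i, n_gap) ((n_i - n_gap) / (n_i + n_gap))^2
  oracle <- function(n_gap) {
    r1 <- fresnel(1.52, n_gap); r2 <- fresnel(1.50, n_gap)
    2 * sqrt(r1 * r2) / (r1 + r2 + 1)
  }
  expect_equal(fringe_visibility(1.0), oracle(1.0))
  expect_gt(fringe_visibility(1.0), fringe_visibility(1.46))
  # all four built-in materials rank air > DS ~ SC > OG
  v <- vapply(clod_materials("reflective"), fringe_visibility, 0)
  expect_true(v[["air"]] > v[["DS"]] && v[["SC"]] > v[["OG"]])
  # symmetric under swapping the two bounding media
  expect_equal(fringe_visibility(1.2, n_glass = 1.52, n_lens = 1.44),
               fringe_visibility(1.2, n_glass = 1.44, n_lens = 1.52))
  # jointly shrinking both mismatches strictly lowers V
  ng <- seq(1.0, 1.49, length.out = 30)
  expect_true(all(diff(vapply(ng, fringe_visibility, 0)) < 0))
  expect_true(all(vapply(ng, fringe_visibility, 0) >= 0) &&
                all(vapply(ng, fringe_visibility, 0) <= 1))
  expect_error(fringe_visibility(0.9), ">= 1")
})

test_that("ring modulation implements the reflected-light fringe law", {
  # dark contact spot: cos(0) = 1 so the factor is 1 - V
  expect_equal(ring_modulation(0, 1, 630, 0.3), 0.7)
  # no visibility, no modulation
  expect_equal(ring_modulation(seq(0, 50, by = 0.5), 1, 630, 0), rep(1, 101))
  # dark fringes at t_m = m lambda / (2 n): modulation minimal there
  lambda <- 632.8
  t1 <- 1 * lambda / (2 * 1.0) / 1000 # um
  expect_equal(ring_modulation(t1, 1.0, lambda, 0.4), 1 - 0.4)
  # the m = 1 dark-ring radius for lambda = 632.8 nm, R = 8 mm, air gap
  geom <- lens_geometry(8, 6)
  r1 <- dark_ring_radii(1, geom, n_gap = 1, wavelength = 632.8)
  expect_equal(r1 * 1000, 71.15, tolerance = 1e-3) # sqrt(lambda R) ~ 71.2 um
  expect_equal(air_gap_profile(r1, geom), t1) # consistency of the two forms
  expect_error(ring_modulation(1, 1, 630, 1.2), "visibility")
  expect_error(ring_modulation(-1, 1, 630, 0.5), ">= 0")
})

test_that("dose-to-pixel forward model inverts exactly through netOD", {
  truth <- ground_truth_response(0.3, 0.1, 1.8, mode_gain = 2.5)
  # zero dose leaves the unexposed level untouched
  expect_equal(dose_to_clean_pixel(0, truth, "transmission", 40000, 1000),
               40000)
  # netOD* = 0.3 + 0.1 = 0.4 at 1 Gy: M = 1000 + 39000 * 10^-0.4
  expect_equal(dose_to_clean_pixel(1, truth, "transmission", 40000, 1000),
               1000 + 39000 * 10^-0.4)
  # round trip recovers g (a D + b D^n) to floating point
  for (D in c(0.05, 0.25, 0.8)) {
    m_t <- dose_to_clean_pixel(D, truth, "transmission", 40000, 1000)
    m_r <- dose_to_clean_pixel(D, truth, "reflective", 40000, 1000)
    nod_t <- compute_netod(40000, m_t, 1000)
    nod_r <- compute_netod(40000, m_r, 1000)
    expect_equal(nod_t, 0.3 * D + 0.1 * D^1.8)
    expect_equal(nod_r / nod_t, 2.5)
  }
  expect_error(dose_to_clean_pixel(-1, truth, "transmission", 40000, 1000),
               ">= 0")
})

test_that("rendering is deterministic and degenerates to the clean model", {
  mat <- clod_materials("reflective")$OG
  cfg <- scan_config("reflective", seed = 11)
  s1 <- render_scan(c(0, 0.5), material = mat, config = cfg)
  s2 <- render_scan(c(0, 0.5), material = mat, config = cfg)
  expect_identical(s1$image$pixels, s2$image$pixels)
  expect_identical(s1$manifest, s2$manifest)
  s3 <- render_scan(c(0, 0.5), material = mat,
                    config = scan_config("reflective", seed = 12))
  expect_false(identical(s1$image$pixels, s3$image$pixels))

  # noiseless, artifact-free: every in-footprint red pixel is the rounded
  # clean value
  clean <- render_clean(0.5)
  man <- clean$manifest
  red <- extract_channel(clean$image, "red")
  win <- roi_window(roi_spec(man$x_mm, man$y_mm, 2), red$dpi)
  vals <- red$pixels[win$row0 + seq_len(win$height),
                     win$col0 + seq_len(win$width)]
  want <- round(dose_to_clean_pixel(0.5, ground_truth_response(),
                                    "reflective", 40000, 2000))
  expect_true(all(vals == want))
  expect_error(render_scan(numeric(0), material = mat, config = cfg),
               "empty")
})

test_that("ROI spread grows with fringe visibility at fixed noise", {
  # same scene, zero pixel noise: the only spread inside the ROI is the
  # point-sampled fringe pattern, which scales with visibility
  sds <- vapply(c(1.0, 1.40, 1.46), function(ng) {
    sc <- render_scan(0.5, material = material_spec("m", ng, 0),
                      config = scan_config("reflective", seed = 4),
                      jitter_gap = FALSE)
    analyze_scan(sc)$sd
  }, 0)
  expect_true(sds[1] > sds[2] && sds[2] > sds[3])
})

test_that("noiseless artifact-free pipeline recovers true netOD to 1e-3", {
  sc <- render_clean(c(0, 0.1, 0.5, 1), seed = 5)
  st <- analyze_scan(sc)
  bg <- attr(st, "background")
  nod <- compute_netod(st$mean[1], st$mean[-1], bg$mean)
  expect_lt(max(abs(nod - sc$manifest$true_netod[-1])), 1e-3)
})
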