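test_that("TIFF write/read round trip preserves counts and metadata", {
  sc <- render_scan(c(0, 0.25), material = clod_materials("transmission")$DS,
                    config = scan_config("transmission", seed = 2))
  path <- tempfile(fileext = ".tiff")
  write_scan(sc, path)
  back <- read_scan(path)
  expect_identical(unname(back$pixels), unname(sc$image$pixels))
  expect_equal(back$dpi, 300)          # restored from the sidecar
  expect_equal(back$bit_depth, 16L)
  man <- attr(back, "manifest")
  expect_equal(man$dose_gy, sc$manifest$dose_gy)

  # dpi override takes precedence over a missing sidecar
  file.remove(paste0(path, ".json"))
  expect_error(read_scan(path), "dpi")
  expect_equal(read_scan(path, dpi = 150)$dpi, 150)
  expect_error(read_scan(tempfile()), "no such file")
})

test_that("8-bit images survive the round trip within their range", {
  img <- scan_image(matrix(as.numeric(0:255), 16, 16), dpi = 300,
                    bit_depth = 8)
  path <- tempfile(fileext = ".tiff")
  write_scan(img, path)
  back <- read_scan(path)
  expect_equal(back$bit_depth, 8L)
  expect_true(max(back$pixels) <= 255)
  expect_identical(unname(back$pixels), unname(img$pixels))
})

test_that("channel extraction selects planes and handles grayscale", {
  arr <- array(c(1, 2, 3), dim = c(2, 2, 3))
  arr[, , 1] <- 10; arr[, , 2] <- 20; arr[, , 3] <- 30
  img <- scan_image(arr, dpi = 300)
  expect_true(all(extract_channel(img, "red")$pixels == 10))
  expect_true(all(extract_channel(img, "green")$pixels == 20))
  expect_error(extract_channel(img, "alpha"), "unknown channel")
  gray <- scan_image(matrix(5, 3, 3), dpi = 300)
  expect_identical(extract_channel(gray, "red"), gray)

  # the generator puts the dose signal only in the red plane
  sc <- render_clean(0.5)
  red <- extract_channel(sc$image, "red")$pixels
  grn <- extract_channel(sc$image, "green")$pixels
  expect_true(any(red != grn))
})

test_that("ROI window conversion reproduces the mm-to-pixel protocol", {
  # 3.5 mm at 300 dpi: 3.5 * 300 / 25.4 = 41.34 px, rounds to 41
  w <- roi_window(roi_spec(20, 20, 3.5), dpi = 300)
  expect_equal(w$height, 41L)
  expect_equal(w$width, 41L)
  # an exact 40-pixel side converts without rounding
  w40 <- roi_window(roi_spec(20, 20, 25.4 / 300 * 40), dpi = 300)
  expect_equal(w40$width, 40L)
  # the strict-emulation override forces 40 px regardless of the side
  expect_equal(roi_window(roi_spec(20, 20, 3.5), dpi = 300, side_px = 40)$width,
               40L)
  # coarser scan: 3.5 mm at 150 dpi = 20.67 px, rounds to 21
  expect_equal(roi_window(roi_spec(20, 20, 3.5), dpi = 150)$width, 21L)
  # centring: the window is centred on the pixel containing the coordinate
  w1 <- roi_window(roi_spec(10, 10, 3.5), dpi = 300)
  ctr_px <- floor(10 / (25.4 / 300))
  expect_equal(w1$col0 + (w1$width - 1L) %/% 2L, ctr_px)
  # physical window side within one pixel of the request
  expect_lt(abs(w$width * 25.4 / 300 - 3.5), 25.4 / 300)
  expect_error(roi_window(roi_spec(1, 1, 3.5), dpi = 300, dim = c(100, 100)),
               "clipped")
})

test_that("ROI statistics match hand-computed and pooled oracles", {
  img <- scan_image(matrix(rep(40000, 16), 4, 4), dpi = 300)
  s <- roi_stats(img, list(row0 = 0L, col0 = 0L, height = 4L, width = 4L))
  expect_equal(s$mean, 40000)
  expect_equal(s$sd, 0)
  expect_equal(s$cv, 0)
  expect_equal(s$n_pixels, 16L)

  m <- scan_image(matrix(c(1, 2, 3, 4), 2, 2), dpi = 300)
  w <- list(row0 = 0L, col0 = 0L, height = 2L, width = 2L)
  s2 <- roi_stats(m, w)
  expect_equal(s2$mean, 2.5)
  expect_equal(s2$sd, sd(1:4))            # N-1 denominator: 1.29099
  expect_equal(s2$cv, sd(1:4) / 2.5)      # 0.51640
  sp <- roi_stats(m, w, sd_type = "population")
  expect_equal(sp$sd, sd(1:4) * sqrt(3 / 4))

  # pooled-moments oracle: stats of a union reproducible from two windows
  set.seed(8)
  big <- scan_image(matrix(round(runif(200, 0, 1000)), 10, 20), dpi = 300)
  wl <- list(row0 = 0L, col0 = 0L, height = 10L, width = 10L)
  wr <- list(row0 = 0L, col0 = 10L, height = 10L, width = 10L)
  wu <- list(row0 = 0L, col0 = 0L, height = 10L, width = 20L)
  a <- roi_stats(big, wl); b <- roi_stats(big, wr); u <- roi_stats(big, wu)
  n <- a$n_pixels + b$n_pixels
  pooled_mean <- (a$n_pixels * a$mean + b$n_pixels * b$mean) / n
  pooled_ss <- (a$n_pixels - 1) * a$sd^2 + a$n_pixels * a$mean^2 +
    (b$n_pixels - 1) * b$sd^2 + b$n_pixels * b$mean^2
  pooled_sd <- sqrt((pooled_ss - n * pooled_mean^2) / (n - 1))
  expect_equal(u$mean, pooled_mean)
  expect_equal(u$sd, pooled_sd)

  expect_warning(roi_stats(scan_image(matrix(0, 2, 2), 300),
                           list(row0 = 0L, col0 = 0L, height = 2L,
                                width = 2L)), "CV undefined")
})
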