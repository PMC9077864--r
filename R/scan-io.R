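# Scan image container, TIFF round trip, and physical-units ROI statistics.

#' Scan image container
#'
#' Integer scanner counts with their resolution, bit depth and channel
#' labels. Pixels are squares of `25.4 / dpi` mm; image coordinates are
#' row-major with the origin at the top-left corner and 0-based pixel
#' indices, so pixel `(i, j)` covers the physical square
#' `[j p, (j+1) p) x [i p, (i+1) p)` mm with `p` the pixel pitch.
#'
#' @param pixels Matrix (single channel) or `h x w x c` array of counts.
#' @param dpi Resolution in dots per inch.
#' @param bit_depth Bits per channel (8 or 16).
#' @param channels Ordered channel labels; defaults to RGB for 3-channel
#'   input and `"gray"` for single-channel input.
#' @return An object of class `scan_image`.
#' @export
scan_image <- function(pixels, dpi, bit_depth = 16, channels = NULL) {
  stopifnot(is.numeric(pixels), is.numeric(dpi), length(dpi) == 1L)
  if (dpi <= 0) stop("dpi must be > 0")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  nc <- if (length(dim(pixels)) == 3L) dim(pixels)[3] else 1L
  if (is.null(channels))
    channels <- if (nc == 3L) c("red", "green", "blue") else "gray"
  if (length(channels) != nc)
    stop("channel labels do not match the channel dimension")
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1))
    stop("counts outside [0, 2^bit_depth - 1]")
  structure(list(pixels = pixels, dpi = dpi,
                 bit_depth = as.integer(bit_depth), channels = channels),
            class = "scan_image")
}

#' @export
print.scan_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("scan_image: %d x %d px, %s, %d-bit, %g dpi\n",
              d[1], d[2], paste(x$channels, collapse = "/"),
              x$bit_depth, x$dpi))
  invisible(x)
}

#' Write a scan image as a 16-bit TIFF with a JSON metadata sidecar
#'
#' The raster is written as an uncompressed baseline TIFF (unsigned
#' integers, RGB or grayscale). Scan metadata -- resolution, bit depth,
#' channel labels and, for generated scans, the ground-truth manifest -- is
#' written to a JSON sidecar at `<path>.json`, which [read_scan()] uses to
#' restore the resolution.
#'
#' @param x A [scan_image()] or a `clod_scan` from [render_scan()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(x, path) {
  manifest <- NULL
  if (inherits(x, "clod_scan")) {
    manifest <- x$manifest
    x <- x$image
  }
  stopifnot(inherits(x, "scan_image"))
  tiff::writeTIFF(x$pixels / (2^x$bit_depth - 1), path,
                  bits.per.sample = x$bit_depth, compression = "none")
  meta <- list(dpi = x$dpi, bit_depth = x$bit_depth, channels = x$channels)
  if (!is.null(manifest)) {
    meta$manifest <- manifest
    for (a in c("background_mm", "seed", "mode", "material", "dpi",
                "M_unexp", "M_bkg", "visibility"))
      meta[[a]] <- attr(manifest, a)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a scan image from TIFF
#'
#' Counts are returned unchanged (no rescaling). The resolution is taken
#' from the JSON sidecar written by [write_scan()] when present, otherwise
#' from the `dpi` argument.
#'
#' @param path TIFF path.
#' @param dpi Explicit resolution override (required when no sidecar
#'   exists).
#' @return A [scan_image()]. For generated scans the sidecar manifest is
#'   attached as attribute `"manifest"`.
#' @export
read_scan <- function(path, dpi = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- tiff::readTIFF(path, info = TRUE)
  bits <- attr(raw, "bits.per.sample")
  if (is.null(bits)) bits <- 16L
  if (!bits %in% c(8, 16)) stop("unsupported sample format: ", bits, " bits")
  nc <- if (length(dim(raw)) == 3L) dim(raw)[3] else 1L
  if (!nc %in% c(1L, 3L)) stop("expected 1 or 3 channels, got ", nc)
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar)
  if (is.null(dpi)) dpi <- meta$dpi
  if (is.null(dpi))
    stop("no resolution metadata found; pass dpi explicitly")
  counts <- round(unclass(raw) * (2^bits - 1))
  attributes(counts) <- list(dim = dim(raw))
  img <- scan_image(counts, dpi = as.numeric(dpi), bit_depth = bits)
  if (!is.null(meta$manifest))
    attr(img, "manifest") <- do.call(rbind.data.frame, meta$manifest)
  img
}

#' Extract a single analysis channel
#'
#' CLOD read-out analyses the red channel (the absorption band of the
#' irradiated LiPCDA polymer); other channels are kept for diagnostics.
#' For a single-channel image, requesting `"red"` (or the stored label)
#' returns the image unchanged.
#'
#' @param img A [scan_image()].
#' @param channel Channel label (default `"red"`).
#' @return Single-channel [scan_image()].
#' @export
extract_channel <- function(img, channel = "red") {
  stopifnot(inherits(img, "scan_image"))
  if (length(img$channels) == 1L) {
    if (!channel %in% c(img$channels, "red")) stop("unknown channel: ", channel)
    return(img)
  }
  i <- match(channel, img$channels)
  if (is.na(i)) stop("unknown channel: ", channel)
  scan_image(img$pixels[, , i], dpi = img$dpi, bit_depth = img$bit_depth,
             channels = channel)
}

#' Square region-of-interest specification in physical units
#'
#' @param x_mm,y_mm ROI centre on the scan bed, mm from the image origin.
#' @param side_mm ROI side length, mm (default 3.5, the standard CLOD
#'   read-out window, about 41 x 41 px at 300 dpi).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x_mm, y_mm, side_mm = 3.5) {
  stopifnot(is.numeric(x_mm), is.numeric(y_mm), is.numeric(side_mm))
  if (side_mm <= 0) stop("side_mm must be > 0")
  structure(list(x_mm = x_mm, y_mm = y_mm, side_mm = side_mm),
            class = "roi_spec")
}

#' Convert a physical ROI to an integer pixel window
#'
#' The side in pixels is `round(side_mm * dpi / 25.4)` (3.5 mm at 300 dpi
#' gives 41 px; pass `side_px = 40` to force the coarser square sometimes
#' quoted for this window). The window is centred on the pixel containing
#' the centre coordinate and uses 0-based, half-open extents.
#'
#' @param spec A [roi_spec()].
#' @param dpi Image resolution.
#' @param dim Optional image dimensions `c(h, w)`; when supplied, a window
#'   clipped by the image edge is an error.
#' @param side_px Optional explicit side in pixels, overriding the rounded
#'   conversion.
#' @return List with 0-based `row0`, `col0` and `height`, `width`.
#' @export
roi_window <- function(spec, dpi, dim = NULL, side_px = NULL) {
  stopifnot(inherits(spec, "roi_spec"), dpi > 0)
  p <- 25.4 / dpi
  if (is.null(side_px)) side_px <- round(spec$side_mm / p)
  side_px <- as.integer(side_px)
  if (side_px < 1L) stop("ROI smaller than one pixel")
  c0 <- floor(spec$x_mm / p)   # pixel containing the centre (0-based)
  r0 <- floor(spec$y_mm / p)
  half <- (side_px - 1L) %/% 2L
  win <- list(row0 = as.integer(r0 - half), col0 = as.integer(c0 - half),
              height = side_px, width = side_px)
  if (!is.null(dim)) {
    if (win$row0 < 0L || win$col0 < 0L ||
        win$row0 + win$height > dim[1] || win$col0 + win$width > dim[2])
      stop("ROI window clipped by the image edge")
  }
  win
}

#' ROI pixel statistics
#'
#' Mean, standard deviation and coefficient of variation of the counts in a
#' pixel window. The sample SD (N-1 denominator) is the default; the
#' population form is available for strict emulation of readers that use
#' it.
#'
#' @param img Single-channel [scan_image()] (or matrix of counts).
#' @param window Pixel window from [roi_window()].
#' @param sd_type `"sample"` (N-1, default) or `"population"` (N).
#' @return An object of class `roi_stats`: `mean`, `sd`, `n_pixels`, `cv`
#'   (`cv = sd / mean`; `NA` with a warning when `mean <= 0`).
#' @export
roi_stats <- function(img, window, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  px <- if (inherits(img, "scan_image")) img$pixels else img
  if (length(dim(px)) == 3L)
    stop("roi_stats needs a single-channel image; see extract_channel()")
  rows <- window$row0 + seq_len(window$height)
  cols <- window$col0 + seq_len(window$width)
  if (window$row0 < 0L || window$col0 < 0L ||
      max(rows) > nrow(px) || max(cols) > ncol(px))
    stop("window outside the image")
  v <- as.numeric(px[rows, cols])
  n <- length(v)
  m <- mean(v)
  s <- if (n > 1L) sd(v) else 0
  if (sd_type == "population") s <- s * sqrt((n - 1) / n)
  cv <- if (m > 0) s / m else {
    warning("ROI mean is not positive; CV undefined")
    NA_real_
  }
  structure(list(mean = m, sd = s, n_pixels = n, cv = cv),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("ROI: mean %.1f, sd %.1f, n %d, cv %.4f\n",
              x$mean, x$sd, x$n_pixels, x$cv))
  invisible(x)
}
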