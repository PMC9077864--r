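# Synthetic CLOD scan generator: sphere-on-flat gap geometry, two-interface
# Fresnel fringe visibility, reflected-light Newton's-ring modulation, and a
# forward model from delivered dose to 16-bit scanner counts.

#' Lens geometry of a rendered CLOD footprint
#'
#' Describes the spherical cap of the dosimeter surface that faces the
#' scanner glass. The air gap under the lens follows the classic
#' sphere-on-flat approximation `t(r) = r^2 / (2 R)` with `R` the base-curve
#' radius.
#'
#' @param base_curve_radius Radius of curvature of the surface facing the
#'   glass, in mm. Default 8 mm (a plausible contact-lens base curve; the
#'   value is a simulator parameter, not a measured one).
#' @param contact_radius Radial extent of the rendered footprint, in mm.
#' @param center Footprint centre on the scan bed, `c(x_mm, y_mm)`.
#' @return An object of class `lens_geometry`.
#' @examples
#' geom <- lens_geometry()
#' air_gap_profile(1, geom) # 62.5 um at r = 1 mm for R = 8 mm
#' @export
lens_geometry <- function(base_curve_radius = 8, contact_radius = 6,
                          center = c(0, 0)) {
  stopifnot(is.numeric(base_curve_radius), length(base_curve_radius) == 1L,
            is.numeric(contact_radius), length(contact_radius) == 1L,
            is.numeric(center), length(center) == 2L)
  if (base_curve_radius <= 0) stop("base_curve_radius must be > 0")
  if (contact_radius <= 0) stop("contact_radius must be > 0")
  if (contact_radius > base_curve_radius)
    stop("contact_radius must not exceed base_curve_radius")
  structure(list(base_curve_radius = base_curve_radius,
                 contact_radius = contact_radius,
                 center = as.numeric(center)),
            class = "lens_geometry")
}

#' Compensating-material specification
#'
#' A compensating material is spread between the dosimeter and the scanner
#' glass to fill the air gap. Its refractive index controls how strongly the
#' two gap interfaces reflect (and hence the Newton's-ring fringe
#' visibility); its pixel-noise SD sets the additive read-out noise of the
#' rendered scans.
#'
#' @param name Material label. The study materials are `"air"` (no
#'   compensation), `"DS"` (Dragon Skin 10 silicone), `"SC"` (SORTA-Clear 40
#'   silicone) and `"OG"` (optical grease); any user-defined label is
#'   accepted.
#' @param refractive_index Refractive index of the gap medium (>= 1).
#' @param pixel_noise_sd Additive Gaussian pixel-noise SD in counts on the
#'   16-bit scale.
#' @return An object of class `material_spec`.
#' @seealso [clod_materials()] for the built-in material set.
#' @export
material_spec <- function(name, refractive_index, pixel_noise_sd) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(refractive_index), length(refractive_index) == 1L,
            is.numeric(pixel_noise_sd), length(pixel_noise_sd) == 1L)
  if (refractive_index < 1) stop("refractive_index must be >= 1")
  if (pixel_noise_sd < 0) stop("pixel_noise_sd must be >= 0")
  structure(list(name = name, refractive_index = refractive_index,
                 pixel_noise_sd = pixel_noise_sd),
            class = "material_spec")
}

# Per-material pixel-noise SDs (counts, 16-bit) by scan mode, anchored to the
# printed 25 cGy ROI pixel-value SDs of the reference study. Refractive
# indices are plausible handbook values for the material class, not measured.
.material_table <- list(
  air = list(index = 1.00, transmission = 766.3, reflective = 577.1),
  DS  = list(index = 1.40, transmission = 696.5, reflective = 495.9),
  SC  = list(index = 1.41, transmission = 695.0, reflective = 492.9),
  OG  = list(index = 1.46, transmission = 611.9, reflective = 373.3)
)

#' Built-in compensating materials
#'
#' Returns the four study materials (air, DS, SC, OG) with the pixel-noise SD
#' appropriate to the requested scan mode.
#'
#' @param mode `"transmission"` or `"reflective"`.
#' @return Named list of [material_spec()] objects.
#' @examples
#' clod_materials("reflective")$OG
#' @export
clod_materials <- function(mode = c("transmission", "reflective")) {
  mode <- match.arg(mode)
  out <- lapply(names(.material_table), function(nm) {
    m <- .material_table[[nm]]
    material_spec(nm, m$index, m[[mode]])
  })
  names(out) <- names(.material_table)
  out
}

#' Scanner acquisition configuration
#'
#' @param mode Acquisition geometry: `"transmission"` (light through the
#'   object) or `"reflective"` (illuminated and read from the same side; the
#'   higher-sensitivity mode at low dose).
#' @param dpi Spatial resolution in dots per inch (default 300).
#' @param bit_depth Bits per channel, 8 or 16 (default 16).
#' @param wavelength Effective illumination wavelength of the analysis (red)
#'   channel, in nm.
#' @param seed Integer seed; renders are bit-identical for equal seeds.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(mode = c("transmission", "reflective"), dpi = 300,
                        bit_depth = 16, wavelength = 630, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(dpi), length(dpi) == 1L, is.numeric(bit_depth),
            is.numeric(wavelength), length(wavelength) == 1L,
            is.numeric(seed), length(seed) == 1L)
  if (dpi <= 0) stop("dpi must be > 0")
  if (!bit_depth %in% c(8, 16)) stop("bit_depth must be 8 or 16")
  if (wavelength <= 0) stop("wavelength must be > 0")
  structure(list(mode = mode, dpi = dpi, bit_depth = as.integer(bit_depth),
                 wavelength = wavelength, seed = as.integer(seed)),
            class = "scan_config")
}

#' Ground-truth dose-response of the generator
#'
#' The generator darkens the red channel following the power-law response
#' `netOD(D) = g (a D + b D^n)`, with `g` the mode gain (1 in transmission,
#' `mode_gain` in reflective mode). The default parameters give a mildly
#' saturating response reaching netOD 0.30 at 1 Gy in transmission, typical
#' of a LiPCDA-based dosimeter read in the red channel over 0-1 Gy; the
#' default mode gain of 2.5 reproduces the reflective/transmission
#' sensitivity ratio reported for CLOD read-out.
#'
#' @param lin_coeff Linear coefficient `a`, netOD/Gy.
#' @param pow_coeff Power-term coefficient `b`, netOD/Gy^n.
#' @param exponent Exponent `n` (dimensionless, > 0). Values below 1 give the
#'   saturating (sensitivity decreasing with dose) shape seen in film-type
#'   dosimeters.
#' @param mode_gain Multiplier applied to netOD in reflective mode.
#' @return An object of class `ground_truth_response`.
#' @export
ground_truth_response <- function(lin_coeff = 0.12, pow_coeff = 0.18,
                                  exponent = 0.65, mode_gain = 2.5) {
  stopifnot(is.numeric(lin_coeff), is.numeric(pow_coeff),
            is.numeric(exponent), is.numeric(mode_gain))
  if (lin_coeff < 0 || pow_coeff < 0) stop("coefficients must be >= 0")
  if (exponent <= 0) stop("exponent must be > 0")
  if (mode_gain <= 0) stop("mode_gain must be > 0")
  structure(list(lin_coeff = lin_coeff, pow_coeff = pow_coeff,
                 exponent = exponent, mode_gain = mode_gain),
            class = "ground_truth_response")
}

# true netOD for a delivered dose under a given scan mode
true_netod <- function(dose_gy, truth, mode) {
  g <- if (identical(mode, "reflective")) truth$mode_gain else 1
  g * (truth$lin_coeff * dose_gy + truth$pow_coeff * dose_gy^truth$exponent)
}

#' Air-gap thickness under a curved dosimeter
#'
#' Sphere-on-flat small-angle approximation: the gap between the glass and a
#' spherical cap of base-curve radius `R` at radial distance `r` from the
#' contact point is `t(r) = r^2 / (2 R)`.
#'
#' @param r Radial distance from the contact point, mm (vectorised).
#' @param geometry A [lens_geometry()].
#' @return Gap thickness in micrometres; `t(0) = 0`, monotone non-decreasing.
#' @export
air_gap_profile <- function(r, geometry) {
  stopifnot(inherits(geometry, "lens_geometry"), is.numeric(r))
  if (any(r < 0 | r > geometry$contact_radius))
    stop("r must lie in [0, contact_radius]")
  1000 * r^2 / (2 * geometry$base_curve_radius)
}

#' Newton's-ring fringe visibility of the gap interfaces
#'
#' Normal-incidence Fresnel intensity reflectances of the glass/gap and
#' gap/lens interfaces, `R_i = ((n_i - n_gap) / (n_i + n_gap))^2`, combined
#' into a two-beam fringe visibility diluted by the unit diffuse background
#' of the dosimeter body itself:
#' `V = 2 sqrt(R1 R2) / (R1 + R2 + 1)`.
#'
#' The unit term in the denominator represents the dominant non-interfering
#' light returned by the scan target, which is why even the uncompensated
#' air gap produces fringes of only a few percent contrast rather than the
#' textbook two-beam value. `V = 0` exactly when the gap index matches both
#' neighbours, and `V` shrinks monotonically as the mismatch at either
#' interface shrinks -- the mechanism by which index-matching compensating
#' materials suppress the ring artifact.
#'
#' @param material A [material_spec()] or a bare numeric gap refractive
#'   index.
#' @param n_glass Refractive index of the scanner glass (default 1.52).
#' @param n_lens Refractive index of the dosimeter surface (default 1.50).
#' @return Visibility in `[0, 1]`.
#' @examples
#' fringe_visibility(1.0)  # air gap
#' fringe_visibility(1.46) # optical grease: orders of magnitude smaller
#' @export
fringe_visibility <- function(material, n_glass = 1.52, n_lens = 1.50) {
  n_gap <- if (inherits(material, "material_spec"))
    material$refractive_index else material
  stopifnot(is.numeric(n_gap), is.numeric(n_glass), is.numeric(n_lens))
  if (any(c(n_gap, n_glass, n_lens) < 1))
    stop("refractive indices must be >= 1")
  r1 <- ((n_glass - n_gap) / (n_glass + n_gap))^2
  r2 <- ((n_lens - n_gap) / (n_lens + n_gap))^2
  2 * sqrt(r1 * r2) / (r1 + r2 + 1)
}

#' Newton's-ring intensity modulation
#'
#' Reflected-light two-beam interference in a thin gap, including the
#' half-wave phase shift at the denser-medium reflection:
#' `factor = 1 - V cos(4 pi n_gap t / lambda)`. At `t = 0` the factor is
#' `1 - V` (the classic dark contact spot); dark fringes sit at gap
#' thicknesses `t_m = m lambda / (2 n_gap)`, i.e. (through
#' [air_gap_profile()]) at radii `r_m = sqrt(m lambda R / n_gap)`.
#'
#' @param t Gap thickness, micrometres (vectorised).
#' @param n_gap Gap refractive index.
#' @param wavelength Illumination wavelength, nm.
#' @param visibility Fringe visibility in `[0, 1]`.
#' @return Multiplicative intensity factor.
#' @export
ring_modulation <- function(t, n_gap, wavelength, visibility) {
  stopifnot(is.numeric(t), is.numeric(n_gap), is.numeric(wavelength),
            is.numeric(visibility), length(visibility) == 1L)
  if (any(t < 0)) stop("gap thickness must be >= 0")
  if (visibility < 0 || visibility > 1)
    stop("visibility must lie in [0, 1]")
  lambda_um <- wavelength / 1000
  1 - visibility * cos(4 * pi * n_gap * t / lambda_um)
}

#' Predicted dark-ring radii
#'
#' Radii of the first dark fringes of the reflected-light Newton's-ring
#' pattern for a sphere-on-flat gap: `r_m = sqrt(m lambda R / n_gap)`.
#'
#' @param m Fringe orders (integer vector, >= 1).
#' @param geometry A [lens_geometry()].
#' @param n_gap Gap refractive index.
#' @param wavelength Wavelength in nm.
#' @return Radii in mm.
#' @export
dark_ring_radii <- function(m, geometry, n_gap = 1, wavelength = 630) {
  stopifnot(all(m >= 1))
  lambda_mm <- wavelength * 1e-6
  sqrt(m * lambda_mm * geometry$base_curve_radius / n_gap)
}

#' Forward model: delivered dose to clean (noise- and artifact-free) counts
#'
#' Inverts the netOD definition for the generator: with true response
#' `netOD* = g (a D + b D^n)`, the exposed pixel value is
#' `M_exp = M_bkg + (M_unexp - M_bkg) 10^(-netOD*)`. Feeding the result back
#' through [compute_netod()] recovers `netOD*` to floating point.
#'
#' @param dose_gy Delivered dose in Gy (vectorised, >= 0).
#' @param truth A [ground_truth_response()].
#' @param mode `"transmission"` or `"reflective"`.
#' @param M_unexp Unexposed pixel value, counts.
#' @param M_bkg Background (no object) pixel value, counts.
#' @return Exposed pixel value in counts (not yet rounded).
#' @export
dose_to_clean_pixel <- function(dose_gy, truth, mode, M_unexp, M_bkg) {
  stopifnot(inherits(truth, "ground_truth_response"))
  mode <- match.arg(mode, c("transmission", "reflective"))
  if (any(dose_gy < 0)) stop("dose must be >= 0")
  if (M_unexp <= M_bkg || M_bkg < 0)
    stop("need M_unexp > M_bkg >= 0")
  M_bkg + (M_unexp - M_bkg) * 10^(-true_netod(dose_gy, truth, mode))
}

#' Render a synthetic CLOD scan
#'
#' Produces a 16-bit RGB raster with one dosimeter footprint per entry of
#' `doses_gy`, plus one leading empty cell whose centre serves as the
#' background (no object) read-out position. The red channel carries the
#' dose signal multiplied by the Newton's-ring modulation over the
#' footprint's radial gap profile; green and blue carry the unmodulated
#' unexposed level. Additive Gaussian noise with the material's pixel-noise
#' SD is applied to all channels, then counts are rounded and clipped to the
#' bit depth. Rendering is bit-identical for equal seeds.
#'
#' By default each footprint receives a random contact-gap phase offset,
#' drawn uniformly over one half-wavelength of optical gap: real contact is
#' never perfect (dust, tilt, surface relief), so the fringe pattern --
#' point-sampled by the scanner grid -- is not reproducible between
#' placements. This is the artifact-irreproducibility mechanism that lets
#' high-visibility gaps (air) degrade dose accuracy in simulated studies;
#' set `jitter_gap = FALSE` for a strictly deterministic pattern (e.g. to
#' measure ring radii).
#'
#' @param doses_gy Delivered doses in Gy, one footprint each (repeat values
#'   for replicates). Must be non-empty and non-negative.
#' @param geometry A [lens_geometry()]; its `center` is ignored (the layout
#'   places footprints on a grid).
#' @param material A [material_spec()].
#' @param config A [scan_config()].
#' @param truth A [ground_truth_response()].
#' @param M_unexp,M_bkg Unexposed and background count levels.
#' @param n_glass,n_lens Refractive indices of scanner glass and dosimeter
#'   surface.
#' @param jitter_gap Randomise each footprint's contact-gap phase (default
#'   `TRUE`).
#' @param margin_mm Spacing added around each footprint cell.
#' @param ncol Number of grid columns (default: up to 6).
#' @return An object of class `clod_scan`: a list with `image` (a
#'   [scan_image()]) and `manifest` (a data frame of footprint positions,
#'   doses and true netOD, with the background position, seed and render
#'   parameters as attributes).
#' @examples
#' sc <- render_scan(c(0, 0.25), material = clod_materials("reflective")$OG,
#'                   config = scan_config("reflective", seed = 7))
#' sc$manifest
#' @export
render_scan <- function(doses_gy,
                        geometry = lens_geometry(),
                        material,
                        config = scan_config(),
                        truth = ground_truth_response(),
                        M_unexp = 40000, M_bkg = 2000,
                        n_glass = 1.52, n_lens = 1.50,
                        jitter_gap = TRUE,
                        margin_mm = 2, ncol = NULL) {
  stopifnot(inherits(material, "material_spec"),
            inherits(config, "scan_config"),
            inherits(geometry, "lens_geometry"),
            inherits(truth, "ground_truth_response"))
  if (length(doses_gy) == 0L) stop("dose list must not be empty")
  if (any(doses_gy < 0)) stop("doses must be >= 0")

  n_fp <- length(doses_gy)
  n_cell <- n_fp + 1L                       # cell 1 is the background cell
  cell_mm <- 2 * geometry$contact_radius + margin_mm
  if (is.null(ncol)) ncol <- min(6L, n_cell)
  nrow <- ceiling(n_cell / ncol)
  px_mm <- 25.4 / config$dpi
  w_px <- ceiling(ncol * cell_mm / px_mm)
  h_px <- ceiling(nrow * cell_mm / px_mm)
  maxc <- 2^config$bit_depth - 1

  # cell centres in mm (x right, y down, origin at image top-left corner)
  cell <- seq_len(n_cell) - 1L
  cx <- (cell %% ncol + 0.5) * cell_mm
  cy <- (cell %/% ncol + 0.5) * cell_mm

  vis <- fringe_visibility(material, n_glass = n_glass, n_lens = n_lens)
  n_gap <- material$refractive_index

  set.seed(config$seed)
  gap_offset_um <- if (jitter_gap)
    runif(n_fp, 0, config$wavelength / (2 * n_gap) / 1000) else
    rep(0, n_fp)

  red <- matrix(M_bkg, h_px, w_px)
  grn <- matrix(M_bkg, h_px, w_px)
  # pixel-centre coordinates (mm)
  xs <- (seq_len(w_px) - 0.5) * px_mm
  ys <- (seq_len(h_px) - 0.5) * px_mm

  for (k in seq_len(n_fp)) {
    x0 <- cx[k + 1L]; y0 <- cy[k + 1L]
    jj <- which(abs(xs - x0) <= geometry$contact_radius)
    ii <- which(abs(ys - y0) <= geometry$contact_radius)
    rr <- sqrt(outer((ys[ii] - y0)^2, (xs[jj] - x0)^2, "+"))
    mask <- rr <= geometry$contact_radius
    t_um <- air_gap_profile(rr[mask], geometry) + gap_offset_um[k]
    fac <- ring_modulation(t_um, n_gap, config$wavelength, vis)
    clean <- dose_to_clean_pixel(doses_gy[k], truth, config$mode,
                                 M_unexp, M_bkg)
    sub_r <- red[ii, jj, drop = FALSE]; sub_g <- grn[ii, jj, drop = FALSE]
    sub_r[mask] <- clean * fac
    sub_g[mask] <- M_unexp
    red[ii, jj] <- sub_r
    grn[ii, jj] <- sub_g
  }

  pix <- array(0, dim = c(h_px, w_px, 3L))
  pix[, , 1] <- red
  pix[, , 2] <- grn
  pix[, , 3] <- grn
  if (material$pixel_noise_sd > 0)
    pix <- pix + rnorm(length(pix), 0, material$pixel_noise_sd)
  pix <- round(pmin(pmax(pix, 0), maxc))

  img <- scan_image(pix, dpi = config$dpi, bit_depth = config$bit_depth,
                    channels = c("red", "green", "blue"))
  manifest <- data.frame(
    footprint = seq_len(n_fp),
    dose_gy = doses_gy,
    x_mm = cx[-1L], y_mm = cy[-1L],
    true_netod = true_netod(doses_gy, truth, config$mode)
  )
  attr(manifest, "background_mm") <- c(x = cx[1L], y = cy[1L])
  attr(manifest, "seed") <- config$seed
  attr(manifest, "mode") <- config$mode
  attr(manifest, "material") <- material$name
  attr(manifest, "dpi") <- config$dpi
  attr(manifest, "M_unexp") <- M_unexp
  attr(manifest, "M_bkg") <- M_bkg
  attr(manifest, "visibility") <- vis
  structure(list(image = img, manifest = manifest), class = "clod_scan")
}

#' @export
print.clod_scan <- function(x, ...) {
  d <- dim(x$image$pixels)
  cat(sprintf("CLOD synthetic scan: %d x %d px, %d footprints, %s mode, material %s\n",
              d[1], d[2], nrow(x$manifest), attr(x$manifest, "mode"),
              attr(x$manifest, "material")))
  invisible(x)
}
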