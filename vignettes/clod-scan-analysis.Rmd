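---
title: "Methods: curved-dosimeter scan analysis and its simulator"
author: "clodr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curved-dosimeter scan analysis and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clodr)
```

## The measurement problem

A contact lens-type ocular dosimeter (CLOD) is a curved radiochromic
dosimeter worn on the eye to measure the lens dose during radiotherapy.
It is read out on a flatbed scanner like Gafchromic film: the active
LiPCDA layer darkens with dose, and the red-channel pixel value of a
region of interest (ROI) is converted to dose through a calibration
curve. Two features distinguish the CLOD read-out from flat-film
dosimetry:

* the doses of interest are low (tens of cGy, out-of-field), so the
  reflective scan mode — roughly 2.5 times more sensitive than
  transmission at these doses — matters;
* the dosimeter is curved, so an air wedge forms between it and the
  scanner glass and produces a Newton's-ring interference artifact.
  Spreading an index-matching compensating material (silicone or optical
  grease) into the gap suppresses the artifact.

`clodr` implements the full analysis chain and a synthetic scan
generator that emulates the physics well enough to exercise every stage.

## Analysis model

**netOD.** For ROI pixel values $M_{unexp}$, $M_{exp}$, $M_{bkg}$
(before irradiation, after, and with an empty bed),
$\mathrm{netOD} = \log_{10}\frac{M_{unexp}-M_{bkg}}{M_{exp}-M_{bkg}}$.
This orientation makes netOD positive for a darkening dosimeter, the
universal convention in radiochromic dosimetry. Write-ups occasionally
print the defining ratio inverted; `compute_netod(convention =
"literal")` reproduces that (negative) orientation so both readings can
be audited, but every downstream stage uses the positive convention.
The first-order uncertainty is
$\sigma_{netOD} = \frac{1}{\ln 10}\sqrt{
\frac{\sigma_{exp}^2+\sigma_{bkg}^2}{(M_{exp}-M_{bkg})^2} +
\frac{\sigma_{unexp}^2+\sigma_{bkg}^2}{(M_{unexp}-M_{bkg})^2}}$,
which the test suite pins against a Monte-Carlo resampling oracle
(agreement well within 5% for pixel SDs up to a few percent of signal).

**Curve fitting.** Both the dose–response curve
$\mathrm{netOD} = aD + bD^n$ and the inverse calibration curve
$D = a\,\mathrm{netOD} + b\,\mathrm{netOD}^n$ are through-origin power
laws fitted by Levenberg–Marquardt least squares. Choices:

* *Unweighted* residuals by default (the protocol being emulated states
  only "least squares"); `weighted = TRUE` applies
  $1/\sigma_{netOD}^2$ weights.
* Replicates are collapsed to per-dose means before fitting (the
  pipeline's default, matching protocols that plot average pixel
  values); the fitting functions themselves accept any point set.
* The unexposed scans define the reference, so the $D=0$ point enters
  as exactly $\mathrm{netOD}=0$.
* Exponent bounds $n \in (0.2, 5)$. Starting values: the linear
  coefficient from a through-origin slope on the two lowest doses, the
  power coefficient from the residual at the highest dose, and — because
  the $aD$ and $bD^n$ terms are nearly collinear for smooth data, which
  makes single-start fits fall into local minima — a multi-start over
  exponent initialisations $\{0.5, 1, 1.5, 2.5, 4\}$ keeping the lowest
  SSR.
* Goodness of fit is the adjusted
  $R^2 = 1-(1-R^2)\frac{N-1}{N-p-1}$ with $p=3$; parameter SDs and the
  covariance come from the fit's variance–covariance matrix.

A consequence of the near-collinearity deserves emphasis: when the data
are close to linear (including the exactly-linear $b=0$ case) the
$a/b/n$ split is not identifiable even though the fitted *curve* is
essentially exact. Tests and users should therefore judge such fits by
their predictions and derivatives, not by individual coefficients; the
marginal coefficient SDs can be large and strongly anticorrelated.

**Sensitivity.** $S(D) = \mathrm{d\,netOD}/\mathrm{d}D =
a + n b D^{n-1}$, verified against central finite differences of the
fitted curve to $10^{-6}$ relative. For $n<1$ (the saturating shape
typical of film-type response at 0–1 Gy) $S$ diverges at $D=0$; the
package returns `Inf` with a warning there.

**Uncertainty budget.** The relative dose uncertainty decomposes into
an experimental part (netOD noise through the calibration slope) and a
fit part (the two coefficient SDs), combined in quadrature; the total is
also evaluated directly from its closed form and the identity is
asserted to $10^{-12}$. Two deliberate fidelity choices: the fit term
omits the coefficient covariance and the exponent's uncertainty, exactly
as in the conventional two-term bookkeeping of the radiochromic
protocol. Because the calibration coefficients are strongly
anticorrelated, this literal form can substantially *overstate* the fit
component; `fit_uncertainty(extended = TRUE)` adds the
$2\,\mathrm{netOD}^{\,n+1}\mathrm{cov}(a,b)$ cross term and the
first-order exponent term for comparison. Percent values are reported at
full precision in JSON and rounded to one decimal in printed tables.

## The synthetic scan generator

The generator is first-class, tested code: it is what makes the
analysis chain verifiable end to end without scanner hardware.

**Geometry and artifact.** Each rendered footprint is a spherical cap on
flat glass with gap $t(r) = r^2/2R$ (base-curve radius $R = 8$ mm,
contact radius 6 mm by default — plausible contact-lens values, not
measurements). The red channel is multiplied by the reflected-light
two-beam fringe law $1 - V\cos(4\pi n_{gap} t/\lambda)$, which includes
the half-wave phase shift, so the contact point is a dark spot and dark
rings sit at $r_m=\sqrt{m\lambda R/n_{gap}}$ — verified in tests by
locating minima of finely rendered radial profiles. The visibility
combines the normal-incidence Fresnel reflectances of the glass/gap and
gap/lens interfaces over a unit diffuse background,
$V = 2\sqrt{R_1R_2}/(R_1+R_2+1)$: the unit term represents the dominant
non-interfering light returned by the dosimeter body, keeping fringe
contrast at the few-percent level seen in practice rather than the
textbook two-beam value. $V$ is exactly 0 at perfect index match and
decreases monotonically as either mismatch shrinks — the mechanism by
which compensating materials work. Default indices: glass 1.52, lens
1.50, air 1.00, Dragon Skin 1.40, SORTA-Clear 1.41, optical grease 1.46
(handbook-plausible values for the material classes), wavelength 630 nm
for the red channel.

**Dose signal.** True response
$\mathrm{netOD}^*(D) = g\,(aD + bD^n)$ with defaults $a=0.12$,
$b=0.18$, $n=0.65$ — a mildly saturating curve reaching netOD 0.30 at
1 Gy in transmission, with sensitivity decreasing in dose as film-type
dosimeters show over 0–1 Gy — and mode gain $g=2.5$ in reflective mode.
Pixel values follow
$M = M_{bkg} + (M_{unexp}-M_{bkg})\,10^{-\mathrm{netOD}^*}$
(defaults $M_{unexp}=40000$, $M_{bkg}=2000$ counts on the 16-bit
scale), so the generator and the netOD stage are exact inverses, which
the tests exploit.

**Noise and irreproducibility.** Additive Gaussian pixel noise, rounded
to integer counts and clipped to the bit depth, at per-material,
per-mode SDs (air/DS/SC/OG: 766.3/696.5/695.0/611.9 counts in
transmission, 577.1/495.9/492.9/373.3 in reflective — the published
25 cGy ROI pixel SDs, the only measured noise scale available). Shot
noise and correlated scanner banding are deliberately not modelled at
this abstraction level. Each footprint additionally receives a random
contact-gap offset drawn uniformly over one half-wave of optical gap:
real contact is never ideal (dust, tilt, surface relief), so fringe
patterns do not reproduce between placements. Rendering is bit-identical
under a fixed seed; "noiseless" configurations set the noise SD to zero
and disable the gap jitter.

**Sampling choice.** The fringe pattern is point-sampled at pixel
centres with no within-pixel integration. Away from the contact point
the fringes are far finer than a 300 dpi pixel, so they alias into a
high-frequency speckle of amplitude $\propto V$ — which is what makes an
uncompensated air gap inflate the ROI SD (and hence the uniformity CV)
the way real artifacts do, at the cost of not being a radiometrically
faithful model of a scanner's pixel aperture. Tests that measure ring
radii render at 6000 dpi where the first rings are resolved.

**Scan layout and metadata.** One footprint per dose entry on a grid,
with a leading empty cell as the background read-out position; green and
blue channels carry the unmodulated unexposed level, so only red carries
dose signal. Written TIFFs are uncompressed 16-bit baseline RGB;
resolution, channel labels and the ground-truth manifest travel in a
JSON sidecar (`<path>.json`), which `read_scan()` uses to restore the
dpi (an explicit `dpi` argument covers foreign files).

## ROI protocol

The standard ROI is a 3.5 mm square: at 300 dpi this is
$3.5 \cdot 300/25.4 = 41.3$ px, rounded to a 41-px window centred on
the pixel containing the requested coordinate (half-open, 0-based
extents; pixels are $25.4/\mathrm{dpi}$ mm squares with the origin at
the image's top-left corner). Readers that quote "about 40 × 40 px" can
be emulated exactly with `side_px = 40`. ROI statistics use the sample
SD ($N-1$); the population form is available since the reference
reader's convention is unknown. A window clipped by the image edge is an
error, not a silent crop.

## The simulated study

`run_calibration_study()` composes everything: per material and mode it
renders a calibration scan (default dose grid 0, 10, 25, 50, 70,
100 cGy — a reconstruction spanning the protocol's stated 0–100 cGy
range and the dose levels its results quote — with 3 replicates), pools
the unexposed footprints as the reference, fits both curves, evaluates
sensitivity and the uncertainty budget at each dose, and renders an
*independent* accuracy scan at 25 and 70 cGy whose calibrated doses give
the percent dose differences. Scan-uniformity CVs are averaged over the
exposed calibration footprints. Every scan derives its seed from the
study seed, so reports reproduce bit for bit.

Problem sizes were chosen so the whole simulated study (8
material–mode combinations, 16 rendered scans at 300 dpi) completes in
a few seconds and the full test suite in well under two minutes: the
default footprint grid keeps images near 1000 × 700 px, and the
parameter-recovery simulation uses 200 replicate fits of 18-point
calibrations.

## What the simulator does and does not establish

Passing tests demonstrate that the analysis chain is internally correct
(exact inverses, algebraic identities, oracle agreement) and that the
modelled mechanisms produce the expected *qualitative* behaviour:
index matching lowers fringe visibility, visibility and noise raise the
ROI CV (air worst, optical grease best, robustly), the reflective mode's
gain survives the full pipeline, and saturating responses yield
decreasing sensitivity. They do not establish quantitative agreement
with any real scanner: the published uniformity CVs and 50 cGy
uncertainties are not reproducible without the raw scans, and the
simulator's CV magnitudes depend on the aliasing-speckle choice above.

Two limitations deserve explicit note. First, the three-parameter
inverse power law cannot exactly represent the true inverse of the
forward power law, leaving a model-mismatch floor of roughly 0.15% in
recovered dose even for noiseless data — tests bound noiseless accuracy
by the calibration fit's own residual rather than by zero. Second, the
average dose difference of a single simulated study is a mean over only
four accuracy cells per material; with white pixel noise averaged over
~1700 ROI pixels, the expected per-material differences are small and
close together for the three compensated materials, so their accuracy
*ranking* in any one study is noise-dominated even though the expected
ordering (air worst, optical grease best) is built into the noise and
visibility inputs. The uniformity CV, a per-pixel statistic, separates
the materials much more strongly and is the reliable single-study
discriminator.
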