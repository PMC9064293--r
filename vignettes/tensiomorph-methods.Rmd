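---
title: "Models and methods behind tensiomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tensiomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tensiomorph)
```

`tensiomorph` implements the biophysical measurement stack used to
characterize convergent thickening in amphibian gastrulation: tissue
surface and interfacial tension from drop shapes and plate compression,
thickening-force traces, the tension-to-force model, and time-lapse
convergence morphometrics. This vignette documents the models, their
assumptions, the tunable constants, and the numerical and design choices —
including the places where the underlying experimental protocols left the
procedure open and this package had to commit to one.

## The capillarity model and its assumptions

The central physical assumption is that embryonic tissue aggregates behave,
on the hour timescale, as liquid drops characterized by an effective
surface tension $\gamma$ (tissue–medium) or interfacial tension
$\sigma$ (tissue–tissue). A sessile aggregate at rest under gravity then
satisfies the Young–Laplace equilibrium

$$\Delta P + \Delta\rho\, g\, z = \gamma\left(\frac{1}{R_1} +
\frac{1}{R_2}\right),$$

with $z$ the depth below the apex and $\Delta\rho$ the tissue–medium
density difference. In the Bashforth–Adams arc-length parametrization the
axisymmetric shape solves

$$\frac{dx}{ds} = \cos\theta,\qquad \frac{dz}{ds} = \sin\theta,\qquad
\frac{d\theta}{ds} = \frac{2}{R_0} + c\,z - \frac{\sin\theta}{x},$$

with apex conditions $(x, z, \theta)(0) = (0, 0, 0)$, apex limit
$\sin\theta/x \to 1/R_0$, and capillary constant
$c = \Delta\rho g / \gamma$. Shape information about tension is carried
entirely by the Bond number $Bo = \Delta\rho g R_0^2/\gamma$: at $Bo = 0$
the shape is a sphere regardless of $\gamma$, so low-Bond shapes cannot
constrain tension — this drives the identifiability rule below.

The tissue density never defaults: $\Delta\rho$ must be supplied by the
user (`fluid_context()` has no default for it), because the relevant
gastrula-tissue density is a measured input, not a constant of the method.
Interfacial-tension fits use the same tissue–medium $\Delta\rho$ by
default; whether an effective deep/epithelial density difference would be
more appropriate is genuinely open, so the value is an explicit argument
rather than a hidden constant.

### Numerical integration

`integrate_profile()` handles the apex singularity with the second-order
series $x \approx s - s^3/6R_0^2$, $z \approx s^2/2R_0$,
$\theta \approx s/R_0$ for $s < 10^{-4} R_0$, then hands off to an
adaptive solver (`deSolve::lsodar`, relative tolerance $10^{-9}$) with
root-stopping at a target tangent angle (default $\pi$) and at $x = 0$.
Samples at the closure pole, where the axisymmetric parametrization is
singular ($x \to 0$, $\theta \to \pi$), are dropped. The meridional radius
$R_1$ is evaluated through the governing equation; the azimuthal radius is
$R_2 = x/\sin\theta$ with the umbilic limit $R_1 = R_2 = R_0$ at the apex.

Two independent checks guard this forward model. First,
`integrate_profile_fixed()` is a from-scratch fixed-step fourth-order
Runge–Kutta integrator of the same system; the test suite requires the two
paths to agree in equatorial radius to better than $10^{-6}$ relative at
$Bo \in \{0.1, 1, 5\}$. Second, `laplace_residual()` re-differentiates the
*sampled* $\theta(s)$ by spline (not through the governing equation, which
would be circular) and verifies the equilibrium equation pointwise to
$10^{-6}\,\Delta P_0$.

A consequence of the model worth stating explicitly: at fixed apex radius,
increasing $Bo$ *decreases* the equatorial radius relative to $R_0$
(numerically: $x_{eq}/R_0$ = 1.000, 0.885, 0.704 at $Bo$ = 0, 1, 5).
Gravity flattening manifests as the width/height aspect ratio increasing
with $Bo$ (1.000, 1.155, 1.406 over the same range), and that is the
monotonicity the property tests assert.

## ADSA fitting

`fit_adsa()` minimizes the mean squared nearest-point distance between the
observed outline and the mirrored theoretical profile over apex radius,
Bond number, apex position, and optionally tilt. Choices that matter:

* **Parametrization.** The fit runs in $(\log R_0, \log Bo, x_0, z_0)$ and
  converts to $\gamma = \Delta\rho g R_0^2 / Bo$ afterwards. In raw
  $(\gamma, R_0)$ form the two parameters are strongly correlated; the
  $(Bo, R_0)$ form conditions the search much better.
* **Optimizer.** Derivative-free Nelder–Mead with three starts bracketing
  the apex-curvature estimate from a least-squares circle fit to the
  apex-most 30% of points (factors 0.7, 1.0, 1.4). Exploratory starts use
  a fast fixed-step RK4 evaluation of the unit-radius profile (the shape
  is exactly scale-equivariant, so only $Bo$ requires integration); the
  final polish re-evaluates through the adaptive integrator at
  $10^{-9}$ tolerance. Distances use nearest-vertex search plus exact
  point-to-segment refinement on the adjacent segments.
* **Identifiability.** Fits with $\hat{Bo} <$ `bo_min` (default 0.05) are
  flagged unidentifiable: below this the gravitational deformation is
  smaller than typical contour noise and the shape is compatible with any
  sufficiently large tension. The threshold is exposed in the fit
  interface. Noise-free synthetic contours generated at $Bo < 0.05$ are
  flagged in 100% of cases, and contours at $Bo > 0.1$ never are.
* **Tilt** is off by default — profile imaging with a mirror gives
  an essentially level support — and can be enabled (`fit_tilt = TRUE`),
  adding a rotation about the apex to the parameter vector.

Measured recovery under the study conditions (Bond $\approx 1$,
$\gamma = 0.22$ mN/m, $R_0 = 0.75$ mm): noise-free error $< 0.02\%$ across
$Bo \in [0.2, 5]$; at 1% radial contour noise with 200 points the median
absolute error over 20 seeds is $\approx 1.8\%$ with median signed error
within $\pm 0.3\%$.

## Contour extraction and QC

`extract_contour()` implements: Gaussian smoothing → Canny edge detection
(Sobel gradients, non-maximum suppression, hysteresis linking; thresholds
default to the 50th/90th percentiles of the nonzero gradient magnitude,
since the original protocols record no threshold values) → selection of the
largest closed region → ordered boundary tracing → parabolic subpixel
refinement of each point along its normal to the gradient-magnitude
maximum → light circular smoothing. Contours are ordered counterclockwise
from the apex-most point and translated to apex-centered physical
coordinates. Images are indexed `[ix, iz]` with depth increasing downward;
pixel `(ix, iz)` has its center at `((ix - 0.5), (iz - 0.5)) * pixel_scale`.

Because a sessile aggregate rests on a support, the extracted closed
boundary contains a flat substrate chord. Points within 2 px of maximum
depth are trimmed before fitting (and the substrate line recorded), since
they belong to the support rather than the free surface; QC is computed on
the full closed silhouette.

Quality control operationalizes the "too irregular for drop-shape
analysis" rejection as: circularity $4\pi A/P^2 \ge 0.6$ and convexity
deficiency $1 - A/A_{hull} \le 0.15$, plus closedness and simplicity
(no self-intersection). The defaults pass strongly gravity-flattened drops
(circularity $\approx 0.89$ at $Bo = 2$) while rejecting lobed or ragged
outlines; both thresholds are configuration values. The original
inspection criteria were qualitative and manual — this automated QC is an
explicit stand-in, not a reconstruction, and `inspection_overlay()`
supports the manual-inspection step it replaces.

## Plate tensiometry and push-back analysis

`plate_sigma()` evaluates
$\sigma = F / \left(\pi R_3^2 (1/R_1 + 1/R_2) - 2\pi R_3 \sin A\right)$
from the force after stress relaxation (the reading time, 180 s, is a
config constant), the two principal profile radii, the plate-contact
radius and contact angle. The formula is symmetric in $R_1, R_2$, so their
identification (equatorial vs meridional) cannot affect the result; a
geometry whose denominator is non-positive is physically inconsistent with
a compressed drop and raises an error. Strains are flagged against the
18–22% working band: above 22% aggregates respond solid-like (tension
readings jump), so `compute_strain()` marks `solid_like_regime` above the
band and `below_protocol` beneath it.

`analyze_pushback()` decomposes a held-platen trace. The protocols report
onset times but not the scoring rule, so the rule here is this module's
explicit operationalization: median-smooth (window 5 samples), fit the
relaxation segment with $F = a + b e^{-t/\tau}$
(`minpack.lm::nlsLM`, with a median-based fallback), set the relaxation
end at $\max(180\,\mathrm{s}, 5\hat\tau)$, estimate the plateau as the
median of the following 600 s and the noise SD as the MAD of the
smoothing residuals, and call onset at the first sustained excursion above
plateau $+ k\cdot$SD ($k = 3$; at least 90% of smoothed samples above
threshold over a 10 min window). The detected crossing is then refined by
intersecting a line fit to the early ramp with the plateau level, which
removes the systematic threshold-crossing lag of
$k\cdot\mathrm{SD}/\mathrm{ramp}$. Because protocols differ on the
reference point, the 30-minute force gain is reported both from detected
onset and from the start of the test. Under the default synthetic
conditions (noise SD 0.01 µN, ramp 0.3 µN per 30 min) the onset is
recovered to within seconds, far inside the ±5 min acceptance window.

## The force model

`predict_force()` is the scalar line-tension product $F = \sigma_{em} L_i$:
the measured deep/superficial interfacial tension acting over the traced
interface contour length. At $\sigma_{em} = 0.22$ mN/m and
$L_i = 1.2$ mm this predicts 0.26 µN, the scale observed in convergence-
and thickening-force assays. The geometric argument connecting a
cross-sectional contour length to a longitudinal convergence force is
narrative (hoop tension from surface minimization); no additional geometry
model is invented here, and forces are reported to two decimals in µN,
matching the field's reporting granularity. `compare_forces()` reports
predicted/measured ratios without a verdict.

## Morphometrics

Regional widths are straight-line separations of declared boundary-point
pairs — not arc lengths — because the underlying measurements are made on
2-D projections of approximately flat explants. Ratios $W_t/W_i$ are
normalized to the first shared timepoint. "Percent per hour" is defined as
the OLS slope of $W_t/W_i$ versus time $\times (-100)$, i.e. linear in the
*ratio* (fraction of initial width per hour), chosen because convergence
data are plotted and reported as $W_t/W_i$; a rate relative to current
width would differ by $<1\%$ over the 2 h windows involved but is not
identical.

`detect_rate_change()` fits a *continuous* two-segment piecewise-linear
model with exhaustive breakpoint search over interior sample times,
keeping the breakpoint only if the two-segment model beats a single line
by an F-criterion (2 extra parameters, default $\alpha = 0.05$); perfect
single lines short-circuit to "no changepoint". The source observations
scored the IMZ/NIMZ divergence time descriptively; the exhaustive-search
changepoint is this module's committed procedure.

The spherical-area correction is a reconstruction: the underlying methods
state only that projected areas were corrected for embryo sphericity. The
construction here assumes regions concentric about the viewing axis, for
which a polar cap of projected radius $r$ on a sphere of radius $R$ has
true area $2\pi R^2 (1 - \cos \arcsin(r/R))$ and annuli are cap
differences. It reduces to factor 1 in the flat limit, exactly 2 at the
hemisphere, and is monotone in between.

Cell length–width ratios come from the second-moment best-fit ellipse
(square root of the polygon-moment eigenvalue ratio), since the original
metric is not defined; circularity is $4\pi A/P^2$. Group summaries use
arithmetic means, SEM, and the classic pooled-variance unpaired two-tailed
t test (matching the stated convention), with a Welch switch; the t and p
are computed from the formulas in-package so the test suite can check them
against `stats::t.test` as an independent reference.

## The synthetic-data module

The measurements this package models were published without raw movies or
force traces, so the generators define the study conditions for all
recovery testing:

* **Drop contours** (`synth_drop_contour()`): points sampled along the
  noise-free Young–Laplace outline, perturbed along the local outward
  *normal* (so the noise level reads directly as contour roughness; the
  empirical point-to-profile deviation scales linearly with the setting),
  optionally tilted. Defaults: $\gamma = 0.22$ mN/m (the measured
  interfacial-tension scale), $\Delta\rho = 40$ kg/m³ (gastrula tissue
  $\approx 1.045$ g/cm³ against culture medium $\approx 1.005$),
  $R_0 = 0.75$ mm, giving $Bo \approx 1$ — squarely in the identifiable
  regime. No noise magnitudes were published; 1% of $R_0$ is the
  calibration choice used in recovery studies.
* **Drop images** (`synth_drop_image()`): the filled silhouette closed
  across the substrate chord, rasterized, Gaussian-blurred (2 px in
  tests), with optional pixel noise, at 7.5 µm/px so the reference drop
  spans ~200 px.
* **Push-back traces** (`synth_pushback_trace()`): preload 0.25 µN (middle
  of the 0.2–0.3 µN protocol band), exponential stress relaxation
  ($\tau = 60$ s, consistent with a 3 min relaxation protocol), plateau,
  then a ramp of 1.7e-10 N/s ($\approx$ 0.3 µN per 30 min, the measured
  thickening-force scale) from a known onset; noise SD 0.01 µN
  (instrument-scale).
* **Track tables** (`synth_track_table()`): paired boundary points whose
  separation follows the continuous piecewise-linear ratio construction.
  Default regimes are the reported convergence regimes: IMZ at a constant
  10 %/hr; NIMZ at 7 %/hr slowing to 0 %/hr at −0.7 h (≈40 min before
  gastrulation onset). Sampling every 0.05 h mirrors 3 min/frame
  time-lapse; positional noise of 3 µm corresponds to about one pixel of
  manual tracking error on a 1 mm-wide field.

Every generator is deterministic per seed (draws run under a saved and
restored RNG state) and records its full ground truth in metadata;
recovery tests read truth *only* from there.

What the generators deliberately do **not** emulate: tissue mechanics,
cell behavior, heterogeneous or correlated contour noise, uneven
illumination or debris in images, instrument drift in force traces, or
lost/occluded track points. Passing recovery tests therefore demonstrate
that the estimators are correct and well-conditioned under the stated
statistical structure — not that they are robust to every artifact of real
microscopy; the QC layer and inspection overlays exist precisely because
real data need human eyes.

## Problem sizes

The test suite and the acceptance script size their simulations as: 200
contour points per synthetic drop; 20 Monte-Carlo seeds for each noisy
recovery study (ADSA, push-back onset, convergence rates and breakpoints);
rendered images of roughly 250×200 px; fixed-step oracle integrations at
$2\times10^5$ steps; track tables of 81 timepoints per region. These sizes
put every Monte-Carlo mean and fraction comfortably past its acceptance
margin while keeping the full suite in the minutes range on a single CPU.

## Known limitations

* The liquid-drop description is an effective model; aggregates showing
  solid-like responses (e.g. above ~22% compression strain) fall outside
  it, which is why the strain regime is flagged rather than silently
  accepted.
* ADSA and plate compression can disagree in absolute magnitude on real
  tissue (historically by an order of magnitude); both paths are
  implemented faithfully and reported separately — the package does not
  attempt to reconcile them.
* The substrate-chord trim assumes the support is at maximum depth in the
  frame; unusual imaging geometries would need the contour supplied
  directly.
* Changepoint inference assumes a single breakpoint; multi-regime series
  would need repeated application.
* The automated QC thresholds approximate, but cannot reproduce, the
  original manual inspection.
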