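# tensiomorph

Tissue surface tensiometry and gastrulation morphometrics in R.

During amphibian gastrulation, the involuting marginal zone (IMZ) of the
embryo converges around the blastopore. Part of that convergence force comes
from *convergent thickening*: a rise in the interfacial tension between the
deep IMZ tissue and its overlying epithelium drives the deep tissue to
minimize its surface, shortening the mediolateral axis and thickening the
tissue. Characterizing this mechanism requires a stack of biophysical
measurements — tissue surface tension from gravity-flattened aggregate
shapes, interfacial tension from parallel-plate compression, thickening
forces from held-platen "push-back" traces, and convergence kinematics from
time-lapse movies. `tensiomorph` implements that measurement stack as a
tested, reusable pipeline, for researchers quantifying tissue-scale forces
in embryos, explants, or aggregates.

## What it computes

**Axisymmetric drop shape analysis (ADSA).** A liquid-like tissue aggregate
resting under gravity takes an equilibrium shape governed by the
Young–Laplace equation

    ΔP + Δρ g z = γ (1/R₁ + 1/R₂)

where ΔP is the apex pressure jump, Δρ the tissue–medium density
difference, z the depth below the apex, γ the tissue surface (or
interfacial) tension, and R₁, R₂ the principal radii of curvature.
`integrate_profile()` integrates the Bashforth–Adams arc-length form of this
equation to generate theoretical drop shapes; `fit_adsa()` estimates γ by
optimally fitting those shapes to an observed aggregate outline (fitting in
Bond number Bo = Δρ g R₀²/γ for conditioning, flagging near-spherical
shapes as unidentifiable). `extract_contour()` turns profile images —
including max-projected confocal stacks — into QC'd outlines via Canny edge
detection with subpixel refinement.

**Parallel-plate tensiometry.** `plate_sigma()` evaluates the compression
relation σ = F / (πR₃²(1/R₁ + 1/R₂) − 2πR₃ sin A) from the post-relaxation
force and the compressed aggregate geometry; `analyze_pushback()`
decomposes a held-platen force trace into stress relaxation, plateau, and
push-back onset (a sustained excursion above plateau + k·SD, refined by
ramp back-extrapolation).

**Force model.** `predict_force()` implements F = σ_em · L_i: interfacial
tension acting over the traced deep/superficial interface contour yields
the tissue's convergence/thickening force.

**Morphometrics.** `region_widths()`, `estimate_rate()` and
`detect_rate_change()` quantify regional convergence (W_t/W_i in %/hr, with
two-segment changepoint fits); `spherical_cap_area()` corrects projected
areas for embryo curvature; `blastopore_closure()` and
`cell_shape_metrics()` cover closure curves and traced-cell shape
statistics; `summarize_groups()` provides the mean/SEM/unpaired-t reporting
conventions.

**Synthetic data.** No raw movies or traces accompany the measurements this
package models, so `synth_drop_contour()`, `synth_drop_image()`,
`synth_pushback_trace()` and `synth_track_table()` generate every input
with known ground truth carried in metadata — all estimators are validated
by parameter recovery.

## Worked example

```r
library(tensiomorph)

# a synthetic aggregate outline at the measured tension scale:
# gamma = 0.22 mN/m, delta_rho = 40 kg/m^3, apex radius 0.75 mm (Bo ~ 1),
# 1% contour noise
cont <- synth_drop_contour(gamma = 0.22e-3, delta_rho = 40, R0 = 7.5e-4,
                           radial_noise_sd = 0.01, seed = 42)
fit <- fit_adsa(cont, delta_rho = 40)
fit
#> Axisymmetric drop shape analysis fit
#>   gamma = 0.2278 mN/m   R0 = 0.7459 mm   Bo = 0.9581
#>   rms residual = 7.23e-06 m over 200 points; converged, identifiable
```

The fitted tension (0.2278 mN/m) recovers the generating value (0.22 mN/m)
to ~3.5% under 1% contour noise; the Bond number near 1 confirms the shape
carries tension information, and the rms residual (~7 µm) matches the
injected noise level.

```r
# the tension-to-force model over a 1.2 mm interface
predict_force(0.22e-3, 1.2e-3)
#> Predicted force: F = sigma * L = 0.22 mN/m x 1.2 mm = 0.26 uN

# push-back trace: relaxation, plateau, onset
analyze_pushback(synth_pushback_trace(seed = 42))
#> Push-back trace analysis
#>   relaxation: tau = 57.8 s (exp fit), end at 289 s
#>   plateau force = 0.1494 uN, noise SD = 0.00741 uN
#>   onset at 3600 s; dF(30 min from onset) = 0.3168 uN
#>   dF(30 min from start) = -0.1074 uN

# regional convergence rates and the NIMZ slow-down
rs <- region_widths(synth_track_table(seed = 42))
estimate_rate(rs, region = "IMZ")
#> Convergence rate, region 'IMZ': 10.02 %/hr (SE 0.04, 81 points, t in [-2.00, 2.00] hr)
detect_rate_change(rs, region = "NIMZ")
#> Rate change, region 'NIMZ': breakpoint at -0.65 hr; 6.82 -> -0.12 %/hr (p = 4.99e-46)
```

The predicted 0.26 µN is the scale of convergence force a 0.22 mN/m
interfacial tension generates over a 1.2 mm interface. The push-back
decomposition finds the generator's 3600 s onset exactly and a ~0.32 µN
force gain over the following 30 minutes. The track analysis recovers the
IMZ converging at ~10 %/hr throughout while the NIMZ slows from ~7 %/hr to
~0 %/hr at a breakpoint near −0.7 h (about 40 min before gastrulation
onset).

`run_pipeline()` chains the stages (synthetic → extract → fit → report;
trace → push-back; tracks → rates) under a single YAML-serializable
configuration with provenance (config hash, seed, package version).

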