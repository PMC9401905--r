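---
title: "Radiometric calibration and canopy phenotyping with uavcal: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiometric calibration and canopy phenotyping with uavcal: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uavcal)
```

## The problem

Multi-lens multispectral cameras on small UAVs record raw digital numbers
(DN), not reflectance. Before any vegetation index or trait model can be
trusted, DN must be converted to surface reflectance against reference
panels imaged in the scene, and the conversion method matters: a single
affine fit misbehaves exactly where crop canopies live, at low visible-band
reflectance, where it can return negative "reflectance". On top of the
radiometric question sits a geometric one: the same plot imaged from
different flight altitudes is seen under different view zenith angles
(VZA), so its pixel mixture of canopy and background — and hence its
reflectance and indices — drifts with altitude.

`uavcal` implements the full chain for a 12-band camera (centers 490, 520,
550, 570, 670, 680, 700, 720, 800, 850, 900, 950 nm; 1280 x 1024 px; FOV
38.26 x 30.97 degrees): three empirical-line calibration methods, spectral
convolution of field-spectrometer spectra to band-equivalent reflectance,
nine vegetation indices, fully constrained linear spectral unmixing,
altitude/view-geometry models, linear VI-trait regression, and a synthetic
scene generator that makes every step testable against known truth.

## Calibration models

With per-band panel mean DN $x$ and nominal panel reflectance $y$, the
three methods are

* **EL** (empirical line): $y = a_1 x + b_1$, ordinary least squares over
  all panels.
* **SEL** (subband empirical line): visible bands (1–7, 490–700 nm) use a
  power law $y = a_2 x^{b_2}$; red-edge/NIR bands (8–12, 720–950 nm) use
  an affine fit. The power fit is done in log–log space, which is
  closed-form and deterministic; an iterative nonlinear fit would add a
  convergence knob without adding accuracy on noiseless panels.
* **PEL** (piecewise empirical line): proportional through the origin,
  $y = a_4 x$, below a reflectance threshold $\tau = 0.03$, affine
  $y = a_5 x + b_5$ above it. $a_5, b_5$ come from all panels (as EL);
  $a_4$ from a through-origin fit restricted to dark panels.

**Branch rule.** The piecewise condition is written on reflectance, which
is unknown at application time. The only self-consistent reading is to
predict with the affine segment first and branch on that prediction:
output $a_4 x$ where $a_5 x + b_5 \le \tau$, else $a_5 x + b_5$. Continuity
at $\tau$ is *not* enforced; it is a property of the data, not of the
method.

**Dark-panel selection.** By default the through-origin fit uses panels
with nominal reflectance at or below `low_panel_max = 0.06` (the 3% and 6%
panels of the standard eight-panel set: 3, 6, 12, 24, 36, 48, 56, 80%),
because two points stabilize a one-parameter fit. When the sensor's true
response is known to break exactly at $\tau$ — as in the package's own
piecewise closed-loop scenes — only panels at or below $\tau$ lie on the
proportional segment, and including the 6% panel would contaminate $a_4$
with affine-branch information; those tests therefore pass
`low_panel_max = 0.03`. With field data the default is the safer choice.

No clamping is applied by default: negative or >1 reflectance is preserved
and counted per band in a diagnostics table, because the negative-value
pathology of EL in dark bands is a *finding* a user should see, not an
artifact to hide. `clamp = c(0, 1)` is available.

## Band-equivalent reflectance

Field-spectrometer spectra are compared with camera bands through the
response-weighted mean

$$R_j = \frac{\int_s^e R(\lambda) S_j(\lambda)\, d\lambda}
             {\int_s^e S_j(\lambda)\, d\lambda}.$$

Both $R$ and $S_j$ are stored as sampled, piecewise-linear functions. Their
product is piecewise quadratic on the merged knot grid, so the numerator is
integrated with Simpson's rule per merged interval (exact for quadratics)
and the denominator with the trapezoidal rule (exact for linear
integrands). The quadrature is therefore exact for the declared function
class — no convergence parameter exists. A constant spectrum returns the
constant to machine precision for any response shape, and the operator is
linear in the spectrum.

True per-lens response functions for this camera family are not published.
When none is supplied the package synthesizes a Gaussian response (FWHM
10 nm, configurable) centered on each band and says so in a message; every
result derived from synthetic responses should be read with that caveat.

## Fully constrained unmixing

A mixed pixel $R$ over endmember spectra $R_i$ follows
$R = \sum_i A_i R_i + e$ with $A_i \ge 0$, $\sum_i A_i = 1$. The solver
augments the endmember matrix with a sum-to-one row scaled by
$\delta = 10^3 \cdot$ (max endmember column norm) and solves the
non-negative least-squares problem with a Lawson–Hanson active-set
iteration implemented in the package; the solution is then renormalized
onto the simplex. The renormalization shift is of order
$\|E\|^2/\delta^2 \approx 10^{-6}$ relative and the final iterate satisfies
both constraints to well below the advertised $10^{-8}$ tolerance (tested
on 10,000 random pixels). Endmember matrices with condition number above
$10^8$ trigger a warning, rank-deficient ones a stronger warning;
unmixing proceeds because a least-norm abundance is still often useful.

The canonical endmember set for a flooded paddy is six-fold: sunlit/shaded
leaf, sunlit/shaded water, sunlit/shaded soil. Two summary factors are
derived from the four background abundances: the NIR attenuation factor
$A_{lw}+A_{sw}+A_{ls}+A_{ss}$ (total background) and the visible-band
enhancement factor $A_{lw}+A_{ls}+A_{ss}-A_{sw}$. The subtraction of
shaded water in the enhancement factor is adopted exactly as defined in
the literature this package follows; its physical motivation (shaded water
darkens the visible signal while the other backgrounds brighten it) is
plausible but the definition is taken as given, not derived.

## Viewing geometry

For a target at horizontal offset $x$ from nadir and altitude $H$:
$\alpha = \arctan(x/H)$ (degrees); a target at the horizontal image edge is
seen at half the horizontal FOV, 19.13 degrees, at every altitude. The
ground sample distance is $2H\tan(\mathrm{fov}_h/2)/\mathrm{width}$, linear
in $H$. ROIs defined at a reference altitude are rescaled by
$H_\mathrm{ref}/H_\mathrm{new}$ per dimension, rounded half away from zero
(bit-for-bit reproducible across platforms, unlike banker's rounding),
minimum one pixel, center preserved.

The altitude-sensitivity metric for a band is the standard deviation of
plot reflectance over all flown altitudes (STD) and its ratio to the
near-nadir reflectance (STDR), with the highest altitude standing in for
the orthophoto direction. STD is the *population* SD (divide by $N$): the
altitude set is enumerated, not sampled.

Throughout, terrain is assumed flat and the camera nadir-pointing
(gimbal-stabilized); lens distortion is assumed removed upstream.

## The synthetic scene generator

The generator is first-class package code, not a test fixture. It emulates
what a field campaign produces, with truth stored alongside:

* **Endmembers**: six spectra over the 12 band centers with seeded
  band-wise jitter, constrained by construction (leaf NIR above all
  backgrounds, leaf red below sunlit soil). Shaded spectra are sunlit
  spectra scaled per band by $s^{\gamma_b}$ with $\gamma_b \sim U[0.8,
  1.25]$: real shadows are spectrally non-uniform, and a single scalar
  factor would make the endmember matrix rank-3 and abundances non-unique.
  At $s = 1$ shaded and sunlit coincide exactly.
* **Geometry coupling**: each plot's background fraction is
  $f = \mathrm{clip}(f_0 + g\,\tan \mathrm{VZA}, 0, 1)$ — a footprint
  elongation heuristic, exposed as parameters ($f_0 = 0.15$, $g = 0.5$
  default), not a hidden constant. Because leaf NIR exceeds background
  NIR by construction, plot NIR reflectance is non-increasing in the
  background fraction, reproducing the observed altitude trend.
* **Sensor transfers**: forward reflectance-to-DN maps that invert each
  calibration model (affine, piecewise, power). The piecewise transfer of
  interest is continuous at $\tau$ with $a_5 > a_4$, so dark-object DN sit
  above the affine extension and an EL fit — exact on the panels —
  systematically overestimates slope into the dark regime and produces
  negative reflectance there, the failure mode PEL exists to fix.
* **Scene furniture**: eight grayscale panels (3–80%), rendered noiseless
  so calibration-recovery tests isolate method error; a flooded-paddy
  strip of nearly pure shaded water so the scene contains genuinely dark
  (<1.2%) pixels; additive Gaussian DN noise truncated at zero when
  requested. All randomness flows from explicit per-call seeds; the
  caller's RNG state is never touched.

What the generator does **not** emulate: radiative transfer (no PROSAIL),
sun-angle or BRDF anisotropy beyond the single background-fraction
heuristic, atmosphere, vignetting, band misregistration, or saturation.
Passing closed-loop tests therefore demonstrates the *methods* are
implemented correctly and are internally consistent — not that any given
field dataset satisfies their assumptions.

## Trait models and metrics

Linear VI-trait models are fitted by OLS with in-sample $R^2$, RMSE and
RRMSE (= RMSE / observed mean, percent); MRPE is
$\mathrm{mean}(|(\hat y - y)/y|) \times 100$. In-sample metrics are the
deliberate choice because the shipped reference catalog (CIgreen-based
LAI/AGB/CCC models per calibration method and per altitude, plus
stage-specific EVI2/WDRVI yield models) reports fit statistics, not
held-out validation; whether those published $R^2$ values were
cross-validated is not stated, so the catalog stores them as printed,
keyed by experiment, method-or-altitude, trait and (for yield) stage.
Canopy chlorophyll content is the product LAI $\times$ SPAD.

Vegetation-index formulas and defaults: red = 670 nm and NIR = 800 nm
(both remappable; red restricted to {670, 680}, NIR to {800, 850, 900,
950}), WDRVI weight $\alpha = 0.1$. Division by zero yields `NA` plus a
diagnostic count rather than an error so whole-image maps always complete.

## Problem sizes and tolerances

The shipped test-suite and acceptance-script scenes use a reduced
160 x 128 px camera with the reference FOV — footprint geometry, GSD
scaling and panel layout are unchanged, and every property tested is
resolution-independent; the native 1280 x 1024 profile is the default for
real imagery. Closed-loop calibration checks demand max absolute error
below 1e-9 (affine/EL) and 1e-6 (piecewise/PEL); convolution agrees with a
0.01 nm brute-force oracle to 1e-6; FCLS constraints hold to 1e-8 and its
objective is verified against an exhaustive 0.01-step simplex grid search
on 3-endmember problems; trait-model recovery is judged at three standard
errors over 200 simulated plots with residual SD 0.3.

## Known limitations

* True spectral response functions are unavailable; Gaussian stand-ins are
  synthesized and flagged.
* The piecewise threshold $\tau = 0.03$ is a fixed convention; nothing in
  the fitting procedure estimates it from data.
* Whether dark panels should ever be excluded per band (e.g., a saturated
  80% panel in NIR) is scene-dependent and left to the caller.
* The unmixing model is strictly linear; nonlinear mixing, endmember
  variability bundles and in-scene endmember extraction are out of scope.
* Geometry assumes flat terrain and square pixels (the horizontal FOV
  drives GSD in both axes).
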