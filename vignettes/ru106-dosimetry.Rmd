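---
title: "Traceable absorbed-dose dosimetry of Ru-106 eye plaques: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traceable absorbed-dose dosimetry of Ru-106 eye plaques: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rudose)
```

## The measurement problem

Ru-106/Rh-106 ophthalmic applicators (here the CCB model) are concave beta
sources sewn onto the sclera to treat uveal melanoma. The beta field falls
off by roughly 2 % per 0.1 mm at the applicator surface, so both the
absolute dose rate and its depth dependence are hard to measure, and clinics
have traditionally relied on the vendor's certificate (a plastic-scintillator
measurement with an 11 % expanded uncertainty at k = 2) without independent
verification. `rudose` implements a verification chain for direct-reading
silicon diode detectors calibrated in external reference beams, the
external-beam-traceability route familiar from TRS-398-style dosimetry:

$$\dot D_{w,Q}(z) = M_Q(z) \cdot N_{D,w,Q_0} \cdot k_{Q,Q_0}(z)$$

where $M_Q$ is the corrected net reading rate at water-equivalent depth $z$,
$N_{D,w,Q_0}$ is the absorbed-dose-to-water calibration coefficient in the
reference quality $Q_0$ (Co-60 or a 6 MeV electron beam), and $k_{Q,Q_0}(z)$
is the depth-dependent beam-quality correction factor for the Ru-106 plaque
field. In the steep plaque gradient $k_{Q,Q_0}$ varies strongly with depth —
from 1.14 at 2 mm to 1.04 at 10 mm for the Co-60 route — which is why the
package treats it as a depth-indexed table, never a constant.

The same formalism applies to passive alanine/EPR dosimetry
($D_w = M_{al} \cdot N_{al} \cdot k_{Q_{Ru},Q_0}$), whose correction factor
is assembled from a chain of staged transport geometries (below).

## What the package computes and what it consumes

The beam-quality factors themselves come from radiation-transport
calculations of the detector in the plaque field and in the calibration
field; those calculations are *inputs* here, consumed either as a packaged
depth table (`ccb_kq_table()`) or as Monte-Carlo dose quartets
(`kq_from_mc()` forms the double ratio
$[(D_w/\bar D_{det})_Q] / [(D_w/\bar D_{det})_{Q_0}]$ and propagates the
four statistical uncertainties in quadrature). The intrinsic-response ratio
$R_{Q_0}/R_Q$ is modelled as exactly unity, with the doubt about that
assumption carried as a type-B budget component (1.0 % for the silicon
diode, 0.5 % for alanine) rather than as a free parameter — making it a
fit parameter would let it absorb real calibration differences.

The packaged correction table is valid only for CCB plaques under the
measurement setup for which the factors were computed; it is shipped as
versioned fixture data, not as physics that generalises to other plaque
models.

## Reading processing

A measurement session is a forward pass (2 to 10 mm, 1 mm steps), a reverse
pass (10 back to 2 mm), and background series before and after zeroing the
electrometer. The processing order is: per-series background subtraction,
per-series statistics, decay referencing, bidirectional merging, session
corrections, dose conversion. Choices worth recording:

* **Background.** The pre and post background rates are averaged and the
  mean rate, scaled to each series' acquisition time, is subtracted
  (`subtract_background()`). A linear-drift interpolation between the two
  background timestamps is available (`drift = TRUE`) but off by default:
  the averaged model is the documented measurement practice, and a drift
  model with only two support points adds a parameter without evidence.
* **Type A per series.** The standard error of the mean of the repeated
  readings, as a percentage (`series_statistics()`). A single reading gives
  `NA`, never 0 — an undefined estimate must not silently shrink a budget.
* **Order of pooling.** Statistics are computed per direction first, then
  the directions are merged (`merge_bidirectional()`). Whether repeats
  should be pooled before or after direction merging is not prescribed by
  the protocol this mirrors; this order was chosen because the forward and
  reverse passes are separated by an electrometer re-zero and should be
  treated as separate estimates. The merged repeatability is the quadrature
  of the pooled SEM with *half the relative forward/reverse difference*,
  so slow systematic drift over the session appears in the repeatability
  rather than being averaged away.
* **Temperature.** Silicon diodes have no documented temperature formula
  for this setup, so the linear coefficient defaults to 0 %/°C (a no-op)
  while the budget still carries a 0.1 % temperature component. The
  coefficient is configurable for detectors that need it.
* **Decay.** Exponential with the Ru-106 half-life, 371.8 d by default
  (the literature value; only its relative uncertainty, 0.04 %, appears in
  printed budgets). Each series is decay-referenced using its own
  timestamp before merging, so a long session does not bias the curve.
* **Depth convention.** All depths are water-equivalent distances from the
  plaque surface centre to the active-volume *front face plus the
  effective-depth offset*. The 0.9 mm photon-specification offset is the
  default (it matched transport calculations better than the 0.3 mm
  electron specification); 0.3 mm remains available via
  `detector_geometry()`.

## Uncertainty budgets

`combine_budget()` is pure quadrature over uncorrelated type A and type B
relative components, per the GUM; correlated-component algebra is out of
scope. Depth-dependent components are stored as depth-indexed tables with
linear interpolation and *no extrapolation* — a budget evaluated outside a
component's tabulated range is an error, not a guess. Where only a printed
range is known (diode measurement repeatability, 0.3–0.8 %), the fixture
stores the endpoints at the depth extremes (2 and 10 mm); the linear ramp
between them is an interpolation convention, not a claim about the true
depth dependence. The diode budget keeps the Ru-106 measurement components
and the two traceability chains (Co-60, 6 MeV) in separate groups, and the
caller selects which to combine, because the grouping of the printed
components is itself ambiguous. One opaque entry, the half-life *resolution*
(0.05), has no operational definition; it is stored and combined as given,
never recomputed. Report rounding is two significant figures, round-half-even
(`round_budget()`), matching standard budget-table presentation:

```{r budget}
b <- alanine_budget()
data.frame(depth_mm = 2:5,
           combined_k1 = sapply(2:5, function(z)
             round_budget(combine_budget(b, z), 2)))
```

## The alanine perturbation chain

The alanine measurement happens in a PMMA phantom with an air gap under the
source; converting it to dose to water at a point in water uses four
perturbation factors formed as successive ratios of five staged geometries:
full setup (g1), air gap filled with PMMA (g2), alanine replaced by water
(g3), holder replaced by water (g4), and a microSilicon-sized water point in
full water (g5). Then

$$k_{gap} = \frac{g_2}{g_1},\quad k_{al} = \frac{g_3}{g_2},\quad
k_{holder} = \frac{g_4}{g_3},\quad k_{vol} = \frac{g_5}{g_4},\quad
k_{tot} = \frac{g_5}{g_1}$$

and the product telescopes to $k_{tot}$ exactly — `perturbation_factors()`
verifies the identity to relative 1e-12 on every call. The orientation
(numerator = later geometry) is fixed by the physics: replacing PMMA with
the less-attenuating water raises the dose, so $k_{holder} > 1$, and the
air gap raises the shallow dose (less attenuation, more backscatter), so
$k_{gap} < 1$ near the surface. Factors are reported at pellet-centre
depths; a front-face convention would shift the grid by half a pellet
thickness and is easy to apply externally if needed. Both the 11 × 0.5 mm
physical pellet layout and the 16 × 0.44 mm layout used in transport
modelling are accepted configurations of `simulate_alanine_stack()`;
neither is canonical.

`volume_average_factor()` quantifies the $k_{vol}$-type correction for a
depth-only profile: point dose over slab-averaged dose across the 18 µm
active thickness, by adaptive quadrature at relative tolerance 1e-8 (the
radial average is trivial for an axial profile, so the disc reduces to a
slab).

## Curve analysis

* **Shallow extrapolation** (`extrapolate_shallow()`): polynomial
  regression of log-dose on depth, default order 2 over all measured
  depths. Log space because the curve is near-exponential, order 2 because
  one curvature term captures the CCB fall-off without chasing noise; both
  are arguments, and order ≥ number of points is rejected. Extrapolated
  points are flagged and carry `NA` uncertainty — no measurement
  uncertainty is invented below the measured range. Measured points are
  never refitted, so the extended curve is continuous at the junction by
  construction.
* **Normalization** (`normalize_curves()`): per-depth ratio with the
  reference interpolated linearly in depth; ratio uncertainty is the
  quadrature of the two curves' relative uncertainties.
* **Certificate agreement** (`certificate_agreement()`): a depth agrees
  when $|r - 1| \le k \sqrt{u_{meas}^2 + u_{cert}^2}/100$ with both
  uncertainties at k = 1 inside the quadrature and k = 2 outside by
  default, matching expanded-uncertainty reporting. The certificate's
  printed expanded value is scaled down by its own coverage factor first.
* **Calibration consistency** (`calibration_consistency()`): both the
  per-depth relative differences and their unweighted mean are reported,
  since which depths enter a single printed mean is rarely stated.

## The synthetic source model

`synthetic_model()` is the package's ground truth for testing:
$D(z) = D_0 e^{-az - bz^2}$ with defaults $D_0 = 0.1$ Gy/min (a typical
CCB surface dose-rate magnitude), $a = 0.2$/mm (the 2 % per 0.1 mm surface
gradient), $b = 0.01$/mm² (mild extra curvature, keeping log-dose strictly
decreasing on 0–10 mm). This family satisfies the surface gradient and
monotone decay and nothing more: it is **not** a model of real CCB
depth-dose curves. Real plaques add source-distribution heterogeneity
(hot spots up to ~25 % above average), Cherenkov-type detector effects and
positioning errors, none of which the generator emulates — so a passing
recovery test demonstrates the correctness of the processing algebra, not
field accuracy.

`simulate_session()` builds the full raw-data timeline: pre background,
forward pass, reverse pass, post background; 10 repeats per depth;
acquisition times interpolating linearly from 10 s at 2 mm to 60 s at
10 mm; source decay across the session clock; a constant additive
background rate (default 1e-4 reading units/s — backgrounds are described
qualitatively in practice, so a small constant is assumed); and mean-one
multiplicative lognormal reading noise. The ideal reading rate is
constructed as $D(z)\,2^{-\Delta t/T_{1/2}} / (N \cdot k_{Q,Q_0}(z))$
divided by the session correction factors, which makes the processing chain
an exact inverse of the generator at zero noise — the basis of the
end-to-end identity test (relative 1e-10 over all nine depths).

The default reading noise is 1.5 % per reading. This is a calibration of
the generator, chosen once: with 10 repeats and two directions, it yields
a per-depth repeatability estimate of ~0.5 %, the middle of the 0.3–0.8 %
band reported for this class of setup. The unbiasedness check runs at 0.5 %
noise over 200 seeded sessions (mean recovered/true ratio within three
standard errors of one); a mean-one lognormal is used so the multiplicative
noise itself introduces no bias.

`simulate_certificate()` applies a systematic vendor bias to the model
(default grid 0–10 mm, 11 % at k = 2); a +8 % bias reproduces the
"systematically lower than certificate yet within expanded uncertainty"
configuration, +30 % violates it. `simulate_geometry_chain()` divides the
model dose by injected factor profiles so that `perturbation_factors()`
recovers them exactly — an inversion property, tested over random smooth
profiles.

## Numerical conventions and degenerate inputs

Interpolation is linear everywhere (k-tables, budgets, cross-dataset
comparison) with hard range errors instead of extrapolation; quadrature
integrals use `integrate()` at relative tolerance 1e-8 (1e-10 for pellet
averages); regression uses `lm()` on raw polynomials in log space; rounding
is `signif()` (round-half-even). Validation failures, range violations and
file parse errors raise distinct condition classes
(`rudose_validation_error`, `rudose_range_error`, `rudose_parse_error`),
which the CLI maps to exit codes 1 (and 2 for usage errors). Timestamps are
POSIXct/UTC, ISO-8601 in files; decay arithmetic is in days. All file
formats are comma-delimited UTF-8 text with `# key: value` metadata lines,
round-tripping numerics at 12 significant digits.

Problem sizes in the test suite and acceptance script — 200 sessions for
the stochastic check, 50 for repeatability, 100 random chains for the
telescoping property — were chosen to give comfortable statistical margins
for the properties checked while keeping the suite quick to run.

## Known limitations

* No radiation transport: geometry doses, k-tables and phase-space-derived
  quantities are inputs, never computed here.
* Uncorrelated-quadrature budgets only; no sensitivity-coefficient
  propagation, no correlations.
* The comparison stage is property-based: real measured plaque dose rates
  are not published, so no test can assert agreement with actual CCB
  measurements — only internal consistency (self-normalization,
  antisymmetry, correctly signed agreement flags on constructed biases).
* Recombination corrections and electrometer driver I/O are out of scope.
* The synthetic family is central-axis only; off-axis profiles, plaque
  heterogeneity and detector-size effects beyond the axial volume average
  are not modelled.
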