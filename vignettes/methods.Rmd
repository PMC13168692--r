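---
title: "Methods: geometric vs 3D morphometrics and the bee heat budget"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric vs 3D morphometrics and the bee heat budget}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beemorph)
```

## The problem

Heat budgets for insects need body surface area (the interface for
radiative, convective and evaporative exchange) and volume (thermal
inertia). The traditional route estimates both from a handful of caliper
measurements by treating each tagma as an ideal solid; the empirical route
measures them on a calibrated 3D surface model of the specimen. `beemorph`
implements both routes, the statistics that quantify their disagreement, and
a steady-state heat budget that shows what a surface-area error does to the
inferred partitioning of heat loss.

## Geometric estimators

The solid assumptions are: head = cylinder, mesosoma = sphere, metasoma =
cylinder joined to a cone. The six measurements map to dimensions as

| measurement | role |
|---|---|
| m1 head width | head cylinder axis length |
| m2 head thickness | head cylinder diameter |
| m3 mesosoma width | sphere diameter |
| m4 metasoma width | cylinder and cone-base diameter |
| m5 tergite 1–3 span | cylinder length |
| m6 tergite 4–6/7 span | cone height |

Two conventions are genuinely underdetermined by the tradition and are
therefore explicit flags with documented defaults:

* **Head diameter.** Nothing forces m2 rather than m1 to be the cylinder
  diameter. We default to diameter = thickness (m2) because the transverse
  cross-section through the head's thickness is the smaller and more nearly
  circular one; `estimate_head(..., diameter = "width")` swaps the roles.
* **End caps.** The head cylinder is closed (two caps) by default, on the
  view that the estimate should be the total surface of the solid. The
  metasoma counts the cylinder lateral surface, one anterior cap and the
  cone lateral surface; the disc where cylinder and cone meet is interior
  and never counted. With m6 = 0 the cone degenerates continuously to a flat
  posterior cap, recovering a closed cylinder. Both choices are arguments
  (`caps`, `anterior_cap`).

Inputs must lie in (0, 100) mm — bees are under 40 mm, so anything larger is
almost certainly a unit mistake (µm or the caliper's display in hundredths).

## Mesh measurement

Surface area is the sum of triangle areas; volume is the divergence-theorem
sum of signed tetrahedra against the origin, |Σ v₁·(v₂×v₃)|/6, which is only
meaningful on a closed, consistently oriented surface. `watertight_report()`
exposes boundary-edge and non-manifold-edge counts, orientation consistency
(every shared edge traversed once in each direction) and the Euler
characteristic; `mesh_volume()` refuses open or inconsistently wound
selections rather than returning a silently wrong number. A tagma cut out of
a closed body leaves boundary loops; these are closed by fanning triangles
to the loop centroid (`cap_boundary_loops()`), the cap contributing to the
volume integral but never to external surface area — mirroring what
"the tagma's volume" means while keeping area strictly the outer surface.
Fan capping assumes roughly planar, star-shaped cut loops, which is what
plane-like tagma cuts produce; strongly non-convex loops would need proper
hole triangulation, which we do not attempt.

Degenerate faces (area < 1e-12 mm²) are dropped at construction with a
message. Calibration multiplies vertices by known/measured scalebar length
and re-checks three verification lengths at a default 2% relative tolerance;
failures abort listing the offending pairs. ASCII OBJ (face groups carry
tagma labels), ASCII PLY and ASCII STL are supported; STL carries no labels,
so label sidecars (face-index ranges) can attach them. Meshes are assumed
hair-free: surface reconstructions capture the body envelope, and hair's
thermal role is a boundary-layer effect that empirical exchange coefficients
already absorb.

## Comparison statistics

Percent error is |G − M|/M × 100 against the model (empirical) measurement;
the mean signed error keeps direction (negative = geometric underestimate).
Paired differences are gated by a Shapiro–Wilk test at α = 0.05: paired
*t* when normality is tenable, Wilcoxon signed-rank otherwise — both
statistics are always reported, so the gate only selects which p-value is
headline. The correction M = G·(1 − e)⁻¹ takes a *fraction*; the argument
name (`percent_error_fraction`) exists to block the ×100 bug, and the
round-trip G → e → M is exact whenever G ≤ M. Cohort-level correction uses
the mean percent error per tagma, and only for tagmata whose paired test is
significant — absent evidence of bias, the default is not to touch the
input (`correction_fractions(..., only_significant = TRUE)`).

## Allometry

Scaling fits are OLS of log₁₀(SA) on log₁₀(V); base-10 throughout (natural
logs would change only the intercept). Isometry (β = 2/3) is tested with a
Wald *t* on the slope, which for a single linear constraint is algebraically
the same as a linear-hypothesis F-test (the test suite cross-checks against
`car::linearHypothesis`). Slopes across measurement methods are compared
with a full log(V) × method interaction model; confidence intervals are
Wald at 95%. With two points the fit is saturated and CI/p are flagged
undefined rather than fabricated.

## Heat budget

Sign convention: gains positive, losses negative, so steady state is the
literal zero sum Q_M + Q_E + Q_R + Q_C = 0 and convection is defined as the
residual Q_C = −Q_M − Q_E − Q_R (not modelled mechanistically). Metabolic
and evaporative routes are linear in air temperature in mass-specific units
(mW g⁻¹) and scaled by body mass (default 0.0753 g, an average worker in
flight). Longwave exchange per tagma is

    [(a · ε_C · σ · T_i⁴) − (ε_S · σ · T_x⁴)] · SA

with defaults a = 0.98 (body absorptivity), ε_C = 0.90 (borosilicate glass
chamber), ε_S = 0.98 (body surface), σ = 5.67×10⁻⁸ W m⁻² K⁻⁴; T_i is the
chamber wall temperature, identified with air temperature, and T_x the
tagma temperature. Kelvin conversion (+273.15) happens only inside this
formula; mm² converts to m² and W to mW. All constants are overridable
(`radiative_constants()`). Because the formula is exactly linear in SA,
correcting a tagma's surface area by (1 − e)⁻¹ rescales its radiative term
by exactly that factor, and since Q_M and Q_E are method-independent, the
between-method difference in Q_C is exactly −(difference in Q_R) — both are
asserted in the tests.

The default grid is 20–50 °C in 5 °C steps. Route regressions fit
Q ~ T_air × method per route with sequential ANOVA; when the interaction is
not significant the additive model's method effect (an intercept shift) is
reported instead. The convection/radiation crossover is found on the fitted
magnitude lines (solving the 2×2 intersection), matching a regression-based
reading of the budget; a raw-grid interpolation variant is also exposed
(`method = "interpolated"`).

## The synthetic generator

No empirical coefficient sets or specimen meshes ship with the package;
everything is generated, deterministically, from a seed.

**Solid meshes.** Icosphere subdivision for spheres; regular angular
discretization (4·2^level segments) for cylinders and cones, with the
junction ring shared so composites are closed. Vertices are inscribed on
the ideal surface, so measured SA and V converge to the analytic values
*from below*, monotonically — a usable one-sided oracle. At the default
level 4 the sphere volume error is about 0.2%. The composite bee is three
disjoint closed solids whose analytic truths are computed by the same
closed-form estimators, guaranteeing identical cap conventions.

**Perturbation.** A seeded sum of four sinusoids of random-direction
projections displaces vertices radially from their component centroid.
Topology is untouched (watertightness preserved); with volume
renormalization, surface area is non-decreasing in amplitude. Amplitude is
capped at 0.3 of the local radius to avoid self-intersection.

**Cohorts.** Eleven specimens by default (a realistic collection-based
paired design), scale factors log-normal with σ_log = 0.06 (workers vary
little), baseline measurements of a typical worker (head 3.7×2.1, mesosoma
4.2, metasoma 4.3×3.1+2.8 mm). True ("model") tagma sizes inflate the
noiseless geometric values by (1 − e)⁻¹ with default fractions e of
head 0.26424/0.39298, mesosoma 0.44056/0.50261 (SA/volume) and a small
metasoma 0.05/0.05 — the torpedo-shaped metasoma genuinely resembles its
solid. Observed geometric values deflate the truth back and add log-normal
noise with σ_log = 0.12, chosen so the percent-error standard error at
n = 11 lands at a few points, the scale a paired caliper-vs-model study
actually shows. Shape scatter around the allometric line is σ_log = 0.04,
and the model's scaling exponent is a parameter (default 2/3). Whole-body
rows add appendage fractions (+43.627% SA, +16.272% V) on the tagmata sum.
What passing tests show is that the *statistics* recover injected truth at
these settings; they cannot show that real bees have these error
magnitudes — the generator emulates the error structure, not bee anatomy
(no hair, no appendage geometry, ideal-solid base shapes).

**Thermal presets.** The default synthetic set has metabolic heat declining
with air temperature, evaporative loss growing, and tagma temperatures
above air that converge as air warms — the qualitative structure of flight
thermal data. The `"crossover"` preset additionally tunes the metabolic
line (pivoting at 50 °C so the hot end is unchanged) by 1-D root finding
until the fitted |Q_C| and |Q_R| lines intersect at exactly 35 °C under the
supplied surface areas: a constructed geometry for testing crossover
detection, computed at call time, not a stored constant.

## Numerical choices and problem sizes

* Degenerate-face threshold 1e-12 mm²; calibration tolerance 2% relative;
  crossover root tolerance 1e-10 °C.
* Icosphere level 4 / 64 angular segments as the default tessellation:
  analytic error well under 1%, meshes of a few thousand faces that measure
  in milliseconds.
* Simulation-based checks use 100–300 seeded replicates of n = 11 cohorts
  (60 for the power check, 100 in the acceptance script, 200 in the
  acceptance tests, 300 for the isometry type-I rate), sizes at which the
  Monte-Carlo error is comfortably below the asserted margins while the
  whole suite runs in well under a minute.
* All generator randomness flows through explicit seeds; `perturb_mesh`
  saves and restores the global RNG state so mesh generation does not
  perturb a caller's random stream.

## Limitations

* No solar (shortwave) radiation: the budget describes a shaded chamber;
  adding insolation would require projected, not total, surface area.
* No conduction, no transient dynamics, no mechanistic convection model —
  Q_C is a residual and inherits every error in the other three routes.
* The shipped thermal coefficients are synthetic. Reproducing a specific
  empirical budget requires supplying the fitted coefficient sets for
  metabolic heat, evaporative loss and tagma temperatures via
  `thermal_model_set()` or the YAML config.
* Tagma label provenance is the user's: the package measures whatever
  partition the labels encode and does not infer cut planes.
* Binary mesh formats are out of scope; readers are ASCII OBJ/PLY/STL.
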