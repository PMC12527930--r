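---
title: "From carbonate budgets to water depths: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From carbonate budgets to water depths: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefrap)
```

## The problem

A reef tracks sea-level rise (SLR) only if its carbonate budget — gross
calcification minus bioerosion, `G` in kg CaCO₃ m⁻² yr⁻¹ — translates into
enough vertical accretion. The translation is not one-to-one: skeletal
carbonate accumulates post-mortem as framework whose void fraction (the
*stacking porosity* φ) depends strongly on the coral assemblage that
produced it. `reefrap` implements the complete chain from budget census to
projected above-reef water depth, with every stage testable against
generated data of known ground truth.

## Budget conversion

The maximum reef accretion potential is

$$\mathrm{RAP}_{max} = \frac{G}{\rho\,(1-\varphi)} \quad [\mathrm{mm\,yr^{-1}}]$$

with mineral density ρ = 2.9 g cm⁻³. The identity anchoring the units: a
budget of 2.9 kg m⁻² yr⁻¹ at zero porosity is exactly a 1 mm yr⁻¹ solid
slab; porosity 0.5 doubles the thickness. The conversion excludes physical
export and chemical dissolution — there are no reliable field rates for
either — so RAP_max is deliberately a *conservatively high* bound, and a
negative value means net framework loss.

Assemblage classes are assigned from species cover via a configurable
species-to-class map; a class takes the site when its share of total coral
cover is strictly above 0.6, otherwise the site uses the pooled `"mixed"`
porosity. The share is computed over coral cover only, which makes the
assignment invariant to uniform rescaling (e.g. cover expressed per
transect rather than per quadrat).

### Porosity defaults

The default scheme carries image-derived porosities for the three branching
classes (*A. palmata* 0.369, *A. cervicornis* 0.554, branching *Porites*
0.473) and the pooled mixed value 0.383. The four head-coral classes
(massive 0.26, submassive 0.31, encrusting 0.34, mixed branching/massive
0.375) are defaults chosen inside the 0.25–0.35 band reported for
massive-framework fabrics and constrained so that the unweighted mean of
the seven class means reproduces the pooled 0.383; they are placeholders
and should be overridden with measured values (`porosity_scheme()`,
`read_porosity_scheme()`) where available.

## Porosity from images

Virtual quadrats (~0.5 × 0.5 m) of fossil outcrop faces are binarized into
framework masks and porosity is the pore-pixel fraction, `1 − framework
fraction` — both are always reported, and they are exact complements.
Design choices:

- **Automatic threshold = Otsu** on the quadrat histogram (via
  `EBImage::otsu`). Manual brightness-adjust-then-threshold workflows are
  not reproducible; a manual `threshold` override is retained for
  replicating a particular operator choice. A constant-intensity image has
  no separable histogram and is rejected (`"degenerate histogram"`) rather
  than silently classed all-framework.
- **No clast-size filter in the estimator.** The ~5 cm delineation floor
  belongs to image preparation (and to the generator, which only draws
  clasts ≥ 5 cm equivalent); the estimator stays a pure pixel fraction.
- **Sample (n−1) standard deviations** per class, matching mean ± s.d.
  reporting; a single-image class reports `NA` rather than a fake zero.
- **Pooled mixed value = unweighted mean of class means**, not of all
  images, so unevenly sampled classes do not bias the pooled figure — the
  pooled value is therefore invariant to per-class image counts.

## Thermal stress

Degree heating weeks accumulate positive SST anomalies above the maximum
monthly mean (MMM) of a fixed 30-year climatology (1982-01-01 to
2011-12-31) over a trailing, inclusive 84-day window, divided by 7 to give
°C-weeks. Three deliberate choices:

- The anomaly threshold is **MMM itself**, not MMM + 1 °C: no hotspot
  floor is applied by default, since the accumulation is defined directly
  on anomalies above the warmest monthly temperature. `hotspot_floor = 1`
  restores the NOAA convention.
- The 12-week accumulation advances **daily** (trailing window); a
  `mode = "block"` alternative evaluates disjoint 84-day blocks, since a
  "per 12-week-period" reading is also defensible. The first 83 days use
  the partial window available.
- DHW is computed **on the multi-model mean SST series**, matching a
  forcing basis built from a single multi-model annual mean. A
  per-model-then-average order is available by composing `dhw_series()`
  over models, but is not the default; the two orders agree only when
  models are identical.

Warming (ΔT) and acidification (ΔpH) anchors are calendar-year
multi-model annual means minus the baseline-period mean, so both are zero
on average over 1982–2011 by construction.

## Projection to 2100

Coral cover follows an annual recursion
`C[y+1] = clip(C[y] + β₀ + β_DHW·DHW_max[y] + β_C·C[y], 0, 100)`.
The coefficients are configuration, not estimates; the shipped defaults
(β₀ = 0.3 % yr⁻¹, β_DHW = −0.12 % yr⁻¹ per °C-week, β_C = −0.01 yr⁻¹)
were chosen once so that SSP-like forcing drives cover toward zero around
2080 under all scenarios while allowing slow recovery in stress-free
periods.

At each anchor year (2040, 2060, 2100), budget components are rescaled
multiplicatively and independently:

- coral production by `(cover_t / cover_0)` times the coral calcification
  modifier `max(0, 1 + a·ΔT + b·ΔpH)` (cover ratio defined as 0 when the
  census cover is 0);
- CCA production, micro- and macro-bioerosion by their own modifiers;
- external (fish/urchin) bioerosion held static — there are no usable
  projections of grazer erosion under warming.

Modifiers are floored at zero: calcification cannot turn negative because
dissolution is excluded from the budget framework, and erosion cannot
reverse sign. No ΔT×ΔpH interaction term is fitted by default — the
response surfaces are modelled as additive in the two stressors — and the
site's porosity class is frozen at its census assignment through 2100 (no
assemblage-succession model; the mixed class would otherwise absorb every
degrading site and mask assemblage-specific signals). Default response
coefficients (per °C and per pH unit) are set to laboratory-scale
sensitivities for Caribbean calcifiers and borers and are replaceable
either directly (`response_model()`) or by fitting an experiment table
(`fit_response_model()`).

## Water depths

Cumulative accretion between anchors is the trapezoid integral of linearly
interpolated RAP_max (a `"step"` hold-previous mode bounds the sensitivity
to that choice; the anchor rates themselves are the only constrained
quantities). The depth increase at an anchor is SLR displacement since the
census epoch minus cumulative accretion — an exact identity the test suite
checks to 10⁻⁹ m on every synthetic site × scenario × anchor.

The 5–95 % envelope pairs the optimistic accretion variant (cover model
with the DHW slope halved) with the 5 % SLR quantile and the pessimistic
variant (slope ×1.5) with the 95 % quantile: perfect dependence, the
widest physically coherent band for the interaction of cover-change and
SLR uncertainty.

The restoration counterfactual adds a constant 4.8 mm yr⁻¹ — the region's
long-term Holocene accretion benchmark — to every anchor rate. Under
linear integration the depth dampening is *exactly* `4.8 mm × elapsed
years` (0.384 m over 2020–2100), independent of site, scenario and SLR
curve; this linearity is asserted, not assumed, in the tests.

Threshold exceedance uses strict `>` at 0.5 m (the boundary counts as
safe) — an arbitrary but fixed and documented convention.

## Cover–accretion regressions

Per-group OLS of RAP_max on percent cover, with groups mirroring the three
broad assemblage types (*A. palmata*-containing; massive-dominated;
submassive/encrusting/small-branched). The reported band is the 95 % CI of
the mean regression line, not a prediction interval. `invert_for_target()`
solves the fitted line for the cover sustaining a target accretion rate;
inversion composed with prediction is the identity for any non-degenerate
fit.

## The synthetic world

The generator exists so that every stage is testable without downloads; it
is first-class, seeded code, and its defaults are the study conditions:

- **Sites**: 429 across three subregions (Florida 113, Mexico 88, Bonaire
  228), censused 2016–2022. Florida draws no *Acropora* (reflecting its
  regional loss) and has low cover and low external bioerosion; Mexico and
  Bonaire retain minority *Acropora*-bearing sites and higher erosion.
  About 30 % of sites are mixed assemblages; the rest have a dominant
  class at a 70–92 % share. Coral production scales with cover at a
  class-specific rate (0.14–0.27 kg m⁻² yr⁻¹ per % cover, branching
  acroporids fastest), so cover–accretion regressions have recoverable
  slopes, and budget noise places a realistic share of sites in net
  erosion.
- **Quadrat images**: rotated ellipses (≥ 5 cm equivalent) are unioned
  until the framework fraction is within 0.005 of target, with
  overshooting proposals rejected and proposal sizes shrinking as the
  deficit closes; the greyscale rendering uses bright-framework /
  dark-pore means (200/60) with Gaussian noise (s.d. 18 by default).
- **Climate**: daily SST 1982–2100 per subregion, model and scenario —
  seasonal sinusoid, a warming ramp accelerating after 2005 to the
  scenario's 2100 magnitude (1.5/2.5/3.5/4.5 °C), fixed model offsets and
  AR(1) weather noise; annual pH declines by 0.1–0.4 units. The series
  fully covers the climatology baseline.
- **SLR curves**: monotone linear-plus-quadratic medians anchored at
  ~3 mm yr⁻¹ near present and 0.50–0.85 m at 2100, with a linearly
  widening 5–95 % fan.

What the generator does **not** emulate: spatial autocorrelation between
sites, 360-day model calendars, El Niño-like interannual clustering of
heat stress, storm-driven physical export, assemblage succession, and real
bathymetry. Tests passing on this world therefore validate the *machinery*
(identities, oracles, recovery of planted structure), not the regional
magnitudes of any real dataset.

## Numerical choices and degenerate inputs

- Nearest-grid extraction treats distances within 1 mm as ties and breaks
  them toward the lower row index; sites outside the grid's bounding box
  warn and use the nearest edge cell; land-masked cells error unless
  `widen = TRUE`.
- Ensemble means use the intersection of model time axes (warning when
  trimmed, error when disjoint).
- A paired scheme comparison with zero-variance differences (identical
  schemes) reports `t = NA, p = 1` instead of dividing by zero.
- Covers are percent in files and function interfaces; porosities are
  fractions; YAML schemes accept either and normalise at the boundary.
- Parameter-recovery checks assert the truth-within-2-SE rate against the
  nominal two-sigma level minus a one-sided binomial allowance for the
  number of replicates, rather than a hard 95 % on a finite sample.

## Problem sizes in the test suite

Module tests run on a 19-site world with 2–3 climate models; the
whole-system checks (conservation, restoration linearity, scenario
ordering) run on the full 429-site, four-scenario world; DHW is
cross-checked against its brute-force oracle on 1,000 random series;
porosity recovery uses 50 generated quadrats at 192 px and coefficient
recovery 100 seeded replicates. These sizes are the package's own choice
of a thorough-but-quick regime; all scale linearly if enlarged.

## Known limitations

- The cover model is linear with a single stress covariate: no thermal
  adaptation, no disease dynamics, no recruitment limitation, no
  hysteresis. It is a configuration surface for scenario analysis, not a
  demographic model.
- Budget responses extrapolate laboratory sensitivities linearly to 2100
  forcing levels.
- Porosity classes are static; a reef eroding to rubble would in reality
  change its stacking fabric.
- Depth outcomes ignore wave transformation, tidal datums and vertical
  land motion; the 0.5 m threshold is indicative, not a flood model.
- Published regional mean accretion rates cannot be recovered exactly from
  regional mean budgets alone, because the conversion is applied per site
  with site-specific porosities before averaging.
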