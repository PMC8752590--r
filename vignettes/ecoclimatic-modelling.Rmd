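---
title: "Ecoclimatic index modelling: methods and design notes"
author: "ecoclimex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ecoclimatic index modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoclimex)
```

## The modelling problem

Semi-mechanistic ecoclimatic niche models ask a different question than
correlative species distribution models: not "where does the climate
resemble places with records?" but "where does the annual climate cycle
permit population growth and year-round survival, given the species'
physiological tolerances?". The answer is summarised per location by the
Ecoclimatic Index (EI, 0–100): the product of an annual growth index and
annual stress survival terms, gated by a degree-day requirement. The
approach is the one popularised by the commercial CLIMEX platform;
`ecoclimex` is an open implementation of that index family, parameterised
here for the fall armyworm, a migratory noctuid crop pest whose invasion
risk is driven by warm, moist growing seasons, intolerance of frost, and
strong sensitivity to drought at the soil surface where pupation occurs.

## The weekly engine

All computation happens on a 52-week year of exactly 7-day weeks (days
365–366 are ignored; the simplification keeps every series a fixed-length
vector and is standard for this model family). Monthly climatologies are
converted to weekly series by linear interpolation between mid-month
anchors, evaluated at each week's mid-point day. Precipitation is first
converted to a daily rate (month total / days in month), interpolated as a
rate, then scaled by 7 — this preserves constant fields exactly and keeps
the annual total within a few percent of the monthly total for smooth
seasonal cycles (the residual comes from the 364-day working year and
linear interpolation; the package documents and tests a 5% bound). Linear,
not spline, interpolation is used: it is monotone between anchors, cannot
overshoot monthly extremes, and is trivially testable. How the commercial
engine derives weekly values from monthly climatologies is not published;
mid-month linear interpolation is this package's documented stand-in.

### Growth indices

The temperature index `TI` is a piecewise-linear trapezoid on the four
temperature thresholds DV0–DV3 (for the shipped fall armyworm profile: 12,
25, 30, 36 °C), driven by weekly mean temperature `(tmin + tmax)/2`. The
moisture index `MI` is the analogous trapezoid on SM0–SM3 (0.15, 0.8, 1.5,
2.0) driven by the weekly soil-moisture index. The exact internal response
curves of the commercial engine are unpublished; the trapezoid honours
every threshold semantic the parameter table defines (zero outside the
outer thresholds, optimum on the inner plateau, monotone ramps between)
and is the standard open approximation. The annual growth index is
`GI_A = 100 · mean(TI · MI)`.

### Soil moisture

Soil moisture is tracked as an index relative to a 100 mm holding
capacity: 0 is bone dry, 1 is field capacity, values above 1 represent
run-off/waterlogging conditions. The weekly balance is a single bucket,

```
SM_w = clamp(SM_{w-1} + (rain_w − E_w) / capacity, 0, smCap)
E_w  = evapCoeff · max(0, tavg_w) · min(1, SM_{w-1})
```

i.e. temperature-proportional evaporative demand, damped by moisture
availability, with no demand below 0 °C. The cap (2.5) deliberately sits
above the wet-stress threshold (2.0) so run-off stress can bind. The cycle
is spun up for two years from SM = 0.5 and the third year reported; for a
periodic forcing the iteration is a contraction, so the reported year is
numerically at the annual attractor (the interior fixed point satisfies
`rain = evapCoeff · tavg · SM*`, which the tests verify to 1e-6). The
bucket's constants (capacity, evaporation coefficient, cap, spin-up) are
all exposed in `soilParams()`. This bucket is this package's own design:
only the meaning of the SM index scale is fixed by the model family, not
the water-balance mechanics.

### Stress, degree-days, and EI

Each of the four stresses accumulates linearly in weekly exceedance:
`S = min(100, 100 · Σ_w rate · max(0, gap_w))`, where the gap is measured
below the threshold for cold (on weekly tmin, so stress sees the nightly
extreme) and dry (on SM), and above it for heat (on weekly tmax) and wet
(on SM). Rates are stored as magnitudes with the direction encoded
explicitly — parameter tables in this tradition print cold and dry rates
with a negative sign as a convention, which is an invitation for
double-negation bugs. The commercial engine compounds stress with an
unpublished annual-accumulation detail; the linear form preserves the
published semantics (zero below threshold, rate-proportional growth) and
is exactly testable. It is the main documented source of divergence from
any published global numbers, which is why this package's validation is
property-based rather than map-matching.

The composite stress index is `SI = Π(1 − S_i/100)`. Interaction stresses
(hot-dry etc.) exist in the index family but the fall armyworm profile
defines no interaction parameters, so `SX` is fixed at 1 and kept as an
explicit field for future profiles. Annual degree-days above DV0 accumulate
as `DD = Σ 7 · max(0, tavg_w − DV0)`; if DD falls below the per-generation
requirement PDD (400 degree-days here), EI is forced to 0 regardless of
growth. Finally `EI = GI_A · SI · SX`, clipped to [0, 100].

One parameter deserves a note: the dry-stress threshold SMDS defaults to
0.1 rather than the lower moisture threshold SM0 = 0.15 with which it is
sometimes equated; the shipped profile follows the tabulated value, and
the key is overridable in any parameter file.

## Irrigation scenarios

Scenario I adds `7 × 2.5` mm to any week receiving strictly less than
25 mm of rain — the additive reading of a "top-up" rule, applied
independently every week of the year. A week at exactly 25 mm receives
nothing (strict comparison). Whether such rules should instead top rainfall
*up to* a target is genuinely ambiguous in the literature; the alternative
is available as `mode = "target"` but is not the default. Scenario II is a
composite map: the scenario-I EI inside an irrigation-area mask, the
rainfed EI elsewhere — a risk surface for a landscape where only mapped
areas are irrigated.

Irrigation is not guaranteed to raise EI in general: on the wet limb of
the moisture trapezoid extra water can push SM past SM2 or into wet
stress. On the dry limb (SM never above SM1 under either run) it provably
cannot hurt, and the tests check exactly that conditional property.

## Classification, areas, performance

EI classes use the conventional half-open intervals — unsuitable (EI = 0),
marginal (0, 10], suitable (10, 30], optimal (30, 100] — applied to
unrounded EI. Areas are latitude-weighted with the spherical-segment
formula `R² Δλ (sin(lat₊) − sin(lat₋))`, R = 6371 km (about 343 km² for a
10-arc-minute cell at the equator, halving by 60° latitude); shares
partition the region exactly. Change tables report per-category percent
change against a baseline, with a category absent from the baseline marked
`NA` rather than an infinite change. Pest–host overlap sums the area where
both EI surfaces exceed 10 (both at least "suitable"). Performance
statistics extract the EI of the cell containing each occurrence record
(nearest-cell), report mean/median/sd, the proportion above EI 10, and a
10-bin histogram with fitted normal-curve parameters; records off-grid or
on nodata cells are excluded with a warning, never silently.

## Sensitivity and uncertainty

One-at-a-time sensitivity perturbs each parameter by ±δ and reports the
percent change in the potential range (area with EI > 0), plus signed
per-category changes. Default steps — ±1 °C for temperatures, ±0.05 for
soil-moisture thresholds, ±50% for rates, ±10% for PDD — are this
package's choices (the commercial tool does not publish its step sizes)
and are fully overridable. Perturbations that violate the threshold
orderings are skipped with a warning. A zero baseline range with a zero
perturbed range counts as 0% change; a zero baseline with a positive
perturbed range is undefined and reported `NA`.

The uncertainty map samples n parameter sets uniformly and independently
from per-parameter ranges (seeded; draws violating the orderings are
rejected and resampled) and reports per cell the percentage of sampled
models with EI > 0 — "proportional model agreement". Zero-width ranges
collapse the map to {0, 100}, matching baseline suitability exactly, which
is both a sanity check and a test anchor.

## Synthetic data: what it does and does not show

The generator produces five archetypal seasonal regimes (tropical wet–dry,
desert, mediterranean, cold continental, humid subtropical): sinusoidal
monthly mean temperature, a fixed diurnal range, annual rainfall spread by
a unimodal von Mises-style monthly weight, and independent per-cell
Gaussian noise. All synthetic cells are land; geography is the job of
masks. The preset parameters are calibrated fixtures, chosen once so that
the engine's qualitative signatures hold — tropical wet–dry optimal
(median EI > 30), desert unsuitable with positive dry stress, cold
continental unsuitable with cold stress at the cap yet a positive
midsummer growth window (the transient-population signature) — and they
are documented as such, not as climatology claims.

Passing tests on these grids demonstrates that the pipeline's mechanics
are correct: index arithmetic, stress accumulation, gating, scenario
composition, accounting identities. They do not demonstrate fidelity to
any real landscape; real climatologies have spatial autocorrelation,
coastlines, elevation gradients and humidity structure the archetypes do
not attempt, and published global risk maps additionally depend on
unpublished internals of the commercial engine that no re-implementation
can reproduce bit-for-bit.

## Numerical and interface choices

- Grids are cell-centre registered, WGS84, row 1 northernmost; occurrence
  points map to cells by `floor`, with points exactly on the outer
  south/east edge assigned to the last row/column.
- Raster I/O is ESRI ASCII (`.asc`, nodata −9999, 12-band stacks as
  `_01.._12` file suffixes), written with 17 significant digits so write →
  read round-trips are exact. All inputs of a run must share one grid; no
  reprojection is attempted.
- Occurrence thinning keeps the first record per cell in input order (a
  documented, deterministic tie-break) and is idempotent.
- Parameter files are flat `key = value` text; negative printed stress
  rates are accepted and stored as magnitudes.
- All generators and sampled stages are pure functions of their parameters
  and an integer seed; the engine itself is deterministic.
- Problem sizes in the shipped tests (50×50 grids, 1000-point occurrence
  sets, ~10–20 uncertainty samples) were chosen to exercise every code
  path at interactive speeds; the engine is vectorised across cells, and
  larger grids scale linearly.

## Known limitations

- No diapause mechanism, no interaction stresses, no humidity-driven
  growth: the shipped profile does not parameterise them.
- The stress accumulator is linear in exceedance; published maps from the
  commercial engine will differ quantitatively.
- The soil bucket is a single layer with temperature-proportional demand;
  it ignores radiation, wind and soil texture.
- Future climates are handled simply as alternative input grids; the
  package takes no position on emission scenarios or downscaling.
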