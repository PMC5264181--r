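---
title: "Salt-marsh stock accounting: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Salt-marsh stock accounting: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marshstocks)
```

This vignette is the package's account of the science it implements: the
stock and production models and their assumptions, the parameters that
matter, what the synthetic survey generator does and does not emulate, the
numerical conventions, and the design choices made where the underlying
field methodology left the design open.

## The accounting model

A *stock* is the amount of biomass or of an element (C, N or P) present per
unit area at a point in time (g m⁻², or Mg ha⁻¹ with 100 g m⁻² = 1 Mg ha⁻¹
exactly). A *production* is the annual range of a stock. The package
computes four stock kinds per species × site:

1. **Plant stocks.** Element content (% of dry weight) times dry biomass
   (g DW m⁻²), per compartment (aboveground = leaves and stems,
   belowground = roots and rhizomes). Litter is tracked as a biomass
   compartment for the seasonal dynamics analysis but excluded from plant
   element stocks, which cover living tissue only.
2. **Sediment stocks.** Content (%) × dry bulk density (g DW cm⁻³) × depth
   (cm) × 10⁴ cm² m⁻². The default depth is 25 cm, the maximum depth at
   which living belowground biomass is found in these marshes; it is a
   parameter (`depth_cm`) because root depth varies across systems.
3. **Annual sediment stocks** (for carbon: the carbon accumulation rate,
   CAR) substitute a sedimentation rate (cm y⁻¹) for the depth. The
   sedimentation rate is a *required input* with no default: it is
   site-specific and cannot be inferred from a vegetation survey, so
   `survey_stocks()` simply skips annual sediment stocks when no rate is
   supplied.
4. **Annual production**, the max–min estimator: replicates are averaged
   within each sampling date, and production is the maximum per-date mean
   minus the minimum. This estimator assumes the sampling dates bracket the
   true seasonal extremes; with bimonthly sampling, a sharp peak between
   two sampling dates is underestimated. Ties between dates are broken by
   the earliest date, so output is deterministic.

### Pairing biomass with contents

Field protocols leave open whether element contents are paired with biomass
per sampling date or as annual means. `mean_annual_plant_stock()` defaults
to per-date pairing — each replicate's stock is `content/100 × biomass`,
then per-date means, then the annual mean — because it preserves any
covariance between tissue content and biomass through the season. When
content is constant, per-date pairing collapses exactly to the simple
product `content/100 × mean annual biomass`, so the two orders can never
disagree on constant-content data; both are exposed through the `order`
argument. The reported standard error is the empirical SE of the per-date
stock means across dates, rather than first-order error propagation of the
product: it is simpler, directly testable, and captures the seasonal
variance a user actually sees.

## Upscaling and the stock table

Coverage tables record, per water body and marsh zone, the zone area (ha)
and the fraction covered by each species. A species' lagoon stock is its
mean per-area stock (averaged across surveyed sites) times its total
covered area. Two semantics matter:

- **Absent is not zero.** A species with no coverage rows in a water body
  contributes nothing there; totals sum over present entries only. An
  explicit zero is a measured zero.
- **Reference-marsh substitution.** Species not surveyed in the focal
  system can enter the table from a comparable reference marsh via
  `merge_reference_stocks()`; such entries must carry a non-empty
  provenance, are tagged `inferred`, may never overlap a measured species,
  and stay tagged through every report.

The assembled `stock_table` keeps per-species, per-compartment, zone and
grand totals as exact sums of its entries; the mid-high marsh share is
`100 × (grand − low-marsh total) / grand`, undefined (`NA`, with a warning)
for an all-zero element. Values are held at full precision and rounded only
in the markdown report (Mg to integers), matching how such tables are
printed.

The packaged fixture of published per-species lagoon stocks contains one
documented inconsistency: the printed sediment-N row total (36312 Mg)
disagrees with the sum of its own five components (36612 Mg), while every
species-level total and the grand totals are self-consistent. The fixture
therefore stores the per-species components and all totals are recomputed
from them; the printed row total is not used anywhere.

## The ordination toolkit

The seasonal-dynamics analysis operates on an observation × variable matrix
(one row per species × site × date × replicate) holding sediment
temperature, organic matter (LOI), pH, six particle-size fractions,
three biomass compartments, six plant element contents and three sediment
element stocks. The sediment stock variables (`S_C`, `S_N`, `S_P`) use a
thin 1 cm surface layer by default — they act as content-density indices in
the ordination, not inventory stocks — and the depth is a parameter
(`s_depth_cm`) because the choice is a convention, not a measurement.

Steps, all implemented in the package and cross-checked in the test suite
against independent implementations (`stats::cmdscale`, `vegan::adonis2`,
`vegan::wascores`):

1. `log(x + 1)` transform (variables span five orders of magnitude;
   the transform maps 0 to 0 and requires non-negative input). Columns are
   *not* standardised by default — the analysis convention here is
   transform-only — though a user can standardise before calling.
2. Euclidean distances.
3. PCO: Gower transform `A = −d²/2`, double-centring
   `B = (I − 11ᵀ/n) A (I − 11ᵀ/n)`, eigendecomposition. Axes are kept
   while `λ > 10⁻⁸ λ_max` (suppressing numerically-zero axes); variance
   explained is over positive eigenvalues only, the classical convention
   for Euclidean-embeddable input, where negative eigenvalues cannot
   occur — if the input is non-Euclidean the negative eigenvalues are
   reported in a warning rather than silently folded in. Axis signs are
   fixed deterministically (the largest-magnitude coordinate on each axis
   is made positive) so results reproduce across linear-algebra backends.
4. Weighted-average variable scores:
   `score(j, k) = Σᵢ xᵢⱼ uᵢₖ / Σᵢ xᵢⱼ`, undefined for an all-zero variable.
5. One-way PERMANOVA. `SS_T = Σ_{i<j} d²ᵢⱼ / N`;
   `SS_W = Σ_g Σ_{i<j∈g} d²ᵢⱼ / n_g`; `SS_A = SS_T − SS_W`;
   `F = (SS_A/(a−1)) / (SS_W/(N−a))`. The null distribution uses full
   uniform label shuffles (seeded; the identity permutation is not
   excluded) and the add-one convention
   `p = (1 + #{F* ≥ F}) / (1 + n_perm)`, so p can never be smaller than
   `1/(n_perm+1)` and the test is exactly valid under exchangeability.
   Degenerate inputs are flagged, not hidden: perfectly separated identical
   points give `F = Inf` (and permutations can still match it, so p stays
   honest); a fully constant dataset gives `F = NaN` with
   `degenerate = TRUE`. A negative within-group sum of squares — possible
   only through floating-point error — is clamped to zero with a warning.

## The synthetic survey generator

`generate_survey()` emulates the sampling design the analysis assumes:
two focal halophytes (*Juncus maritimus* at three sites, *Spartina
maritima* at two — the low marsh at the northern site being too fragmented
to sample), six bimonthly dates from February to December, three replicate
quadrats per date.

- **Seasonality** is a single-harmonic cosine,
  `peak × (1 − a/2 + (a/2)·cos(2π(month − peak_month)/12))`: the simplest
  shape consistent with a spring–summer maximum. A secondary December rise
  seen in some field series is deliberately not modelled; this is a
  documented limitation, and it means the generator's winter minimum is
  cleaner than real data's.
- **Replicate noise** is lognormal with unit mean and configured CV
  (biomass must stay positive); **contents** are normal truncated to
  [0, 100]; **LOI and pH** are uniform within configured ranges (field
  reports give ranges, not SDs, so the spread inside the range is a free
  choice, not an estimate); **particle-size fractions** are Dirichlet, so
  they sum to 100 exactly; **temperature** follows a seasonal cosine
  (8.5 °C December minimum to 22.2 °C June maximum) plus Gaussian noise.
- **Defaults** encode the qualitative field structure: belowground exceeds
  aboveground biomass with annual-mean ratios of 1.9 (*S. maritima*) and
  1.6 (*J. maritimus*), *J. maritimus* carries more biomass and litter and
  a more organic (LOI 12–28% vs 6–12%), less dense sediment. Peak biomass
  magnitudes (aboveground 500–1250 g DW m⁻², belowground 950–2000) and
  content means (plant C ≈ 36–38%, N ≈ 0.9–1.2%, P ≈ 0.12–0.15%; sediment
  C 2.5–6%) are set once at values typical of temperate Atlantic marshes.
- **Seeding** is hierarchical: one master seed is hashed with the stream
  labels (species/site/variable), so adding or removing a species never
  perturbs another species' draws — a property the test suite asserts.

`generate_coverage()` splits a configured total marsh area (default
4400 ha) across five water bodies with Dirichlet shares; a low zone exists
only in the three water bodies where the pioneer forms stands (so distinct
zone areas always sum to the total), the pioneer occupies only the low
zone, and the mid-high species share their zone with summed fractions kept
below 1 (uncovered area is bare sediment).

What passing tests on generated data therefore show: the estimators recover
known inputs under the design's replication and noise structure. What they
do not show: robustness to the features the generator omits — bimodal
seasonality, spatial autocorrelation between quadrats, tidal forcing,
content–biomass covariance (contents are drawn independently of biomass),
and measurement error in coverage mapping.

## Verification scale and known limitations

The test suite verifies the ordination code on random 8–20-point Euclidean
configurations against brute-force oracles and against `stats::cmdscale` /
`vegan::adonis2`; the permutation test's type-I error is calibrated on
1000 simulated null datasets of 12 observations with 999 permutations each
(rejection rate must fall in 0.05 ± 0.02); parameter recovery runs the full
generator → estimator chain over 100 seeds at the design's replication
(3 replicates × 6 dates). These sizes were chosen as the smallest at which
the properties are sharp.

Limitations worth knowing:

- The max–min production estimator is biased low whenever sampling misses
  the true extremes, and is noise-sensitive: with k dates the expected
  range of pure noise is positive, so production estimates from weakly
  seasonal series overstate true production.
- Upscaling propagates no uncertainty: lagoon totals are point estimates
  (per-area SEs are reported but stop at the per-area level), matching how
  such tables are conventionally published.
- The PERMANOVA is one-way with unrestricted permutations; nested or
  multi-factor designs (sites within species, repeated dates) are out of
  scope.
- Published per-area field results that depend on undeposited raw data or
  an unstated sedimentation rate (e.g. specific CAR values) cannot be
  recomputed; the package reproduces the published *lagoon-scale table*
  exactly from its per-species values and validates the *methods* on
  synthetic data instead.
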