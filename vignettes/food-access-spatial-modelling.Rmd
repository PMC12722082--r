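---
title: "Measuring culturally appropriate food access and modelling area-level diabetes rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring culturally appropriate food access and modelling area-level diabetes rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodaccess)
```

## The problem

Food-desert measures built on supermarket distance say nothing about whether
the food on offer is culturally appropriate. For Asian American and Native
Hawaiian or Pacific Islander (AAPI) communities, ethnic restaurants and
groceries are a major source of fresh and culturally preferred food, and
their availability may relate to cardiometabolic outcomes in ways a
supermarket-only measure cannot capture. `foodaccess` implements an
ecological, census-tract (CT) level workflow linking both kinds of access
measure to area-level AAPI diabetes rates, together with a synthetic county
on which every stage can be validated against known ground truth.

This vignette records the modelling choices, their assumptions, and what the
package's tests do and do not establish.

## Outlet classification

Outlets arrive as point records with a list of controlled category strings.
Classification is two-axis and rule-based:

* **Type** — precedence `excluded > restaurant > grocery > neither`. An
  outlet carrying any excluded category (non-food businesses, location-less
  services) is dropped; otherwise any category on the restaurant list makes
  it a restaurant; otherwise any category *containing* one of the grocery
  keywords (`grocery`, `farmer's market`, `food market`, `health market`) as
  a substring makes it a grocery; the rest are `neither`. Restaurant
  precedence over grocery reflects that the restaurant list is the first
  split in the coding scheme; it is a documented (not configurable-away)
  convention.
* **Content** — precedence `aapi > ambiguous > non_aapi`. One clearly AAPI
  category (a cuisine or food of the Asia-Pacific region) marks the outlet
  AAPI regardless of co-occurring generic terms — the intent is
  "majority-AAPI food". Generic terms that *may* cover AAPI food
  (`grocery`, `herbs & spices`, ...) mark it ambiguous; everything else is
  non-AAPI.

Category matching is exact string equality after lower-casing and whitespace
normalisation (substring matching only for the grocery keywords): the input
is a controlled vocabulary, so fuzzy matching would add failure modes
without adding coverage. Ambiguous restaurants and groceries **must** be
resolved through a two-column resolution table (`outlet_id`, `content`).
In the original workflow this step was a manual web review; externalising it
as an input file makes that review reproducible and auditable, and an
unresolved outlet is a hard error listing the offending ids rather than a
silent default. Outlets typed `neither` never need resolution because the
fifth group is not split by content.

The result is a partition: every retained outlet lands in exactly one of
{AAPI restaurants, non-AAPI restaurants, AAPI groceries, non-AAPI groceries,
neither}. The shipped `default_lexicon()` covers common category names and
the generator's vocabulary; real registries carry hundreds of categories and
users are expected to extend it.

## Access measures

Six ethnic-store variables summarise three aspects of tract-level access,
plus two supermarket-distance shares:

| measure | definition | zero-denominator rule |
|---|---|---|
| `rest_ratio`, `groc_ratio` | AAPI : non-AAPI count | 0/0 → 0; k/0 → missing |
| `rest_per_aapi`, `groc_per_aapi` | AAPI outlets / AAPI population | 0/0 → 0; k/0 → missing |
| `rest_intensity`, `groc_intensity` | tract share of county AAPI total | all-zero county → 0 + warning |
| `fara_ct`, `fara_aapi` | % of (total, AAPI) population beyond the distance threshold | zero population → missing |

Zero-denominator ratios are *missing, not zero or infinite*: a tract with
three AAPI restaurants and no non-AAPI ones is not comparable to one with
none of either, and coding either case 0 would conflate them. Missingness
flags accompany every such value, and the regression stage uses listwise
deletion (logged).

The distance share uses representative population points (default 25 per
tract on a jittered sub-grid, each carrying an equal population share) and
Euclidean distance to the nearest supermarket with a ½-mile threshold
(804.672 m in a metre-based projected plane). This is a population-point
approximation to gridded population placement; it is straight-line by
design — at sub-mile scale the reference atlas is also straight-line-based.
Because the generator splits total and AAPI population equally across the
same points, the two shares coincide *on synthetic data*; on real data,
where AAPI population concentrates in sub-areas of a tract, they differ.
The Spearman screen consequently drops one of the pair on synthetic runs,
which conveniently mirrors the screening behaviour seen with real data.

Point-in-tract assignment is by point-in-polygon with boundary points
assigned to the covering tract with the lexicographically smallest id — an
arbitrary but deterministic tie-break.

## Rate downscaling

Disease counts arrive as SRA-level yearly case counts with small cells
suppressed. The chain is:

1. **Average first**: yearly counts are averaged over the reporting window
   (default 7 years) before any rate is formed.
2. **Reallocate the residual**: the county mean annual total minus the sum
   of reported SRA means is split among suppressed SRAs in proportion to
   their AAPI populations. A negative residual (reported exceeding the
   county total) is a data-consistency error, not something to clamp.
3. **Apportion cases to tracts** by the tract share of SRA AAPI population,
   then convert to rates per 100,000. Apportioning *cases* (not rate
   values) is the interpretation chosen where the source description is
   ambiguous: it is the one that satisfies the stated constant-rate
   assumption — every populated tract inherits exactly its SRA's rate — and
   it conserves cases exactly. Fractional cases are retained; rounding
   would break conservation. Zero-AAPI tracts get rate 0 with a
   `zero_pop` provenance flag, and each tract row records whether its SRA
   was `reported` or `reallocated`.

Reallocation operates on the mean-annual scale. The alternative — summing
totals over the window, reallocating, then annualising — gives the same
answer up to the fixed factor of the window length, since both the county
total and the reported sums scale together; the mean-annual convention is
used because rates are annual.

## Spatial statistics

**Weights.** Queen contiguity connects tracts sharing at least one boundary
point (a single corner suffices). Adjacency is detected by snapped shared
ring vertices plus a vertex-on-edge test; this is exact for tiling polygons
(the generator's grid, typical census geographies) but would miss contact
between polygons that touch only in the interior of both edges with no
vertex involved — a case that does not arise in tract tilings. kNN weights
(default k = 8) take each tract's k nearest centroids, directed, ties
broken by smaller id; asymmetry is left as-is because kNN weights serve
only the residual diagnostics, never the spatial-lag likelihood. Row
standardisation divides each nonempty row by its sum; islands survive as
empty rows (with a warning at construction, and a hard error if they reach
the spatial-lag fit).

**Moran's I** follows the standard cross-product form; under the null its
expectation is −1/(n−1). Two inference routes: the Cliff–Ord normal
approximation (analytic moments under normality), and a permutation test
(default 999 draws, explicit seed) with pseudo p-value
`(1 + #{|I_perm − E| ≥ |I_obs − E|}) / (B + 1)` — two-sided by distance
from the null expectation, bounded below by 1/(B+1). Permutation is the
default because the downscaled rates are emphatically non-normal (piecewise
constant across SRAs); the normal route is used in simulation loops for
speed. Missing values are dropped listwise with the weights subset and
re-standardised.

**Screening.** Spearman correlations (pairwise-complete) feed a greedy
screen: scanning pairs in column order, whenever |ρ| > 0.90 the later
column is dropped. The screen is order-dependent by construction; the
pipeline lists the preferred representative of each measure aspect first so
the survivor set matches the analysis intent. Constant columns have
undefined correlations and never trigger drops.

## Regression

`fit_ols()` is least squares with t-based intervals and the Gaussian ML
log-likelihood (σ² at its ML value, so the OLS log-likelihood equals the
spatial-lag log-likelihood at ρ = 0). `fit_slr()` fits
`y = ρWy + Xβ + ε` by maximum likelihood:

* log-determinant via the eigenvalues of W, computed once and reusable
  across fits under the same weights (the eigenvalue route is right for
  n in the hundreds; larger problems would want sparse/Chebyshev
  approximations, deliberately not implemented);
* concentrated likelihood over ρ through the two-residual decomposition
  `e(ρ) = e0 − ρ e_d`, maximised by Brent search on `(1/λ_min, 1)` to
  tolerance 1e-8 (the upper bound is 1 for row-standardised weights);
* β and σ² in closed form given ρ̂;
* standard errors from the observed information — a central-difference
  numerical Hessian of the full log-likelihood at (ρ̂, β̂, σ̂²) with step
  1e-5·max(1, |θ|) — and two-sided normal-approximation (Wald) p-values.
  `rho_fixed` fits the profile at a fixed ρ instead, enabling
  likelihood-ratio comparisons; `rho_fixed = 0` reproduces OLS exactly.

AIC counts the regression coefficients plus ρ and σ². The exposure and
covariates (default: population density, percent obese, percent over 65)
are z-scored; the outcome stays on its natural scale, so a coefficient is
the rate change per 1 SD of exposure. The outcome's spatial lag `Wy` is on
the outcome's own scale.

`run_model_battery()` fits one OLS and one SLR per surviving exposure,
tests OLS residuals for spatial dependence under both queen and kNN
weights, flags exposures whose OLS inference is suspect, and sorts the
report AIC-best first. A failing exposure yields an NA row with a warning
rather than aborting the battery.

## The synthetic county

The generator exists so that the full pipeline — including suppression and
reallocation — can be exercised with known truth. Defaults describe a
mid-size urban county and are fixed once:

* 25 × 25 = 625 square tracts of 2 km side, in 25 SRAs of 5 × 5 blocks
  (square grids exercise queen corner-adjacency and SRA nesting; real
  geographies load through the same GeoJSON reader);
* tract population log-normal (median 5000, sdlog 0.4); AAPI share
  Beta(1.5, 12) (mean ≈ 11%); percent over 65, percent obese and percent
  below 200% FPL as truncated normals around 14.4, 23.3 and 30;
* outlets Poisson with 3.7 per 1000 residents (≈12,000 county-wide),
  placed uniformly within tract; the probability that a restaurant/grocery
  is AAPI follows a logistic curve in tract AAPI share with slope
  `aapi_outlet_affinity` (default 2); ≈30% of groceries carry only generic
  categories and are content-ambiguous, with their true content emitted as
  the resolution table; a few percent are excluded-category records.
  Poisson counts are the standard choice absent any stated distribution;
* supermarkets Poisson with 1.2 per 10,000 residents;
* latent tract rates `y = (I − ρW)⁻¹(Xβ + ε)` with ρ = 0.5,
  β = (1.5, 10, 7) on the z-scored covariates and ε of SD 22 (rate units
  per 100,000), shifted by |min| + 0.5 so rates are positive — rates cannot
  be negative and the model is linear, so a level shift (absorbed by the
  intercept under row-standardised W) is the least intrusive repair;
* expected annual tract cases `rate × pop_aapi / 1e5`, yearly counts
  Poisson over 7 years, summed to SRA; SRAs with mean annual count below
  11 (a common public-health small-cell rule) are suppressed. The rate
  scale was chosen so SRA mean annual counts straddle that threshold —
  county mean annual totals in the hundreds, reported SRAs in the tens,
  a realistic minority suppressed — matching the arithmetic of published
  county-level case totals rather than any single narrated mean.

All randomness flows from one root seed through fixed per-stage substreams,
so identical configurations give identical counties.

**What the generator does not emulate:** street networks or travel-time
distance, realistic coastline/irregular tract shapes, within-tract
clustering of AAPI population (hence the synthetic coincidence of the two
distance shares), spatially structured covariates, and registry noise such
as miscoded categories or stale listings. Passing tests therefore establish
the *correctness of the computations* under the stated model, not the
substantive conclusions one would draw from any real county.

## Numerical and validation notes

* Moran's I is checked to 1e-12 against a brute-force double sum and
  against an independent implementation (`ape::Moran.I`); OLS to 1e-10
  against the normal equations; the Brent ρ̂ to 1e-3 against a 1e-4-step
  grid search of the concentrated likelihood at n = 400.
* Case conservation (tract → SRA → county) holds to 1e-9 relative.
* Simulation calibration at the generator's own conditions: 95% Wald CIs
  cover ρ = 0.5 and β in ≥90% of 100 counties of 400 tracts; with no true
  effect the OLS exposure test rejects at ≈5% (1000 simulations), and
  residual Moran's I on correctly specified non-spatial models rejects at
  ≈5% (500 simulations, n = 225). Problem sizes were chosen as the
  smallest at which these frequency properties are stable.
* Degenerate inputs are errors, not guesses: zero-variance vectors in
  Moran/correlations/z-scores, rank-deficient designs (naming the collinear
  columns), islands reaching the SLR, negative residuals in reallocation,
  tract populations inconsistent with their SRA total.

## Known limitations

* Wald p-values for the SLR (a likelihood-ratio route is available through
  `rho_fixed`); no spatial error or Durbin models, no impact
  decompositions, no local Moran.
* The queen detector assumes boundary contact involves a vertex (true for
  tilings); the eigenvalue log-determinant limits comfortable n to a few
  thousand.
* Downscaled rates are constant within SRA by construction; models on them
  inherit that block structure, and ρ̂ on downscaled (as opposed to latent)
  rates is correspondingly inflated. This mirrors the real analysis's
  stated assumption and is flagged in the battery output rather than
  hidden.
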