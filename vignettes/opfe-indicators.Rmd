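---
title: "Measuring the takeaway food environment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the takeaway food environment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opfetf)
```

# The measurement problem

Counting food outlets per area treats a salad bar and a fried-chicken shop
as interchangeable exposures. Online delivery platforms record the menu:
each single-meal product, the food groups it contains, whether it carries
unhealthy proxy foods, and how many times it sold in a month. `opfetf`
turns those records into outlet-level impact indicators and maps their
spatial pattern. This vignette documents the models, every tunable
parameter, the synthetic data generator, and the choices made where the
design was genuinely open.

# Classification

The two-level taxonomy (3 Level I, 14 Level II categories) is shipped as a
CSV registry (`inst/extdata/taxonomy.csv`). Meals are classified from their
item categories by three rules: a single Level II category names the meal;
equal Level I quantities give priority to the smallest Level I code (Meal
before Snacks and Beverage before Other) and take the modal Level II code
within it; otherwise the overall modal Level II code wins.

Open points we had to fix:

- **"Same or similar quantities"** is operationalized as *exactly equal*
  Level I counts by default. A relative tolerance (`level1_tol`, default 0)
  widens the tie window to `max - min <= tol * max` for users who want
  "similar" to mean something looser; no principled value exists, so the
  default is the strictest reading.
- **Modal ties** break to the smallest Level II code under natural ordering
  (Level I number, then suffix number). Any fixed rule would do; this one
  is deterministic and mirrors the Level I priority direction.
- **Items, not grams.** Classification counts item occurrences; weights are
  not part of the classification inputs.

Outlets take their single meal type, else the modal type subject to a
dominance check: the max/min category-count ratio (MMR) must reach
`mmr_cutoff` (default **1.5**, exposed in every entry point). The cutoff is
*provisional* — it is a tuning parameter of the classification system with
no theoretical derivation — and an exact tie or a failed check yields
Unknown (`3-1`).

# Meal scores

The healthy score is `l = j_fried + j_sugar + j_salt`, each indicator 1
when the meal contains the proxy food. Missing labels raise an error rather
than imputing 0: silent imputation would systematically understate
unhealthiness. DDS counts distinct food groups over the 12-group registry
(`inst/extdata/food_groups.csv`); a meal with no food groups is invalid
(diversity of "no food" is meaningless), so valid DDS lies in 1–12.

## Normalizing DDS and its reciprocal

The impact indicators need DDS (and its reciprocal) on a common, bounded
scale. The source construction says only "normalized", so the scheme is a
package decision:

- **Default `"max"` scaling**: divide by the maximum, i.e.
  `(1/dds_i) / max_k (1/dds_k)` and `dds_i / max_k dds_k`. Values lie in
  (0, 1]; every meal keeps a positive weight.
- **`"minmax"`** is available for sensitivity analysis but is *not* the
  default because it maps the most diverse meal's reciprocal weight to
  exactly 0, erasing that meal's sales from TUHII/UHII entirely.

Normalization is computed over the **full post-exclusion meal set**, not
per outlet: the impact sums run within outlets, but a dataset-wide scale is
what makes outlets comparable. The same scheme is applied to both the DDS
and reciprocal-DDS weights; we found no reason to treat them differently.

# Outlet indicators

With `l_i`, normalized weights and monthly sales `S_i` over an outlet's
meals:

- `W = N_h / N_t`, the healthy-meal fraction;
- `TUHII = Σ l_i · r_i · S_i` (r = normalized reciprocal DDS) — healthy
  meals contribute nothing;
- `HII = Σ d_i · S_i` (d = normalized DDS), defined only when `W = 1`;
- `UHII = Σ r_i · S_i`, defined only when `W < 1`. **UHII deliberately
  includes healthy meals' terms**: the defining sum carries no healthy-score
  factor, so an unhealthy outlet's popular healthy meals still add to its
  unhealthy-group impact. This surprises users but is the faithful
  construction; TUHII is the variant that zeroes healthy meals.

Exactly one of HII/UHII is defined per outlet, so healthy and unhealthy
food environments can be compared side by side.

## Standardization and grouping

Z-scores use the sample (n−1) standard deviation. The standardization
population follows the analysis groups: `z_TUHII` over all outlets,
`z_HII` within the healthy subset, `z_UHII` within the unhealthy subset —
each group is analysed separately downstream, so each gets its own scale.
Quartile labels follow the lower-closed chain (top label at `x ≥ q75`,
then `[q50, q75)`, `[q25, q50)`, `< q25`), for `W` as `H/rH/ruH/uH` and for
standardized indicators as `Q4..Q1`. Sample quantiles use linear
interpolation (R type 7) by default; the type is exposed
(`quantile_type`) since no convention was prescribed. With constant input
the chain forces every value into the top label; the package warns rather
than errors, since downstream code can still proceed.

Group differences use Levene's test centered at the mean (the classic
form) as a gate at 0.05: homoscedastic data go to one-way ANOVA, otherwise
Welch's ANOVA. Groups with fewer than two observations are dropped with a
warning. No multiple-testing correction is applied across category
comparisons.

# Spatial analysis

- **Weights.** `w_ij = 1/d_ij^p`, default `p = 1`, no distance cutoff
  (both configurable). Coincident points (two outlets at the same address)
  get a distance floor of 15 m — half the default raster cell — to keep
  weights finite; the floor applies only to zero distances.
- **Moran's I** uses the standard cross-product form with expectation
  `−1/(n−1)`. Significance defaults to the randomization-variance
  (Cliff–Ord) normal approximation; a permutation test (999 relabellings,
  two-sided pseudo p) is available where the normal approximation is
  doubtful. Both are implemented in-package and verified against a
  brute-force double-loop evaluation in the test suite.
- **Kernel density** uses the quartic kernel
  `K(d) = 3/(πh²)(1−(d/h)²)²` on a 30 m grid by default, padded by one
  bandwidth around the points. The kernel integrates to one, so the surface
  mass approximates the summed point weights (verified to 2% on fine
  grids). The bandwidth default is a Silverman-style rule
  (`pooled sd × n^(−1/6)`, floored at 5 cells) because only the resolution,
  not the bandwidth, was prescribed.
- **Polygon aggregation** joins outlets to subdistrict polygons by
  ray-casting point-in-polygon with boundary points counted inside; a point
  on a shared boundary goes to the *first* matching polygon in file order —
  deterministic and order-documented. Outlets outside all polygons go to an
  `unassigned` bucket so totals are conserved exactly.
- **Counting method & comparison.** Per-polygon outlet counts (all /
  healthy `W = 1` / unhealthy `W < 1`), z-standardized across polygons, are
  compared with per-polygon indicator sums by Spearman rank correlation
  (exact p where untied, t-approximation with ties).
- **CRS.** Inputs in lon/lat are projected with a local equirectangular
  projection centred on the data centroid. Over a city-scale study area
  (tens of km) its distance distortion is under 0.1%, well below the 30 m
  raster resolution; a full projected CRS library would add nothing at this
  scale. Density surfaces are exported as plain-text ESRI ASCII grids
  (`.asc`), a single-band raster format any GIS reads.

# The synthetic data generator

No delivery-platform crawl can be redistributed, so the generator *is* the
test bed. `default_paperlike_config()` encodes the study conditions the
package emulates:

- **800 outlets** in a 5 × 2 grid of 2 km subdistrict polygons (10
  subdistricts), 10–35 meals each (≈ 18,000 meals), placed uniformly.
- Outlet types ST/ND/SET/WFF/HLR/UN with mixture
  (0.12, 0.30, 0.30, 0.08, 0.10, 0.10): set meals and noodles dominate,
  mirroring the menu mix such platforms show.
- Per-meal-category unhealthy-label probabilities chosen so the expected
  healthy scores order **HLR (0.14) < ND (0.30) < overall < ST (0.64) <
  WFF (0.79)**, and food-group count `1 + Binomial(11, p)` so expected DDS
  orders **ST (4.6) < ND (4.7) < overall < WFF (5.6) < HLR (6.3)**. These
  are emulation parameters reproducing the qualitative structure, not
  claims about any particular market.
- **15% exclusively-healthy outlets** (`healthy_outlet_rate`): meal labels
  are not independent across a menu in reality — some outlets simply sell
  no unhealthy food — and without this outlet-level heterogeneity the
  healthy group (`W = 1`) would be practically empty at 10–35 meals per
  menu.
- Log-normal monthly sales (meanlog 4.3, sdlog 0.8; WFF 4.8 — western
  fast-food sells more per product), food-group inclusion weights per
  category (HLR favours vegetables/fruits/pulses), a 2% exclusion-flag
  rate, and 80% own-category menus (UN outlets draw uniformly, so their
  menus classify to Unknown).
- An optional **planted cluster** overrides the type mixture and scales
  sales inside one polygon, giving spatial detection tests a known ground
  truth.

What the generator does *not* emulate: spatial clustering of outlets along
streets, price, menu churn over time, correlated label noise from photo
interpretation, and within-polygon density gradients. Passing tests
therefore show the estimators recover structure *of this kind*; they are
not a validation against real platform data.

## Problem sizes in the test suite

The acceptance-style checks run 20 replicates of the full 800-outlet
pipeline for the ordering recovery, 50 replicates of a 300-outlet planted
cluster for density-peak detection at 30 m resolution, 100 random ≤50-point
instances for the Moran oracle and 1,000 outlets for the aggregation
oracle. These sizes give comfortable statistical margins (the ordering gaps
are tens of standard errors at n ≈ 18,000 meals) while keeping the whole
suite around two minutes.

# Record exclusion

Records are excluded by the ten upstream-assigned flags (i–x: sauce
ingredients, separate beverages, concomitant food, POT/fried-BBQ/seafood
categories, group meals, separate dishes, delicatessen items, single
soups, non-Meal items, unrecognizable) plus the meal-category restriction
to the five analysable types (ST, ND, SET, WFF, HLR). Recognizing, say, a
"group meal" from its name is human interpretation and happens upstream;
the filter is flag-driven. Category-based drops are attributed to rule iv
(POT/F_BBQ/SF), ix (snacks and beverages) or x (unknown), and every
excluded record is attributed to exactly one rule — the first matching in
i–x order — so exclusion reports partition the drops.

# Known limitations

- The MMR cutoff (1.5) is provisional; sensitivity of outlet categories to
  it should be checked on real data.
- The healthy score rests on three proxy labels; it cannot see oil, salt
  or sugar quantities, and label errors propagate linearly into TUHII.
- Moran's I here is global; no local indicators (LISA) or buffer-based
  neighbourhoods are provided.
- The equirectangular projection is inappropriate for continental-scale
  extents; supply projected coordinates in that case.
- Single-meal DDS is used as a nutrition proxy although DDS was designed
  for daily/weekly individual intake; the mapping between the two is an
  open research question, not a package setting.
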