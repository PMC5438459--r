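---
title: "Modelling resource load, availability, and gaps for ASD diagnostic services"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling resource load, availability, and gaps for ASD diagnostic services}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resourcegaps)
```

## The problem

Autism spectrum disorder is diagnosed at facilities that are scarce,
spatially clustered, and often oversubscribed. Two questions drive this
package: *how far* do families live from the nearest diagnostic center, and
*how much demand* does each center face relative to what it can serve? The
pipeline answers both on simulated populations: census-style region tables
give where people live in aggregate; Monte-Carlo placement turns them into
individual locations; assignment rules turn locations into center
catchments; and the metrics turn catchments into per-center loads, a
location-indexed availability surface, and a gap map.

## Geometry

All distances are great-circle distances computed with the haversine formula
on a sphere of radius 6371.0088 km (the IUGG mean radius). No ellipsoid is
used: the sub-0.5% error of a spherical earth is far below the dominant
error source, which is pretending that populations are uniform within their
regions. Radius comparisons are inclusive (`d <= radius`), nearest-center
ties are broken by smallest `center_id`, and longitudes are normalized to
[-180, 180); longitude differences are taken on the circle, so the
antimeridian needs no special handling.

Each region is modeled as a disc of the region's land area centred on its
centroid, `R = sqrt(A/π)`. Points are sampled uniformly per unit area (the
`sqrt` transform on the radial coordinate) and placed with the exact
spherical destination formula, so a sampled radial distance *is* the
haversine distance to the centroid. Treating the disc's area as locally flat
is valid for `R` up to roughly 500 km — far beyond any county-scale region —
and degenerate discs (`A = 0`) collapse to the centroid rather than erroring.

## Placement and assignment

`place_population()` draws `round(population × sampling_fraction)`
individuals per region. The sampling fraction is a desk-scale device: 1.0
simulates every recorded resident, smaller values keep national-scale tables
tractable. Rounding is round-half-to-even so halving the fraction halves
expected totals exactly and totals are reproducible. Regions with
population 0 simply contribute nobody.

Two assignment rules are implemented because the two analyses need different
things:

- **Nearest** (`assign_nearest()`), for distance-to-care summaries: the
  quantity of interest is the distance to the *closest* option.
- **Tiered random** (`assign_tiered_random()`), for load estimation: real
  families do not deterministically pick the closest center, so each
  individual is assigned uniformly at random among the centers within the
  smallest radius tier — 25, 100, 500, 3000 km by default — that contains at
  least one center. Tier escalation is per-individual: each person's tier is
  the smallest radius serving *them*. Uniform choice (rather than
  distance-weighted) is the deliberate minimal reading of "random
  assignment among nearby centers".

Synthetic geographies cannot guarantee a center within 3000 km of everyone,
so individuals beyond the largest tier are assigned to their nearest center
with `fallback = TRUE` — flagged and reported, never dropped, so assignment
always partitions the population and per-center counts always sum to the
individual count.

## The metrics

**Resource load.** `RL = (N·p)/(s·o)` is an annual demand-to-capacity ratio.
The defaults are field estimates: `s = 5` specialists per center, `o = 200`
patients per specialist per year, and `p = 0.195%` of the population needing
a screening, derived as 6.5% (population at a diagnosis-appropriate age) ×
3% (fraction of those needing screening) by `derive_screening_fraction()`.
RL is linear in `N`: a center serving 512,821 people faces ~1000 requests —
exactly its 1000-per-year capacity, `RL = 1` — while 3,076,923 people mean
`RL = 6`, six-fold overload.

When the pipeline runs on a down-sampled population (`run_pipeline()`,
`analysis/03_resource_load.R`), catchment counts are scaled back up by
`1/sampling_fraction` before computing RL, so loads estimate the full
population's demand, not the sample's; a diagnosed convenience sample, when
present, is excluded from demand because it is a biased subsample of people
already counted in the regional populations.

**Resource availability.** The availability at a location sums each center's
contribution, down-weighted by that center's load and by distance:

`RA_l = Σ_r w(RL_r) · decay(d(r,l); z)`

The implemented default is the minimal form satisfying the properties the
metric is defined by — summation over resources, down-weighting by load and
by distance, and "one adequate resource within reach ⇒ RA = 1":

- `w(RL) = 1 / max(RL, 1)` (`clamp_load_floor = TRUE`). The clamp encodes
  that availability measures *access*, not surplus: a half-empty center still
  provides at most one center's worth of access. The unclamped `1/RL` is
  selectable for sensitivity analyses (note it diverges as RL → 0).
- `decay(d; z) = 1` for `d ≤ z`, else `z/d` (`capped_inverse`). Exact at the
  boundary, no division at `d = 0`, and heavy-tailed — distant centers
  contribute a little rather than nothing. `exponential` (`exp(-d/z)`) and
  `hard_cutoff` are selectable alternatives; the capped-inverse tail means
  that in a geography with many centers even remote locations can sum past
  1, which the hard cutoff avoids at the cost of discontinuity.

`z = 30` km is the willingness-to-travel distance for a diagnosis, chosen
because roughly 70% of diagnosed individuals in comparable distance analyses
live within 30 km of a center; it is a `metric_params()` field, not a
constant. A **resource gap** is `RA < 1`, strictly: `RA = 1` — exactly one
adequate reachable center — is not a gap.

**Distance summaries** report mean, sample SD (n−1), median (midpoint
convention for even n), maximum, and the percentage within `z` (inclusive).
Sample SD and the midpoint median are conventions chosen here; nothing in
the metric definitions forces either.

**The availability grid** is an axis-aligned lat/lon lattice (default 0.25°,
no projection), `ceiling(span/resolution) + 1` points per axis so both bbox
edges are included, each point evaluated exactly like a single-location
call; gap flags come from the same strict threshold, so the grid and
point-wise calls can never disagree.

## The synthetic scenario generator

The generator emulates the statistical structure the analysis assumes of
real data, with one master seed and deterministic per-stage substreams so
any stage can be regenerated independently:

- **Regions**: centroids uniform in the scenario bounding box; populations
  and land areas log-normal. Heavy-tailed sizes match the skew of real
  county tables; the `us_like_small` preset (300 regions, median population
  10,000 with log-sd 1.25, median area 1,600 km² with log-sd 1.0, over a
  continental-US-like box) totals ~7M people and runs every stage in
  seconds.
- **Centers**: host regions drawn with probability proportional to
  population (uniform placement selectable), located uniformly within the
  host disc; `s` and `o` constant at 5 and 200 by default.
- **Diagnosed individuals**: a two-component mixture. With probability `q`
  (`diagnosis_bias`) an individual is placed near a uniformly chosen center
  at an exponential radial distance (`bias_scale_km`, default 10 km); with
  probability `1−q` they are placed as general population. The mixture is
  the simplest generative form with a tunable effect size for the
  diagnosed-live-closer phenomenon; `q = 0` makes the diagnosed sample
  statistically indistinguishable from the background, `q = 0.8` (the
  `biased_diagnosis` preset) produces an effect the pipeline detects in
  essentially every seeded replicate.

What the generator does **not** emulate: within-region population clustering
(real populations concentrate in towns, so simulated distances run somewhat
long — a known, accepted bias of the uniform-within-region model), real
political geography, coastlines, road networks, demographic covariates, or
any calibrated effect size for the diagnosis bias (the synthetic `q` and
scale are free parameters, not estimates). Passing tests therefore
demonstrate the pipeline's correctness and sensitivity, not empirical claims
about any real country.

## Numerical choices and edge cases

- Exact distance ties in nearest assignment: smallest `center_id`, making
  runs reproducible across platforms.
- Tier boundaries and `pct_within_z`: inclusive (`d ≤ r`), consistently with
  every other radius comparison.
- The `RA = 1` boundary is exact in exact arithmetic; floating-point
  round-trips through the destination formula can land a constructed point
  at `z + 4e-15` km, so boundary checks in tests probe strictly inside.
- `decay(0) = 1` by construction — no division at distance zero.
- Uniform in-tier choice is implemented by random-key argmin (iid uniform
  keys, out-of-tier keys at +∞), which vectorizes over individuals while
  remaining an exactly uniform draw.
- Outputs are written atomically (temp file + rename) with numerics at 6
  significant digits, so identical config + seed gives byte-identical
  artifact bundles.

## Problem sizes

The shipped analysis scripts and test suite use the `us_like_small` scale
(300 regions, 80 centers, ~5×10⁴ simulated individuals, 0.5–2° grids) and
100-replicate bias-recovery runs at 60 regions / 12 centers / ~600
individuals per arm — sizes chosen so the full study re-runs from scratch in
about a minute on a laptop while leaving every distributional property
measurable. All of it scales linearly in individuals × centers; a
full-population national run (sampling fraction 1.0) is the same code path.

## Limitations

Uniform-within-region placement overstates distances where populations
cluster; the center registry model treats `s` and `o` as homogeneous when
real staffing varies widely; the availability algebra's decay and load-floor
choices are defensible but not unique (both are pluggable); and the tiered
assignment ignores capacity constraints and any preference for "better"
centers farther away. These are faithful simplifications of the modelled
design, not oversights.
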