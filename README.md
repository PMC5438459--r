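# resourcegaps

Tools for studying the spatial accessibility of autism (ASD) diagnostic
services. Families seeking an ASD diagnosis depend on centers that are few,
unevenly placed, and frequently oversubscribed; this package quantifies that
mismatch. It simulates where people live from census-style region tables,
assigns them to diagnostic centers, and computes demand-to-supply metrics
per center and per location, so that overburdened centers and underserved
regions can be identified and mapped. Everything runs on a seeded synthetic
scenario generator, so the full pipeline is testable without any external
data download.

## The model

**Population placement.** Each region (a county-like areal unit with
centroid, land area `A` km², and population) is modeled as a disc of equal
area, radius `R = sqrt(A/π)`; simulated individuals are placed uniformly per
unit area within it. All distances are great-circle (haversine) on a sphere
of radius 6371.0088 km.

**Assignment.** Two rules, used by different analyses:

- *nearest*: each individual goes to the center minimizing haversine
  distance (distance-to-care summaries);
- *tiered random*: each individual is assigned uniformly at random among the
  centers within the smallest radius of 25, 100, 500, or 3000 km that
  contains at least one center (resource-load computation). Individuals with
  no center inside the largest tier fall back to nearest, flagged.

**Resource load** of a center `r` with `N` assigned individuals:

    RL_r = (N · p) / (s · o)

where `p = 0.195%` is the fraction of the population needing an autism
screening (6.5% at a diagnosis-appropriate age × 3% of those needing
screening), `s` the number of specialists at the center (default 5), and `o`
the annual per-specialist caseload (default 200). `RL = 1` means demand
exactly matches annual capacity; `RL = 6` means six-fold overload.

**Resource availability** at a location `l`:

    RA_l = Σ_r  [ 1 / max(RL_r, 1) ] · decay(d(r, l); z)

with `decay(d; z) = 1` for `d ≤ z` and `z/d` beyond, and `z = 30` km the
distance an average family is willing to travel for a diagnosis. One
adequately loaded center (`RL ≤ 1`) within `z` yields `RA = 1` exactly. A
**resource gap** is any location with `RA < 1`.

## Worked example

```r
library(resourcegaps)

center <- data.frame(center_id = "C1", name = "clinic", lat = 40, lon = -100,
                     s = 5, o = 200)
p <- derive_screening_fraction(0.065, 0.03)   # 0.00195
resource_load(center, data.frame(center_id = "C1", n_assigned = 512821), p)$rl
#> [1] 1.00000095
resource_load(center, data.frame(center_id = "C1", n_assigned = 3076923), p)$rl
#> [1] 5.99999985
```

A center serving 512,821 people receives `512821 × 0.00195 ≈ 1000`
screening requests a year — exactly its `5 × 200` capacity, so `RL = 1`;
at 3,076,923 people it carries six times the demand it can handle.

The end-to-end synthetic study lives in `analysis/01_simulate.R` through
`analysis/05_diagnosis_bias.R`; each script prints what it found and writes
its tables under `results/`. A single call runs the whole pipeline too:

```r
run_pipeline("results/run", preset = "us_like_small", rule = "tiered", seed = 1)
```

which writes the assignment CSV, per-center loads, distance summaries, the
availability grid as GeoJSON, and a manifest sufficient to reproduce the run
byte-for-byte.

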