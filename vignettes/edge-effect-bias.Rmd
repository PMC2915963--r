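---
title: "Quantifying edge-effect bias in food-environment measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying edge-effect bias in food-environment measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(edgebias)
```

## Why a simulation

Availability and accessibility indices are computed from outlet locations
observed inside a study boundary. Locations near that boundary are scored
from an artificially truncated outlet set: the nearest supermarket may sit
just across the line. The size of the resulting bias cannot be read off real
data — the censored outlets are, by construction, unobserved — so `edgebias`
measures it in a setting where the truth is known: outlets are simulated on
the unit square, measures are computed once from the whole square (the gold
standard) and once from an internal subset that mimics a bounded study area,
and the two are compared at every evaluation site.

## The outlet model

Real food outlets aggregate around commercial developments and town centers;
a count model without spatial structure (we also examined negative-binomial
tract counts) misses exactly the clustering that drives local censoring
loss. The simulator is therefore a thinned cluster process:

1. `J` cluster centers are drawn uniformly on the unit square, once, and
   held fixed for all replicates of a scenario.
2. Candidate outlets are proposed uniformly and accepted with probability
   `min(1, λ(s*)/λ_max)`, where `λ(s) = Σ_j exp(−|s − x_j|²/2φ)` sums a
   unit-peak Gaussian kernel over the centers, until exactly `N` outlets are
   accepted.

`φ` is the squared dispersal scale (window units²): outlets scatter around
their centers with standard deviation `√φ` per axis. `λ_max` is the maximum
of `λ` over the predefined evaluation mesh rather than the continuum
maximum; the ratio is clipped at 1, which leaves acceptance proportional to
`λ` wherever `λ ≤ λ_max` and only flattens (never inverts) the few
between-mesh peaks that exceed it. Kernel normalisation constants cancel in
the ratio and are omitted.

Two parameter sets span the settings of interest. Centers held fixed across
replicates make the mapped error fields interpretable — hot-spots sit where
the centers actually are — and mirror the fact that a region's commercial
geography does not resample between studies.

| scenario  | N outlets | J centers | φ     | replicates |
|-----------|-----------|-----------|-------|------------|
| urban     | 2000      | 15        | 0.01  | 500        |
| non-urban | 300       | 5         | 0.005 | 500        |

The urban setting has more outlets, more centers and looser clustering; the
non-urban setting has few outlets tightly packed around a handful of town
centers. What the generator does *not* emulate: linear (road-strip) outlet
arrangements, a diffuse background component away from all centers,
population surfaces, and network rather than Euclidean distances. The
measures studied are invariant to distance rescaling, so unit-square results
transfer across spatial scales, but conclusions about, say, strip-mall
geometries are outside what a passing test here can support.

## Geometry and evaluation sites

The window carries three nested structures, all owned by `study_geometry()`:

* a 15×15 **tract grid** (the analog of Census tracts) supplying the
  spatial unit for counts;
* a 20×20 **evaluation mesh**, one site per subcell — 400 sites;
* the **guard inset** δ = 0.1: the internal square `[0.1, 0.9]²` is the
  simulated "study area", the surrounding strip the guard area whose
  outlets censoring removes.

δ must be a multiple of the mesh spacing so the internal boundary lies on
mesh lines and exactly `(p − 2δp)² = 256` sites are internal. By default
sites sit at subcell centers: a deterministic lattice makes the
distance-to-boundary bins (half-open, width 0.05, midpoints 0.025–0.375)
deterministic too, with ring populations 60, 52, …, 4 — every bin populated,
including the deepest, which a jittered mesh leaves empty about a third of
the time. `generate_location_points(jitter = TRUE)` restores uniform
placement within subcells; the internal count stays 256 either way. Sites
are fixed across replicates — otherwise "per-site median over replicates"
would not be a meaningful field.

## Measures and conventions

At a site `i` with distances `d_i1 … d_iN` to the outlets:

* `CI_i` — outlets in the site's tract cell; `√CI_i` stabilises its
  variance for regression use.
* `CP` — cumulative opportunity, `Σ 1/d_ij` over a reference set: the `k`
  nearest (`k` = 1–3), a buffer, or all outlets. The reciprocal weighting
  encodes distance decay of access: near outlets dominate, far outlets
  still contribute. `CP` over the `k` nearest is therefore *not* the
  nearest-distance itself — the two react in opposite directions to
  censoring.
* `D_i` — distance to the nearest outlet, kept as a plain distance.

Degenerate inputs are fixed by convention: an empty reference set gives
`CP = 0` with a warning and leaves nearest-based measures `NA` (flagged
missing and excluded from summaries, never silently zeroed); nearest-
neighbour ties resolve by outlet index; an outlet coincident with a site
contributes `Inf` (a zero-probability event under the generator).

## Error metrics and aggregation

Censoring retains outlets in the *closed* internal square — a point exactly
on the dashed boundary belongs to the study area. For each internal site and
measure,

* percentage error: `100·|full − internal| / |full|`, with `0/0 → 0` and a
  flagged `NA` when only the denominator vanishes;
* absolute bias: `|full − internal|`.

The full-window value is the denominator: it is the truth the censored
estimate should have recovered. Absolute values are used because the two
families err in opposite directions (counts and `CP` can only shrink,
nearest distance can only grow); the sign structure itself is asserted by
the test suite. Consequences worth knowing: `CP`-family percentage errors
are bounded by 100 (the internal value is a subsum), while `D` errors may
exceed 100.

Per site, the median over the 500 replicates of each metric is the site's
error level (even-length medians are the midpoint of the central pair;
medians are taken over defined values, and a site with more than 5% of
replicates undefined is flagged missing). Sites are then grouped by distance
bin and each bin reports min/median/max over its sites — the layout of the
binned tables written by `analysis/02_run_experiments.R`. A requested bin
with no sites yields a flagged empty row rather than disappearing.

Replicate seeds are spawned from the master seed up front, so a run is
bit-reproducible; isolated replicate failures are tolerated up to 1% of the
run and counted in the output, beyond which the run aborts.

## What the experiments show

```{r headline}
geom <- study_geometry()
urban <- run_experiment(scenario_presets()$urban, geom, master_seed = 1)
bias_table(urban, "med_abs_bias")
```

The patterns the test suite asserts at full scale: median absolute bias is
zero beyond the first distance bin for every measure except `CP total`; the
nearest-distance measure is unbiased at the median even in the nearest bin
under urban densities; `CP total` keeps double-digit median percentage
errors in *every* bin (about 24% at the boundary and 16% at the window
center for the urban run above), and its absolute bias dominates the
non-urban scenario's in every bin — whole-region cumulative indices are the
clear casualty of edge censoring. In the sparse non-urban setting the
availability count is zero-median-biased at the boundary, yet individual
boundary sites reach percentage errors of 60–100% when a tract cell is cut
by the boundary with a cluster center in the severed part; the contour maps
show exactly those hot-spots around near-boundary centers.

One caution when comparing against percentage-error figures reported
elsewhere: with the full-window denominator above, a deep-interior
cumulative error much above ~20% is not attainable under uniformly drawn
centers (the guard strip simply cannot hold the required share of
inverse-distance mass), and our deepest-bin urban values sit in the 10–17%
range across center draws. Normalising by the censored value instead
(`100·|full − internal|/internal`) inflates the same runs to ≈32% at the
boundary and ≈19% at the center. Quoted error levels are only comparable
conditional on the denominator convention, which published accounts do not
always state.

## Problem sizes and costs

The full design — 500 replicates × (256 internal sites × 2000 outlets) —
is a deliberate desk scale: the urban experiment runs in about half a
minute on one CPU (the distance matrix is vectorised; only the k-nearest
partial sort loops over sites), the non-urban one in a few seconds.
Property tests run on 20–200-outlet fixtures against brute-force oracles;
the generator's distributional checks use a single-center case with 10⁴
outlets against direct kernel sampling.

## Limitations

* Percentage error is undefined where the truth is zero; such records are
  flagged, not imputed, and enter no summary.
* The guard width study is one-sided: δ = 0.1 quantifies censoring for a
  10% guard, and widening δ weakly increases count bias (tested), but no
  optimal-guard search is performed.
* Gravity-type composite measures (attraction/distance ratios) and
  population-normalised densities are out of scope, as are smoothed
  (density-estimated) availability surfaces — the unsmoothed `CI` shown
  here is the *best* case for availability near edges.
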