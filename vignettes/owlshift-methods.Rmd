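---
title: "Methods: climate-envelope projection of montane owl habitat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-envelope projection of montane owl habitat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owlshift)
```

## The model

`owlshift` forecasts shifts in vegetation-based owl breeding habitat from
the climatic identity of vegetation types. Each Ecological Response Unit
(ERU) — a mapped vegetation type such as ponderosa pine forest or
pinyon-juniper woodland — is summarized by a *climate envelope*: the
pre-reference-period mean $\bar{x}_v$ and inter-annual standard deviation
$s_v$ of each of several climate variables over the ERU's mapped extent.
The exposure of a location to change is the standardized departure of its
projected late-century climate from an envelope,

$$ VS_v = \frac{|\bar{x}_v - Val_v|}{2\,s_v}, $$

aggregated over variables. The core modelling assumptions are:

* **Vegetation tracks climate.** Where the 2090 climate of a cell falls
  within the envelope of an ERU, that ERU is an admissible future state of
  the cell. Where it falls outside every envelope, the nearest envelope
  (minimum mean $VS$) is taken as the single admissible outcome.
* **Succession constrains transitions.** Upland shrub types are never
  projected to convert to woodland or forest — site factors, shrub
  recruitment strategies and fire regimes perpetuate shrub dominance — so
  shrubland may only move to shrubland, grassland or desert types.
  Woodlands at their lower ecotone may be projected to grassland or
  shrubland. Riparian types are excluded from projection entirely: their
  distribution is hydrologically, not climatically, controlled, so
  riparian cells are carried through unchanged and riparian is never
  produced as an outcome elsewhere.
* **Interpretation errs towards inclusion.** Climate envelopes overlap,
  so a cell often has several admissible outcomes. Habitat rendering is
  *inclusive* by default (a cell is projected habitat if *any* candidate
  is a profile vegetation type); the single most-likely outcome (lowest
  aggregate $VS$) is available as a stricter alternative.

A species is represented by a *habitat profile*: a set of ERUs plus the
model zones (biogeographic regions) where the profile applies, optionally
with a distinct 2090 zone set to allow projected range expansion.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `k` (admission half-width) | 2 | SD | coheres with the $2s$ scaling of the score: admitted $\iff$ per-variable $VS \le 1$ |
| `aggregation` | mean | — | the least-surprising symmetric combination of per-variable scores; `max` gives a conservative alternative |
| `mode` | inclusive | — | errs toward commission, matching how such profiles are parameterized |
| `buffer_m` | 1000 | m | conventional allowance for positional error in mapping and records; cells at exactly the distance are included |
| `connectivity` | rook | — | shared-edge adjacency is the raster analogue of dissolving polygons on shared boundaries; queen offered for sensitivity |
| `iterations` | 500 | — | randomization-null replicates |
| McNemar trigger | any cell < 5 | — | the rule used in the published analyses of this kind; switchable to `always`/`never` |

## The synthetic world

The generator emulates the structure the analysis assumes, not any real
landscape:

* **Elevation** is a base plane plus seeded Gaussian hills, rescaled into
  the band range (1000–3500 m by default).
* **Vegetation** follows eight elevation bands — desert scrub, grassland,
  Gambel oak shrubland, pinyon-juniper woodland, ponderosa pine forest,
  mixed conifer with aspen, spruce-fir forest, alpine tundra — with cells
  within 30 m of a band boundary flipped to the adjacent band with
  probability 0.5, and riparian corridors meandering through the wooded
  zones. Model zones are four contiguous vertical slabs.
* **Climate** is linear in elevation per variable (five generic variables
  with distinct lapse rates) plus seeded spatial noise. Variable names
  are placeholders: only one variable of the published envelope set is
  publicly described, so no attempt is made to name the others.
* **Warming** is an *equivalent uplift* (default 300 m): the 2090 value at
  a cell is the present value of a site that much lower. One knob moves
  all variables coherently through their lapse rates and directly encodes
  the upslope-shift hypothesis. The default corresponds to the upper end
  of observed vegetation shifts of 15 m or more per decade sustained over
  roughly ten decades.
* **Scales chosen once:** the inter-annual SD of every variable defaults
  to the climate change from 150 m of elevation (so the $k = 2$ admission
  window spans ±300 m equivalent), and spatial noise to 5 m equivalent.
  These keep band-edge cells admissible to their own envelope, which is
  what makes the zero-warming recovery property exact.
* **Occurrence records** are placed uniformly in habitat except for a
  commission fraction (default 0.15) biased to riparian cells within 1 km
  of habitat, mirroring the field observation that most records outside
  mapped montane habitat fall in riparian stringers nestled within it.
  Gaussian positional error (default SD 50 m) is added; records coarser
  than 1 km precision are excluded at source.

What the synthetic world does **not** emulate: real hypsography (mountain
ranges taper, so upslope shifts destroy much more area than on a rescaled
plane-plus-hills surface), disturbance (fire is the dominant catalyst of
rapid type conversion and is deliberately outside the model), spatially
autocorrelated climate noise, and non-climatic habitat factors (cavities,
prey). Passing tests therefore demonstrate the correctness of the
machinery under its own assumptions, not predictive skill on real
landscapes.

## Numerical choices

* **Percent change display** is rounded to the nearest multiple of 5 with
  ties away from zero; this is the display convention that reproduces
  published regional percent-change values from their extent pairs. The
  raw value is always retained.
* **Most-likely ties** are broken by taxonomy order, for determinism.
  Note that with *unequal* band widths the climatically nearest envelope
  near a band boundary can be the neighbouring band's even under an
  unchanged climate; the inclusive candidate set always contains the
  current ERU in that situation (the recovery property), but the
  most-likely outcome can flip within roughly half a band of a boundary.
* **Persistence fallback**: if the transition rules empty a cell's
  candidate set, the current ERU is retained — a cell is never projected
  to "no vegetation".
* **Buffering** is centre-to-centre Euclidean on the planar grid;
  boundary cells at exactly the buffer distance are included, making the
  operation oracle-checkable by brute force.
* **Patch SD** is the sample SD (n − 1), defined as 0 for a single patch;
  an empty mask reports absent (NA) summaries, not zeros.
* **The z-test** is a pooled two-proportion test of the observed capture
  proportion against the aggregate of all null draws, with a Yates-style
  continuity correction $(1/n_1 + 1/n_2)/2$ capped so it never overshoots
  the observed difference; it reproduces
  `prop.test(..., alternative = "greater")`. When the pooled proportion
  is degenerate (0 or 1) the p-value comes from the exact comparison and
  is flagged. The empirical exceedance count is always reported alongside,
  so conclusions never rest on the parametric form alone. Random points
  are drawn uniformly over sampling-region *cells*, with replacement —
  exact, scale-consistent, and equivalent to uniform point sampling at
  the model's resolution.
* **McNemar correction** is triggered by *any* 2×2 cell below 5 and the
  corrected form $(|b-c|-1)^2/(b+c)$ is applied verbatim even when
  $b = c$ (where `stats::mcnemar.test()` instead skips its correction);
  the trigger is switchable to the always/never conventions.
* **Detection thinning** (non-overlapping 250 m discs) is greedy in input
  order and therefore order-dependent; sort first to impose a priority.

## Design decisions that were genuinely open

* The multi-variable combination of per-variable scores is not fixed by
  the method's public description; the mean was chosen as the default and
  the max exposed by flag. This is the main deviation risk when comparing
  against analyses built on the original vulnerability surfaces.
* Whether "most likely" outcomes should be defined by climate-space
  distance or categorical suitability is likewise open; both are
  expressible here through `k` and `mode`.
* Dissolve adjacency for patch counts is not stated for the original
  GIS workflow; rook is the default (closest analogue of a polygon
  dissolve on shared edges) and queen is available for sensitivity.
* The command-line surface is provided as the `run_*()` family of
  functions writing rasters, tables and a manifest; a shell wrapper would
  add nothing over `Rscript -e`.

## Problem sizes

The test suite exercises the pipeline on landscapes between 10×10 and
250-column grids (seconds in total); the full default world is 200×200
cells at 100 m, which the acceptance script uses together with 500
randomization iterations of 148 points. The z-test calibration check uses
1000 synthetic replicates of a 200-record null. All randomness is seeded;
every generator and pipeline stage is deterministic given its seed.

## Known limitations

Scores are continuous; no low/moderate/high vulnerability categories are
assigned. Envelope variable selection is an input, not reproduced. No
vector-polygon geodata support (rasters and CSV/ASCII-grid text formats
only), no reprojection, no fire or disturbance modelling, and no riparian
habitat modelling — riparian cells are static pass-throughs.
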