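---
title: "Methods: buffered spatiotemporal annotation, clustering, and cross-grain diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: buffered spatiotemporal annotation, clustering, and cross-grain diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatannot)
```

## The annotation model

`spatannot` attaches environmental summaries to point occurrence records
`(id, longitude, latitude, date)` from gridded layer time series. The unit
of environmental data is a *scene*: one layer's grid of values at one
timestamp. A layer is described by its spatial grain (pixel size, meters),
temporal grain (`static`, `annual`, `monthly`, `sixteen_day`, `daily`),
nodata sentinel, valid range, and a path template locating scene files.

An annotation request fixes two grains the user controls:

* **Spatial buffer** `r_s` (meters, ≥ 0): the disc of radius `r_s` around
  the record's coordinate. A pixel belongs to the buffer iff its *center*
  lies inside the disc. With `r_s = 0` (or any radius smaller than the
  distance to the nearest pixel center) the buffer degrades to the single
  containing cell, so plain grid-cell intersection is the zero limit of the
  same code path rather than a separate mode.
* **Temporal buffer** `r_t` (days, ≥ 1): the trailing window of `r_t`
  consecutive days ending on the observation date. The observation day
  always counts, hence the minimum of 1. Windows are never centered:
  conditions *before* an observation are what the organism experienced.

For each record × layer the engine resolves which scene timestamps serve
the window (all window days for daily layers; catalog timestamps inside
the window for 16-day and monthly products — possibly none; the calendar
year's scene for annual products; the single scene for static ones),
masks each scene with the buffer, and **pools all valid pixel-day samples
into one mean and one sample standard deviation**. Pixels are valid when
not nodata and inside the layer's declared valid range; range screening is
the pipeline's quality-control step.

Two readings of "aggregate across days after buffering at the daily level"
are defensible: pooling all pixel-days, or averaging daily means. We pool.
Pooling makes `valid_sample_count` directly interpretable as the evidence
behind the mean, and makes the standard deviation a total spatiotemporal
spread; averaging daily means would weight a nearly-clouded day equally
with a clear one. The alternative is isolated behind the aggregation step
if a variant is ever wanted.

The standard deviation uses the unbiased `n − 1` convention and is absent
for `n = 1` — a singleton sample has no spread, and reporting 0 would be
misleading. Statuses are exclusive and exhaustive: `ok` (≥ 1 valid
sample), `no_valid_data` (scenes existed, all masked pixels invalid),
`out_of_coverage` (no scene timestamp in the window), `out_of_extent`
(coordinate off the layer grid). Failed records keep their row in every
output so the record set is never silently filtered.

## Geometry conventions and numerical choices

Grids are geographic (WGS84), square cells in degrees, row 1 at the north
edge. Cells are half-open: a point on a shared edge belongs to the cell to
its east/south, so every in-extent point maps to exactly one cell and
there are no ties to break. Indices are 1-based, as in R.

Distances for buffer inclusion use a local equirectangular metric:
`dy = Δlat · 111320` m, `dx = Δlon · 111320 · cos(lat_center)` m. At the
radii this tool targets (≤ 10 km cap by default) the deviation from
geodesic distance is far below a pixel at any latitude where the grid
model itself is sensible; the metric lives in one function and is a
documented swap-in point for a geodesic alternative. Pixel inclusion is
center-in-disc — fully deterministic, and the convention most common in
rasterization defaults; any-overlap inclusion is the noted variant.

Degenerate inputs behave, rather than error, wherever a meaningful result
exists: empty timestamp resolutions signal `out_of_coverage` downstream;
sub-pixel radii fall back to the containing cell; empty record sets
annotate to empty result tables with zero retrievals. Validation errors
(negative radii, zero-day buffers, inverted ranges, malformed catalogs)
are classed conditions raised at construction time.

Buffer caps (defaults 10,000 m and 365 days) are enforced at request
validation — the pixel count grows with the square of the spatial radius,
so unbounded requests are a foot-gun.

## Retrieval planning

The expensive unit of work is the scene retrieval. A naive annotator
fetches one scene per (record, resolved timestamp): 500 records sharing a
location and date with a 7-day buffer on a daily layer cost 3,500
retrievals. The planner instead groups records by

* **geohash cell** of the coordinates — precision 4 for grains ≥ 1,000 m,
  5 for 250–1,000 m, 6 below 250 m. The monotone rule (finer layers,
  longer hashes) is fixed by the product grains the breakpoints bracket:
  1-km temperature products, 250-m vegetation indices, 30-m scenes.
* **temporal bin** — year for annual/static layers, year-month for
  16-day/monthly, year-month-week for daily. Weeks are fixed 7-day blocks
  from the 1st of the month (W1 = days 1–7, …, W5 = days 29–31):
  deterministic, locale-free, and never straddling a month boundary the
  way ISO weeks would. Bins depend on the layer's temporal grain only; we
  considered tying them also to the spatial precision but found no rule
  that ever changes the distinct-key count, which is what matters.

Each cluster requires the union of its members' resolved timestamps, and a
retrieval is one distinct `(layer, timestamp, geohash tile)` key, cached
globally — if two temporal bins of the same tile need the same timestamp
the tile is fetched once. Tiles are the geohash cell's bounding box padded
by the buffer radius plus two cells, so a member's mask can never cross a
tile boundary: this is what guarantees the central correctness property,
*clustered results equal naive results record by record*, which the test
suite enforces to 10⁻¹⁰ over randomized datasets (they are in fact
bitwise-equal, since both drivers pool the same values in the same order).
Clusters share no mutable state beyond the read-only tile cache, so they
are independent work units; parallel execution is a contract here, not an
implementation.

## Regraining and cross-grain deltas

`coarsen_spatial()` aggregates `k × k` pixel blocks by their
nodata-excluded mean (output nodata only when a whole block is), trimming
non-divisible grids at the south/east edges — trimming is deterministic,
padding would fabricate data. Note the block-mean route coarsens by
integer factors; a 30 m → 1 km regrain is approximated by the nearest
integer factor rather than a resampler's fractional kernel.
`composite_layers()` builds a single long-term mean layer or a 12-layer
monthly climatology (per-cell, nodata-excluded; empty months are marked,
not fabricated). `annotate_grain_agnostic()` is the status-quo
comparator: bare containing-cell intersection on a composite, with the
record's date either ignored (long-term) or coarsened to its month
(climatology). It reuses the engine's radius-0 path — one geometry code
path, one set of geometry tests.

`cross_grain_delta()` inner-joins two per-record annotations on ids valid
under both (larger buffers succeed more often, so comparing unmatched sets
would bias toward the small-buffer survivors) and reports
`delta = value_a − value_b`, its absolute value, and optional covariates.
`delta_summary()` gives the two summary forms used for scale diagnostics:
median absolute delta and the fraction exceeding a threshold. Hypothesis
tests on deltas are left to general-purpose statistics tooling.

## The synthetic generator, and what passing tests show

`make_layer_series()` draws scenes from

```
value(cell, day) = base + A·cos(2π(doy − peak)/365)
                 + gradient·(col − 1) + H(cell) + ε(cell, day)
```

with `H` a static Gaussian field (sd `heterogeneity_sd`), `ε` i.i.d. noise
(sd `noise_sd`), and each pixel independently cloud-masked with
probability `cloud_fraction`. Day of year uses a 365-day cycle (day 366 of
leap years reuses 365), so the cosine sums to zero exactly over one
calendar year of daily scenes — which is what makes long-term composites
checkable against the closed-form de-seasonalized field to 10⁻⁶. The
noise-free generating function is returned alongside the scenes, giving
the engine-level recovery test an exact oracle: with zero noise and cloud,
a radius-0, 1-day annotation returns `g(cell, day)` bit-for-bit.

The generator emulates the features the engine must survive — seasonality,
spatial structure at two scales, missingness — and deliberately not the
rest of real remote sensing: clouds are spatially uncorrelated, there are
no orbital revisit gaps, no QA bitfields, no sensor radiometry, no
reprojection artifacts. Passing tests therefore demonstrate the
correctness of the geometry, aggregation, accounting and comparison logic,
not robustness to real product quirks.

Qualitative scale-dependence patterns are reproduced on this generator as
part of the acceptance suite, at problem sizes chosen to keep the full
validation run under a minute of compute per property: spatial cross-grain
|Δ| (120 m vs 990 m buffers, 100 m pixels) has strictly increasing median
across heterogeneity levels {0, 0.05, 0.15, 0.4} over 20 seeded 40 × 40
landscapes; temporal cross-grain |Δ| (1-day vs 30-day buffers, amplitude-1
annual cosine) is larger for records on the steep flank of the seasonal
cycle (a quarter cycle from the peak) than at the extremum. The
equivalence oracles run on 100 randomized 12 × 12 daily datasets and
1,000 random record/buffer draws against a brute-force all-cells-all-days
enumeration written independently of the engine.

## File formats

Rasters are Arc/Info ASCII grids — an established plain-text,
self-georeferencing raster format — one file per (layer, timestamp),
located by a strftime path template in a YAML/JSON catalog. Values are
stored at physical scale after applying a declared scale factor at read
time, keeping all downstream statistics unit-consistent. Occurrence input
is CSV with required columns `id, longitude, latitude, date`
(case-insensitive, ISO-8601 dates only, extra columns passed through);
invalid rows go to a rejection report with row numbers and reasons.
Results are a ZIP bundle (values CSV, parameters TXT, metadata TXT with
layer citations) written with a built-in store-method ZIP writer with
fixed timestamps, so identical runs produce byte-identical archives.

## Known limitations

* Point records only; polygon occurrences and uncertainty-weighted kernels
  are out of scope.
* No reprojection: layers must already share the geographic grid model.
* 16-day products are matched by timestamp-in-window; composite-period
  overlap matching is a possible variant the catalog metadata could
  support.
* Annual products match by calendar year of the observation date; the
  temporal buffer is ignored for them, as no window rule is defensible
  without product-specific semantics.
* Cloud masking in the generator is spatially uncorrelated; correlated
  cloud fields would exercise the missing-data paths more realistically
  and are a noted extension.
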