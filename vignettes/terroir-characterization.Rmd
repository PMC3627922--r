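---
title: "Characterizing viticultural areas from gridded terrain, climate, and soil data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing viticultural areas from gridded terrain, climate, and soil data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(terroirgrid)
```

## The problem

American Viticultural Areas (AVAs) are legally delineated wine-grape
appellations. Their official descriptions have historically leaned on point
measurements — a handful of weather stations, a contour line, a soil
association name. This package implements the complementary, spatially
continuous approach: derive environmental surfaces from gridded data
(a DEM, monthly climate normals, a soil survey), summarize each surface
over every appellation polygon, and compare appellations through those
summaries and through standardized principal components analysis of the
combined layer stack.

The pipeline has five computational stages, each exposed as plain
functions and driven end to end by the numbered scripts under
`analysis/`:

1. **Terrain** — slope, aspect, aspect sectors from the DEM.
2. **Solar** — growing-season clear-sky insolation via a horizon-angle
   viewshed model.
3. **Climate indices** — GDD, BEDD, frost-free days, growing-season
   precipitation from monthly normals.
4. **Soils** — dominant-component aggregation of a SSURGO-style survey to
   attribute rasters.
5. **Zonal summary and PCA** — per-zone means, class proportions,
   contrasts, and per-zone PCA.

## Data model and conventions

Rasters are plain matrices on a regular, square-celled, north-up lattice
in projected meters (`grid` objects); all stages require co-registered
inputs and refuse misaligned ones — reprojection is upstream of this
package, exactly as a practitioner would pre-project everything to a
common UTM zone. Nodata is `NA`; nodata in any input propagates to any
derived layer at that cell, and every summary ignores nodata cells.

Raster I/O uses the ESRI ASCII Grid format, written at full double
precision so write/read round trips are bit-faithful; zone, water, and
soil map-unit polygons travel as GeoJSON. Polygon membership of a cell is
decided by its **center** (cell-center containment): it matches the common
zonal-statistics convention and makes every membership count exactly
testable. Points on a polygon boundary count as inside; boundary/center
coincidences are measure-zero in practice, and the synthetic zone
generator insets its rectangles so they never occur in tests.

## Terrain

Slope and aspect use Horn's 3x3 weighted finite-difference stencil — the
default in mainstream GIS software, which is why it was adopted here (the
Zevenbergen–Thorne variant would be a one-line substitution). Slope is
reported in percent rise, `100 * sqrt(gx^2 + gy^2)`. Aspect is the
downslope azimuth, degrees clockwise from north; a cell with exactly zero
gradient gets a flat sentinel and its own category, never folded into
north. Edges are handled by edge replication. Aspect sectors are the
eight 45° windows centered on the cardinal/intercardinal directions,
left-closed (337.5° is N), so the sectors exactly partition the circle
and the boundary assignment is deterministic.

## Solar model

Insolation is a seasonal accumulation in Wh/m², intended — like the
surfaces it emulates — as a *comparative* index of topographic exposure,
not a calibrated radiation climatology. The model:

* **Sun lattice.** Ordinal days 91–304 (1 April – 31 October) in 14-day
  steps, hours in 2-hour steps at bin centers, each position weighted by
  the hours it represents. Declination uses the Cooper approximation;
  sub-degree accuracy is sufficient for a seasonal sum used
  comparatively. All positions are evaluated at one mean latitude per
  tile.
* **Direct beam.** `S0 * T^m * cos(incidence)` per unobstructed
  position, with solar constant `S0 = 1367` W/m², transmissivity
  `T = 0.5` (clear sky), and relative optical air mass
  `m = exp(-0.000118 * elevation) / cos(zenith)`. Negative incidence on
  the tilted facet contributes zero.
* **Obstruction.** A horizon-angle viewshed: for each cell, the maximum
  elevation angle along each of 32 azimuth rays within a configurable
  search radius (rays walked in one-cell steps, nearest-cell sampling).
  The sun is blocked when its altitude is below the horizon angle
  linearly interpolated at its azimuth.
* **Diffuse sky.** A uniform-radiance hemisphere integrated over the
  8 x 8 zenith/azimuth sky-map sectors, restricted per azimuth column to
  the unobstructed zenith range. The zenith integral has a closed form,
  so only azimuth is discretized — at `sqrt(sky_cells)` steps (200 for
  the default 40,000-cell sky). Diffuse is scaled so that it is 30% of
  global radiation on an unobstructed horizontal surface
  (`diffuse_proportion = 0.3`).
* **Tiling.** Large extents are split into north–south bands
  (`tile_by_latitude`) so each band keeps a near-constant mean latitude,
  with an overlap strip; band surfaces are feather-blended
  (`blend_mosaic`) with complementary linear ramps across the strip, so
  the mosaic is always a convex combination of the overlapping tiles.
  On the 100 x 100 composite-terrain fixture the tiled-and-blended
  surface stays within 1% of a single-pass computation (the acceptance
  script recomputes this margin).

Because the sector-weighting constants of the commercial implementation
this emulates are not published, correctness is established against
independent oracles instead: a flat unobstructed cell agrees with a
direct numeric integration over the same sun lattice to machine
precision, a fully obstructed cell accumulates exactly zero, and a
south-facing slope at 46°N receives strictly more than its north-facing
twin.

## Climate indices

From monthly normals `tavg = (tmax + tmin)/2` per month, April–October
(days per month 30, 31, 30, 31, 31, 30, 31; 214 days total):

* **GDD** = `sum_m max(0, tavg_m - 10) * days_m` (C-degrees). The
  monthly contribution is clamped at zero — heat accumulation cannot be
  negative, though the clamp only binds in months below the base.
* **BEDD** additionally caps the monthly mean daily rate at 9 C-degrees:
  `sum_m min(9, max(0, tavg_m - 10)) * days_m` — the only construction
  possible from monthly normals, mirroring a daily cap applied month by
  month. BEDD ≤ GDD everywhere, with equality wherever monthly means
  stay at or below 19 °C; the gap between the two separates appellations
  with peaky mid-season heat from those with even accumulation.
* **FFD** = first fall frost DOY − last spring frost DOY. A cell whose
  spring date falls after its fall date is degenerate input; it becomes
  nodata with a logged warning rather than a negative season.
* **GSP** = April–October precipitation sum (mm).

Leap years are irrelevant (the season excludes February) and the day
counts are fixed as listed.

## Soils

The survey model mirrors SSURGO's relational core: map-unit polygons,
components with area percents, horizons with depth bounds. Aggregation is
**dominant component** — the component with the largest percent, ties
broken to the lexicographically smallest component key so results are
reproducible run-to-run. For the categorical drainage attribute, dominant
*condition* (summing percents over components sharing a class) is
available as a config alternative, since either method is plausible for
categorical maps. Attribute values per component:

* drainage class: the seven-level ordinal scale ED…VPD coded 1–7;
* depth to restrictive layer: the recorded depth, or the censored value
  200 cm when no restriction was found within the survey depth (the
  SSURGO convention);
* AWC and pH: thickness-weighted means over the 0–50 cm window, with
  horizons missing the attribute excluded from numerator and
  denominator, and `NA` when nothing in the window carries a value.

Rasterization assigns each cell the attribute of the map unit containing
its center; 10 m is the conventional resolution for representing
map-unit boundaries, though the synthetic workflows use the DEM's cell
size.

## Zonal summaries and contrasts

Zonal means are arithmetic means over data cells with centers in the zone
(water masked first); class proportions are per-class cell fractions that
sum to one per zone. Cross-zone "Average" rows are **unweighted** by
area, and average only the zones reporting a class — this is exactly how
the published drainage-class table's Average row is constructed, which
the package reproduces from the shipped copy of that table (well-drained
column average 83.3%). Contrasts difference any summary variable, or the
derived GDD−BEDD gap, between named zone pairs; they are antisymmetric
and vanish on the diagonal. Values are kept at full precision internally
and rounded only at serialization.

The published per-AVA mean table is shipped as a fixture
(`read_ava_means()`), and the package's contrast machinery reproduces its
printed inter-AVA differences (58 C° gap contrast, 14 C° GDD contrast,
28- and 52-day FFD contrasts). The source text occasionally disagrees
with its own table's arithmetic by a rounding unit (e.g., a "149 fewer
GDD" statement where the table rows difference to 148); the package
reports the table arithmetic and makes no attempt to reconstruct
unrounded source values.

## PCA

The stack is the seven layers elevation, AWC, pH, depth, GDD, FFD, GSP —
slope, aspect, and insolation are DEM-derived (redundant with elevation),
drainage is categorical, and BEDD shares its source with GDD, so all are
excluded. Layers are standardized to z-scores over the common validity
mask; the decomposed covariance matrix is then the correlation matrix of
the raw layers, which makes the analysis invariant to affine rescaling of
any input. The population (1/n) standard deviation is the default — at
raster cell counts the sample/population distinction is negligible, but
it is pinned (and config-selectable) so tests are exact. A constant layer
has no z-score and is rejected by name. Eigenvector signs are fixed by
making each vector's largest-magnitude component positive; sign choices
in published biplots are tool-internal and unrecoverable, so only
magnitudes and relative signs are comparable. All mask cells enter the
decomposition (no thinning).

## The synthetic generator

Real inputs for this analysis are multi-gigabyte archives; the generator
produces inputs with just enough structure to exercise every documented
interaction:

* temperature couples to elevation linearly at a configurable lapse rate
  (default −6.5 °C/km, the standard environmental rate), with optional
  additive Gaussian noise;
* precipitation rises with elevation (default 60 mm/km over the season);
* the frost window narrows by 3 days per 100 m at each end, with
  `first_fall >= last_spring` enforced;
* tmax/tmin sit a fixed diurnal range (12 °C) either side of tavg, so
  `tmax >= tmin` by construction;
* soil map units partition the extent (jittered rectangles), components'
  percents sum to 100, and the generator records its own ground-truth
  dominant attributes for oracle tests;
* every output is a pure function of the configuration and seed.

What the generator does **not** emulate: the regression machinery behind
real climate normals, flood-stratigraphy soil patterns, coastline or
hydrology geometry, or any real appellation's shape. Passing tests
therefore demonstrate that the *machinery* is correct under the assumed
structure, not that real archives would yield any particular values.

## Numerical choices and degenerate inputs

* Bilinear resampling reproduces affine surfaces exactly at interior
  cell centers and never interpolates across nodata (any nodata
  contributor poisons the target cell); categorical resampling is
  nearest-neighbor and can never invent classes.
* Water masking and zone membership share the cell-center rule, so
  masking is idempotent.
* Self-intersecting zone rings are rejected by default; `"keep"` retains
  them under the even-odd rule, which resolves bow-ties
  deterministically.
* DEMs smaller than 3 x 3, empty component lists, unknown keys, zones
  with no data cells, and frost-date inversions all fail loudly (error
  or warning + nodata) rather than silently.

## Problem sizes

The shipped workflows and tests run on deliberately modest grids — the
full analysis region is 80 x 80 cells at 100 m, the mosaic consistency
fixture 100 x 100, and the PCA sampling check 10,000 cells — sizes chosen
so the entire suite re-runs in seconds while still exercising every code
path at raster scale.

## Limitations

* Insolation magnitudes are comparative indices; no cloud climatology or
  measured-radiation calibration is attempted, and agreement with any
  particular GIS product's absolute output is out of scope.
* Degree-days from monthly normals systematically differ from
  station-based daily sums; no reconciliation is attempted.
* Reprojection, multi-band imagery, and on-the-fly warping are out of
  scope; inputs must arrive on a common projected grid.
* The frost-date surfaces are consumed as given; deriving medians from
  daily station records is upstream.
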