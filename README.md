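# terroirgrid

Terrain, climate, and soil characterization of wine-grape appellations
from gridded environmental data.

American Viticultural Areas (AVAs) are federally delineated wine-grape
appellations. Their official descriptions often rest on a few weather
stations and broad physical sketches, yet the environmental factors that
matter to *Vitis vinifera* — seasonal heat, growing-season length,
precipitation (a powdery-mildew proxy), topographic exposure, soil
drainage, water-holding capacity, depth, and pH — are all available as
continuous surfaces. `terroirgrid` is for viticulture researchers and
GIS analysts who want to characterize and compare appellations from
those surfaces rather than from point measurements.

## What it computes

Given a DEM, monthly climate normals, frost-date surfaces, a
SSURGO-style soil survey, and appellation/water polygons (all on a
common projected grid), the package derives:

- **Terrain** — Horn slope in percent rise, downslope aspect with a
  flat class, and 45° aspect sectors.
- **Insolation** — growing-season clear-sky radiation (Wh/m²) from a
  horizon-angle viewshed: direct beam
  `S₀ · Tᵐ · cos θ` summed over a 14-day x 2-hour sun lattice
  (day 91–304), with air mass `m = e^(−0.000118·z)/cos ζ`, plus a
  uniform diffuse sky integrated over 8 x 8 sky sectors above the
  per-azimuth horizon, scaled to 30% of global on flat open ground;
  large extents are processed in overlapping latitude bands and
  feather-blended.
- **Climate indices** — growing degree-days
  `GDD = Σₘ max(0, T̄ₘ − 10) · dₘ`, biologically effective degree-days
  `BEDD = Σₘ min(9, max(0, T̄ₘ − 10)) · dₘ` (April–October, 214 days),
  frost-free days, and growing-season precipitation.
- **Soils** — dominant-component aggregation to drainage class, depth
  to restrictive layer (censored at 200 cm), and 0–50 cm depth-weighted
  AWC and pH rasters.
- **Zonal summaries** — per-appellation means, drainage and aspect
  proportions, cross-zone column averages, and pairwise contrasts
  (including the GDD−BEDD gap, which separates peaky from even seasonal
  heat accumulation).
- **PCA** — z-score-standardized principal components of the
  seven-layer stack (elevation, AWC, pH, depth, GDD, FFD, precipitation)
  with variance fractions and sign-fixed loadings.

A synthetic-data module generates every input with the statistical
structure the analysis assumes (elevation-coupled temperature,
precipitation, and frost dates; partitioned soil surveys with recorded
ground truth; zone and water polygons), so the full pipeline runs and is
tested without any download. Rasters travel as ESRI ASCII Grid, vectors
as GeoJSON.

## Worked example

The package ships the published per-AVA summary tables for the thirteen
inland Pacific Northwest appellations as fixtures. Contrasting the
GDD−BEDD gap between two famously similar-heat appellations:

```r
library(terroirgrid)
t1 <- read_ava_means()
ct <- contrast(t1, list(c("Walla Walla Valley", "Red Mountain")),
               "gdd_bedd_gap")
ct$differences
#> Walla Walla Valley vs Red Mountain
#>                                 58
head(ct$ranking, 3)
#> [1] "Wahluke Slope"      "Walla Walla Valley" "Snake River Valley"
```

Red Mountain records only 14 C° more GDD than Walla Walla Valley, yet
Walla Walla's GDD−BEDD gap is 58 C° larger — its heat arrives in a
mid-season peak, while Red Mountain accumulates evenly. The gap ranking
puts Wahluke Slope (the hottest appellation by GDD) first.

The same machinery on a synthetic lapse-rate region, end to end:

```r
cfg <- fixture_config(extent = c(40, 40), cell = 100, dem_kind = "plane",
                      dem_params = list(base = 150, gx = 0.02, gy = 0.035),
                      n_zones = 4, seed = 1)
dem     <- make_dem(cfg)
zones   <- make_zones(cfg)
normals <- make_monthly_normals(dem, cfg)
sm <- summarize_zones(list(
  elevation = dem,
  gdd  = growing_degree_days(normals),
  bedd = biologically_effective_degree_days(normals),
  ffd  = frost_free_days(normals$last_spring_frost,
                         normals$first_fall_frost),
  gsp  = growing_season_precipitation(normals)), zones)
sm$means
#>     zone elevation  gdd bedd   ffd   gsp
#> 1 zone01       205 1491 1274 162.7 135.3
#> 2 zone02       245 1436 1239 160.3 137.7
#> 3 zone03       275 1394 1210 158.5 139.5
#> 4 zone04       315 1341 1173 156.1 141.9
```

(GDD and BEDD rounded for display.) Zone GDD falls, and precipitation
rises, exactly as elevation climbs — the generating lapse structure
recovered through the full raster pipeline.

## The analysis workflow

The numbered drivers under `analysis/` run the whole study on a
synthetic region and write their outputs under `results/`:

```sh
Rscript analysis/01_simulate_region.R   # inputs: DEM, normals, soils, zones
Rscript analysis/02_terrain_solar.R     # slope/aspect/insolation surfaces
Rscript analysis/03_climate_soils.R     # GDD/BEDD/FFD/GSP + soil rasters
Rscript analysis/04_zonal_summary.R     # summary/drainage/aspect tables
Rscript analysis/05_pca.R               # per-zone PCA loadings
```

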