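#!/usr/bin/env Rscript
# Step 2 -- terrain derivatives and growing-season insolation.
#
# Slope (percent rise) and downslope aspect come from the Horn stencil;
# aspect is classified into the eight 45-degree sectors plus flat.
# Clear-sky insolation accumulates over the April-October sun lattice
# via the horizon-angle viewshed; the DEM is split into latitude bands
# with overlap and the tile surfaces are feather-blended back together,
# as the calculation guidelines for large extents require.

source("analysis/00_config.R")

dem <- read_raster(file.path(INPUT_DIR, "dem.asc"))

slope <- compute_slope(dem)
aspect <- compute_aspect(dem)
sectors <- classify_aspect(aspect)
write_raster(slope, file.path(SURFACE_DIR, "slope.asc"))
write_raster(aspect, file.path(SURFACE_DIR, "aspect.asc"))
write_raster(sectors, file.path(SURFACE_DIR, "aspect_class.asc"))
writeLines(c("aspect_class.asc integer codes:",
             sprintf("%d = %s", ASPECT_SECTORS, names(ASPECT_SECTORS))),
           file.path(SURFACE_DIR, "aspect_class_legend.txt"))

cat(sprintf("slope: mean %.1f%%, max %.1f%%\n",
            mean(slope$values), max(slope$values)))
cat(sprintf("flat cells: %d\n", sum(aspect$values == ASPECT_FLAT)))

tiles <- tile_by_latitude(dem, max_extent_deg = 3000 / 111320,
                          overlap = 500)
cat(sprintf("insolation over %d latitude tile(s)...\n", length(tiles)))
ins_tiles <- lapply(tiles, compute_insolation_dem, params = SOLAR,
                    max_radius = HORIZON_RADIUS)
insolation <- blend_mosaic(ins_tiles)
write_raster(insolation, file.path(SURFACE_DIR, "insolation.asc"))

cat(sprintf("insolation: mean %.0f Wh/m2 (%.1f kWh/m2), range %.0f-%.0f\n",
            mean(insolation$values), mean(insolation$values) / 1000,
            min(insolation$values), max(insolation$values)))
cat(sprintf("surfaces written under %s\n", SURFACE_DIR))
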