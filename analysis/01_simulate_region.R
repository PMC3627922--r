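#!/usr/bin/env Rscript
# Step 1 -- materialize the synthetic study region.
#
# Writes the complete input tree (DEM, monthly climate normals, frost
# dates, zone/water polygons, soil survey tables) that the later drivers
# read back through the package's standard-format readers, exactly as a
# run on real elevation/climate/soil archives would.

source("analysis/00_config.R")

write_fixture_tree(STUDY_CFG, INPUT_DIR)

dem <- read_raster(file.path(INPUT_DIR, "dem.asc"))
zones <- read_vector(file.path(INPUT_DIR, "zones.geojson"),
                     water = file.path(INPUT_DIR, "water.geojson"))

cat(sprintf("study region: %d x %d cells at %g m\n",
            nrow(dem$values), ncol(dem$values), dem$cellsize))
cat(sprintf("elevation range: %.0f-%.0f m\n",
            min(dem$values), max(dem$values)))
cat(sprintf("%d zones (%s), %d water polygon(s)\n",
            length(zones$zones),
            paste(zone_ids(zones), collapse = ", "), length(zones$water)))
cat(sprintf("inputs written under %s\n", INPUT_DIR))
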