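#!/usr/bin/env Rscript
# Step 3 -- climate-index and soil-attribute surfaces.
#
# GDD (base 10 C), BEDD (daily cap 9 C-degrees), frost-free days, and
# growing-season precipitation from the monthly normals; drainage class,
# depth to restrictive layer, AWC and pH (both 0-50 cm depth-weighted)
# from the soil survey by dominant-component aggregation.

source("analysis/00_config.R")

read_month <- function(var)
  stats::setNames(lapply(SEASON_MONTHS, function(m)
    read_raster(file.path(INPUT_DIR, sprintf("%s_%s.asc", var, m)))),
    SEASON_MONTHS)

normals <- monthly_normals(
  tmax = read_month("tmax"), tmin = read_month("tmin"),
  ppt = read_month("ppt"),
  last_spring_frost = read_raster(file.path(INPUT_DIR,
                                            "last_spring_frost.asc")),
  first_fall_frost = read_raster(file.path(INPUT_DIR,
                                           "first_fall_frost.asc")))

gdd <- growing_degree_days(normals)
bedd <- biologically_effective_degree_days(normals)
ffd <- frost_free_days(normals$last_spring_frost, normals$first_fall_frost)
gsp <- growing_season_precipitation(normals)
write_raster(gdd, file.path(SURFACE_DIR, "gdd.asc"))
write_raster(bedd, file.path(SURFACE_DIR, "bedd.asc"))
write_raster(ffd, file.path(SURFACE_DIR, "ffd.asc"))
write_raster(gsp, file.path(SURFACE_DIR, "gsp.asc"))

cat(sprintf("GDD:  mean %.0f C-deg (range %.0f-%.0f)\n",
            mean(gdd$values), min(gdd$values), max(gdd$values)))
cat(sprintf("BEDD: mean %.0f C-deg; BEDD <= GDD everywhere: %s\n",
            mean(bedd$values), all(bedd$values <= gdd$values + 1e-9)))
cat(sprintf("FFD:  mean %.0f days; GSP: mean %.0f mm\n",
            mean(ffd$values), mean(gsp$values)))

survey <- read_soil_survey(file.path(INPUT_DIR, "mapunits.geojson"),
                           file.path(INPUT_DIR, "components.csv"),
                           file.path(INPUT_DIR, "horizons.csv"))
dem <- read_raster(file.path(INPUT_DIR, "dem.asc"))
ext <- c(dem$xmin, dem$ymax - nrow(dem$values) * dem$cellsize,
         dem$xmin + ncol(dem$values) * dem$cellsize, dem$ymax)
for (attribute in c("drainage", "depth", "awc", "ph")) {
  g <- rasterize_attribute(survey, attribute, cell = dem$cellsize,
                           extent = ext)
  write_raster(g, file.path(SURFACE_DIR, sprintf("soil_%s.asc", attribute)))
}
writeLines(c("soil_drainage.asc integer codes:",
             sprintf("%d = %s", DRAINAGE_CLASSES, names(DRAINAGE_CLASSES))),
           file.path(SURFACE_DIR, "drainage_legend.txt"))
cat(sprintf("soil attribute surfaces for %d map units written under %s\n",
            length(survey$mapunits), SURFACE_DIR))
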