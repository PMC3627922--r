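# Shared configuration for the analysis workflow.
#
# The study region is synthetic (no external downloads): a composite
# terrain with a regional gradient and a central hill, six appellation-like
# zones, a small lake, and an eight-unit soil survey. All drivers source
# this file; everything downstream is a pure function of these settings.

library(terroirgrid)

SEED <- 20130416L

STUDY_CFG <- fixture_config(
  extent = c(80, 80), cell = 100,          # 8 x 8 km at 100 m
  dem_kind = "composite",
  dem_params = list(base = 250, gx = 0.012, gy = 0.02,
                    amplitude = 180, width = 1800),
  lapse_rate = -6.5,                        # deg C / km
  ppt_gradient = 60,                        # mm / km of elevation
  frost_coupling = 3,                       # days / 100 m, each season end
  noise_sd = list(temp = 0.15, ppt = 1.5, frost = 1),
  n_mapunits = 18,
  n_zones = 6,
  water = TRUE,
  seed = SEED)

SOLAR <- solar_params(latitude = 46)        # inland Pacific Northwest
HORIZON_RADIUS <- 1000                      # m; terrain shading search

INPUT_DIR <- "results/inputs"
SURFACE_DIR <- "results/surfaces"
TABLE_DIR <- "results/tables"

for (d in c(INPUT_DIR, SURFACE_DIR, TABLE_DIR))
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
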