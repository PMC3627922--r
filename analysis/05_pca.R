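#!/usr/bin/env Rscript
# Step 5 -- standardized PCA of the seven-layer environmental stack,
# run separately for every zone (as each appellation was analyzed on its
# own cells). Writes pca_<zone>.csv with an eigenvalue/variance header
# block followed by the per-layer loadings.

source("analysis/00_config.R")

zones <- read_vector(file.path(INPUT_DIR, "zones.geojson"),
                     water = file.path(INPUT_DIR, "water.geojson"))
surf <- function(f) read_raster(file.path(SURFACE_DIR, f))
layers <- list(elevation = read_raster(file.path(INPUT_DIR, "dem.asc")),
               awc = surf("soil_awc.asc"),
               ph = surf("soil_ph.asc"),
               depth = surf("soil_depth.asc"),
               gdd = surf("gdd.asc"),
               ffd = surf("ffd.asc"),
               gsp = surf("gsp.asc"))
layers <- lapply(layers, apply_water_mask, zones = zones)

mask_to_zone <- function(g, member) {
  v <- g$values
  v[!member] <- NA
  grid_create(v, g$xmin, g$ymax, g$cellsize, g$crs)
}

overview <- NULL
for (id in zone_ids(zones)) {
  member <- terroirgrid:::polygon_membership(layers$elevation,
                                             zones$zones[[id]])
  zone_layers <- lapply(layers, mask_to_zone, member = member)
  pc <- tryCatch(principal_components(stack_spec(zone_layers)),
                 error = function(e) {
                   cat(sprintf("%s: skipped (%s)\n", id, conditionMessage(e)))
                   NULL
                 })
  if (is.null(pc)) next
  out <- file.path(TABLE_DIR, sprintf("pca_%s.csv", id))
  con <- file(out, "w")
  writeLines(c(
    sprintf("# zone: %s (n = %d cells)", id, pc$n),
    sprintf("# eigenvalues: %s",
            paste(sprintf("%.6f", pc$eigenvalues), collapse = ", ")),
    sprintf("# variance_fractions: %s",
            paste(sprintf("%.6f", pc$variance_fractions), collapse = ", ")),
    sprintf("# cumulative_fractions: %s",
            paste(sprintf("%.6f", pc$cumulative_fractions),
                  collapse = ", "))), con)
  df <- data.frame(layer = rownames(pc$loadings),
                   round(pc$loadings, 6), check.names = FALSE)
  names(df)[-1] <- sprintf("PC%d", seq_len(ncol(pc$loadings)))
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  overview <- rbind(overview, data.frame(
    zone = id, n = pc$n,
    pc1_pct = round(100 * pc$variance_fractions[1], 1),
    two_pc_pct = round(100 * cumulative_variance(pc, 2), 1),
    four_pc_pct = round(100 * cumulative_variance(pc, 4), 1)))
}

cat("variance explained by zone:\n")
print(overview, row.names = FALSE)
cat(sprintf("\nall zones reach >= 60%% with two components: %s\n",
            all(overview$two_pc_pct >= 60)))
cat(sprintf("all zones reach >= 85%% with four components: %s\n",
            all(overview$four_pc_pct >= 85)))
cat(sprintf("per-zone loadings written under %s\n", TABLE_DIR))
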