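#' Synthetic study-region fixtures
#'
#' Generates every input the pipeline consumes -- DEMs, elevation-coupled
#' monthly climate normals, frost-date surfaces, SSURGO-style soil
#' surveys, and zone/water polygons -- with the statistical structure the
#' analysis assumes: temperature falls with elevation at a fixed lapse
#' rate, precipitation rises with elevation, and the frost window
#' narrows with elevation. Every generator is a pure function of its
#' configuration (including the seed); the same config yields identical
#' output on every run.
#'
#' @name synthetic_data
NULL

# Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Sea-level monthly mean temperature (deg C) and precipitation (mm),
# April-October: a continental, semi-arid seasonal course typical of the
# inland Pacific Northwest basins.
SEA_LEVEL_TAVG <- c(`04` = 12, `05` = 16.5, `06` = 20.5, `07` = 24,
                    `08` = 23.5, `09` = 19, `10` = 12.5)
SEA_LEVEL_PPT <- c(`04` = 28, `05` = 22, `06` = 16, `07` = 9,
                   `08` = 10, `09` = 14, `10` = 24)

#' Fixture configuration
#'
#' @param extent grid size as `c(rows, cols)`.
#' @param cell cell size, meters.
#' @param dem_kind `"plane"`, `"hill"`, `"valley"`, or `"composite"`.
#' @param dem_params list of analytic DEM parameters: `base` (m), `gx`,
#'   `gy` (m/m gradients, plane/composite), `amplitude` (m, hill/valley/
#'   composite), `width` (m, Gaussian length scale).
#' @param lapse_rate temperature change with elevation, deg C per km
#'   (negative; default -6.5, the standard environmental lapse rate).
#' @param ppt_gradient growing-season precipitation change, mm per km of
#'   elevation.
#' @param frost_coupling days the frost window narrows per 100 m of
#'   elevation (applied to each end of the season).
#' @param diurnal_range fixed tmax - tmin spread, deg C; tmax/tmin are
#'   derived as tavg +/- half this range, so tmax >= tmin by
#'   construction.
#' @param noise_sd named list of additive Gaussian noise SDs: `temp`
#'   (deg C), `ppt` (mm), `frost` (days).
#' @param n_mapunits soil map-unit count.
#' @param n_zones zone polygon count.
#' @param water add a water polygon overlapping the first zone?
#' @param seed integer; fully determines every generated output.
#' @param crs CRS tag stamped on all outputs.
#' @return a `fixture_config` list.
#' @export
fixture_config <- function(extent = c(60, 60), cell = 100,
                           dem_kind = c("plane", "hill", "valley",
                                        "composite"),
                           dem_params = list(),
                           lapse_rate = -6.5,
                           ppt_gradient = 60,
                           frost_coupling = 3,
                           diurnal_range = 12,
                           noise_sd = list(temp = 0, ppt = 0, frost = 0),
                           n_mapunits = 6,
                           n_zones = 4,
                           water = FALSE,
                           seed = 42,
                           crs = "local-m") {
  dem_kind <- match.arg(dem_kind)
  dp <- utils::modifyList(list(base = 200, gx = 0.02, gy = 0.03,
                               amplitude = 300, width = 2000), dem_params)
  ns <- utils::modifyList(list(temp = 0, ppt = 0, frost = 0), noise_sd)
  structure(list(extent = extent, cell = cell, dem_kind = dem_kind,
                 dem_params = dp, lapse_rate = lapse_rate,
                 ppt_gradient = ppt_gradient,
                 frost_coupling = frost_coupling,
                 diurnal_range = diurnal_range, noise_sd = ns,
                 n_mapunits = n_mapunits, n_zones = n_zones,
                 water = water, seed = as.integer(seed), crs = crs),
            class = "fixture_config")
}

#' Generate a synthetic DEM
#'
#' Analytic terrain surfaces whose parameters are recorded in the
#' `dem_params` attribute for oracle tests: an exact plane, a Gaussian
#' hill, an incised valley (plateau minus a Gaussian channel), or a
#' composite (plane + hill + seeded roughness).
#'
#' @param config a [fixture_config()].
#' @return elevation `grid` (meters).
#' @export
make_dem <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  nr <- config$extent[1]; nc <- config$extent[2]
  cell <- config$cell
  p <- config$dem_params
  g0 <- grid_create(matrix(0, nr, nc), xmin = 0, ymax = nr * cell,
                    cellsize = cell, crs = config$crs)
  x <- matrix(rep(grid_x(g0), each = nr), nr, nc)
  y <- matrix(rep(grid_y(g0), nc), nr, nc)
  cx <- nc * cell / 2; cy <- nr * cell / 2
  z <- switch(config$dem_kind,
    plane = p$base + p$gx * x + p$gy * y,
    hill = p$base + p$amplitude *
      exp(-((x - cx)^2 + (y - cy)^2) / (2 * p$width^2)),
    valley = p$base + p$amplitude *
      (1 - exp(-(y - cy)^2 / (2 * p$width^2))),
    composite = with_seed(config$seed, {
      p$base + p$gx * x + p$gy * y +
        p$amplitude * exp(-((x - cx)^2 + (y - cy)^2) / (2 * p$width^2)) +
        matrix(stats::rnorm(nr * nc, sd = p$amplitude / 50), nr, nc)
    }))
  out <- grid_like(g0, z)
  attr(out, "dem_params") <- c(list(kind = config$dem_kind), p)
  out
}

#' Generate elevation-coupled monthly climate normals
#'
#' Monthly mean temperature follows a sea-level seasonal course plus
#' `lapse_rate * elevation / 1000` plus optional Gaussian noise; tmax and
#' tmin sit a fixed half diurnal range above and below it.
#' Growing-season precipitation increases with elevation by
#' `ppt_gradient` mm/km (spread evenly over the seven months, floored at
#' zero). Frost dates move with elevation by `frost_coupling` days per
#' 100 m at each end of the season, with `first_fall >= last_spring`
#' enforced.
#'
#' @param dem elevation `grid` from [make_dem()].
#' @param config a [fixture_config()].
#' @return a [monthly_normals()].
#' @export
make_monthly_normals <- function(dem, config) {
  stopifnot(is_grid(dem), inherits(config, "fixture_config"))
  elev <- dem$values
  nr <- nrow(elev); nc <- ncol(elev)
  half <- config$diurnal_range / 2
  ns <- config$noise_sd
  with_seed(config$seed + 1L, {
    tmax <- list(); tmin <- list(); ppt <- list()
    for (m in SEASON_MONTHS) {
      tavg <- SEA_LEVEL_TAVG[[m]] + config$lapse_rate * elev / 1000
      if (ns$temp > 0)
        tavg <- tavg + matrix(stats::rnorm(nr * nc, sd = ns$temp), nr, nc)
      pm <- SEA_LEVEL_PPT[[m]] +
        (config$ppt_gradient / length(SEASON_MONTHS)) * elev / 1000
      if (ns$ppt > 0)
        pm <- pm + matrix(stats::rnorm(nr * nc, sd = ns$ppt), nr, nc)
      tmax[[m]] <- grid_like(dem, tavg + half)
      tmin[[m]] <- grid_like(dem, tavg - half)
      ppt[[m]] <- grid_like(dem, pmax(pm, 0))
    }
    spring <- 110 + config$frost_coupling * elev / 100
    fall <- 285 - config$frost_coupling * elev / 100
    if (ns$frost > 0) {
      spring <- spring + matrix(stats::rnorm(nr * nc, sd = ns$frost), nr, nc)
      fall <- fall + matrix(stats::rnorm(nr * nc, sd = ns$frost), nr, nc)
    }
    fall <- pmax(fall, spring)
    clamp <- function(x) pmin(pmax(x, 1), 366)
    monthly_normals(tmax, tmin, ppt,
                    last_spring_frost = grid_like(dem, clamp(spring)),
                    first_fall_frost = grid_like(dem, clamp(fall)))
  })
}

# Jittered partition of [0, total] into n segments (returns n+1 cut
# points including the ends).
jitter_cuts <- function(n, total, jitter = 0.25) {
  cuts <- seq(0, total, length.out = n + 1)
  if (n > 1) {
    step <- total / n
    mid <- cuts[2:n] + stats::runif(n - 1, -jitter, jitter) * step
    cuts[2:n] <- sort(mid)
  }
  cuts
}

#' Generate a synthetic SSURGO-style soil survey
#'
#' Map units form a jittered rectangular partition of the extent; each
#' map unit carries 1-3 components with percents summing to 100, and
#' each component 2-4 horizons with AWC in 0.05-0.25 cm/cm, pH in
#' 5.5-8.5, and an optional restrictive depth. The ground-truth dominant
#' attributes of every map unit are recorded in the `truth` attribute
#' for oracle tests.
#'
#' @param config a [fixture_config()].
#' @return a [soil_survey()] with a `truth` data.frame attribute
#'   (`mukey`, `cokey`, `drainage_code`, `depth`, `awc`, `ph`).
#' @export
make_soil_survey <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_mapunits
  width <- config$extent[2] * config$cell
  height <- config$extent[1] * config$cell
  with_seed(config$seed + 2L, {
    nrow_blk <- max(1L, floor(sqrt(n)))
    per_row <- diff(floor(seq(0, n, length.out = nrow_blk + 1)))
    ycuts <- jitter_cuts(nrow_blk, height)
    mapunits <- list()
    idx <- 0L
    for (r in seq_len(nrow_blk)) {
      xcuts <- jitter_cuts(per_row[r], width)
      for (b in seq_len(per_row[r])) {
        idx <- idx + 1L
        mapunits[[sprintf("mu%02d", idx)]] <-
          poly_rect(xcuts[b], ycuts[r], xcuts[b + 1], ycuts[r + 1])
      }
    }
    class_pool <- names(DRAINAGE_CLASSES)
    class_prob <- c(0.05, 0.10, 0.60, 0.10, 0.10, 0.04, 0.01)
    comp_rows <- list(); hor_rows <- list(); truth_rows <- list()
    for (mukey in names(mapunits)) {
      ncomp <- sample.int(3L, 1L)
      raw <- stats::runif(ncomp, 0.5, 1.5)
      pct <- round(100 * raw / sum(raw))
      pct[1] <- pct[1] + (100L - sum(pct))   # force exact total
      for (ci in seq_len(ncomp)) {
        cokey <- sprintf("%s_c%d", mukey, ci)
        depth <- if (stats::runif(1) < 0.6)
          round(stats::runif(1, 30, 200)) else NA_real_
        comp_rows[[cokey]] <- data.frame(
          mukey = mukey, cokey = cokey, percent = pct[ci],
          drainage_class = sample(class_pool, 1L, prob = class_prob),
          depth_to_restrictive = depth, stringsAsFactors = FALSE)
        nh <- sample(2:4, 1L)
        bounds <- cumsum(c(0, round(stats::runif(nh, 10, 40))))
        hor_rows[[cokey]] <- data.frame(
          cokey = cokey,
          top = bounds[-length(bounds)], bottom = bounds[-1],
          awc = round(stats::runif(nh, 0.05, 0.25), 3),
          ph = round(stats::runif(nh, 5.5, 8.5), 2),
          stringsAsFactors = FALSE)
      }
    }
    components <- do.call(rbind, c(comp_rows, make.row.names = FALSE))
    horizons <- do.call(rbind, c(hor_rows, make.row.names = FALSE))
    survey <- soil_survey(mapunits, components, horizons, crs = config$crs)
    truth <- do.call(rbind, lapply(names(mapunits), function(mk) {
      ck <- select_dominant_component(survey, mk)
      data.frame(mukey = mk, cokey = ck,
                 drainage_code = component_attribute(survey, ck, "drainage"),
                 depth = component_attribute(survey, ck, "depth"),
                 awc = component_attribute(survey, ck, "awc"),
                 ph = component_attribute(survey, ck, "ph"),
                 stringsAsFactors = FALSE)
    }))
    attr(survey, "truth") <- truth
    survey
  })
}

#' Generate zone and water polygons
#'
#' Non-overlapping rectangular zones laid out in panels over the extent,
#' inset from the panel edges so cell centers never sit on a shared
#' boundary. With `config$water`, a water rectangle overlapping zone 1
#' is added. Zone areas (m^2) are recorded in the `areas` attribute.
#'
#' @param config a [fixture_config()].
#' @return a [zone_set()] with zones named `zone01`, `zone02`, ...
#' @export
make_zones <- function(config) {
  stopifnot(inherits(config, "fixture_config"))
  n <- config$n_zones
  width <- config$extent[2] * config$cell
  height <- config$extent[1] * config$cell
  inset <- config$cell / 4
  nrow_blk <- max(1L, floor(sqrt(n)))
  per_row <- diff(floor(seq(0, n, length.out = nrow_blk + 1)))
  ycuts <- seq(0, height, length.out = nrow_blk + 1)
  zones <- list(); areas <- numeric(0)
  idx <- 0L
  for (r in seq_len(nrow_blk)) {
    xcuts <- seq(0, width, length.out = per_row[r] + 1)
    for (b in seq_len(per_row[r])) {
      idx <- idx + 1L
      x1 <- xcuts[b] + inset; x2 <- xcuts[b + 1] - inset
      y1 <- ycuts[r] + inset; y2 <- ycuts[r + 1] - inset
      zones[[sprintf("zone%02d", idx)]] <- poly_rect(x1, y1, x2, y2)
      areas[sprintf("zone%02d", idx)] <- (x2 - x1) * (y2 - y1)
    }
  }
  water <- list()
  if (isTRUE(config$water)) {
    wside <- min(width, height) / 5
    water[[1]] <- poly_rect(inset, inset, inset + wside, inset + wside)
  }
  zs <- zone_set(zones, water = water, crs = config$crs)
  attr(zs, "areas") <- areas
  zs
}

#' Write a complete fixture input tree
#'
#' Materializes a configuration as the on-disk inputs the pipeline
#' reads: `dem.asc`, per-month `tmax_MM.asc` / `tmin_MM.asc` /
#' `ppt_MM.asc`, frost-date grids, `zones.geojson` (plus
#' `water.geojson`), `mapunits.geojson`, `components.csv`,
#' `horizons.csv`.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_tree <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dem <- make_dem(config)
  write_raster(dem, file.path(dir, "dem.asc"))
  normals <- make_monthly_normals(dem, config)
  for (m in SEASON_MONTHS) {
    write_raster(normals$tmax[[m]], file.path(dir, sprintf("tmax_%s.asc", m)))
    write_raster(normals$tmin[[m]], file.path(dir, sprintf("tmin_%s.asc", m)))
    write_raster(normals$ppt[[m]], file.path(dir, sprintf("ppt_%s.asc", m)))
  }
  write_raster(normals$last_spring_frost,
               file.path(dir, "last_spring_frost.asc"))
  write_raster(normals$first_fall_frost,
               file.path(dir, "first_fall_frost.asc"))
  zones <- make_zones(config)
  write_vector(zones, file.path(dir, "zones.geojson"),
               water_path = if (length(zones$water))
                 file.path(dir, "water.geojson"))
  survey <- make_soil_survey(config)
  muzs <- zone_set(survey$mapunits, crs = config$crs)
  write_vector(muzs, file.path(dir, "mapunits.geojson"), id_field = "mukey")
  utils::write.csv(survey$components, file.path(dir, "components.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$horizons, file.path(dir, "horizons.csv"),
                   row.names = FALSE)
  invisible(dir)
}
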