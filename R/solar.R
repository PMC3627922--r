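#' Solar model parameters
#'
#' Parameter set for the clear-sky growing-season insolation model: a
#' horizon-angle viewshed, a lattice of sun positions over the season, and
#' a uniform diffuse sky. Defaults reproduce the study configuration:
#' season from ordinal day 91 to 304 (1 April to 31 October) sampled at
#' 14-day and 2-hour intervals, 32 viewshed azimuth directions, an 8 x 8
#' zenith/azimuth sky map over a 40,000-cell hemisphere raster, diffuse
#' proportion 0.3, and transmissivity 0.5 (generally clear sky).
#'
#' @param latitude site latitude in decimal degrees (mean latitude of the
#'   DEM extent; the model evaluates all sun positions at this single
#'   latitude).
#' @param sky_cells cells in the hemisphere projection raster; sets the
#'   azimuth discretization of the diffuse integral (its square root is
#'   the number of azimuth steps around the horizon).
#' @param day_start,day_end,day_step ordinal-day season window and lattice
#'   step (days).
#' @param hour_step hour lattice step (hours); positions sit at bin
#'   centers.
#' @param n_azimuth_viewshed number of horizon-angle directions.
#' @param n_zenith_div,n_azimuth_div sky-map sector divisions.
#' @param diffuse_proportion fraction of global radiation that is diffuse
#'   on an unobstructed horizontal surface, in (0, 1).
#' @param transmissivity atmospheric transmissivity in \[0, 1\] (fraction
#'   transmitted through one vertical air mass).
#' @param solar_constant top-of-atmosphere irradiance, W/m^2.
#' @return an object of class `solar_params`.
#' @export
solar_params <- function(latitude,
                         sky_cells = 40000,
                         day_start = 91, day_end = 304, day_step = 14,
                         hour_step = 2,
                         n_azimuth_viewshed = 32,
                         n_zenith_div = 8, n_azimuth_div = 8,
                         diffuse_proportion = 0.3,
                         transmissivity = 0.5,
                         solar_constant = 1367) {
  stopifnot(diffuse_proportion > 0, diffuse_proportion < 1,
            transmissivity >= 0, transmissivity <= 1,
            day_start >= 1, day_start <= day_end, day_end <= 366,
            day_step >= 1, hour_step > 0,
            n_azimuth_viewshed >= 4, sky_cells >= 16)
  structure(list(latitude = latitude, sky_cells = sky_cells,
                 day_start = day_start, day_end = day_end,
                 day_step = day_step, hour_step = hour_step,
                 n_azimuth_viewshed = n_azimuth_viewshed,
                 n_zenith_div = n_zenith_div, n_azimuth_div = n_azimuth_div,
                 diffuse_proportion = diffuse_proportion,
                 transmissivity = transmissivity,
                 solar_constant = solar_constant),
            class = "solar_params")
}

#' Solar declination (Cooper approximation)
#'
#' @param day ordinal day of year.
#' @return declination in degrees. Sub-degree accuracy, sufficient for a
#'   seasonal accumulation used comparatively.
#' @export
solar_declination <- function(day) {
  23.45 * sin(2 * pi * (284 + day) / 365)
}

#' Sun positions on the configured day/hour lattice
#'
#' Zenith and azimuth of the sun at the parameter latitude for each
#' (ordinal day, hour) on the season lattice, from the standard
#' declination / hour-angle formulas. Positions below the astronomical
#' horizon are excluded. Each retained position carries the number of
#' hours it represents (`day_step * hour_step`).
#'
#' @param params a [solar_params()].
#' @return data.frame with columns `day`, `hour`, `zenith`, `azimuth`
#'   (degrees, azimuth clockwise from north) and `weight_h` (hours).
#' @export
sun_positions <- function(params) {
  days <- seq(params$day_start, params$day_end, by = params$day_step)
  hours <- seq(params$hour_step / 2, 24, by = params$hour_step)
  lat <- params$latitude * pi / 180
  out <- expand.grid(day = days, hour = hours)
  decl <- solar_declination(out$day) * pi / 180
  H <- (out$hour - 12) * 15 * pi / 180
  cosz <- sin(lat) * sin(decl) + cos(lat) * cos(decl) * cos(H)
  up <- cosz > 1e-12
  out <- out[up, , drop = FALSE]
  decl <- decl[up]; H <- H[up]; cosz <- cosz[up]
  east <- -cos(decl) * sin(H)
  north <- sin(decl) * cos(lat) - cos(decl) * cos(H) * sin(lat)
  az <- (atan2(east, north) * 180 / pi) %% 360
  data.frame(day = out$day, hour = out$hour,
             zenith = acos(pmin(1, cosz)) * 180 / pi,
             azimuth = az,
             weight_h = params$day_step * params$hour_step,
             row.names = NULL)
}

#' Horizon elevation angles by viewshed azimuth
#'
#' For every DEM cell and each of `n_azimuth_viewshed` compass directions,
#' the maximum elevation angle (degrees above horizontal) to any DEM cell
#' sampled along that ray within `max_radius`, or 0 if nothing obstructs.
#' Rays are walked in one-cell steps with nearest-cell sampling.
#'
#' @param dem elevation `grid` (meters).
#' @param params a [solar_params()] (supplies the direction count).
#' @param max_radius search radius in meters, at least one cell.
#' @return object of class `horizon_set`: list with `angles` (array
#'   rows x cols x directions), `azimuths` (degrees), and the DEM
#'   georeferencing.
#' @export
compute_horizon_angles <- function(dem, params, max_radius) {
  stopifnot(is_grid(dem), inherits(params, "solar_params"))
  if (!is.numeric(max_radius) || max_radius < dem$cellsize)
    stop("max_radius must be at least one cell")
  v <- dem$values
  nr <- nrow(v); nc <- ncol(v)
  naz <- params$n_azimuth_viewshed
  azimuths <- (seq_len(naz) - 1) * 360 / naz
  nsteps <- floor(max_radius / dem$cellsize)
  angles <- array(0, dim = c(nr, nc, naz))
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (k in seq_len(naz)) {
    az <- azimuths[k] * pi / 180
    dx <- sin(az); dy <- cos(az)
    best <- matrix(0, nr, nc)
    for (s in seq_len(nsteps)) {
      d <- s * dem$cellsize
      rr <- rows - round(dy * s)   # north = decreasing row
      cc <- cols + round(dx * s)
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      if (!any(ok)) break
      zs <- matrix(NA_real_, nr, nc)
      zs[ok] <- v[cbind(rr[ok], cc[ok])]
      ang <- atan2(zs - v, d) * 180 / pi
      upd <- which(!is.na(ang) & ang > best)
      best[upd] <- ang[upd]
    }
    best[is.na(v)] <- NA
    angles[, , k] <- best
  }
  structure(list(angles = angles, azimuths = azimuths,
                 xmin = dem$xmin, ymax = dem$ymax,
                 cellsize = dem$cellsize, crs = dem$crs),
            class = "horizon_set")
}

# Horizon angle at an arbitrary azimuth, linearly interpolated between the
# two adjacent viewshed directions; returns a matrix over all cells.
horizon_at_azimuth <- function(horizons, azimuth) {
  naz <- length(horizons$azimuths)
  step <- 360 / naz
  pos <- (azimuth %% 360) / step
  k0 <- floor(pos) %% naz
  w <- pos - floor(pos)
  h0 <- horizons$angles[, , k0 + 1]
  h1 <- horizons$angles[, , (k0 + 1) %% naz + 1]
  (1 - w) * h0 + w * h1
}

#' Growing-season clear-sky insolation
#'
#' Accumulated radiation (Wh/m^2) per cell over the configured season.
#' The direct beam sums `solar_constant * transmissivity^m(zenith) *
#' cos(incidence)` over all sun-lattice positions whose altitude clears
#' the interpolated horizon angle at the sun azimuth, with relative
#' optical air mass `m = exp(-0.000118 * elevation) / cos(zenith)`.
#' The diffuse component integrates a uniform-radiance sky over the
#' zenith/azimuth sky-map sectors restricted to the unobstructed part of
#' each azimuth column (exact in zenith, discretized in azimuth at the
#' resolution implied by `sky_cells`), scaled so that diffuse is
#' `diffuse_proportion` of global radiation on an unobstructed horizontal
#' surface. Negative incidence contributes zero.
#'
#' @param dem elevation `grid`.
#' @param slope slope `grid` from [compute_slope()] (percent rise).
#' @param aspect aspect `grid` from [compute_aspect()].
#' @param horizons a `horizon_set` from [compute_horizon_angles()].
#' @param params a [solar_params()].
#' @return insolation `grid` in Wh/m^2 (non-negative; zero under full
#'   obstruction).
#' @export
compute_insolation <- function(dem, slope, aspect, horizons, params) {
  stopifnot(is_grid(dem), inherits(params, "solar_params"))
  check_aligned(dem, slope, "dem/slope")
  check_aligned(dem, aspect, "dem/aspect")
  if (!identical(dim(horizons$angles)[1:2], dim(dem$values)))
    stop("horizon set does not match DEM dimensions")
  elev <- dem$values
  s_rad <- atan(slope$values / 100)
  a_deg <- aspect$values
  a_deg[which(a_deg == ASPECT_FLAT)] <- 0  # slope is 0 there; term vanishes
  a_rad <- a_deg * pi / 180
  S0 <- params$solar_constant
  Tr <- params$transmissivity
  sun <- sun_positions(params)
  direct <- matrix(0, nrow(elev), ncol(elev))
  flat_unobst <- matrix(0, nrow(elev), ncol(elev))
  elev0 <- ifelse(is.na(elev), 0, elev)
  for (i in seq_len(nrow(sun))) {
    zen <- sun$zenith[i] * pi / 180
    azi <- sun$azimuth[i]
    cosz <- cos(zen)
    m <- exp(-0.000118 * elev0) / cosz
    beam <- S0 * Tr^m * sun$weight_h[i]
    h <- horizon_at_azimuth(horizons, azi)
    vis <- (90 - sun$zenith[i]) > h
    cosi <- cosz * cos(s_rad) +
      sin(zen) * sin(s_rad) * cos((azi * pi / 180) - a_rad)
    direct <- direct + ifelse(vis, beam * pmax(cosi, 0), 0)
    flat_unobst <- flat_unobst + beam * cosz
  }
  # Uniform diffuse sky over the sky-map sectors. For each azimuth substep
  # the zenith integral of cos(incidence) * sin(z) has a closed form:
  #   int (cosz cos s + sinz sin s cos(da)) sinz dz
  #     = cos s * sin(z)^2/2 + sin s cos(da) * (z/2 - sin(2z)/4)
  A <- function(z) sin(z)^2 / 2
  B <- function(z) z / 2 - sin(2 * z) / 4
  n_sub <- max(params$n_azimuth_div,
               round(sqrt(params$sky_cells)))  # azimuth steps around horizon
  dphi <- 2 * pi / n_sub
  zen_edges <- seq(0, pi / 2, length.out = params$n_zenith_div + 1)
  sky <- matrix(0, nrow(elev), ncol(elev))
  cos_s <- cos(s_rad); sin_s <- sin(s_rad)
  for (j in seq_len(n_sub)) {
    phi_deg <- (j - 0.5) * 360 / n_sub
    h <- horizon_at_azimuth(horizons, phi_deg)
    zmax_open <- (90 - h) * pi / 180          # unobstructed zenith ceiling
    cos_da <- cos(phi_deg * pi / 180 - a_rad)
    # zenith beyond which the facet no longer sees this azimuth column
    z_clamp <- ifelse(cos_da < 0, atan(cos_s / (sin_s * (-cos_da))), pi / 2)
    z_clamp[which(sin_s == 0)] <- pi / 2
    zmax <- pmin(zmax_open, z_clamp)
    for (b in seq_len(params$n_zenith_div)) {
      z1 <- zen_edges[b]; z2 <- zen_edges[b + 1]
      zt <- pmin(pmax(zmax, z1), z2)
      sky <- sky + dphi * (cos_s * (A(zt) - A(z1)) +
                           sin_s * cos_da * (B(zt) - B(z1)))
    }
  }
  sky_flat_unobst <- pi  # same integral, flat facet, no obstruction
  dp <- params$diffuse_proportion
  diffuse_flat <- dp / (1 - dp) * flat_unobst
  diffuse <- diffuse_flat * pmax(sky, 0) / sky_flat_unobst
  total <- direct + diffuse
  total[is.na(elev) | is.na(slope$values) | is.na(aspect$values)] <- NA
  grid_like(dem, total)
}

#' One-call insolation from a DEM
#'
#' Convenience wrapper chaining [compute_slope()], [compute_aspect()],
#' [compute_horizon_angles()], and [compute_insolation()].
#'
#' @inheritParams compute_horizon_angles
#' @return insolation `grid` in Wh/m^2.
#' @export
compute_insolation_dem <- function(dem, params, max_radius) {
  sl <- compute_slope(dem)
  as <- compute_aspect(dem)
  hz <- compute_horizon_angles(dem, params, max_radius)
  compute_insolation(dem, sl, as, hz, params)
}

#' Split a DEM into north-south tiles with overlap
#'
#' Large extents are divided into latitude bands so the sun-position
#' lattice can be evaluated at a near-constant mean latitude per tile;
#' adjacent tiles share an overlap strip that [blend_mosaic()] later
#' feathers across. A DEM smaller than the band limit comes back as a
#' single tile, unchanged.
#'
#' @param dem elevation `grid`.
#' @param max_extent_deg maximum tile height in degrees of latitude
#'   (converted at 111,320 m per degree).
#' @param overlap overlap strip height in meters (>= 0).
#' @return list of `grid` tiles ordered north to south.
#' @export
tile_by_latitude <- function(dem, max_extent_deg, overlap = 0) {
  stopifnot(is_grid(dem), overlap >= 0)
  meters_per_deg <- 111320
  max_h <- max_extent_deg * meters_per_deg
  nr <- nrow(dem$values)
  height <- nr * dem$cellsize
  if (height <= max_h) return(list(dem))
  ntile <- ceiling(height / max_h)
  core <- ceiling(nr / ntile)
  ov_rows <- ceiling(overlap / dem$cellsize)
  if (ov_rows >= core)
    stop("overlap larger than tile height")
  tiles <- vector("list", ntile)
  for (t in seq_len(ntile)) {
    r1 <- (t - 1) * core + 1
    r2 <- min(t * core, nr)
    r1e <- max(1L, r1 - ov_rows)
    r2e <- min(nr, r2 + ov_rows)
    sub <- dem$values[r1e:r2e, , drop = FALSE]
    tiles[[t]] <- grid_create(sub, dem$xmin,
                              dem$ymax - (r1e - 1) * dem$cellsize,
                              dem$cellsize, dem$crs)
  }
  tiles
}

#' Blend tiled surfaces back into one mosaic
#'
#' Tiles (north to south, sharing the column layout) are reassembled:
#' outside overlaps the mosaic equals the unique covering tile; inside an
#' overlap strip of L rows, the two tiles are combined with complementary
#' linear ramp weights `(L - j + 0.5)/L` and `(j - 0.5)/L`, so the mosaic
#' is always a convex combination of the overlapping values.
#'
#' @param tiles list of co-registered `grid` tiles from a
#'   [tile_by_latitude()] split (same columns, overlapping row ranges).
#' @return single mosaicked `grid`.
#' @export
blend_mosaic <- function(tiles) {
  stopifnot(length(tiles) >= 1)
  if (length(tiles) == 1L) return(tiles[[1]])
  ord <- order(vapply(tiles, function(t) t$ymax, numeric(1)),
               decreasing = TRUE)
  tiles <- tiles[ord]
  cell <- tiles[[1]]$cellsize
  ymax <- tiles[[1]]$ymax
  nc <- ncol(tiles[[1]]$values)
  r_start <- vapply(tiles, function(t)
    as.integer(round((ymax - t$ymax) / cell)) + 1L, integer(1))
  r_end <- r_start + vapply(tiles, function(t) nrow(t$values), integer(1)) - 1L
  for (t in seq_along(tiles)[-1]) {
    if (r_start[t] > r_end[t - 1] + 1L) stop("gap between tiles")
    if (ncol(tiles[[t]]$values) != nc) stop("tiles have different columns")
  }
  nr <- max(r_end)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  for (t in seq_along(tiles)) {
    rows <- r_start[t]:r_end[t]
    w <- rep(1, length(rows))
    if (t > 1) {                       # ramp up across overlap with north tile
      L <- r_end[t - 1] - r_start[t] + 1L
      if (L > 0) w[seq_len(L)] <- (seq_len(L) - 0.5) / L
    }
    if (t < length(tiles)) {           # ramp down toward south tile
      L <- r_end[t] - r_start[t + 1] + 1L
      if (L > 0)
        w[(length(rows) - L + 1):length(rows)] <- (L - seq_len(L) + 0.5) / L
    }
    vals <- tiles[[t]]$values
    wmat <- matrix(w, length(rows), nc)
    wmat[is.na(vals)] <- 0
    vals[is.na(vals)] <- 0
    num[rows, ] <- num[rows, ] + wmat * vals
    den[rows, ] <- den[rows, ] + wmat
  }
  out <- num / den
  out[den == 0] <- NA
  grid_create(out, tiles[[1]]$xmin, ymax, cell, tiles[[1]]$crs)
}
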