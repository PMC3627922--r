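#' Terrain derivatives: slope, aspect, aspect sectors
#'
#' Slope and aspect are computed from a DEM with Horn's 3x3 weighted
#' finite-difference stencil, the default of mainstream GIS packages.
#' Slope is reported in percent rise (100 * rise/run); aspect is the
#' downslope azimuth in degrees clockwise from north, with zero-slope
#' cells carrying the flat sentinel value.
#'
#' @name terrain
NULL

#' Sentinel value marking flat (zero-slope) cells in an aspect grid
#' @export
ASPECT_FLAT <- -1

# Pad a matrix by replicating its edge rows/columns once.
pad_replicate <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

# Horn gradient components (dz/dx eastward, dz/dy northward) for every
# cell. Edge cells use edge replication; any NA in the 3x3 neighborhood
# yields NA at the center.
horn_gradient <- function(dem) {
  v <- dem$values
  if (nrow(v) < 3 || ncol(v) < 3)
    stop("DEM must be at least 3 x 3 cells")
  p <- pad_replicate(v)
  nr <- nrow(v); nc <- ncol(v)
  sh <- function(dr, dc) p[(1 + dr):(nr + dr), (1 + dc):(nc + dc)]
  a <- sh(0, 0); b <- sh(0, 1); cc <- sh(0, 2)   # northern row
  d <- sh(1, 0);                f  <- sh(1, 2)
  g <- sh(2, 0); h <- sh(2, 1); i2 <- sh(2, 2)   # southern row
  cell <- dem$cellsize
  dzdx <- ((cc + 2 * f + i2) - (a + 2 * d + g)) / (8 * cell)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + i2)) / (8 * cell)
  # a nodata center is itself nodata in the output even though the Horn
  # stencil does not read the center value
  dzdx[is.na(v)] <- NA
  dzdy[is.na(v)] <- NA
  list(dzdx = dzdx, dzdy = dzdy)
}

#' Slope in percent rise from a DEM
#'
#' @param dem `grid` of elevations in meters, at least 3 x 3 cells, with
#'   cell size in the same units as elevation.
#' @return `grid` of slope in percent rise
#'   (`100 * sqrt((dz/dx)^2 + (dz/dy)^2)`), nodata wherever the 3x3
#'   neighborhood touches nodata.
#' @examples
#' dem <- make_dem(fixture_config(extent = c(8, 8), dem_kind = "plane",
#'                                dem_params = list(gx = 0.03, gy = 0.04)))
#' s <- compute_slope(dem)
#' s$values[4, 4]  # 5% on the interior of a 3-4 plane
#' @export
compute_slope <- function(dem) {
  g <- horn_gradient(dem)
  grid_like(dem, 100 * sqrt(g$dzdx^2 + g$dzdy^2))
}

#' Downslope aspect in compass degrees from a DEM
#'
#' Azimuth of steepest descent, degrees clockwise from north in
#' `[0, 360)`. Cells with zero gradient receive [ASPECT_FLAT].
#'
#' @inheritParams compute_slope
#' @return `grid` of aspect degrees with the flat sentinel.
#' @export
compute_aspect <- function(dem) {
  g <- horn_gradient(dem)
  az <- (atan2(-g$dzdx, -g$dzdy) * 180 / pi) %% 360
  flat <- g$dzdx == 0 & g$dzdy == 0
  az[which(flat)] <- ASPECT_FLAT
  grid_like(dem, az)
}

#' Aspect sector codes and labels
#'
#' Integer codes for the eight 45-degree compass sectors plus flat:
#' N=1, NE=2, E=3, SE=4, S=5, SW=6, W=7, NW=8, Flat=9.
#' @export
ASPECT_SECTORS <- c(N = 1L, NE = 2L, E = 3L, SE = 4L,
                    S = 5L, SW = 6L, W = 7L, NW = 8L, Flat = 9L)

#' Classify aspect into eight compass sectors plus flat
#'
#' Sectors are 45 degrees wide, centered on the cardinal and intercardinal
#' azimuths, left-closed/right-open (N = \[337.5, 22.5)), so every non-flat
#' azimuth falls in exactly one sector. Flat cells keep their own category.
#'
#' @param aspect aspect `grid` from [compute_aspect()].
#' @return `grid` of integer sector codes per [ASPECT_SECTORS], with a
#'   `legend` attribute naming the codes.
#' @export
classify_aspect <- function(aspect) {
  a <- aspect$values
  code <- ((a + 22.5) %/% 45) %% 8 + 1
  code[which(a == ASPECT_FLAT)] <- ASPECT_SECTORS[["Flat"]]
  out <- grid_like(aspect, code)
  attr(out, "legend") <- ASPECT_SECTORS
  out
}
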