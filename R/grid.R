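#' Gridded raster surfaces
#'
#' A `grid` is the package's raster container: a numeric matrix of cell
#' values on a regular, north-up, projected (planar, meter-unit) lattice.
#' Row 1 is the northern edge. Nodata cells are stored as `NA`; every
#' summary operation in the package ignores them, and nodata in any input
#' layer propagates to nodata in any derived layer at that cell.
#'
#' @param values numeric matrix; row 1 is the northernmost row. `NA`
#'   entries mark nodata cells.
#' @param xmin x coordinate (m) of the western edge of the western column.
#' @param ymax y coordinate (m) of the northern edge of the northern row.
#' @param cellsize cell edge length in meters; cells are square.
#' @param crs free-text tag identifying the projected coordinate system
#'   (e.g. `"UTM11N-NAD83"`). Operations combining grids require equal tags.
#' @return An object of class `grid`.
#' @examples
#' g <- grid_create(matrix(1:12, 3, 4), xmin = 0, ymax = 300, cellsize = 100)
#' dim(g$values)
#' @export
grid_create <- function(values, xmin, ymax, cellsize, crs = "local-m") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  stopifnot(is.numeric(cellsize), length(cellsize) == 1L)
  if (!is.finite(cellsize) || cellsize <= 0)
    stop("cellsize must be strictly positive")
  g <- structure(
    list(values = values, xmin = as.numeric(xmin), ymax = as.numeric(ymax),
         cellsize = as.numeric(cellsize), crs = as.character(crs)),
    class = "grid")
  g
}

#' @export
print.grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid> %d x %d cells, cellsize %g m, crs '%s'\n",
              nrow(v), ncol(v), x$cellsize, x$crs))
  cat(sprintf("  extent: x [%g, %g], y [%g, %g]\n",
              x$xmin, x$xmin + ncol(v) * x$cellsize,
              x$ymax - nrow(v) * x$cellsize, x$ymax))
  fin <- sum(!is.na(v))
  cat(sprintf("  data cells: %d / %d", fin, length(v)))
  if (fin > 0)
    cat(sprintf("; range [%g, %g]", min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  cat("\n")
  invisible(x)
}

is_grid <- function(x) inherits(x, "grid")

#' Cell-center coordinates of a grid
#'
#' @param g a `grid`.
#' @return `grid_x`: x coordinates of the column centers (west to east).
#'   `grid_y`: y coordinates of the row centers (north to south).
#' @keywords internal
#' @export
grid_x <- function(g) g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$cellsize

#' @rdname grid_x
#' @export
grid_y <- function(g) g$ymax - (seq_len(nrow(g$values)) - 0.5) * g$cellsize

#' Nodata mask of a grid
#'
#' @param g a `grid`.
#' @return logical matrix, `TRUE` where the cell is nodata.
#' @export
nodata_mask <- function(g) is.na(g$values)

# Stop unless two grids share lattice and CRS. All analysis operations
# require pre-aligned inputs; reprojection is out of scope.
check_aligned <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s have different dimensions", what))
  tol <- 1e-9 * max(1, a$cellsize)
  if (abs(a$xmin - b$xmin) > tol || abs(a$ymax - b$ymax) > tol ||
      abs(a$cellsize - b$cellsize) > tol)
    stop(sprintf("%s are not co-registered (origin/cellsize differ)", what))
  if (!identical(a$crs, b$crs))
    stop(sprintf("CRS mismatch: '%s' vs '%s'", a$crs, b$crs))
  invisible(TRUE)
}

# Derive a grid from `g` with new values, preserving georeferencing.
grid_like <- function(g, values) {
  grid_create(values, g$xmin, g$ymax, g$cellsize, g$crs)
}

#' Read a single-band raster from an ESRI ASCII Grid file
#'
#' The package stores rasters in the ESRI ASCII Grid (`.asc`) plain-text
#' format: a six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, `NODATA_value`) followed by rows of values, northern row
#' first. An optional sidecar `<path>.prj` holds the CRS tag as free text.
#'
#' @param path path to the `.asc` file.
#' @return a [grid_create()] object with nodata cells set to `NA` and the
#'   CRS tag read from the sidecar (or `"unspecified"`).
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path))
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop(sprintf("malformed ASCII grid header line: '%s'", ln))
    hdr[[tolower(parts[1])]] <- parts[2]
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop(sprintf("missing georeferencing header fields in %s", path))
  ncols <- as.integer(hdr$ncols); nrows <- as.integer(hdr$nrows)
  cellsize <- as.numeric(hdr$cellsize)
  nod <- if (!is.null(hdr$nodata_value)) as.numeric(hdr$nodata_value) else NA
  vals <- scan(path, what = double(), skip = 6L, quiet = TRUE)
  if (length(vals) != ncols * nrows)
    stop(sprintf("expected %d values, found %d in %s",
                 ncols * nrows, length(vals), path))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  if (!is.na(nod)) m[m == nod] <- NA
  crs <- "unspecified"
  prj <- paste0(path, ".prj")
  if (file.exists(prj)) crs <- trimws(readLines(prj, n = 1L))
  xll <- as.numeric(hdr$xllcorner); yll <- as.numeric(hdr$yllcorner)
  grid_create(m, xmin = xll, ymax = yll + nrows * cellsize,
              cellsize = cellsize, crs = crs)
}

#' Write a grid to an ESRI ASCII Grid file
#'
#' Values are serialized at full double precision (`%.17g`) so a write/read
#' round trip is lossless for finite values; nodata cells are written as the
#' `NODATA_value` (-9999 by default, adjusted if that value occurs in the
#' data). The CRS tag goes to a `<path>.prj` sidecar.
#'
#' @param grid a `grid`.
#' @param path output path (`.asc` conventionally).
#' @param nodata numeric value standing for nodata in the file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path, nodata = -9999) {
  stopifnot(is_grid(grid))
  v <- grid$values
  while (any(v == nodata, na.rm = TRUE)) nodata <- nodata * 10 - 1
  nrows <- nrow(v); ncols <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncols),
    sprintf("nrows %d", nrows),
    sprintf("xllcorner %.17g", grid$xmin),
    sprintf("yllcorner %.17g", grid$ymax - nrows * grid$cellsize),
    sprintf("cellsize %.17g", grid$cellsize),
    sprintf("NODATA_value %.17g", nodata)), con)
  v[is.na(v)] <- nodata
  for (i in seq_len(nrows))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  writeLines(grid$crs, paste0(path, ".prj"))
  invisible(path)
}

#' Resample a grid to a new cell size
#'
#' Continuous surfaces are resampled with bilinear interpolation between
#' the four surrounding input cell centers; categorical surfaces take the
#' nearest input cell center. Nodata is never interpolated across: a
#' bilinear target becomes nodata if any of its four contributing cells is
#' nodata. The output covers the same extent, anchored at the input origin.
#'
#' @param grid input `grid`.
#' @param target_cell output cell size, meters, > 0.
#' @param kind `"continuous"` (bilinear) or `"categorical"` (nearest).
#' @return resampled `grid`.
#' @export
resample <- function(grid, target_cell, kind = c("continuous", "categorical")) {
  stopifnot(is_grid(grid))
  kind <- match.arg(kind)
  if (!is.numeric(target_cell) || length(target_cell) != 1L ||
      !is.finite(target_cell) || target_cell <= 0)
    stop("target_cell must be strictly positive")
  v <- grid$values
  width <- ncol(v) * grid$cellsize
  height <- nrow(v) * grid$cellsize
  ncols <- max(1L, floor(width / target_cell))
  nrows <- max(1L, floor(height / target_cell))
  xout <- grid$xmin + (seq_len(ncols) - 0.5) * target_cell
  yout <- grid$ymax - (seq_len(nrows) - 0.5) * target_cell
  # fractional column/row position of each output center on the input
  # cell-center lattice (1-based)
  fc <- (xout - grid$xmin) / grid$cellsize + 0.5
  fr <- (grid$ymax - yout) / grid$cellsize + 0.5
  out <- matrix(NA_real_, nrows, ncols)
  if (kind == "categorical") {
    ic <- pmin(pmax(round(fc), 1L), ncol(v))
    ir <- pmin(pmax(round(fr), 1L), nrow(v))
    out <- matrix(v[cbind(rep(ir, ncols), rep(ic, each = nrows))],
                  nrows, ncols)
    return(grid_create(out, grid$xmin, grid$ymax, target_cell, grid$crs))
  }
  c0 <- pmin(pmax(floor(fc), 1L), ncol(v) - 1L)
  r0 <- pmin(pmax(floor(fr), 1L), nrow(v) - 1L)
  if (ncol(v) == 1L) c0 <- rep(1L, ncols)
  if (nrow(v) == 1L) r0 <- rep(1L, nrows)
  wc <- pmin(pmax(fc - c0, 0), 1)
  wr <- pmin(pmax(fr - r0, 0), 1)
  c1 <- pmin(c0 + 1L, ncol(v))
  r1 <- pmin(r0 + 1L, nrow(v))
  R0 <- rep(r0, ncols); R1 <- rep(r1, ncols)
  C0 <- rep(c0, each = nrows); C1 <- rep(c1, each = nrows)
  WR <- rep(wr, ncols); WC <- rep(wc, each = nrows)
  z00 <- v[cbind(R0, C0)]; z01 <- v[cbind(R0, C1)]
  z10 <- v[cbind(R1, C0)]; z11 <- v[cbind(R1, C1)]
  zz <- (1 - WR) * ((1 - WC) * z00 + WC * z01) +
        WR * ((1 - WC) * z10 + WC * z11)
  out <- matrix(zz, nrows, ncols)
  grid_create(out, grid$xmin, grid$ymax, target_cell, grid$crs)
}

#' Mask water features out of a grid
#'
#' Cells whose centers fall inside any water polygon of the zone set become
#' nodata; all other cells are unchanged. Masking is idempotent.
#'
#' @param grid a `grid`.
#' @param zones a [zone_set()] whose `water` member holds the water
#'   polygons (in the grid CRS). An empty water set leaves the grid as is.
#' @return masked `grid`.
#' @export
apply_water_mask <- function(grid, zones) {
  stopifnot(is_grid(grid), inherits(zones, "zone_set"))
  if (length(zones$water) == 0L) return(grid)
  if (!identical(zones$crs, grid$crs))
    stop(sprintf("CRS mismatch: zones '%s' vs grid '%s'", zones$crs, grid$crs))
  v <- grid$values
  inside <- matrix(FALSE, nrow(v), ncol(v))
  for (poly in zones$water)
    inside <- inside | polygon_membership(grid, poly)
  v[inside] <- NA
  grid_like(grid, v)
}
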