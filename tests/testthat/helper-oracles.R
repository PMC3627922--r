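# Independent oracles and fixture builders shared across the suite.
# Each oracle is a deliberately naive re-derivation (explicit loops,
# closed forms) kept separate from the implementation it checks.

# Constant-temperature monthly normals on a small grid.
const_normals <- function(tavg, ppt = 10, n = 4, cell = 100,
                          spring = 120, fall = 290, diurnal = 12) {
  g <- function(v) grid_create(matrix(v, n, n), 0, n * cell, cell)
  months <- SEASON_MONTHS
  tmax <- tmin <- pp <- list()
  for (m in months) {
    tv <- if (length(tavg) == 1) tavg else tavg[[m]]
    tmax[[m]] <- g(tv + diurnal / 2)
    tmin[[m]] <- g(tv - diurnal / 2)
    pp[[m]] <- g(ppt)
  }
  monthly_normals(tmax, tmin, pp, g(spring), g(fall))
}

# Analytic plane DEM: z = base + gx*x + gy*y at cell centers.
plane_dem <- function(gx, gy, n = 8, cell = 100, base = 0) {
  make_dem(fixture_config(extent = c(n, n), cell = cell, dem_kind = "plane",
                          dem_params = list(base = base, gx = gx, gy = gy)))
}

# Naive Horn stencil at one interior cell (explicit neighbor fetch).
oracle_horn <- function(v, cell, i, j) {
  a <- v[i - 1, j - 1]; b <- v[i - 1, j]; cc <- v[i - 1, j + 1]
  d <- v[i, j - 1];                       f <- v[i, j + 1]
  g <- v[i + 1, j - 1]; h <- v[i + 1, j]; ii <- v[i + 1, j + 1]
  dzdx <- ((cc + 2 * f + ii) - (a + 2 * d + g)) / (8 * cell)
  dzdy <- ((a + 2 * b + cc) - (g + 2 * h + ii)) / (8 * cell)
  list(slope_pct = 100 * sqrt(dzdx^2 + dzdy^2),
       aspect = if (dzdx == 0 && dzdy == 0) ASPECT_FLAT
                else (atan2(-dzdx, -dzdy) * 180 / pi) %% 360)
}

# Exhaustive ray walk for the horizon angle of one cell and azimuth.
oracle_horizon <- function(dem, i, j, azimuth, max_radius) {
  v <- dem$values
  best <- 0
  az <- azimuth * pi / 180
  nsteps <- floor(max_radius / dem$cellsize)
  for (s in seq_len(nsteps)) {
    rr <- i - round(cos(az) * s)
    cc <- j + round(sin(az) * s)
    if (rr < 1 || rr > nrow(v) || cc < 1 || cc > ncol(v)) next
    ang <- atan2(v[rr, cc] - v[i, j], s * dem$cellsize) * 180 / pi
    if (!is.na(ang) && ang > best) best <- ang
  }
  best
}

# Direct numeric integration for a flat, unobstructed cell over the same
# sun-position lattice; uniform-sky diffuse is the configured fraction of
# global on that surface, so total = direct / (1 - diffuse_proportion).
oracle_flat_insolation <- function(params, elev) {
  sun <- sun_positions(params)
  total_direct <- 0
  for (i in seq_len(nrow(sun))) {
    cosz <- cos(sun$zenith[i] * pi / 180)
    m <- exp(-0.000118 * elev) / cosz
    total_direct <- total_direct +
      params$solar_constant * params$transmissivity^m * cosz * sun$weight_h[i]
  }
  total_direct / (1 - params$diffuse_proportion)
}

# Hand-coded even-odd ray cast (horizontal ray to +x), independent of the
# sp-based membership in the package.
oracle_point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

oracle_point_in_poly <- function(px, py, poly) {
  hit <- FALSE
  for (ring in poly) hit <- xor(hit, oracle_point_in_ring(px, py, ring))
  hit
}

# Build a 7-layer stack from a matrix of cell values (columns in stack
# order).
stack_from_matrix <- function(M, nr, nc) {
  stopifnot(nrow(M) == nr * nc)
  layers <- lapply(seq_len(ncol(M)), function(k)
    grid_create(matrix(M[, k], nr, nc), 0, nr * 10, 10))
  names(layers) <- STACK_LAYERS
  stack_spec(layers)
}

# Power iteration with deflation: leading eigenpairs of a symmetric
# matrix, independent of eigen().
oracle_eigen <- function(C, k = ncol(C), iters = 20000) {
  p <- ncol(C)
  vals <- numeric(k)
  vecs <- matrix(0, p, k)
  A <- C
  set.seed(99)
  for (m in seq_len(k)) {
    v <- stats::rnorm(p)
    v <- v / sqrt(sum(v^2))
    for (it in seq_len(iters)) {
      w <- A %*% v
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- as.numeric(w) / nw
      if (sum(abs(w - v)) < 1e-14 || sum(abs(w + v)) < 1e-14) { v <- w; break }
      v <- w
    }
    lam <- as.numeric(t(v) %*% A %*% v)
    vals[m] <- lam
    vecs[, m] <- v
    A <- A - lam * tcrossprod(v)
  }
  list(values = vals, vectors = vecs)
}
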