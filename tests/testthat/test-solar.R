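test_that("sun-position lattice matches the season configuration", {
  p <- solar_params(46)
  sun <- sun_positions(p)
  expect_equal(length(unique(sun$day)), 16)  # ceil(214/14) days
  expect_true(all(sun$zenith >= 0 & sun$zenith < 90))
  # night hours are excluded
  expect_false(any(sun$hour %in% c(1, 23)))
  # equinox noon at the equator: zenith equals |declination|, well under 0.5 deg
  peq <- solar_params(0, day_start = 80, day_end = 80, hour_step = 24)
  seq_ <- sun_positions(peq)
  expect_equal(nrow(seq_), 1)
  expect_lt(seq_$zenith, 0.5)
  expect_equal(seq_$zenith, abs(solar_declination(80)), tolerance = 0.01)
})

test_that("horizon angles: flat terrain, single wall, and brute-force oracle", {
  p <- solar_params(46, n_azimuth_viewshed = 16)
  flat <- grid_create(matrix(50, 8, 8), 0, 800, 100)
  hz <- compute_horizon_angles(flat, p, max_radius = 500)
  expect_true(all(hz$angles == 0))
  expect_true(all(hz$angles >= 0 & hz$angles <= 90))
  # wall of height h at distance d due east
  wall <- grid_create(matrix(0, 5, 5), 0, 500, 100)
  wall$values[, 5] <- 120
  hzw <- compute_horizon_angles(wall, p, max_radius = 450)
  east <- which(hzw$azimuths == 90)
  d <- 4 * 100
  expect_equal(hzw$angles[3, 1, east], atan2(120, d) * 180 / pi,
               tolerance = 1e-10)
  # random terrain vs exhaustive ray walk, one cell, all azimuths
  set.seed(33)
  rough <- grid_create(matrix(stats::runif(400, 0, 60), 20, 20), 0, 2000, 100)
  hzr <- compute_horizon_angles(rough, p, max_radius = 1200)
  for (k in seq_along(hzr$azimuths))
    expect_equal(hzr$angles[10, 11, k],
                 oracle_horizon(rough, 10, 11, hzr$azimuths[k], 1200),
                 tolerance = 1e-10)
  expect_error(compute_horizon_angles(flat, p, max_radius = 10), "one cell")
})

test_that("flat unobstructed insolation matches independent integration", {
  p <- solar_params(46)
  dem <- grid_create(matrix(300, 8, 8), 0, 800, 100)
  ins <- compute_insolation_dem(dem, p, max_radius = 400)
  oracle <- oracle_flat_insolation(p, 300)
  expect_lt(abs(ins$values[4, 4] - oracle) / oracle, 0.005)
  expect_true(all(ins$values >= 0))
})

test_that("full obstruction yields zero insolation", {
  p <- solar_params(46)
  dem <- grid_create(matrix(100, 6, 6), 0, 600, 100)
  hz <- compute_horizon_angles(dem, p, max_radius = 300)
  hz$angles[] <- 90
  ins <- compute_insolation(dem, compute_slope(dem), compute_aspect(dem),
                            hz, p)
  expect_true(all(ins$values == 0))
})

test_that("south-facing slopes receive more radiation than north-facing at 46N", {
  p <- solar_params(46)
  south <- plane_dem(0, 0.2, n = 9, cell = 100, base = 500)  # faces south
  north <- plane_dem(0, -0.2, n = 9, cell = 100, base = 500) # faces north
  iS <- compute_insolation_dem(south, p, 400)$values[5, 5]
  iN <- compute_insolation_dem(north, p, 400)$values[5, 5]
  expect_gt(iS, iN)
})

test_that("with no diffuse and unit transmissivity the beam sum is exact", {
  p <- solar_params(46, diffuse_proportion = 1e-9, transmissivity = 1)
  dem <- grid_create(matrix(0, 6, 6), 0, 600, 100)
  ins <- compute_insolation_dem(dem, p, 300)
  sun <- sun_positions(p)
  closed <- p$solar_constant *
    sum(cos(sun$zenith * pi / 180) * sun$weight_h)
  expect_lt(abs(ins$values[3, 3] - closed) / closed, 0.001)
})

test_that("hour-lattice refinement converges on a flat cell", {
  dem <- grid_create(matrix(200, 6, 6), 0, 600, 100)
  val <- function(hs) {
    p <- solar_params(46, hour_step = hs)
    compute_insolation_dem(dem, p, 300)$values[3, 3]
  }
  v4 <- val(4); v2 <- val(2); v1 <- val(1); v05 <- val(0.5)
  expect_lt(abs(v1 - v05), abs(v2 - v1))
  expect_lt(abs(v2 - v1), abs(v4 - v2))
})

test_that("latitude tiling partitions with overlap and blending is convex", {
  dem <- plane_dem(0.01, 0.02, n = 40, cell = 100, base = 200)
  # small DEM: single unchanged tile
  one <- tile_by_latitude(dem, max_extent_deg = 1)
  expect_length(one, 1)
  expect_identical(one[[1]]$values, dem$values)
  # force 2 tiles with a 500 m overlap strip
  tiles <- tile_by_latitude(dem, max_extent_deg = 2000 / 111320,
                            overlap = 500)
  expect_length(tiles, 2)
  expect_equal(nrow(tiles[[1]]$values), 25)  # 20 core + 5 overlap rows
  expect_equal(nrow(tiles[[2]]$values), 25)
  # tiles agree on the shared strip (cut from the same DEM): tile 1 holds
  # global rows 1-25, tile 2 rows 16-40, so rows 16-25 are shared
  expect_identical(tiles[[1]]$values[16:25, ], tiles[[2]]$values[1:10, ])
  # identical tiles blend to themselves; mosaic covers the full extent
  mos <- blend_mosaic(tiles)
  expect_equal(dim(mos$values), dim(dem$values))
  expect_equal(mos$values, dem$values, tolerance = 1e-12)
  # ramp midpoint gives the average of two differing tiles
  ta <- tiles; ta[[1]]$values[] <- 10; ta[[2]]$values[] <- 20
  m2 <- blend_mosaic(ta)
  expect_true(all(m2$values >= 10 & m2$values <= 20))  # convex combination
  # symmetric ramp across the 10-row strip: its middle averages the tiles
  expect_equal(mean(m2$values[20:21, 1]), 15)
  expect_true(all(diff(m2$values[, 1]) >= 0))          # monotone ramp
  expect_true(all(m2$values[1:15, ] == 10))
  expect_true(all(m2$values[26:40, ] == 20))
  # gaps are rejected
  gap <- list(tiles[[1]],
              grid_create(tiles[[2]]$values, tiles[[2]]$xmin,
                          tiles[[2]]$ymax - 2000, 100))
  expect_error(blend_mosaic(gap), "gap")
  expect_error(tile_by_latitude(dem, max_extent_deg = 2000 / 111320,
                                overlap = 5000), "overlap")
})
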