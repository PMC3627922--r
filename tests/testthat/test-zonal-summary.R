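test_that("zonal means average data cells with centers in each zone", {
  g <- grid_create(matrix(3.25, 12, 12), 0, 1200, 100)
  zs <- zone_set(list(a = poly_rect(50, 50, 550, 550),
                      b = poly_rect(650, 650, 1150, 1150)))
  zm <- zonal_mean(g, zs)
  expect_equal(unname(zm), c(3.25, 3.25))
  # nodata cells are excluded from the mean
  g2 <- grid_create(matrix(c(10, 20, NA, NA), 1, 4), 0, 100, 100)
  zs2 <- zone_set(list(z = poly_rect(0, 0, 300, 100)))
  expect_equal(unname(zonal_mean(g2, zs2)), 15)
  # a zone with no data cells warns and reports NA
  zs3 <- zone_set(list(z = poly_rect(300, 0, 400, 100)))
  g3 <- grid_create(matrix(c(1, 1, 1, NA), 1, 4), 0, 100, 100)
  expect_warning(zm3 <- zonal_mean(g3, zs3), "no data cells")
  expect_true(is.na(zm3[["z"]]))
  expect_error(zonal_mean(g, zone_set(list(a = poly_rect(0, 0, 1, 1)),
                                      crs = "other")), "CRS")
})

test_that("zonal means match a brute-force membership oracle", {
  set.seed(27)
  g <- grid_create(matrix(stats::rnorm(900), 30, 30), 0, 3000, 100)
  g$values[sample(900, 40)] <- NA
  # edges kept off the cell-center lattice; on-boundary centers are a
  # documented convention (counted inside), not exercised here
  zones <- list(z1 = poly_rect(120, 140, 1430, 1210),
                z2 = poly_rect(1500, 200, 2960, 2820),
                z3 = poly_rect(80, 1600, 1400, 2910))
  zs <- zone_set(zones)
  zm <- zonal_mean(g, zs)
  for (id in names(zones)) {
    acc <- c()
    for (i in 1:30) for (j in 1:30) {
      if (oracle_point_in_poly(grid_x(g)[j], grid_y(g)[i], zones[[id]]) &&
          !is.na(g$values[i, j]))
        acc <- c(acc, g$values[i, j])
    }
    expect_equal(zm[[id]], mean(acc), tolerance = 1e-12)
  }
  # invariant to polygon vertex order (reversed ring)
  rev_zones <- lapply(zones, function(p) list(p[[1]][rev(seq_len(nrow(p[[1]]))), ]))
  expect_equal(zonal_mean(g, zone_set(rev_zones)), zm)
})

test_that("class proportions sum to one and report absent classes as zero", {
  vals <- matrix(NA_real_, 3, 3)
  vals[1, ] <- DRAINAGE_CLASSES[["WD"]]
  vals[2, ] <- DRAINAGE_CLASSES[["WD"]]
  vals[3, ] <- DRAINAGE_CLASSES[["SPD"]]
  g <- grid_create(vals, 0, 300, 100)
  zs <- zone_set(list(z = poly_rect(0, 0, 300, 300)))
  p <- zonal_class_proportions(g, zs, classes = DRAINAGE_CLASSES)
  expect_equal(unname(p["z", "WD"]), 2 / 3, tolerance = 1e-12)
  expect_equal(unname(p["z", "SPD"]), 1 / 3, tolerance = 1e-12)
  expect_equal(unname(p["z", "ED"]), 0)
  expect_equal(sum(p["z", ]), 1, tolerance = 1e-9)
  # single-class zone
  g1 <- grid_create(matrix(5, 2, 2), 0, 200, 100)
  p1 <- zonal_class_proportions(g1, zone_set(list(z = poly_rect(0, 0, 200, 200))))
  expect_equal(unname(p1["z", "5"]), 1)
  # empty intersection warns
  expect_warning(zonal_class_proportions(
    g1, zone_set(list(far = poly_rect(900, 900, 950, 950)))), "no data")
})

test_that("summarize_zones assembles means and unit-sum proportions", {
  cfg <- fixture_config(extent = c(20, 20), cell = 100, n_zones = 4,
                        n_mapunits = 3, seed = 9)
  dem <- make_dem(cfg)
  zones <- make_zones(cfg)
  normals <- make_monthly_normals(dem, cfg)
  survey <- make_soil_survey(cfg)
  ext <- c(0, 0, 2000, 2000)
  layers <- list(
    elevation = dem,
    gdd = growing_degree_days(normals),
    bedd = biologically_effective_degree_days(normals),
    ffd = frost_free_days(normals$last_spring_frost,
                          normals$first_fall_frost),
    gsp = growing_season_precipitation(normals),
    drainage = rasterize_attribute(survey, "drainage", cell = 100,
                                   extent = ext),
    aspect_class = classify_aspect(compute_aspect(dem)))
  sm <- summarize_zones(layers, zones)
  expect_equal(nrow(sm$means), 4)
  expect_true(all(rowSums(sm$drainage_proportions) - 1 < 1e-9))
  expect_true(all(abs(rowSums(sm$aspect_proportions) - 1) < 1e-9))
  expect_true(all(sm$means$bedd <= sm$means$gdd))
  # a constant layer summarizes to the constant in every zone
  layers$gsp <- grid_create(matrix(88, 20, 20), 0, 2000, 100)
  sm2 <- summarize_zones(layers, zones)
  expect_true(all(sm2$means$gsp == 88))
  expect_error(summarize_zones(list(bogus = dem), zones), "no recognized")
})

test_that("published-table contrasts reproduce the printed differences", {
  t1 <- read_ava_means()
  gap <- contrast(t1, list(c("Walla Walla Valley", "Red Mountain")),
                  "gdd_bedd_gap")
  expect_identical(unname(gap$differences), 58)
  gdd <- contrast(t1, list(c("Red Mountain", "Walla Walla Valley")), "gdd")
  expect_identical(unname(gdd$differences), 14)
  ffd <- contrast(t1, list(c("Red Mountain", "Rattlesnake Hills"),
                           c("Walla Walla Valley", "Rattlesnake Hills")),
                  "ffd")
  expect_identical(unname(ffd$differences), c(28, 52))
  # antisymmetry and zero diagonal
  ab <- contrast(t1, list(c("Yakima Valley", "Lake Chelan"),
                          c("Lake Chelan", "Yakima Valley"),
                          c("Red Mountain", "Red Mountain")), "gdd")
  expect_equal(unname(ab$differences[1]), -unname(ab$differences[2]))
  expect_equal(unname(ab$differences[3]), 0)
  # the warmest appellations head the GDD ranking
  expect_equal(gdd$ranking[1:2], c("Wahluke Slope", "Red Mountain"))
  expect_error(contrast(t1, list(c("Nowhere", "Red Mountain")), "gdd"),
               "unknown zone")
  expect_error(contrast(t1, list(c("Red Mountain", "Yakima Valley")),
                        "magma"), "unknown variable")
})

test_that("column averages are unweighted means across zones", {
  t2 <- read_ava_drainage()
  expect_equal(round(column_average(t2, "WD"), 1), 83.3)
  # averaging only the appellations reporting a class
  expect_equal(round(column_average(t2, "ED"), 1), 8.6)
  expect_equal(round(column_average(t2, "SPD"), 1), 3.0)
  one <- data.frame(zone = "only", gdd = 1234)
  expect_equal(column_average(one, "gdd"), 1234)
  eq <- data.frame(zone = c("a", "b", "c"), ffd = c(160, 160, 160))
  expect_equal(column_average(eq, "ffd"), 160)
})
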