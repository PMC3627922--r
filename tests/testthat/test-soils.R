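# Compact hand-built survey shared by several blocks: two rectangular
# map units splitting a 200 x 400 m extent into west/east halves.
tiny_survey <- function() {
  mapunits <- list(
    muA = poly_rect(0, 0, 200, 200),
    muB = poly_rect(200, 0, 400, 200))
  components <- data.frame(
    mukey = c("muA", "muA", "muA", "muB", "muB"),
    cokey = c("a1", "a2", "a3", "B", "A"),
    percent = c(45, 35, 20, 50, 50),
    drainage_class = c("WD", "SPD", "ED", "MWD", "WD"),
    depth_to_restrictive = c(108, NA, 0, NA, NA),
    stringsAsFactors = FALSE)
  horizons <- data.frame(
    cokey = c("a1", "a1", "a2", "B", "A"),
    top = c(0, 30, 0, 0, 0),
    bottom = c(30, 60, 100, 10, 100),
    awc = c(0.2, 0.1, 0.15, 0.12, 0.18),
    ph = c(6.5, 7.5, 7.0, 5.0, 7.0),
    stringsAsFactors = FALSE)
  soil_survey(mapunits, components, horizons)
}

test_that("dominant component selection follows percent with cokey tie-break", {
  s <- tiny_survey()
  expect_equal(select_dominant_component(s, "muA"), "a1")  # 45/35/20
  expect_equal(select_dominant_component(s, "muB"), "A")   # 50/50 tie -> "A"
  expect_error(select_dominant_component(s, "muZ"), "unknown mukey")
  single <- soil_survey(list(m = poly_rect(0, 0, 1, 1)),
                        data.frame(mukey = "m", cokey = "only", percent = 100,
                                   drainage_class = "WD",
                                   depth_to_restrictive = NA),
                        data.frame(cokey = "only", top = 0, bottom = 50,
                                   awc = 0.1, ph = 7))
  expect_equal(select_dominant_component(single, "m"), "only")
})

test_that("depth-weighted means integrate horizon overlap with the window", {
  h <- data.frame(top = c(0, 30), bottom = c(30, 60), awc = c(0.2, 0.1),
                  ph = c(6, 7))
  expect_equal(depth_weighted_mean(h, "awc"), (30 * 0.2 + 20 * 0.1) / 50)
  single <- data.frame(top = 0, bottom = 100, awc = NA, ph = 7.0)
  expect_equal(depth_weighted_mean(single, "ph"), 7.0)
  # partial coverage weights by the covered thickness only
  shallow <- data.frame(top = 0, bottom = 10, awc = 0.08, ph = 5)
  expect_equal(depth_weighted_mean(shallow, "ph"), 5.0)
  # missing attribute drops the horizon from numerator and denominator
  expect_true(is.na(depth_weighted_mean(single, "awc")))
  mixed <- data.frame(top = c(0, 20), bottom = c(20, 50), awc = c(NA, 0.12),
                      ph = c(6, 7))
  expect_equal(depth_weighted_mean(mixed, "awc"), 0.12)
  # bounded by the contributing values
  set.seed(8)
  for (r in 1:10) {
    nh <- sample(2:4, 1)
    b <- cumsum(c(0, stats::runif(nh, 5, 40)))
    h <- data.frame(top = b[-length(b)], bottom = b[-1],
                    awc = stats::runif(nh, 0.05, 0.25),
                    ph = stats::runif(nh, 5, 8.5))
    m <- depth_weighted_mean(h, "awc")
    expect_gte(m, min(h$awc)); expect_lte(m, max(h$awc))
  }
})

test_that("depth to restrictive layer is censored at the survey depth", {
  s <- tiny_survey()
  expect_equal(depth_to_restrictive(s, "a1"), 108)
  expect_equal(depth_to_restrictive(s, "a2"), 200)  # none recorded
  expect_equal(depth_to_restrictive(s, "a3"), 0)    # restriction at surface
  expect_equal(depth_to_restrictive(s, "a2", survey_max = 150), 150)
  expect_error(depth_to_restrictive(s, "zz"), "unknown cokey")
})

test_that("attribute rasterization assigns dominant-component values by cell center", {
  s <- tiny_survey()
  ext <- c(0, 0, 400, 200)
  awc <- rasterize_attribute(s, "awc", cell = 10, extent = ext)
  # west half: dominant a1, awc (30*0.2 + 20*0.1)/50 = 0.16
  expect_true(all(awc$values[, 1:20] == 0.16))
  # east half: tie-broken component A, single horizon 0.18
  expect_true(all(awc$values[, 21:40] == 0.18))
  expect_equal(length(unique(as.vector(awc$values))), 2)
  drain <- rasterize_attribute(s, "drainage", cell = 10, extent = ext)
  expect_true(all(drain$values[, 1:20] == DRAINAGE_CLASSES[["WD"]]))
  # dominant condition for muB: WD 50 vs MWD 50, alphabetical class tie
  drain2 <- rasterize_attribute(s, "drainage", cell = 10, extent = ext,
                                method = "condition")
  expect_true(all(drain2$values[, 21:40] %in% DRAINAGE_CLASSES))
  expect_error(rasterize_attribute(s, "bulk_density", extent = ext),
               "unknown attribute")
  # cells outside every map unit stay nodata
  wide <- rasterize_attribute(s, "ph", cell = 10, extent = c(0, 0, 500, 200))
  expect_true(all(is.na(wide$values[, 41:50])))
})

test_that("generated surveys rasterize identically to a brute-force oracle", {
  cfg <- fixture_config(extent = c(20, 20), cell = 50, n_mapunits = 5,
                        seed = 14)
  s <- make_soil_survey(cfg)
  ext <- c(0, 0, 1000, 1000)
  for (attribute in c("awc", "drainage", "depth")) {
    g <- rasterize_attribute(s, attribute, cell = 50, extent = ext)
    truth <- attr(s, "truth")
    for (i in seq(1, 20, by = 3)) for (j in seq(1, 20, by = 3)) {
      px <- grid_x(g)[j]; py <- grid_y(g)[i]
      hits <- names(s$mapunits)[vapply(s$mapunits, function(p)
        oracle_point_in_poly(px, py, p), logical(1))]
      if (!length(hits)) {
        expect_true(is.na(g$values[i, j]))
      } else {
        tr <- truth[truth$mukey == hits[1], ]
        expected <- switch(attribute, awc = tr$awc,
                           drainage = tr$drainage_code, depth = tr$depth)
        expect_equal(g$values[i, j], expected, tolerance = 1e-12)
      }
    }
    # aggregation is deterministic across runs
    g2 <- rasterize_attribute(s, attribute, cell = 50, extent = ext)
    expect_identical(g$values, g2$values)
  }
})

test_that("survey constructor enforces horizon and percent invariants", {
  mu <- list(m = poly_rect(0, 0, 1, 1))
  comp <- data.frame(mukey = "m", cokey = "c", percent = 60,
                     drainage_class = "WD", depth_to_restrictive = NA)
  expect_error(soil_survey(mu, transform(comp, percent = 130),
                           data.frame(cokey = "c", top = 0, bottom = 10,
                                      awc = 0.1, ph = 7)), "100")
  expect_error(soil_survey(mu, comp,
                           data.frame(cokey = "c", top = 10, bottom = 10,
                                      awc = 0.1, ph = 7)), "top < bottom")
  expect_error(soil_survey(mu, comp,
                           data.frame(cokey = c("c", "c"), top = c(0, 5),
                                      bottom = c(10, 15), awc = 0.1, ph = 7)),
               "overlapping")
  expect_error(soil_survey(mu, transform(comp, drainage_class = "XX"),
                           data.frame(cokey = "c", top = 0, bottom = 10,
                                      awc = 0.1, ph = 7)), "drainage")
})

test_that("a single-unit survey rasterizes to a constant and 100% of its class", {
  cfg <- fixture_config(extent = c(10, 10), cell = 100, n_mapunits = 1,
                        seed = 2)
  s <- make_soil_survey(cfg)
  ext <- c(0, 0, 1000, 1000)
  drain <- rasterize_attribute(s, "drainage", cell = 100, extent = ext)
  truth <- attr(s, "truth")
  expect_true(all(drain$values == truth$drainage_code[1]))
  zs <- zone_set(s$mapunits, crs = s$crs)
  props <- zonal_class_proportions(drain, zs, classes = DRAINAGE_CLASSES)
  expect_equal(unname(props[1, truth$drainage_code[1]]), 1)
})
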