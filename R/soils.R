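#' SSURGO-style soil surveys and dominant-component aggregation
#'
#' A soil survey is modeled after the SSURGO relational layout: map-unit
#' polygons keyed by `mukey`, a component table (one or more soil
#' components per map unit with area percents), and a horizon table
#' (depth-bounded layers per component carrying AWC and pH). Thematic
#' rasters take each map unit's dominant component -- the component with
#' the largest area percent -- as the aggregation method.
#'
#' @name soils
NULL

#' Ordered drainage classes and integer codes
#'
#' SSURGO's seven-level ordinal drainage scale, excessively drained (ED)
#' through very poorly drained (VPD), coded 1-7.
#' @export
DRAINAGE_CLASSES <- c(ED = 1L, SED = 2L, WD = 3L, MWD = 4L,
                      SPD = 5L, PD = 6L, VPD = 7L)

#' Assemble a soil survey object
#'
#' @param mapunits named list of polygons (name = `mukey`, value = list of
#'   ring matrices in the target CRS).
#' @param components data.frame with columns `mukey`, `cokey`, `percent`
#'   (0-100), `drainage_class` (one of `names(DRAINAGE_CLASSES)`), and
#'   `depth_to_restrictive` (cm, `NA` when no restriction was recorded).
#' @param horizons data.frame with columns `cokey`, `top`, `bottom` (cm),
#'   `awc` (cm/cm), `ph`. `NA` attribute values are allowed and excluded
#'   from depth-weighted means.
#' @param crs CRS tag.
#' @return an object of class `soil_survey`.
#' @export
soil_survey <- function(mapunits, components, horizons, crs = "local-m") {
  stopifnot(is.data.frame(components), is.data.frame(horizons))
  if (is.null(names(mapunits)) || anyDuplicated(names(mapunits)))
    stop("mapunits must be uniquely keyed by mukey")
  if (!all(components$drainage_class %in% names(DRAINAGE_CLASSES)))
    stop("unknown drainage class in component table")
  ps <- tapply(components$percent, components$mukey, sum)
  if (any(ps > 100 + 1e-9))
    stop("component percents within a mapunit must sum to <= 100")
  if (any(horizons$top >= horizons$bottom))
    stop("every horizon needs top < bottom")
  for (ck in unique(horizons$cokey)) {
    h <- horizons[horizons$cokey == ck, , drop = FALSE]
    h <- h[order(h$top), , drop = FALSE]
    if (nrow(h) > 1 && any(h$top[-1] < h$bottom[-nrow(h)] - 1e-9))
      stop(sprintf("overlapping horizons in component %s", ck))
  }
  structure(list(mapunits = mapunits,
                 components = components,
                 horizons = horizons,
                 crs = as.character(crs)),
            class = "soil_survey")
}

#' Read a soil survey from its three delimited tables
#'
#' Map-unit geometry comes from a GeoJSON file with a `mukey` attribute;
#' component and horizon tables are CSV with the [soil_survey()] field
#' names.
#'
#' @param geojson_path map-unit polygons (GeoJSON, `mukey` property).
#' @param components_csv,horizons_csv CSV paths.
#' @param crs CRS tag.
#' @return a [soil_survey()].
#' @export
read_soil_survey <- function(geojson_path, components_csv, horizons_csv,
                             crs = "local-m") {
  zs <- read_vector(geojson_path, id_field = "mukey", crs = crs)
  comp <- utils::read.csv(components_csv, stringsAsFactors = FALSE)
  hor <- utils::read.csv(horizons_csv, stringsAsFactors = FALSE)
  comp$mukey <- as.character(comp$mukey)
  comp$cokey <- as.character(comp$cokey)
  hor$cokey <- as.character(hor$cokey)
  soil_survey(zs$zones, comp, hor, crs = crs)
}

#' Dominant component of a map unit
#'
#' The component with the largest area percent; ties break to the
#' lexicographically smallest `cokey` so aggregation is deterministic.
#'
#' @param survey a [soil_survey()].
#' @param mukey map-unit key.
#' @return the dominant component's `cokey`.
#' @export
select_dominant_component <- function(survey, mukey) {
  comp <- survey$components
  rows <- comp[comp$mukey == mukey, , drop = FALSE]
  if (!nrow(rows)) {
    if (!mukey %in% names(survey$mapunits))
      stop(sprintf("unknown mukey '%s'", mukey))
    stop(sprintf("mapunit '%s' has no components", mukey))
  }
  rows <- rows[order(-rows$percent, rows$cokey), , drop = FALSE]
  rows$cokey[1]
}

#' Depth-weighted mean of a horizon attribute
#'
#' Attribute values are weighted by each horizon's thickness of overlap
#' with the depth window (default 0-50 cm). Horizons missing the
#' attribute are excluded and their thickness removed from the
#' denominator; a window with no attribute coverage returns `NA`.
#'
#' @param horizons data.frame of one component's horizons (`top`,
#'   `bottom`, plus the attribute column).
#' @param attribute `"awc"` or `"ph"`.
#' @param window depth window in cm, `c(top, bottom)`.
#' @return weighted mean, or `NA_real_` with no coverage.
#' @export
depth_weighted_mean <- function(horizons, attribute = c("awc", "ph"),
                                window = c(0, 50)) {
  attribute <- match.arg(attribute)
  top <- pmax(horizons$top, window[1])
  bot <- pmin(horizons$bottom, window[2])
  ov <- pmax(0, bot - top)
  val <- horizons[[attribute]]
  use <- ov > 0 & !is.na(val)
  if (!any(use)) return(NA_real_)
  sum(val[use] * ov[use]) / sum(ov[use])
}

#' Depth to restrictive layer, censored at survey depth
#'
#' Returns the recorded depth when present; when no restrictive layer was
#' found within the survey depth, the censored value `survey_max`
#' (200 cm, the SSURGO survey convention).
#'
#' @param survey a [soil_survey()].
#' @param cokey component key.
#' @param survey_max censoring depth in cm.
#' @return depth in cm.
#' @export
depth_to_restrictive <- function(survey, cokey, survey_max = 200) {
  comp <- survey$components
  row <- comp[comp$cokey == cokey, , drop = FALSE]
  if (!nrow(row)) stop(sprintf("unknown cokey '%s'", cokey))
  d <- row$depth_to_restrictive[1]
  if (is.na(d)) survey_max else d
}

# Attribute value of one component, by attribute name.
component_attribute <- function(survey, cokey, attribute, survey_max = 200) {
  switch(attribute,
    drainage = {
      comp <- survey$components
      DRAINAGE_CLASSES[[comp$drainage_class[comp$cokey == cokey][1]]]
    },
    depth = depth_to_restrictive(survey, cokey, survey_max),
    awc = depth_weighted_mean(
      survey$horizons[survey$horizons$cokey == cokey, , drop = FALSE], "awc"),
    ph = depth_weighted_mean(
      survey$horizons[survey$horizons$cokey == cokey, , drop = FALSE], "ph"),
    stop(sprintf("unknown attribute '%s'", attribute)))
}

# Dominant-condition value for categorical attributes: the class with the
# largest summed percent over a mapunit's components.
dominant_condition_value <- function(survey, mukey, attribute) {
  if (attribute != "drainage")
    stop("dominant-condition aggregation applies to categorical attributes")
  comp <- survey$components
  rows <- comp[comp$mukey == mukey, , drop = FALSE]
  if (!nrow(rows)) stop(sprintf("mapunit '%s' has no components", mukey))
  agg <- tapply(rows$percent, rows$drainage_class, sum)
  cls <- names(agg)[order(-agg, names(agg))][1]
  DRAINAGE_CLASSES[[cls]]
}

#' Rasterize a soil attribute at survey resolution
#'
#' Each cell takes the attribute of the dominant component of the map
#' unit containing its center (cell-center containment); cells outside
#' all map units are nodata. Attributes: `"drainage"` (integer codes per
#' [DRAINAGE_CLASSES]), `"depth"` (cm, censored per
#' [depth_to_restrictive()]), `"awc"` and `"ph"` (depth-weighted over
#' 0-50 cm). For the categorical drainage attribute,
#' `method = "condition"` instead sums percents over components sharing a
#' class (dominant condition).
#'
#' @param survey a [soil_survey()].
#' @param attribute attribute name.
#' @param cell output cell size in meters (default 10, fine enough to
#'   represent map-unit boundaries).
#' @param extent numeric `c(xmin, ymin, xmax, ymax)` of the output grid.
#' @param method `"component"` (dominant component, default) or
#'   `"condition"`.
#' @param survey_max censoring depth for `"depth"`, cm.
#' @return a `grid` of attribute values.
#' @export
rasterize_attribute <- function(survey, attribute, cell = 10, extent,
                                method = c("component", "condition"),
                                survey_max = 200) {
  method <- match.arg(method)
  if (!attribute %in% c("drainage", "depth", "awc", "ph"))
    stop(sprintf("unknown attribute '%s'", attribute))
  nrows <- max(1L, round((extent[4] - extent[2]) / cell))
  ncols <- max(1L, round((extent[3] - extent[1]) / cell))
  g <- grid_create(matrix(NA_real_, nrows, ncols),
                   xmin = extent[1], ymax = extent[4],
                   cellsize = cell, crs = survey$crs)
  v <- g$values
  for (mukey in names(survey$mapunits)) {
    inside <- polygon_membership(g, survey$mapunits[[mukey]])
    if (!any(inside)) next
    val <- if (method == "condition" && attribute == "drainage") {
      dominant_condition_value(survey, mukey, attribute)
    } else {
      ck <- select_dominant_component(survey, mukey)
      component_attribute(survey, ck, attribute, survey_max)
    }
    v[inside & is.na(v)] <- val
  }
  grid_like(g, v)
}
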