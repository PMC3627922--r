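#' Zone sets: appellation polygons and water features
#'
#' A `zone_set` holds named appellation polygons plus an optional set of
#' water polygons to exclude from all summaries. Polygons are stored as
#' lists of rings; each ring is a two-column (x, y) matrix in projected
#' meters, not repeating the first vertex. Interior rings (holes) and
#' multi-part geometries are handled by the even-odd containment rule.
#'
#' @param zones named list of polygons (name = zone id, value = list of
#'   ring matrices). Zone ids must be unique and non-empty.
#' @param water list of water polygons in the same CRS (may be empty).
#' @param crs CRS tag, matching the grids the zones will be used with.
#' @return an object of class `zone_set`.
#' @export
zone_set <- function(zones, water = list(), crs = "local-m") {
  ids <- names(zones)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every zone needs a non-empty id")
  if (anyDuplicated(ids))
    stop(sprintf("duplicate zone ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  structure(list(zones = zones, water = water, crs = as.character(crs)),
            class = "zone_set")
}

#' @export
print.zone_set <- function(x, ...) {
  cat(sprintf("<zone_set> %d zones (%s), %d water polygons, crs '%s'\n",
              length(x$zones),
              paste(utils::head(names(x$zones), 5), collapse = ", "),
              length(x$water), x$crs))
  invisible(x)
}

#' Zone ids of a zone set
#' @param zones a `zone_set`.
#' @export
zone_ids <- function(zones) names(zones$zones)

# Rectangle polygon helper (one ring, counter-clockwise).
poly_rect <- function(xmin, ymin, xmax, ymax) {
  list(cbind(x = c(xmin, xmax, xmax, xmin),
             y = c(ymin, ymin, ymax, ymax)))
}

# TRUE if any two non-adjacent edges of the ring properly intersect
# (bow-tie detection). O(n^2); rings in this package are small.
ring_self_intersects <- function(ring) {
  n <- nrow(ring)
  if (n < 4) return(FALSE)
  seg <- function(i) rbind(ring[i, ], ring[if (i == n) 1 else i + 1, ])
  cross <- function(o, a, b)
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  for (i in seq_len(n - 2)) {
    for (j in seq(i + 2, n)) {
      if (i == 1 && j == n) next  # adjacent through closure
      s1 <- seg(i); s2 <- seg(j)
      d1 <- cross(s2[1, ], s2[2, ], s1[1, ])
      d2 <- cross(s2[1, ], s2[2, ], s1[2, ])
      d3 <- cross(s1[1, ], s1[2, ], s2[1, ])
      d4 <- cross(s1[1, ], s1[2, ], s2[2, ])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

# Even-odd membership of points in a multi-ring polygon via
# sp::point.in.polygon; boundary points count as inside.
points_in_polygon <- function(px, py, poly) {
  inside <- rep(FALSE, length(px))
  for (ring in poly) {
    hit <- sp::point.in.polygon(px, py, ring[, 1], ring[, 2]) > 0
    inside <- xor(inside, hit)
  }
  inside
}

# Logical matrix of cell-center containment for one polygon on a grid.
polygon_membership <- function(grid, poly) {
  xs <- grid_x(grid)
  ys <- grid_y(grid)
  # restrict to the polygon bounding box to keep the test cheap
  allx <- do.call(rbind, poly)
  bb <- c(min(allx[, 1]), max(allx[, 1]), min(allx[, 2]), max(allx[, 2]))
  jin <- which(xs >= bb[1] & xs <= bb[2])
  iin <- which(ys >= bb[3] & ys <= bb[4])
  out <- matrix(FALSE, nrow(grid$values), ncol(grid$values))
  if (!length(jin) || !length(iin)) return(out)
  px <- rep(xs[jin], each = length(iin))
  py <- rep(ys[iin], times = length(jin))
  out[iin, jin] <- points_in_polygon(px, py, poly)
  out
}

# ---- GeoJSON I/O -----------------------------------------------------------

geojson_poly_rings <- function(geom) {
  ring_mat <- function(coords) {
    m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
    # GeoJSON closes rings by repeating the first vertex; drop it
    if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    m
  }
  switch(geom$type,
    Polygon = lapply(geom$coordinates, ring_mat),
    MultiPolygon = unlist(lapply(geom$coordinates,
                                 function(pp) lapply(pp, ring_mat)),
                          recursive = FALSE),
    stop(sprintf("unsupported geometry type '%s'", geom$type)))
}

#' Read appellation zones (and optionally water features) from GeoJSON
#'
#' Each feature of the FeatureCollection becomes one zone, identified by the
#' `id_field` property. Geometries may be Polygon or MultiPolygon. Invalid
#' (self-intersecting) rings are rejected by default; with
#' `on_invalid = "keep"` they are retained and containment follows the
#' even-odd rule, which resolves bow-ties deterministically.
#'
#' @param path GeoJSON file of zone polygons.
#' @param id_field property naming each zone (default `"zone_id"`).
#' @param water optional path to a GeoJSON file whose polygons are all
#'   treated as water features.
#' @param crs CRS tag to record (GeoJSON itself carries none for projected
#'   data in this pipeline).
#' @param on_invalid `"reject"` (error on self-intersecting rings) or
#'   `"keep"`.
#' @return a [zone_set()].
#' @export
read_vector <- function(path, id_field = "zone_id", water = NULL,
                        crs = "local-m", on_invalid = c("reject", "keep")) {
  on_invalid <- match.arg(on_invalid)
  if (!file.exists(path)) stop(sprintf("vector file not found: %s", path))
  fc <- jsonlite::read_json(path)
  feats <- fc$features
  if (is.null(feats) || length(feats) == 0L)
    stop(sprintf("no features in %s", path))
  zones <- list()
  for (ft in feats) {
    id <- ft$properties[[id_field]]
    if (is.null(id))
      stop(sprintf("feature missing id attribute '%s'", id_field))
    id <- as.character(id)
    if (id %in% names(zones))
      stop(sprintf("duplicate zone id '%s'", id))
    rings <- geojson_poly_rings(ft$geometry)
    if (on_invalid == "reject" && any(vapply(rings, ring_self_intersects,
                                             logical(1))))
      stop(sprintf("zone '%s' has a self-intersecting ring", id))
    zones[[id]] <- rings
  }
  wat <- list()
  if (!is.null(water)) {
    wfc <- jsonlite::read_json(water)
    for (ft in wfc$features)
      wat[[length(wat) + 1L]] <- geojson_poly_rings(ft$geometry)
  }
  zone_set(zones, water = wat, crs = crs)
}

#' Write a zone set to GeoJSON
#'
#' Zones go to `path`; water polygons, if any, to `water_path`.
#'
#' @param zones a [zone_set()].
#' @param path output GeoJSON path for the zone polygons.
#' @param water_path optional output path for the water polygons.
#' @param id_field property name for the zone id.
#' @return `path`, invisibly.
#' @export
write_vector <- function(zones, path, water_path = NULL,
                         id_field = "zone_id") {
  stopifnot(inherits(zones, "zone_set"))
  poly_coords <- function(poly) {
    lapply(poly, function(ring) {
      closed <- rbind(ring, ring[1, , drop = FALSE])
      lapply(seq_len(nrow(closed)), function(i) c(closed[i, 1], closed[i, 2]))
    })
  }
  feat <- function(id, poly) {
    props <- stats::setNames(list(id), id_field)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = poly_coords(poly)))
  }
  fc <- list(type = "FeatureCollection",
             features = unname(Map(feat, names(zones$zones), zones$zones)))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(water_path) && length(zones$water)) {
    wfc <- list(type = "FeatureCollection",
                features = lapply(seq_along(zones$water), function(i)
                  feat(sprintf("water_%d", i), zones$water[[i]])))
    jsonlite::write_json(wfc, water_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
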