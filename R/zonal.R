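#' Per-appellation zonal summaries and contrasts
#'
#' Zonal machinery behind the appellation comparison tables: per-zone
#' means of every continuous surface, drainage-class and aspect-sector
#' proportions, cross-zone column averages, and pairwise contrasts
#' (including the GDD-BEDD gap, whose magnitude separates appellations
#' with peaky versus even seasonal heat accumulation).
#'
#' @name zonal_summary
NULL

# Cell-membership matrix (logical) for each zone; shared by the zonal ops.
zone_membership <- function(grid, zones) {
  stopifnot(is_grid(grid), inherits(zones, "zone_set"))
  if (!identical(zones$crs, grid$crs))
    stop(sprintf("CRS mismatch: zones '%s' vs grid '%s'",
                 zones$crs, grid$crs))
  lapply(zones$zones, function(poly) polygon_membership(grid, poly))
}

#' Zonal mean of a surface
#'
#' Arithmetic mean over cells whose centers fall inside each zone
#' polygon, excluding nodata cells (water is expected to be masked
#' upstream with [apply_water_mask()]). A zone containing no data cells
#' yields `NA` with a warning.
#'
#' @param grid a `grid`.
#' @param zones a [zone_set()] in the grid CRS.
#' @return named numeric vector, one value per zone.
#' @export
zonal_mean <- function(grid, zones) {
  mem <- zone_membership(grid, zones)
  out <- vapply(names(mem), function(id) {
    vals <- grid$values[mem[[id]]]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      warning(sprintf("zone '%s' contains no data cells", id))
      return(NA_real_)
    }
    mean(vals)
  }, numeric(1))
  out
}

#' Zonal class proportions of a categorical surface
#'
#' Fraction of each class among a zone's data cells. Classes absent from
#' a zone are reported as 0; zones with no data cells yield a row of `NA`
#' with a warning. Fractions sum to 1 per zone.
#'
#' @param class_grid `grid` of integer class codes.
#' @param zones a [zone_set()].
#' @param classes integer class codes defining the columns (default: all
#'   codes present in the grid).
#' @return matrix, zones x classes, of fractions.
#' @export
zonal_class_proportions <- function(class_grid, zones, classes = NULL) {
  mem <- zone_membership(class_grid, zones)
  if (is.null(classes))
    classes <- sort(unique(class_grid$values[!is.na(class_grid$values)]))
  cls_names <- if (!is.null(names(classes))) names(classes)
               else as.character(classes)
  out <- matrix(NA_real_, length(mem), length(classes),
                dimnames = list(names(mem), cls_names))
  for (id in names(mem)) {
    vals <- class_grid$values[mem[[id]]]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      warning(sprintf("zone '%s' contains no data cells", id))
      next
    }
    out[id, ] <- vapply(classes, function(cl) mean(vals == cl), numeric(1))
  }
  out
}

#' Summarize all derived surfaces per zone
#'
#' Assembles the per-appellation summary table: zonal means of elevation,
#' slope, insolation (reported in kWh/m^2), AWC, depth, pH, GDD, BEDD,
#' FFD and growing-season precipitation, plus drainage-class and
#' aspect-sector proportions. Layers are taken from a named list; any of
#' the named layers may be omitted and its columns are skipped.
#'
#' @param layers named list of `grid`s; recognized names: `elevation`,
#'   `slope`, `insolation` (Wh/m^2), `awc`, `depth`, `ph`, `gdd`, `bedd`,
#'   `ffd`, `gsp`, `drainage` (class codes), `aspect_class` (sector
#'   codes).
#' @param zones a [zone_set()].
#' @return list with `means` (data.frame, zones x variables),
#'   `drainage_proportions` and `aspect_proportions` (matrices or `NULL`).
#' @export
summarize_zones <- function(layers, zones) {
  mean_vars <- c("elevation", "slope", "insolation", "awc", "depth", "ph",
                 "gdd", "bedd", "ffd", "gsp")
  present <- intersect(mean_vars, names(layers))
  if (!length(present) && !any(c("drainage", "aspect_class") %in%
                               names(layers)))
    stop("no recognized layers supplied")
  means <- data.frame(zone = names(zones$zones), row.names = NULL,
                      stringsAsFactors = FALSE)
  for (v in present) {
    m <- zonal_mean(layers[[v]], zones)
    if (v == "insolation") m <- m / 1000  # Wh -> kWh
    means[[v]] <- unname(m[means$zone])
  }
  drain <- NULL
  if ("drainage" %in% names(layers))
    drain <- zonal_class_proportions(layers$drainage, zones,
                                     classes = DRAINAGE_CLASSES)
  aspect <- NULL
  if ("aspect_class" %in% names(layers))
    aspect <- zonal_class_proportions(layers$aspect_class, zones,
                                      classes = ASPECT_SECTORS)
  list(means = means, drainage_proportions = drain,
       aspect_proportions = aspect)
}

# Resolve a variable column from a zone summary table, supporting the
# derived GDD-BEDD gap.
summary_variable <- function(summaries, variable) {
  df <- if (is.data.frame(summaries)) summaries else summaries$means
  if (!"zone" %in% names(df)) stop("summary table needs a 'zone' column")
  if (variable == "gdd_bedd_gap") {
    if (!all(c("gdd", "bedd") %in% names(df)))
      stop("gdd and bedd columns required for the GDD-BEDD gap")
    vals <- df$gdd - df$bedd
  } else {
    if (!variable %in% names(df))
      stop(sprintf("unknown variable '%s'", variable))
    vals <- df[[variable]]
  }
  stats::setNames(vals, df$zone)
}

#' Pairwise zone contrasts and rankings
#'
#' For each named zone pair, the difference `value(a) - value(b)` of a
#' summary variable; `variable = "gdd_bedd_gap"` contrasts the per-zone
#' GDD minus BEDD difference. Contrasts are antisymmetric and vanish on
#' the diagonal. Rankings order zones by the variable, largest first.
#'
#' @param summaries a data.frame with a `zone` column and variable
#'   columns (e.g. `summarize_zones(...)$means`, or a published summary
#'   table), or the list returned by [summarize_zones()].
#' @param pairs list of `c(zone_a, zone_b)` character pairs.
#' @param variable variable name, or `"gdd_bedd_gap"`.
#' @return list with `variable`, `differences` (named numeric,
#'   `"a vs b"`), and `ranking` (zone ids, descending value).
#' @export
contrast <- function(summaries, pairs, variable) {
  vals <- summary_variable(summaries, variable)
  diffs <- vapply(pairs, function(p) {
    if (!all(p %in% names(vals)))
      stop(sprintf("unknown zone in pair: %s", paste(p, collapse = ", ")))
    unname(vals[p[1]] - vals[p[2]])
  }, numeric(1))
  names(diffs) <- vapply(pairs, function(p) paste(p, collapse = " vs "),
                         character(1))
  list(variable = variable, differences = diffs,
       ranking = names(sort(vals, decreasing = TRUE)))
}

#' Unweighted cross-zone average of a summary column
#'
#' Mean across zones of a variable or class fraction, unweighted by zone
#' area -- the construction of a summary table's "Average" row. Missing
#' entries (classes absent from a zone's survey) are excluded by
#' default, matching how published drainage-class tables average only the
#' appellations reporting a class.
#'
#' @param summaries data.frame with a `zone` column (means or class
#'   proportions in the columns).
#' @param variable column name.
#' @param na.rm drop missing entries before averaging (default `TRUE`).
#' @return the column mean.
#' @export
column_average <- function(summaries, variable, na.rm = TRUE) {
  vals <- summary_variable(summaries, variable)
  if (!length(vals)) stop("no zones in summary")
  mean(vals, na.rm = na.rm)
}

#' Published appellation summary tables
#'
#' The package ships the published mean-site-characteristics table
#' (`ava_table1.csv`: per-AVA means of elevation, slope, insolation, AWC,
#' depth, pH, GDD, BEDD, FFD, PPT) and drainage-class proportion table
#' (`ava_table2.csv`, percent by class with `-` for classes absent from
#' an AVA and `<0.01` for sub-precision traces) for the thirteen inland
#' Pacific Northwest AVAs, as worked-example fixtures for [contrast()]
#' and [column_average()].
#'
#' @return `read_ava_means()`: data.frame with `zone` plus the ten mean
#'   columns. `read_ava_drainage()`: data.frame with `zone` plus the
#'   seven class-percent columns (numeric; absent classes `NA`, traces
#'   0).
#' @export
read_ava_means <- function() {
  path <- system.file("extdata", "ava_table1.csv", package = "terroirgrid",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_ava_means
#' @export
read_ava_drainage <- function() {
  path <- system.file("extdata", "ava_table2.csv", package = "terroirgrid",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (cl in names(DRAINAGE_CLASSES)) {
    x <- df[[cl]]
    x[x == "-"] <- NA
    x[x == "<0.01"] <- "0"    # below printed precision
    df[[cl]] <- as.numeric(x)
  }
  df
}
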