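#' Growing-season climate indices from monthly normals
#'
#' Heat accumulation, frost, and precipitation surfaces are derived from
#' monthly climate normal grids for the April-October growing season, the
#' window used for *Vitis vinifera* suitability in the inland Pacific
#' Northwest.
#'
#' @name climate_indices
NULL

#' Growing-season months and their day counts
#'
#' April through October; 214 days total.
#' @export
SEASON_MONTHS <- c("04", "05", "06", "07", "08", "09", "10")

#' @rdname SEASON_MONTHS
#' @export
SEASON_DAYS <- c(`04` = 30, `05` = 31, `06` = 30, `07` = 31,
                 `08` = 31, `09` = 30, `10` = 31)

#' Bundle monthly climate normal grids
#'
#' @param tmax,tmin,ppt named lists of `grid`s keyed by month `"04"`..
#'   `"10"`: monthly normal maximum/minimum temperature (deg C) and
#'   precipitation (mm).
#' @param last_spring_frost,first_fall_frost `grid`s of median frost dates
#'   (day of year).
#' @return an object of class `monthly_normals`.
#' @export
monthly_normals <- function(tmax, tmin, ppt,
                            last_spring_frost, first_fall_frost) {
  miss <- setdiff(SEASON_MONTHS, Reduce(intersect, list(
    names(tmax), names(tmin), names(ppt))))
  if (length(miss))
    stop(sprintf("missing month(s): %s", paste(miss, collapse = ", ")))
  ref <- tmax[["04"]]
  for (m in SEASON_MONTHS) {
    check_aligned(ref, tmax[[m]], "tmax grids")
    check_aligned(ref, tmin[[m]], "tmin grids")
    check_aligned(ref, ppt[[m]], "ppt grids")
    bad <- tmax[[m]]$values < tmin[[m]]$values
    if (any(bad, na.rm = TRUE))
      stop(sprintf("tmax < tmin at %d cell(s) in month %s",
                   sum(bad, na.rm = TRUE), m))
  }
  check_aligned(ref, last_spring_frost, "frost grids")
  check_aligned(ref, first_fall_frost, "frost grids")
  for (g in list(last_spring_frost, first_fall_frost)) {
    doy <- g$values
    if (any(doy < 1 | doy > 366, na.rm = TRUE))
      stop("frost day-of-year values must lie in [1, 366]")
  }
  structure(list(tmax = tmax[SEASON_MONTHS], tmin = tmin[SEASON_MONTHS],
                 ppt = ppt[SEASON_MONTHS],
                 last_spring_frost = last_spring_frost,
                 first_fall_frost = first_fall_frost),
            class = "monthly_normals")
}

#' Monthly mean temperature
#'
#' Cell-wise average of the monthly normal maximum and minimum
#' temperatures; nodata in either input propagates.
#'
#' @param tmax,tmin co-registered temperature `grid`s (deg C).
#' @return `grid` of (tmax + tmin) / 2.
#' @export
monthly_mean_temperature <- function(tmax, tmin) {
  check_aligned(tmax, tmin, "tmax/tmin")
  grid_like(tmax, (tmax$values + tmin$values) / 2)
}

# Shared monthly accumulation: f(tavg_month) * days_in_month, summed.
accumulate_season <- function(normals, daily_rate) {
  stopifnot(inherits(normals, "monthly_normals"))
  acc <- NULL
  for (m in SEASON_MONTHS) {
    tavg <- monthly_mean_temperature(normals$tmax[[m]], normals$tmin[[m]])
    contrib <- daily_rate(tavg$values) * SEASON_DAYS[[m]]
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  grid_like(normals$tmax[["04"]], acc)
}

#' Growing degree-days (GDD)
#'
#' April-October heat accumulation: for each month, the mean temperature
#' less the base (clamped at zero -- no negative degree-days) times the
#' days in the month, summed over the season. A constant 20 deg C season
#' gives 10 x 214 = 2140 C-degrees.
#'
#' @param normals a [monthly_normals()].
#' @param base base temperature, deg C (default 10, the *V. vinifera*
#'   threshold).
#' @return `grid` of accumulated C-degrees (>= 0).
#' @export
growing_degree_days <- function(normals, base = 10) {
  accumulate_season(normals, function(tavg) pmax(tavg - base, 0))
}

#' Biologically effective degree-days (BEDD)
#'
#' Growing degree-days with the daily accumulation additionally capped at
#' `cap` C-degrees, after Gladstones' observation that vine phenological
#' development is most active between 10 and 19 deg C. Applied to monthly
#' normals, the cap limits each month's mean daily rate:
#' `min(cap, max(0, tavg - base)) * days`. BEDD <= GDD everywhere, with
#' equality wherever the monthly means stay at or below `base + cap`.
#'
#' @inheritParams growing_degree_days
#' @param cap daily accumulation cap, C-degrees (default 9).
#' @return `grid` of accumulated C-degrees (>= 0).
#' @export
biologically_effective_degree_days <- function(normals, base = 10, cap = 9) {
  accumulate_season(normals, function(tavg) pmin(pmax(tavg - base, 0), cap))
}

#' Frost-free days (FFD)
#'
#' Cell-wise difference between the median first fall frost and median
#' last spring frost day-of-year surfaces. Cells where the spring date
#' falls after the fall date are degenerate; they become nodata and a
#' warning reports their count.
#'
#' @param last_spring,first_fall co-registered day-of-year `grid`s.
#' @return `grid` of growing-season length in days.
#' @export
frost_free_days <- function(last_spring, first_fall) {
  check_aligned(last_spring, first_fall, "frost grids")
  d <- first_fall$values - last_spring$values
  neg <- which(d < 0)
  if (length(neg)) {
    warning(sprintf(
      "%d cell(s) with last spring frost after first fall frost set to nodata",
      length(neg)))
    d[neg] <- NA
  }
  grid_like(last_spring, d)
}

#' Growing-season precipitation (GSP)
#'
#' Cell-wise sum of the April-October monthly precipitation normals; a
#' proxy for powdery mildew (\emph{Uncinula necator}) risk.
#'
#' @param normals a [monthly_normals()].
#' @return `grid` of precipitation in mm (>= 0).
#' @export
growing_season_precipitation <- function(normals) {
  stopifnot(inherits(normals, "monthly_normals"))
  acc <- NULL
  for (m in SEASON_MONTHS) {
    v <- normals$ppt[[m]]$values
    acc <- if (is.null(acc)) v else acc + v
  }
  grid_like(normals$ppt[["04"]], acc)
}
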