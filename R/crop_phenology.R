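#' Crop parameter set
#'
#' Bundles the FAO-56-style parameters of one crop: the three crop
#' coefficients (`kc_ini`, `kc_mid`, `kc_end`), the four growth-stage
#' fractions of the growing period (initial, development, mid-season,
#' late), rooting depths for the rain-fed and irrigated regimes, and the
#' critical depletion factor `p` that sets the readily available water as
#' a fraction of the total available water.
#'
#' @param crop_id character identifier, e.g. `"wheat"`.
#' @param kc_ini,kc_mid,kc_end dimensionless crop coefficients, all > 0.
#' @param stage_fractions numeric length-4 vector of non-negative stage
#'   fractions (initial, development, mid, late) summing to 1.
#' @param zr_rainfed,zr_irrigated rooting depth in metres, > 0.
#' @param p critical depletion factor, strictly between 0 and 1.
#' @return An object of class `crop_parameters`.
#' @examples
#' crop_parameters("wheat", 0.3, 1.15, 0.3, c(0.15, 0.25, 0.40, 0.20),
#'                 zr_rainfed = 1.5, zr_irrigated = 1.0, p = 0.55)
#' @export
crop_parameters <- function(crop_id, kc_ini, kc_mid, kc_end,
                            stage_fractions, zr_rainfed, zr_irrigated, p) {
  stopifnot(is.character(crop_id), length(crop_id) == 1L)
  kc <- c(kc_ini = kc_ini, kc_mid = kc_mid, kc_end = kc_end)
  if (any(!is.finite(kc)) || any(kc <= 0))
    stop("all kc values must be finite and > 0")
  stage_fractions <- as.numeric(stage_fractions)
  if (length(stage_fractions) != 4L || any(stage_fractions < 0))
    stop("stage_fractions must be four non-negative numbers")
  if (abs(sum(stage_fractions) - 1) > 1e-9)
    stop("stage_fractions must sum to 1 (got ", sum(stage_fractions), ")")
  if (!is.finite(p) || p <= 0 || p >= 1)
    stop("p must lie strictly in (0, 1)")
  if (zr_rainfed <= 0 || zr_irrigated <= 0)
    stop("rooting depths must be > 0")
  structure(list(crop_id = crop_id,
                 kc_ini = kc_ini, kc_mid = kc_mid, kc_end = kc_end,
                 stage_fractions = stage_fractions,
                 zr_rainfed = zr_rainfed, zr_irrigated = zr_irrigated,
                 p = p),
            class = "crop_parameters")
}

#' @export
print.crop_parameters <- function(x, ...) {
  cat(sprintf("<crop_parameters> %s\n", x$crop_id))
  cat(sprintf("  kc ini/mid/end : %.2f / %.2f / %.2f\n",
              x$kc_ini, x$kc_mid, x$kc_end))
  cat(sprintf("  stage fractions: %s\n",
              paste(format(x$stage_fractions), collapse = " ")))
  cat(sprintf("  zr rainfed %.2f m, irrigated %.2f m, p = %.2f\n",
              x$zr_rainfed, x$zr_irrigated, x$p))
  invisible(x)
}

#' Growing season
#'
#' One growing period of a crop in a region: planting and harvest
#' day-of-year and the harvested area attached to this period. When
#' `harvest_doy < planting_doy` the season wraps the year boundary and the
#' harvest falls in the following calendar year.
#'
#' @param planting_doy,harvest_doy day-of-year in 1..366.
#' @param harvested_area harvested area in km^2, >= 0.
#' @return An object of class `growing_season`.
#' @export
growing_season <- function(planting_doy, harvest_doy, harvested_area = 0) {
  if (planting_doy < 1 || planting_doy > 366 ||
      harvest_doy < 1 || harvest_doy > 366)
    stop("planting/harvest day-of-year must lie in 1..366")
  if (harvested_area < 0) stop("harvested_area must be >= 0")
  s <- structure(list(planting_doy = as.integer(planting_doy),
                      harvest_doy = as.integer(harvest_doy),
                      harvested_area = as.numeric(harvested_area)),
                 class = "growing_season")
  len <- season_length(s)
  if (len < 1 || len > 366) stop("season length must lie in 1..366 days")
  s
}

#' Nominal season length in days
#'
#' Length of the growing period on a 365-day nominal year, inclusive of
#' both planting and harvest days. Wrap-around seasons count the days from
#' planting to year end plus those from new year to harvest.
#'
#' @param season a [growing_season()].
#' @return integer number of days.
#' @export
season_length <- function(season) {
  p <- season$planting_doy
  h <- season$harvest_doy
  if (h >= p) h - p + 1L else 365L - p + 1L + h
}

#' Scale the four growth stages to a season
#'
#' Converts the crop's stage fractions, reported as shares of the growing
#' period, into four contiguous day intervals covering the season exactly.
#' Stage boundaries use cumulative-fraction rounding,
#' `b_k = round(L * sum(fractions[1:k]))`, so per-stage rounding errors
#' cannot accumulate and the intervals always total the season length.
#'
#' @param params a [crop_parameters()].
#' @param season a [growing_season()]; its nominal length sets `L`.
#' @return A data.frame with columns `stage`, `start`, `end`, `length`
#'   (season-day coordinates, 1-based, inclusive).
#' @examples
#' p <- crop_parameters("x", 0.3, 1.2, 0.5, rep(0.25, 4), 1, 1, 0.5)
#' scale_stages_to_calendar(p, growing_season(1, 120))
#' @export
scale_stages_to_calendar <- function(params, season) {
  stage_intervals(params$stage_fractions, season_length(season))
}

# Stage boundaries for an arbitrary season length (used per calendar year,
# where leap days can stretch the actual length by one day).
stage_intervals <- function(fractions, len) {
  if (len < 1) stop("season length must be >= 1 day")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("stage fractions must sum to 1")
  b <- floor(len * cumsum(fractions) + 0.5)  # half-up rounding
  b[4] <- len
  start <- c(1, b[-4] + 1)
  data.frame(stage = c("initial", "development", "mid", "late"),
             start = as.integer(start), end = as.integer(b),
             length = as.integer(b - start + 1))
}

# Continuous piecewise-linear kc over season position t in [0, L]:
# constant kc_ini over the initial stage, linear rise over development,
# constant kc_mid over mid-season, linear fall/rise to kc_end over late.
# Daily values sample this curve at day centres (t = d - 0.5), which makes
# the series continuous across stage boundaries by construction.
kc_at <- function(t, params, bounds, len) {
  b1 <- bounds[1]; b2 <- bounds[2]; b3 <- bounds[3]
  ifelse(t <= b1, params$kc_ini,
  ifelse(t <= b2, params$kc_ini +
           (params$kc_mid - params$kc_ini) * (t - b1) / (b2 - b1),
  ifelse(t <= b3, params$kc_mid,
         params$kc_mid +
           (params$kc_end - params$kc_mid) * (t - b3) / (len - b3))))
}

#' Daily crop-coefficient series over a date span
#'
#' Builds the daily kc series for one growing season over a span of
#' calendar dates. The season is instantiated in every calendar year it
#' fits: planting at `planting_doy`, harvest at `harvest_doy` of the same
#' year, or of the following year for wrap-around seasons. Days outside
#' any season instance take `off_season_kc` (bare soil / cover vegetation,
#' 0.5 by default in the engine configuration). Day-of-year 366 maps to
#' day 365 in non-leap years, so calendars defined on leap years remain
#' usable everywhere.
#'
#' @param params a [crop_parameters()].
#' @param season a [growing_season()].
#' @param off_season_kc kc applied outside the growing season.
#' @param span contiguous `Date` vector (daily) to cover.
#' @return An object of class `kc_series`: list with `dates`, `values`
#'   (daily kc) and `in_season` (logical).
#' @export
build_kc_curve <- function(params, season, off_season_kc, span) {
  span <- as.Date(span)
  if (length(span) == 0L) stop("empty span")
  if (any(diff(span) != 1)) stop("span must be contiguous daily dates")
  values <- rep(as.numeric(off_season_kc), length(span))
  in_season <- rep(FALSE, length(span))
  wrap <- season$harvest_doy < season$planting_doy
  y0 <- as.integer(format(span[1], "%Y")) - 1L  # catch wrap from prior year
  y1 <- as.integer(format(span[length(span)], "%Y"))
  for (y in y0:y1) {
    plant <- doy_to_date(season$planting_doy, y)
    harv <- doy_to_date(season$harvest_doy, if (wrap) y + 1L else y)
    len <- as.integer(harv - plant) + 1L
    iv <- stage_intervals(params$stage_fractions, len)
    idx <- as.integer(plant - span[1]) + seq_len(len)  # position in span
    keep <- idx >= 1L & idx <= length(span)
    if (!any(keep)) next
    d <- seq_len(len)[keep]
    values[idx[keep]] <- kc_at(d - 0.5, params, iv$end[1:3], len)
    in_season[idx[keep]] <- TRUE
  }
  structure(list(dates = span, values = values, in_season = in_season,
                 off_season_kc = as.numeric(off_season_kc)),
            class = "kc_series")
}

#' @export
print.kc_series <- function(x, ...) {
  cat(sprintf("<kc_series> %s .. %s (%d days, %d in season)\n",
              format(x$dates[1]), format(x$dates[length(x$dates)]),
              length(x$dates), sum(x$in_season)))
  invisible(x)
}

# Date of a day-of-year in a given calendar year; doy 366 falls back to
# Dec 31 in non-leap years.
doy_to_date <- function(doy, year) {
  jan1 <- as.Date(sprintf("%d-01-01", year))
  ndays <- as.integer(as.Date(sprintf("%d-12-31", year)) - jan1) + 1L
  jan1 + (min(doy, ndays) - 1L)
}

#' Consolidate multiple growing periods to at most two
#'
#' Regional calendars can report more than two growing periods per crop;
#' the model simulates at most two. When more than two are reported the
#' two with the largest harvested areas are retained (ties broken by the
#' earliest planting day, then by harvest day) and each discarded period's
#' harvested area is added to the retained period nearest in planting day
#' (circular day-of-year distance), so total harvested area is conserved
#' exactly.
#'
#' @param seasons non-empty list of [growing_season()].
#' @return List of at most two `growing_season` objects.
#' @export
consolidate_seasons <- function(seasons) {
  if (length(seasons) == 0L) stop("at least one growing season is required")
  if (length(seasons) <= 2L) return(seasons)
  area <- vapply(seasons, function(s) s$harvested_area, numeric(1))
  plant <- vapply(seasons, function(s) s$planting_doy, integer(1))
  harv <- vapply(seasons, function(s) s$harvest_doy, integer(1))
  ord <- order(-area, plant, harv)
  keep <- sort(ord[1:2])
  drop <- setdiff(seq_along(seasons), keep)
  out <- seasons[keep]
  for (i in drop) {
    dd <- abs(plant[keep] - plant[i])
    dd <- pmin(dd, 365L - dd)  # circular distance on the year
    j <- which.min(dd)         # ties resolve to the earlier retained season
    out[[j]]$harvested_area <- out[[j]]$harvested_area + area[i]
  }
  out
}

#' Regional crop calendar
#'
#' Holds, for one region, the growing periods of every (crop, regime)
#' combination. Seasons are consolidated to at most two per combination on
#' retrieval via [consolidate_seasons()].
#'
#' @param region_id identifier of the calendar region.
#' @param entries data.frame with columns `crop_id`, `regime`
#'   (`"rainfed"` or `"irrigated"`), `planting_doy`, `harvest_doy`,
#'   `harvested_area_km2`; one row per growing period.
#' @return An object of class `crop_calendar`.
#' @export
crop_calendar <- function(region_id, entries) {
  need <- c("crop_id", "regime", "planting_doy", "harvest_doy",
            "harvested_area_km2")
  if (!all(need %in% names(entries)))
    stop("calendar entries need columns: ", paste(need, collapse = ", "))
  if (!all(entries$regime %in% c("rainfed", "irrigated")))
    stop("regime must be 'rainfed' or 'irrigated'")
  structure(list(region_id = region_id, entries = entries),
            class = "crop_calendar")
}

#' @export
print.crop_calendar <- function(x, ...) {
  cat(sprintf("<crop_calendar> region %s: %d growing period(s), %d crop(s)\n",
              as.character(x$region_id), nrow(x$entries),
              length(unique(x$entries$crop_id))))
  invisible(x)
}

#' Growing seasons of a crop/regime in a calendar
#'
#' @param calendar a [crop_calendar()].
#' @param crop_id,regime selection.
#' @return Consolidated list (at most two) of [growing_season()], or an
#'   empty list if the combination is absent from the calendar.
#' @export
calendar_seasons <- function(calendar, crop_id, regime) {
  e <- calendar$entries
  e <- e[e$crop_id == crop_id & e$regime == regime, , drop = FALSE]
  if (nrow(e) == 0L) return(list())
  seasons <- lapply(seq_len(nrow(e)), function(i)
    growing_season(e$planting_doy[i], e$harvest_doy[i],
                   e$harvested_area_km2[i]))
  consolidate_seasons(seasons)
}

#' Read a crop parameter table
#'
#' Reads a delimited table with columns `crop_id, kc_ini, kc_mid, kc_end,
#' f_ini, f_dev, f_mid, f_late, zr_rainfed_m, zr_irrigated_m, p` into a
#' named list of [crop_parameters()].
#'
#' @param path CSV file path.
#' @return Named list of `crop_parameters`, keyed by `crop_id`.
#' @export
read_crop_parameters <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(d)), function(i)
    crop_parameters(d$crop_id[i], d$kc_ini[i], d$kc_mid[i], d$kc_end[i],
                    c(d$f_ini[i], d$f_dev[i], d$f_mid[i], d$f_late[i]),
                    d$zr_rainfed_m[i], d$zr_irrigated_m[i], d$p[i]))
  names(out) <- d$crop_id
  out
}

#' Write a crop parameter table
#'
#' @param crops named list of [crop_parameters()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_crop_parameters <- function(crops, path) {
  d <- do.call(rbind, lapply(crops, function(p)
    data.frame(crop_id = p$crop_id, kc_ini = p$kc_ini, kc_mid = p$kc_mid,
               kc_end = p$kc_end,
               f_ini = p$stage_fractions[1], f_dev = p$stage_fractions[2],
               f_mid = p$stage_fractions[3], f_late = p$stage_fractions[4],
               zr_rainfed_m = p$zr_rainfed, zr_irrigated_m = p$zr_irrigated,
               p = p$p)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read regional crop calendars
#'
#' Reads a CSV with columns `region_id, crop_id, regime, planting_doy,
#' harvest_doy, harvested_area_km2` (one row per growing period) into a
#' list of [crop_calendar()] keyed by region.
#'
#' @param path CSV file path.
#' @return Named list of `crop_calendar`.
#' @export
read_crop_calendar <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  by_region <- split(d, d$region_id)
  out <- lapply(names(by_region), function(r)
    crop_calendar(r, by_region[[r]]))
  names(out) <- names(by_region)
  out
}

#' Write regional crop calendars
#'
#' @param calendars list of [crop_calendar()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_crop_calendar <- function(calendars, path) {
  d <- do.call(rbind, lapply(calendars, function(cal) {
    e <- cal$entries
    e$region_id <- cal$region_id
    e[, c("region_id", "crop_id", "regime", "planting_doy", "harvest_doy",
          "harvested_area_km2")]
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
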