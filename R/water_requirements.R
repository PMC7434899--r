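#' Daily green and blue water partition
#'
#' Green water is the actual evapotranspiration of the stressed
#' (precipitation-only) run. Blue water is the irrigation requirement:
#' the difference between the unstressed and stressed actual
#' evapotranspiration — the unstressed run evapotranspires at the
#' potential rate `kc * et0` — and is only counted on irrigated land.
#'
#' @param et_act_stressed stressed actual evapotranspiration, mm/day
#'   (vectorised).
#' @param et_pot potential (= unstressed actual) evapotranspiration,
#'   mm/day.
#' @param regime `"rainfed"` or `"irrigated"`.
#' @return List with numeric vectors `gw` and `bw` (mm/day).
#' @examples
#' daily_green_blue(3, 5, "irrigated")  # gw 3, bw 2
#' @export
daily_green_blue <- function(et_act_stressed, et_pot,
                             regime = c("rainfed", "irrigated")) {
  regime <- match.arg(regime)
  if (any(et_act_stressed < 0) || any(et_pot < 0))
    stop("evapotranspiration must be >= 0")
  if (any(et_act_stressed > et_pot + 1e-9))
    stop("stressed actual ET cannot exceed potential ET")
  bw <- pmax(et_pot - et_act_stressed, 0)
  list(gw = et_act_stressed,
       bw = if (regime == "irrigated") bw else rep(0, length(bw)))
}

#' Crop water requirement result
#'
#' Monthly and annual green and blue requirements for one crop, regime
#' and location. `monthly` carries 12 rows per simulated year; annual
#' values are the monthly sums.
#'
#' @param crop_id,regime identification of the simulated combination.
#' @param monthly data.frame with columns `year`, `month` (1..12), `gw`,
#'   `bw` (mm/month), 12 rows per year.
#' @return An object of class `cwr_result`.
#' @export
cwr_result <- function(crop_id, regime, monthly) {
  stopifnot(all(c("year", "month", "gw", "bw") %in% names(monthly)))
  if (any(monthly$gw < -1e-9) || any(monthly$bw < -1e-9))
    stop("monthly requirements must be >= 0")
  if (regime == "rainfed" && any(monthly$bw != 0))
    stop("blue water must be identically 0 for the rain-fed regime")
  monthly <- monthly[order(monthly$year, monthly$month), , drop = FALSE]
  rownames(monthly) <- NULL
  ann <- aggregate(cbind(gw, bw) ~ year, data = monthly, FUN = sum)
  structure(list(crop_id = crop_id, regime = regime,
                 monthly = monthly, annual = ann),
            class = "cwr_result")
}

#' @export
print.cwr_result <- function(x, ...) {
  cat(sprintf("<cwr_result> %s / %s, year(s) %s\n", x$crop_id, x$regime,
              paste(x$annual$year, collapse = ", ")))
  cat(sprintf("  annual gw: %s mm\n",
              paste(sprintf("%.1f", x$annual$gw), collapse = ", ")))
  cat(sprintf("  annual bw: %s mm\n",
              paste(sprintf("%.1f", x$annual$bw), collapse = ", ")))
  invisible(x)
}

#' Aggregate a balance trace to monthly crop water requirements
#'
#' Sums the daily green and blue requirements over each calendar month of
#' the crop's growing season. Only days flagged in-season contribute;
#' off-season days influence the result solely through soil-moisture
#' carry-over. Days of a season that wraps the year boundary contribute
#' to their actual calendar month and year.
#'
#' @param trace a `balance_trace` from [run_water_balance()] (stressed
#'   run) covering the reporting span.
#' @param kc a `kc_series` over the same span; supplies dates and
#'   in-season flags.
#' @param regime `"rainfed"` or `"irrigated"`.
#' @return A [cwr_result()] with 12 monthly rows per calendar year of the
#'   span.
#' @export
aggregate_cwr <- function(trace, kc, regime = c("rainfed", "irrigated")) {
  regime <- match.arg(regime)
  if (nrow(trace) != length(kc$dates))
    stop("trace and kc series spans differ (", nrow(trace), " vs ",
         length(kc$dates), " days)")
  gb <- daily_green_blue(trace$et_act, trace$et_pot, regime)
  yr <- as.integer(format(kc$dates, "%Y"))
  mo <- as.integer(format(kc$dates, "%m"))
  years <- sort(unique(yr))
  grid <- expand.grid(month = 1:12, year = years)
  key <- paste(yr, mo)
  gkey <- paste(grid$year, grid$month)
  w <- as.numeric(kc$in_season)  # off-season days carry zero weight
  gw_m <- rowsum(gb$gw * w, key)
  bw_m <- rowsum(gb$bw * w, key)
  monthly <- data.frame(year = grid$year, month = grid$month,
                        gw = as.numeric(gw_m[match(gkey, rownames(gw_m))]),
                        bw = as.numeric(bw_m[match(gkey, rownames(bw_m))]))
  monthly$gw[is.na(monthly$gw)] <- 0
  monthly$bw[is.na(monthly$bw)] <- 0
  cwr_result(attr(trace, "crop_id") %||% "crop", regime, monthly)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Average crop water requirements over years
#'
#' Element-wise arithmetic mean of the monthly (and hence annual) fields
#' over the simulated years, e.g. to form a multi-year climatological
#' product from yearly simulations.
#'
#' @param result a [cwr_result()] holding one or more years, or a list of
#'   single-year `cwr_result`s on identical crop/regime.
#' @return A `cwr_result` with a single pseudo-year (labelled by the
#'   first year) holding the means.
#' @export
multi_year_average <- function(result) {
  if (!inherits(result, "cwr_result")) {
    if (length(result) == 0L) stop("no results to average")
    ids <- vapply(result, function(r) paste(r$crop_id, r$regime), "")
    if (length(unique(ids)) != 1L)
      stop("results must share crop and regime")
    monthly <- do.call(rbind, lapply(result, `[[`, "monthly"))
    result <- cwr_result(result[[1]]$crop_id, result[[1]]$regime, monthly)
  }
  m <- result$monthly
  avg <- aggregate(cbind(gw, bw) ~ month, data = m, FUN = mean)
  monthly <- data.frame(year = min(m$year), month = avg$month,
                        gw = avg$gw, bw = avg$bw)
  cwr_result(result$crop_id, result$regime, monthly)
}

#' Simulate crop water requirements for one cell
#'
#' Full point pipeline for one crop, regime and soil profile: for each
#' (consolidated) growing season the store is spun up from
#' `initial_moisture_fraction * taw` over the selected spin-up years,
#' then the production years are simulated in a single continuous
#' stressed run and aggregated to monthly green and blue requirements.
#' With two growing seasons, each is simulated independently and the
#' monthly fields are summed.
#'
#' @param forcing a [daily_forcing()] covering all spin-up and production
#'   years in full.
#' @param params a [crop_parameters()].
#' @param seasons a [growing_season()] or list of them (consolidated to
#'   at most two via [consolidate_seasons()]).
#' @param profile a [soil_profile()].
#' @param regime `"rainfed"` or `"irrigated"`.
#' @param config an [engine_config()].
#' @param production_years integer vector of calendar years to report.
#' @param spin_years integer vector of spin-up years; defaults to a
#'   seeded draw from the forcing years via [select_spin_up_years()].
#' @param return_traces keep the daily production traces as attribute
#'   `"traces"` (one per season).
#' @return A [cwr_result()] over the production years.
#' @export
simulate_cwr <- function(forcing, params, seasons, profile,
                         regime = c("rainfed", "irrigated"),
                         config = engine_config(),
                         production_years = NULL,
                         spin_years = NULL,
                         return_traces = FALSE) {
  regime <- match.arg(regime)
  if (inherits(seasons, "growing_season")) seasons <- list(seasons)
  seasons <- consolidate_seasons(seasons)
  yr <- as.integer(format(forcing$dates, "%Y"))
  avail <- sort(unique(yr))
  if (is.null(production_years)) production_years <- max(avail)
  if (!all(production_years %in% avail))
    stop("forcing does not cover production years ",
         paste(setdiff(production_years, avail), collapse = ", "))
  if (is.null(spin_years))
    spin_years <- select_spin_up_years(avail, config$spin_up_years,
                                       config$seed)
  if (!all(spin_years %in% avail))
    stop("forcing does not cover spin-up years ",
         paste(setdiff(spin_years, avail), collapse = ", "))

  prod_idx <- which(yr %in% production_years)
  cap <- water_capacity(params, profile, regime)
  total <- NULL
  traces <- list()
  for (season in seasons) {
    # splice spin-up years (in draw order) ahead of the production span
    idx <- c(unlist(lapply(spin_years, function(y) which(yr == y))),
             prod_idx)
    kc_parts <- lapply(spin_years, function(y)
      build_kc_curve(params, season, config$off_season_kc,
                     forcing$dates[yr == y]))
    kc_prod <- build_kc_curve(params, season, config$off_season_kc,
                              forcing$dates[prod_idx])
    kc_all <- c(unlist(lapply(kc_parts, `[[`, "values")), kc_prod$values)
    trace <- run_water_balance(
      forcing$precip[idx], forcing$et0_daily[idx], kc_all, cap, profile,
      s0 = config$initial_moisture_fraction * cap$taw, stressed = TRUE,
      runoff_fraction = config$surface_runoff_fraction)
    ptrace <- trace[seq(nrow(trace) - length(prod_idx) + 1, nrow(trace)),
                    , drop = FALSE]
    class(ptrace) <- class(trace)
    attr(ptrace, "crop_id") <- params$crop_id
    res <- aggregate_cwr(ptrace, kc_prod, regime)
    if (return_traces) traces[[length(traces) + 1L]] <- ptrace
    total <- if (is.null(total)) res else {
      m <- total$monthly
      m$gw <- m$gw + res$monthly$gw
      m$bw <- m$bw + res$monthly$bw
      cwr_result(params$crop_id, regime, m)
    }
  }
  out <- cwr_result(params$crop_id, regime, total$monthly)
  if (return_traces) attr(out, "traces") <- traces
  out
}
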