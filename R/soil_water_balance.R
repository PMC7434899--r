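#' Soil profile of one grid cell
#'
#' @param theta_diff maximum soil moisture storage capacity, i.e. water
#'   content at field capacity minus at wilting point, in mm per metre of
#'   soil; > 0.
#' @param f_max maximum infiltration rate in mm/day; >= 0.
#' @return An object of class `soil_profile`.
#' @export
soil_profile <- function(theta_diff, f_max) {
  if (!is.finite(theta_diff) || theta_diff <= 0)
    stop("theta_diff must be finite and > 0")
  if (!is.finite(f_max) || f_max < 0)
    stop("f_max must be finite and >= 0")
  structure(list(theta_diff = as.numeric(theta_diff),
                 f_max = as.numeric(f_max)),
            class = "soil_profile")
}

#' Root-zone water capacity
#'
#' Total available water is the storage capacity integrated over the
#' rooting depth, `TAW = theta_diff * zr`; readily available water is the
#' share a crop can take up without stress, `RAW = p * TAW`.
#'
#' @param params a [crop_parameters()]; supplies `p` and the rooting depth.
#' @param profile a [soil_profile()].
#' @param regime `"rainfed"` or `"irrigated"`; selects the rooting depth.
#' @return An object of class `water_capacity` with fields `taw` and
#'   `raw` (mm).
#' @examples
#' p <- crop_parameters("x", 0.3, 1.2, 0.5, rep(0.25, 4), 1, 1, 0.5)
#' water_capacity(p, soil_profile(200, 10), "rainfed")  # taw 200, raw 100
#' @export
water_capacity <- function(params, profile, regime = c("rainfed", "irrigated")) {
  regime <- match.arg(regime)
  zr <- if (regime == "rainfed") params$zr_rainfed else params$zr_irrigated
  if (zr <= 0) stop("rooting depth must be > 0")
  taw <- profile$theta_diff * zr
  raw <- params$p * taw
  if (!(raw > 0 && raw < taw))
    stop("readily available water must satisfy 0 < raw < taw")
  structure(list(taw = taw, raw = raw), class = "water_capacity")
}

#' Split precipitation into effective precipitation and surface runoff
#'
#' A fixed fraction of daily precipitation (5% by default) is partitioned
#' to surface runoff; the remainder infiltrates as effective
#' precipitation.
#'
#' @param p daily precipitation, mm/day (vectorised); >= 0.
#' @param runoff_fraction fraction routed to surface runoff.
#' @return List with numeric vectors `p_eff` and `surface_runoff`.
#' @examples
#' effective_precipitation(10)  # p_eff 9.5, surface_runoff 0.5
#' @export
effective_precipitation <- function(p, runoff_fraction = 0.05) {
  if (any(!is.finite(p)) || any(p < 0))
    stop("precipitation must be finite and >= 0")
  if (runoff_fraction < 0 || runoff_fraction >= 1)
    stop("runoff_fraction must lie in [0, 1)")
  list(p_eff = (1 - runoff_fraction) * p,
       surface_runoff = runoff_fraction * p)
}

#' Soil moisture stress coefficient
#'
#' Reduction factor on potential evapotranspiration: 1 when root-zone
#' moisture is at or above the readily available water, declining linearly
#' to 0 at zero moisture below it.
#'
#' @param s root-zone soil moisture, mm (vectorised); >= 0.
#' @param cap a [water_capacity()].
#' @return Dimensionless value(s) in \[0, 1\].
#' @export
stress_coefficient <- function(s, cap) {
  if (any(s < 0)) stop("soil moisture must be >= 0")
  ifelse(s >= cap$raw, 1, s / cap$raw)
}

#' Deep percolation below the root zone
#'
#' Zero while moisture is below the readily available water; above it,
#' drainage ramps linearly with the previous day's moisture, reaching the
#' soil's maximum infiltration rate at total available water.
#'
#' @param s_prev previous-day soil moisture, mm (vectorised), in
#'   \[0, taw\].
#' @param cap a [water_capacity()].
#' @param profile a [soil_profile()]; supplies `f_max`.
#' @return Percolation in mm/day.
#' @export
deep_percolation <- function(s_prev, cap, profile) {
  if (any(s_prev < 0 | s_prev > cap$taw + 1e-9))
    stop("soil moisture must lie in [0, taw]")
  ifelse(s_prev >= cap$raw,
         profile$f_max * (s_prev - cap$raw) / (cap$taw - cap$raw),
         0)
}

#' Advance the soil water balance by one day
#'
#' Executes one explicit daily step of the root-zone bucket:
#' effective precipitation is added, actual evapotranspiration
#' (`ks * kc * et0`, with `ks` evaluated on the previous day's moisture in
#' the stressed run and fixed at 1 otherwise) and deep percolation
#' (also on the previous day's moisture) are removed. If the tentative
#' balance goes negative, evapotranspiration and percolation are scaled by
#' a common factor so the store closes exactly at zero; if it exceeds the
#' total available water, the excess leaves as sub-surface runoff and the
#' store closes at `taw`.
#'
#' In the well-watered (`stressed = FALSE`) run the crop always
#' evapotranspires at the potential rate, independent of the soil state:
#' any storage deficit is understood as implicitly supplied by
#' irrigation, which is never simulated as a balance input. The
#' proportional closure therefore applies to the stressed run only, and
#' the exact per-day balance identity is a stressed-run property.
#'
#' @param s previous-day soil moisture, mm.
#' @param precip daily precipitation, mm/day.
#' @param et0 daily reference evapotranspiration, mm/day.
#' @param kc crop coefficient of the day.
#' @param cap a [water_capacity()].
#' @param profile a [soil_profile()].
#' @param stressed logical; `FALSE` forces `ks = 1` (well-watered run).
#' @param runoff_fraction surface-runoff share of precipitation.
#' @return List with `s` (new moisture, mm) and `fluxes`, a list holding
#'   `p_eff`, `surface_runoff`, `et_pot`, `et_act`, `d`, `r`, `ks` for the
#'   day. The balance identity
#'   `s_new - s = p_eff - et_act - d - r` holds to floating-point
#'   round-off.
#' @export
step_day <- function(s, precip, et0, kc, cap, profile, stressed = TRUE,
                     runoff_fraction = 0.05) {
  if (!is.finite(precip) || !is.finite(et0) || precip < 0 || et0 < 0)
    stop("forcing must be finite and >= 0")
  taw <- cap$taw; raw <- cap$raw; f_max <- profile$f_max
  p_eff <- (1 - runoff_fraction) * precip
  et_pot <- kc * et0
  ks <- if (!stressed || s >= raw) 1 else s / raw
  et_act <- ks * et_pot
  d <- if (s >= raw) f_max * (s - raw) / (taw - raw) else 0
  s_new <- s + p_eff - et_act - d
  if (s_new < 0) {
    if (stressed) {
      den <- et_act + d
      lambda <- if (den > 0) (s + p_eff) / den else 0
      et_act <- lambda * et_act
      d <- lambda * d
    }
    s_new <- 0
  }
  r <- 0
  if (s_new > taw) {
    r <- s_new - taw
    s_new <- taw
  }
  list(s = s_new,
       fluxes = list(p_eff = p_eff, surface_runoff = runoff_fraction * precip,
                     et_pot = et_pot, et_act = et_act, d = d, r = r, ks = ks))
}

#' Run the daily soil water balance over a forcing series
#'
#' Iterates [step_day()]'s arithmetic over a daily series (inlined for
#' speed; the two paths are kept literally identical). Returns the full
#' audit trail needed for water-balance closure checks and for the
#' green/blue partition.
#'
#' @param precip,et0_daily daily forcing vectors, mm/day, equal length.
#' @param kc_values daily crop coefficients, same length.
#' @param cap a [water_capacity()].
#' @param profile a [soil_profile()].
#' @param s0 initial soil moisture, mm, in \[0, taw\].
#' @param stressed logical; `FALSE` forces `ks = 1` throughout.
#' @param runoff_fraction surface-runoff share of precipitation.
#' @return A data.frame of class `balance_trace` with one row per day:
#'   `s`, `p_eff`, `surface_runoff`, `et_pot`, `et_act`, `d`, `r`, `ks`,
#'   plus attribute `s0`.
#' @export
run_water_balance <- function(precip, et0_daily, kc_values, cap, profile,
                              s0, stressed = TRUE, runoff_fraction = 0.05) {
  n <- length(precip)
  if (length(et0_daily) != n || length(kc_values) != n)
    stop("precip, et0_daily and kc_values must have equal length")
  if (any(!is.finite(precip)) || any(precip < 0) ||
      any(!is.finite(et0_daily)) || any(et0_daily < 0))
    stop("forcing must be finite and >= 0")
  taw <- cap$taw; raw <- cap$raw; f_max <- profile$f_max
  if (!is.finite(s0) || s0 < 0 || s0 > taw)
    stop("s0 must lie in [0, taw]")
  p_eff_v <- (1 - runoff_fraction) * precip
  et_pot_v <- kc_values * et0_daily
  s_out <- numeric(n); et_act_v <- numeric(n); d_v <- numeric(n)
  r_v <- numeric(n); ks_v <- numeric(n)
  s <- s0
  for (t in seq_len(n)) {
    p_eff <- p_eff_v[t]
    et_pot <- et_pot_v[t]
    ks <- if (!stressed || s >= raw) 1 else s / raw
    et_act <- ks * et_pot
    d <- if (s >= raw) f_max * (s - raw) / (taw - raw) else 0
    s_new <- s + p_eff - et_act - d
    if (s_new < 0) {
      if (stressed) {
        den <- et_act + d
        lambda <- if (den > 0) (s + p_eff) / den else 0
        et_act <- lambda * et_act
        d <- lambda * d
      }
      s_new <- 0
    }
    r <- 0
    if (s_new > taw) {
      r <- s_new - taw
      s_new <- taw
    }
    s_out[t] <- s_new; et_act_v[t] <- et_act; d_v[t] <- d
    r_v[t] <- r; ks_v[t] <- ks
    s <- s_new
  }
  out <- data.frame(s = s_out, p_eff = p_eff_v,
                    surface_runoff = runoff_fraction * precip,
                    et_pot = et_pot_v, et_act = et_act_v, d = d_v, r = r_v,
                    ks = ks_v)
  attr(out, "s0") <- s0
  class(out) <- c("balance_trace", "data.frame")
  out
}

#' Disaggregate monthly reference evapotranspiration to daily values
#'
#' Spreads each month's total uniformly over its days, so monthly sums of
#' the output reproduce the input exactly (including leap Februaries).
#'
#' @param monthly_et0 numeric vector of monthly totals, mm/month, one per
#'   calendar month of `dates`, in order; >= 0.
#' @param dates contiguous daily `Date` vector covering whole months.
#' @return Daily ET0, mm/day, aligned with `dates`.
#' @examples
#' d <- seq(as.Date("2001-01-01"), as.Date("2001-01-31"), by = "day")
#' disaggregate_et0(31, d)  # 1 mm/day throughout January
#' @export
disaggregate_et0 <- function(monthly_et0, dates) {
  if (any(!is.finite(monthly_et0)) || any(monthly_et0 < 0))
    stop("monthly ET0 must be finite and >= 0")
  dates <- as.Date(dates)
  ym <- format(dates, "%Y-%m")
  months <- unique(ym)
  if (length(monthly_et0) != length(months))
    stop("need one monthly value per calendar month of the span (",
         length(months), " months, got ", length(monthly_et0), " values)")
  ndays <- tabulate(match(ym, months))
  rep(monthly_et0 / ndays, times = ndays)
}

#' Daily forcing for one cell
#'
#' @param dates contiguous daily `Date` vector.
#' @param precip daily precipitation, mm/day.
#' @param et0_daily daily reference evapotranspiration, mm/day.
#' @return An object of class `daily_forcing`.
#' @export
daily_forcing <- function(dates, precip, et0_daily) {
  dates <- as.Date(dates)
  if (length(precip) != length(dates) || length(et0_daily) != length(dates))
    stop("forcing series must match the date span")
  if (any(!is.finite(precip)) || any(precip < 0) ||
      any(!is.finite(et0_daily)) || any(et0_daily < 0))
    stop("forcing must be finite and >= 0")
  structure(list(dates = dates, precip = as.numeric(precip),
                 et0_daily = as.numeric(et0_daily)),
            class = "daily_forcing")
}

#' Engine configuration
#'
#' Run-level constants of the balance engine. Defaults are the model's
#' standard values: 5% of precipitation to surface runoff, off-season
#' kc of 0.5, initial moisture at 50% of total available water, and a
#' three-year spin-up over seeded randomly selected forcing years.
#'
#' @param off_season_kc kc outside the growing season.
#' @param surface_runoff_fraction share of precipitation lost to surface
#'   runoff.
#' @param initial_moisture_fraction spin-up start moisture as a fraction
#'   of `taw`, in \[0, 1\].
#' @param spin_up_years number of spin-up years simulated before the
#'   production period.
#' @param seed integer seed governing the spin-up year selection.
#' @return An object of class `engine_config`.
#' @export
engine_config <- function(off_season_kc = 0.5,
                          surface_runoff_fraction = 0.05,
                          initial_moisture_fraction = 0.5,
                          spin_up_years = 3L,
                          seed = 1L) {
  if (initial_moisture_fraction < 0 || initial_moisture_fraction > 1)
    stop("initial_moisture_fraction must lie in [0, 1]")
  if (spin_up_years < 0) stop("spin_up_years must be >= 0")
  structure(list(off_season_kc = off_season_kc,
                 surface_runoff_fraction = surface_runoff_fraction,
                 initial_moisture_fraction = initial_moisture_fraction,
                 spin_up_years = as.integer(spin_up_years),
                 seed = as.integer(seed)),
            class = "engine_config")
}

#' Select the spin-up climate years
#'
#' Draws the spin-up years (with replacement) from the available forcing
#' years using an isolated seeded generator, leaving the global RNG state
#' untouched. The draw is made once per run and reused for every crop,
#' regime and cell, so all simulations of a run share the same spin-up
#' climate.
#'
#' @param years integer vector of available forcing years.
#' @param n number of spin-up years.
#' @param seed integer seed.
#' @return Integer vector of `n` years (in draw order).
#' @export
select_spin_up_years <- function(years, n = 3L, seed = 1L) {
  if (length(years) < 1L) stop("no forcing years available for spin-up")
  if (n == 0L) return(integer(0))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  years[sample.int(length(years), n, replace = TRUE)]
}

#' Spin up the soil water store
#'
#' Starts the store at `initial_moisture_fraction * taw` and simulates the
#' configured spin-up years of forcing in order (stressed run, with the
#' crop's seasonal kc cycle in every year), returning the final-day state.
#' Production simulations start from this state, which erases most of the
#' sensitivity to the assumed initial moisture.
#'
#' @param forcing a [daily_forcing()] covering the spin-up years.
#' @param kc a `kc_series` over the same span, from [build_kc_curve()].
#' @param cap a [water_capacity()].
#' @param profile a [soil_profile()].
#' @param config an [engine_config()].
#' @return Final-day soil moisture, mm.
#' @export
spin_up <- function(forcing, kc, cap, profile, config = engine_config()) {
  if (length(forcing$dates) == 0L) stop("spin-up forcing is empty")
  if (!identical(as.integer(forcing$dates), as.integer(kc$dates)))
    stop("forcing and kc series must share the same date span")
  trace <- run_water_balance(forcing$precip, forcing$et0_daily, kc$values,
                             cap, profile,
                             s0 = config$initial_moisture_fraction * cap$taw,
                             stressed = TRUE,
                             runoff_fraction = config$surface_runoff_fraction)
  trace$s[nrow(trace)]
}
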