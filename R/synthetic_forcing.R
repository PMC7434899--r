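# Run expr with a private, seeded RNG stream, restoring the caller's
# RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic climate scenario
#'
#' Statistical description of a synthetic climate: daily precipitation is
#' an independent Bernoulli occurrence times a wet-day depth per cell and
#' day, and reference evapotranspiration follows a sinusoidal annual
#' cycle delivered as monthly totals,
#' `et0(doy) = mean + amplitude * cos(2 * pi * (doy - phase) / 365)`
#' (clamped at zero).
#'
#' @param wet_day_probability probability of a wet day, in \[0, 1\].
#' @param mean_wet_depth mean wet-day depth, mm.
#' @param et0_annual_mean annual-mean daily reference ET, mm/day.
#' @param et0_seasonal_amplitude amplitude of the annual ET0 cycle,
#'   mm/day.
#' @param phase day-of-year of the ET0 peak.
#' @param seed integer seed for the precipitation draws.
#' @param depth_model `"exponential"` (exponential wet-day depths with
#'   the given mean) or `"constant"` (every wet day delivers exactly
#'   `mean_wet_depth`, used by the humid preset to guarantee daily
#'   saturation).
#' @return An object of class `climate_scenario`.
#' @export
climate_scenario <- function(wet_day_probability, mean_wet_depth,
                             et0_annual_mean, et0_seasonal_amplitude,
                             phase = 196, seed = 1L,
                             depth_model = c("exponential", "constant")) {
  depth_model <- match.arg(depth_model)
  if (wet_day_probability < 0 || wet_day_probability > 1)
    stop("wet_day_probability must lie in [0, 1]")
  if (mean_wet_depth < 0 || et0_annual_mean < 0 ||
      et0_seasonal_amplitude < 0)
    stop("depths and ET0 parameters must be >= 0")
  structure(list(wet_day_probability = wet_day_probability,
                 mean_wet_depth = mean_wet_depth,
                 et0_annual_mean = et0_annual_mean,
                 et0_seasonal_amplitude = et0_seasonal_amplitude,
                 phase = phase, seed = as.integer(seed),
                 depth_model = depth_model),
            class = "climate_scenario")
}

#' Named climate presets
#'
#' Three analytic end-member climates used throughout the test suite:
#' * `"humid"` — rain every day with a constant depth large enough that
#'   effective precipitation exceeds crop demand plus the maximum
#'   infiltration rate, so the store never leaves saturation and blue
#'   water is identically zero;
#' * `"arid"` — no rain at all, so green water is zero when the store
#'   starts empty and blue water equals the full potential demand on
#'   irrigated land;
#' * `"seasonal"` — intermittent rain (30% wet days, 8 mm mean depth)
#'   against a marked annual ET0 cycle (3.5 +/- 2.5 mm/day peaking in
#'   July), producing realistic stress episodes.
#'
#' @param name one of `"humid"`, `"arid"`, `"seasonal"`.
#' @param seed integer seed stored in the scenario.
#' @return A [climate_scenario()].
#' @export
scenario_preset <- function(name = c("seasonal", "humid", "arid"),
                            seed = 42L) {
  name <- match.arg(name)
  switch(name,
    seasonal = climate_scenario(0.3, 8, 3.5, 2.5, phase = 196,
                                seed = seed),
    humid = climate_scenario(1, 120, 3, 1, phase = 196, seed = seed,
                             depth_model = "constant"),
    arid = climate_scenario(0, 0, 5.5, 1.5, phase = 196, seed = seed))
}

sinusoid_et0 <- function(doy, scenario) {
  pmax(scenario$et0_annual_mean +
         scenario$et0_seasonal_amplitude *
           cos(2 * pi * (doy - scenario$phase) / 365), 0)
}

#' Generate synthetic gridded climate forcing
#'
#' Draws daily precipitation per cell and day (Bernoulli occurrence times
#' the scenario's wet-day depth model) and builds monthly ET0 totals from
#' the scenario's sinusoidal daily cycle (identical across cells). The
#' result is reproducible from the scenario seed and independent of the
#' caller's RNG state.
#'
#' @param scenario a [climate_scenario()].
#' @param spec a [grid_spec()].
#' @param years integer vector of calendar years to generate.
#' @return A [gridded_forcing()].
#' @export
generate_climate <- function(scenario, spec, years) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  nd <- length(dates)
  ncell <- spec$n_rows * spec$n_cols
  precip <- with_seed(scenario$seed, {
    wet <- stats::runif(ncell * nd) < scenario$wet_day_probability
    depth <- if (scenario$depth_model == "constant")
      rep(scenario$mean_wet_depth, ncell * nd)
    else if (scenario$mean_wet_depth > 0)
      stats::rexp(ncell * nd, rate = 1 / scenario$mean_wet_depth)
    else rep(0, ncell * nd)
    array(wet * depth, c(spec$n_rows, spec$n_cols, nd))
  })
  doy <- as.integer(format(dates, "%j"))
  et0_day <- sinusoid_et0(doy, scenario)
  ym <- format(dates, "%Y-%m")
  months <- unique(ym)
  et0_month <- as.numeric(rowsum(et0_day, ym)[months, 1])
  et0_monthly <- array(rep(et0_month, each = ncell),
                       c(spec$n_rows, spec$n_cols, length(months)))
  gridded_forcing(spec, dates, precip, et0_monthly)
}

#' Generate a synthetic soil parameter grid
#'
#' Storage capacity is drawn uniformly in 100..250 mm/m and the maximum
#' infiltration rate uniformly in 5..50 mm/day, spanning the realistic
#' range from sandy to clayey soils.
#'
#' @param spec a [grid_spec()].
#' @param seed integer seed.
#' @return A [soil_grid()].
#' @export
generate_soil <- function(spec, seed = 1L) {
  ncell <- spec$n_rows * spec$n_cols
  with_seed(seed, soil_grid(
    spec,
    matrix(stats::runif(ncell, 100, 250), spec$n_rows, spec$n_cols),
    matrix(stats::runif(ncell, 5, 50), spec$n_rows, spec$n_cols)))
}

#' Generate synthetic regional crop calendars
#'
#' Splits the grid into four quadrant regions and builds calendars that
#' deliberately cover the structural cases the model must handle: region
#' 1 has a single growing period per crop and regime, region 2 a double
#' season for the first crop, region 3 three reported periods for the
#' first crop (exercising consolidation to two), and region 4 a season
#' that wraps the year boundary. Planting days and harvested areas are
#' jittered from the seed.
#'
#' @param spec a [grid_spec()].
#' @param crops character vector of crop ids.
#' @param seed integer seed.
#' @return List with `region_map` (integer matrix) and `calendars`
#'   (named list of [crop_calendar()], keys `"1"`..`"4"`).
#' @export
generate_calendar <- function(spec, crops, seed = 1L) {
  rows <- seq_len(spec$n_rows)
  cols <- seq_len(spec$n_cols)
  region_map <- outer(rows > spec$n_rows / 2, cols > spec$n_cols / 2,
                      function(a, b) 1L + a * 2L + b * 1L)
  storage.mode(region_map) <- "integer"
  with_seed(seed, {
    calendars <- lapply(1:4, function(reg) {
      rowsl <- list()
      for (ci in seq_along(crops)) for (rg in c("rainfed", "irrigated")) {
        base_plant <- 60 + round(stats::runif(1, 0, 60)) + 15 * (ci - 1)
        len <- 110 + round(stats::runif(1, 0, 40))
        area <- round(stats::runif(1, 10, 100), 1)
        entry <- function(p, h, a)
          data.frame(crop_id = crops[ci], regime = rg,
                     planting_doy = ((p - 1) %% 365) + 1,
                     harvest_doy = ((h - 1) %% 365) + 1,
                     harvested_area_km2 = a)
        e <- entry(base_plant, base_plant + len, area)
        if (reg == 2L && ci == 1L)
          e <- rbind(e, entry(base_plant + 180, base_plant + 180 + len,
                              area / 2))
        if (reg == 3L && ci == 1L)
          e <- rbind(e,
                     entry(base_plant + 130, base_plant + 130 + len,
                           area / 2),
                     entry(base_plant + 240, base_plant + 240 + 90,
                           area / 4))
        if (reg == 4L)
          e <- entry(300 + 5 * (ci - 1), 60 + 5 * (ci - 1), area)
        rowsl[[length(rowsl) + 1L]] <- e
      }
      crop_calendar(as.character(reg), do.call(rbind, rowsl))
    })
    names(calendars) <- as.character(1:4)
    list(region_map = region_map, calendars = calendars)
  })
}

#' Built-in crop parameter presets
#'
#' Three FAO-56-style parameter sets — a wheat-like winter cereal, a
#' maize-like summer cereal and a rice-like paddy crop — spanning the
#' relevant ranges of crop coefficients, stage fractions, rooting depths
#' and depletion factors.
#'
#' @return Named list of [crop_parameters()].
#' @export
preset_crops <- function() {
  list(
    wheat = crop_parameters("wheat", 0.3, 1.15, 0.3,
                            c(0.15, 0.25, 0.40, 0.20),
                            zr_rainfed = 1.5, zr_irrigated = 1.0,
                            p = 0.55),
    maize = crop_parameters("maize", 0.3, 1.20, 0.4,
                            c(0.17, 0.28, 0.33, 0.22),
                            zr_rainfed = 1.7, zr_irrigated = 1.0,
                            p = 0.55),
    rice = crop_parameters("rice", 1.05, 1.20, 0.75,
                           c(0.20, 0.20, 0.40, 0.20),
                           zr_rainfed = 0.8, zr_irrigated = 0.5,
                           p = 0.20))
}

#' Write a complete synthetic input bundle
#'
#' Generates climate, soil, calendars and crop parameters for a preset
#' and writes them, in the formats the grid engine reads, to a directory:
#' `precip.nc`, `et0.nc`, `soil.nc`, `regions.nc`, `calendar.csv`,
#' `crops.csv`. The climate uses `seed`, the soil `seed + 1` and the
#' calendars `seed + 2`, so one integer reproduces the whole bundle.
#'
#' @param out_dir output directory (created if needed).
#' @param preset climate preset name, see [scenario_preset()].
#' @param rows,cols grid dimensions (cell size fixed at 0.5 degrees for
#'   the synthetic grids).
#' @param years integer vector of calendar years of forcing.
#' @param seed integer master seed.
#' @return Invisibly, a list with the generated objects (`spec`,
#'   `forcing`, `soil`, `region_map`, `calendars`, `crops`) and `paths`.
#' @export
synth_bundle <- function(out_dir, preset = "seasonal", rows = 10L,
                         cols = 10L, years = 2001:2005, seed = 42L) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  spec <- grid_spec(rows, cols, 0.5)
  scenario <- scenario_preset(preset, seed = seed)
  forcing <- generate_climate(scenario, spec, years)
  soil <- generate_soil(spec, seed = seed + 1L)
  cal <- generate_calendar(spec, names(preset_crops()), seed = seed + 2L)
  crops <- preset_crops()
  paths <- list(precip = file.path(out_dir, "precip.nc"),
                et0 = file.path(out_dir, "et0.nc"),
                soil = file.path(out_dir, "soil.nc"),
                regions = file.path(out_dir, "regions.nc"),
                calendar = file.path(out_dir, "calendar.csv"),
                crops = file.path(out_dir, "crops.csv"))
  write_forcing(forcing, paths$precip, paths$et0)
  write_soil(soil, paths$soil)
  write_region_map(cal$region_map, spec, paths$regions)
  write_crop_calendar(cal$calendars, paths$calendar)
  write_crop_parameters(crops, paths$crops)
  invisible(list(spec = spec, scenario = scenario, forcing = forcing,
                 soil = soil, region_map = cal$region_map,
                 calendars = cal$calendars, crops = crops, paths = paths))
}

#' Read a synthetic input bundle
#'
#' Reads back a directory written by [synth_bundle()], inferring the grid
#' specification from the precipitation file's coordinates.
#'
#' @param dir bundle directory.
#' @return List with `spec`, `forcing`, `soil`, `region_map`,
#'   `calendars`, `crops`.
#' @export
read_bundle <- function(dir) {
  pp <- file.path(dir, "precip.nc")
  nc <- ncdf4::nc_open(pp)
  lon <- nc$dim$lon$vals
  lat <- nc$dim$lat$vals
  ncdf4::nc_close(nc)
  cell <- if (length(lon) > 1) lon[2] - lon[1] else 2 * (lon[1] + 180)
  spec <- grid_spec(length(lat), length(lon), cell,
                    origin_lon = lon[1] - cell / 2,
                    origin_lat = lat[1] + cell / 2)
  list(spec = spec,
       forcing = read_forcing(pp, file.path(dir, "et0.nc"), spec),
       soil = read_soil(file.path(dir, "soil.nc"), spec),
       region_map = read_region_map(file.path(dir, "regions.nc"), spec),
       calendars = read_crop_calendar(file.path(dir, "calendar.csv")),
       crops = read_crop_parameters(file.path(dir, "crops.csv")))
}
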