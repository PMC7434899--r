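# Shared fixtures and independent oracles for the suite. Everything is
# generated in code; expensive objects are built once and cached for the
# whole run.

test_params <- function(p = 0.5, kc = c(0.3, 1.2, 0.5),
                        fractions = rep(0.25, 4), zr = 1.0) {
  crop_parameters("testcrop", kc[1], kc[2], kc[3], fractions,
                  zr_rainfed = zr, zr_irrigated = zr, p = p)
}

test_profile <- function(theta_diff = 200, f_max = 10)
  soil_profile(theta_diff, f_max)

# Literal transcription of the daily balance: stress coefficient and
# percolation evaluated on the previous day's store, proportional closure
# when the balance sum goes negative, saturation excess to sub-surface
# runoff. Kept as a separate, naive code path to pin the engine against.
oracle_step_day <- function(s_prev, precip, et0, kc, taw, raw, f_max,
                            stressed = TRUE, rf = 0.05) {
  P_eff <- (1 - rf) * precip
  ET_pot <- kc * et0
  ks <- if (!stressed) 1 else if (s_prev < raw) s_prev / raw else 1
  ETa <- ks * ET_pot
  D <- if (raw <= s_prev && s_prev <= taw)
    f_max * (s_prev - raw) / (taw - raw) else 0
  bal <- s_prev + P_eff - ETa - D
  if (bal < 0) {
    if (stressed) {
      lambda <- if (ETa + D > 0) (s_prev + P_eff) / (ETa + D) else 0
      ETa <- lambda * ETa
      D <- lambda * D
    }
    bal <- 0
  }
  R <- 0
  if (bal > taw) {
    R <- bal - taw
    bal <- taw
  }
  list(s = bal, p_eff = P_eff, et_pot = ET_pot, et_act = ETa, d = D,
       r = R, ks = ks)
}

oracle_run <- function(precip, et0, kc, taw, raw, f_max, s0,
                       stressed = TRUE, rf = 0.05) {
  n <- length(precip)
  out <- data.frame(s = numeric(n), p_eff = numeric(n),
                    et_pot = numeric(n), et_act = numeric(n),
                    d = numeric(n), r = numeric(n), ks = numeric(n))
  s <- s0
  for (t in seq_len(n)) {
    st <- oracle_step_day(s, precip[t], et0[t], kc[t], taw, raw, f_max,
                          stressed, rf)
    out[t, ] <- c(st$s, st$p_eff, st$et_pot, st$et_act, st$d, st$r, st$ks)
    s <- st$s
  }
  out
}

# Brute-force transcription of the stated season-consolidation rule.
oracle_consolidate <- function(seasons) {
  if (length(seasons) <= 2) return(seasons)
  area <- sapply(seasons, `[[`, "harvested_area")
  plant <- sapply(seasons, `[[`, "planting_doy")
  harv <- sapply(seasons, `[[`, "harvest_doy")
  ord <- order(-area, plant, harv)
  keep <- sort(ord[1:2])
  out <- seasons[keep]
  for (i in setdiff(seq_along(seasons), keep)) {
    d <- abs(plant[keep] - plant[i])
    d <- pmin(d, 365 - d)
    j <- which.min(d)
    out[[j]]$harvested_area <- out[[j]]$harvested_area + area[i]
  }
  out
}

# One shared seasonal grid scenario (10x10, 3 crops, 5 forcing years),
# plus its grid-run result, cached for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

seasonal_inputs <- function() {
  if (is.null(.fixture_cache$inputs)) {
    spec <- grid_spec(10, 10, 0.5)
    scenario <- scenario_preset("seasonal", seed = 42)
    .fixture_cache$inputs <- list(
      spec = spec,
      forcing = generate_climate(scenario, spec, 2001:2005),
      soil = generate_soil(spec, seed = 43),
      cal = generate_calendar(spec, names(preset_crops()), seed = 44),
      crops = preset_crops())
  }
  .fixture_cache$inputs
}

seasonal_run <- function() {
  if (is.null(.fixture_cache$run)) {
    x <- seasonal_inputs()
    .fixture_cache$run <- run_grid(
      x$forcing, x$soil, x$cal$region_map, x$cal$calendars, x$crops,
      years = 2004, config = engine_config(seed = 1))
  }
  .fixture_cache$run
}

# Point forcing for one cell of a gridded forcing object.
point_forcing <- function(forcing, r, c) {
  daily_forcing(forcing$dates, forcing$precip[r, c, ],
                disaggregate_et0(forcing$et0_monthly[r, c, ],
                                 forcing$dates))
}
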