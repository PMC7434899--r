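test_that("water capacity follows taw = theta_diff * zr, raw = p * taw", {
  p <- test_params(p = 0.5, zr = 1.0)
  cap <- water_capacity(p, test_profile(200), "rainfed")
  expect_equal(cap$taw, 200)
  expect_equal(cap$raw, 100)
  p2 <- test_params(p = 0.55)
  p2$zr_rainfed <- 0.6
  cap2 <- water_capacity(p2, test_profile(150), "rainfed")
  expect_equal(cap2$taw, 90)
  expect_equal(cap2$raw, 49.5)
  # regime selects the rooting depth
  p3 <- test_params()
  p3$zr_irrigated <- 0.5
  expect_equal(water_capacity(p3, test_profile(200), "irrigated")$taw, 100)
  # p = 1 would make raw = taw, which the parameter validator forbids
  expect_error(test_params(p = 1), "p must")
})

test_that("effective precipitation routes a fixed 5% to surface runoff", {
  expect_equal(effective_precipitation(10), list(p_eff = 9.5,
                                                 surface_runoff = 0.5))
  expect_equal(effective_precipitation(0)$p_eff, 0)
  expect_equal(effective_precipitation(100),
               list(p_eff = 95, surface_runoff = 5))
  expect_error(effective_precipitation(-1), ">= 0")
})

test_that("stress coefficient is piecewise linear in soil moisture", {
  cap <- water_capacity(test_params(p = 0.5), test_profile(200), "rainfed")
  expect_equal(stress_coefficient(cap$raw, cap), 1)
  expect_equal(stress_coefficient(cap$taw, cap), 1)
  expect_equal(stress_coefficient(0, cap), 0)
  expect_equal(stress_coefficient(0.5 * cap$raw, cap), 0.5)
  expect_error(stress_coefficient(-1, cap), ">= 0")
})

test_that("deep percolation ramps linearly from raw to taw", {
  cap <- water_capacity(test_params(p = 0.5), test_profile(200, 10),
                        "rainfed")
  prof <- test_profile(200, 10)
  expect_equal(deep_percolation(cap$taw, cap, prof), 10)
  expect_equal(deep_percolation(cap$raw, cap, prof), 0)
  expect_equal(deep_percolation((cap$raw + cap$taw) / 2, cap, prof), 5)
  expect_equal(deep_percolation(0.5 * cap$raw, cap, prof), 0)
})

test_that("a daily step handles drainage, dry soil and closure", {
  p <- test_params(p = 0.5)
  prof <- test_profile(200, 10)
  cap <- water_capacity(p, prof, "rainfed")
  # saturated store with no rain and no demand: percolation only
  st <- step_day(cap$taw, 0, 0, 1.0, cap, prof)
  expect_equal(st$s, cap$taw - prof$f_max)
  expect_equal(st$fluxes$d, prof$f_max)
  expect_equal(st$fluxes$et_act, 0)
  expect_equal(st$fluxes$r, 0)
  # empty store: ks(0) = 0 shuts evapotranspiration off entirely
  st2 <- step_day(0, 0, 5, 1.0, cap, prof, stressed = TRUE)
  expect_equal(st2$s, 0)
  expect_equal(st2$fluxes$et_act, 0)
  expect_equal(st2$fluxes$ks, 0)
  # proportional closure: demand above storage scales ETa and D jointly,
  # preserving their ratio; checked against the closed-form factor
  s0 <- 120  # above raw, so both ETa and D are active
  precip <- 1
  et0 <- 100; kc <- 1.5
  st3 <- step_day(s0, precip, et0, kc, cap, prof, stressed = TRUE)
  p_eff <- 0.95 * precip
  ks <- if (s0 < cap$raw) s0 / cap$raw else 1
  eta0 <- ks * kc * et0
  d0 <- prof$f_max * (s0 - cap$raw) / (cap$taw - cap$raw)
  expect_true(s0 + p_eff - eta0 - d0 < 0)  # closure branch is exercised
  lambda <- (s0 + p_eff) / (eta0 + d0)
  expect_equal(st3$fluxes$et_act, lambda * eta0)
  expect_equal(st3$fluxes$d, lambda * d0)
  expect_equal(st3$fluxes$et_act / st3$fluxes$d, eta0 / d0)
  expect_equal(st3$s, 0)
  # dry store below raw: percolation is zero and ETa alone is scaled to
  # exactly exhaust storage plus the day's effective rain
  s4 <- 0.2 * cap$raw
  st4 <- step_day(s4, 1, 200, 1.5, cap, prof, stressed = TRUE)
  expect_equal(st4$s, 0)
  expect_equal(st4$fluxes$d, 0)
  expect_equal(st4$fluxes$et_act, s4 + 0.95)
  expect_error(step_day(100, NaN, 1, 1, cap, prof), "finite")
})

test_that("monthly ET0 disaggregation is uniform and conservative", {
  jan <- seq(as.Date("2001-01-01"), as.Date("2001-01-31"), by = "day")
  expect_equal(disaggregate_et0(31, jan), rep(1, 31))
  yr <- seq(as.Date("2004-01-01"), as.Date("2004-12-31"), by = "day")
  expect_equal(disaggregate_et0(rep(0, 12), yr), rep(0, 366))
  set.seed(11)
  m <- runif(12, 0, 150)
  daily <- disaggregate_et0(m, yr)
  sums <- as.numeric(rowsum(daily, format(yr, "%m")))
  expect_equal(sums, m, tolerance = 1e-12)
  expect_equal(sum(format(yr, "%m") == "02"), 29)  # leap February used
  expect_error(disaggregate_et0(-1, jan), ">= 0")
  expect_error(disaggregate_et0(c(1, 2), jan), "per calendar month")
})

test_that("balance closes exactly and the store stays in [0, taw]", {
  set.seed(101)
  for (i in 1:100) {
    p <- test_params(p = runif(1, 0.2, 0.8),
                     kc = sort(runif(3, 0.2, 1.3))[c(1, 3, 2)],
                     zr = runif(1, 0.4, 1.8))
    prof <- test_profile(runif(1, 100, 250), runif(1, 0, 50))
    cap <- water_capacity(p, prof, "rainfed")
    n <- 730
    precip <- rbinom(n, 1, runif(1, 0.05, 0.6)) *
      rexp(n, 1 / runif(1, 2, 20))
    et0 <- pmax(3.5 + 2.5 * cos(2 * pi * ((1:n) - 196) / 365) +
                  rnorm(n, 0, 0.3), 0)
    kc <- runif(n, 0.3, 1.3)
    s0 <- runif(1, 0, cap$taw)
    tr <- run_water_balance(precip, et0, kc, cap, prof, s0)
    s_prev <- c(s0, tr$s[-n])
    residual <- tr$s - s_prev - (tr$p_eff - tr$et_act - tr$d - tr$r)
    expect_true(all(abs(residual) < 1e-9))
    expect_true(all(tr$s >= 0 & tr$s <= cap$taw))
    expect_true(all(tr$ks >= 0 & tr$ks <= 1))
    expect_true(all(tr$et_act <= tr$et_pot + 1e-12))
    expect_true(all(tr$d >= 0 & tr$r >= 0))
    expect_true(all(abs(tr$surface_runoff - (precip - tr$p_eff)) < 1e-12))
  }
})

test_that("engine trace matches the literal-transcription oracle", {
  set.seed(202)
  for (i in 1:100) {
    p <- test_params(p = runif(1, 0.2, 0.8), zr = runif(1, 0.5, 1.5))
    prof <- test_profile(runif(1, 100, 250), runif(1, 0, 50))
    cap <- water_capacity(p, prof, "rainfed")
    n <- 730
    precip <- rbinom(n, 1, 0.3) * rexp(n, 1 / 8)
    et0 <- pmax(3.5 + 2.5 * cos(2 * pi * ((1:n) - 196) / 365), 0)
    kc <- runif(n, 0.3, 1.3)
    s0 <- runif(1, 0, cap$taw)
    stressed <- i %% 2 == 0
    tr <- run_water_balance(precip, et0, kc, cap, prof, s0,
                            stressed = stressed)
    want <- oracle_run(precip, et0, kc, cap$taw, cap$raw, prof$f_max,
                       s0, stressed = stressed)
    expect_identical(tr$s, want$s)
    expect_identical(tr$et_act, want$et_act)
    expect_identical(tr$d, want$d)
    expect_identical(tr$r, want$r)
    expect_identical(tr$ks, want$ks)
  }
})

test_that("more rain never reduces seasonal evapotranspiration", {
  set.seed(303)
  p <- test_params(p = 0.5)
  prof <- test_profile(180, 15)
  cap <- water_capacity(p, prof, "rainfed")
  n <- 365
  precip <- rbinom(n, 1, 0.25) * rexp(n, 1 / 6)
  et0 <- pmax(4 + 2 * cos(2 * pi * ((1:n) - 196) / 365), 0)
  kc <- rep(1, n)
  base <- sum(run_water_balance(precip, et0, kc, cap, prof,
                                0.5 * cap$taw)$et_act)
  for (day in c(30, 120, 200, 320)) {
    bumped <- precip
    bumped[day] <- bumped[day] + 20
    tot <- sum(run_water_balance(bumped, et0, kc, cap, prof,
                                 0.5 * cap$taw)$et_act)
    expect_gte(tot, base - 1e-9)
  }
})

test_that("unstressed run evapotranspires at the potential rate", {
  p <- test_params()
  prof <- test_profile(150, 20)
  cap <- water_capacity(p, prof, "rainfed")
  n <- 400
  set.seed(5)
  precip <- rbinom(n, 1, 0.1) * rexp(n, 1 / 4)
  et0 <- rep(5, n)
  kc <- runif(n, 0.3, 1.3)
  tr <- run_water_balance(precip, et0, kc, cap, prof, s0 = 0,
                          stressed = FALSE)
  expect_equal(tr$et_act, tr$et_pot)
  expect_true(all(tr$ks == 1))
})

test_that("spin-up hits the analytic end-members and is seed-stable", {
  p <- test_params(p = 0.6)  # raw > 0.5 taw: no drainage from the start
  prof <- test_profile(200, 10)
  cap <- water_capacity(p, prof, "rainfed")
  span <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  kc <- build_kc_curve(p, growing_season(100, 250), 0.5, span)
  # no rain, positive demand: the store depletes monotonically towards
  # zero (geometrically, once below raw), ending at a negligible level
  dry <- daily_forcing(span, rep(0, length(span)), rep(4, length(span)))
  expect_lt(spin_up(dry, kc, cap, prof), 1e-4)
  # saturating rain: the store ends full
  wet <- daily_forcing(span, rep(100, length(span)), rep(4, length(span)))
  expect_equal(spin_up(wet, kc, cap, prof), cap$taw)
  # identical seeds give identical year selections; different seeds vary
  y <- 1998:2005
  expect_identical(select_spin_up_years(y, 3, 7),
                   select_spin_up_years(y, 3, 7))
  draws <- vapply(1:20, function(s)
    paste(select_spin_up_years(y, 3, s), collapse = "-"), "")
  expect_gt(length(unique(draws)), 1)
  # the draw leaves the caller's RNG stream untouched
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(select_spin_up_years(y, 3, 1))
  expect_identical(runif(1), a)
})

test_that("two spin-ups from opposite initial stores converge", {
  x <- seasonal_inputs()
  fp <- point_forcing(x$forcing, 3, 3)
  p <- x$crops$wheat
  prof <- soil_profile(x$soil$theta_diff[3, 3], x$soil$f_max[3, 3])
  cap <- water_capacity(p, prof, "rainfed")
  kc <- build_kc_curve(p, growing_season(100, 250), 0.5, fp$dates)
  ends <- vapply(c(0, 1), function(f) {
    cfg <- engine_config(initial_moisture_fraction = f)
    spin_up(fp, kc, cap, prof, cfg)
  }, numeric(1))
  expect_lt(abs(diff(ends)), 0.01 * cap$taw)
})
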