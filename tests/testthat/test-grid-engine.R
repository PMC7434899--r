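make_uniform_inputs <- function(nr, nc, years = 2001:2002) {
  spec <- grid_spec(nr, nc, 0.5)
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  set.seed(77)
  pr1 <- rbinom(length(dates), 1, 0.3) * rexp(length(dates), 1 / 8)
  et0d <- pmax(3.5 + 2.5 * cos(2 * pi *
                 (as.integer(format(dates, "%j")) - 196) / 365), 0)
  ym <- format(dates, "%Y-%m")
  et0m <- as.numeric(rowsum(et0d, ym)[unique(ym), 1])
  precip <- array(rep(pr1, each = nr * nc),
                  c(nr, nc, length(dates)))
  et0 <- array(rep(et0m, each = nr * nc), c(nr, nc, length(et0m)))
  forcing <- gridded_forcing(spec, dates, precip, et0)
  soil <- soil_grid(spec, matrix(180, nr, nc), matrix(15, nr, nc))
  region_map <- matrix(1L, nr, nc)
  cal <- crop_calendar("1", data.frame(
    crop_id = "wheat", regime = c("rainfed", "irrigated"),
    planting_doy = 100, harvest_doy = 240, harvested_area_km2 = 10))
  list(spec = spec, forcing = forcing, soil = soil,
       region_map = region_map, calendars = list("1" = cal),
       crops = preset_crops()["wheat"])
}

test_that("a 1x1 grid reduces to the point pipeline", {
  x <- make_uniform_inputs(1, 1)
  cfg <- engine_config(seed = 4)
  res <- run_grid(x$forcing, x$soil, x$region_map, x$calendars, x$crops,
                  years = 2002, config = cfg)
  fp <- point_forcing(x$forcing, 1, 1)
  want <- simulate_cwr(fp, x$crops$wheat, growing_season(100, 240, 10),
                       soil_profile(180, 15), "rainfed", cfg,
                       production_years = 2002,
                       spin_years = res$spin_years)
  expect_identical(res$fields$wheat$rainfed$annual_gw[1, 1],
                   sum(want$monthly$gw))
  expect_identical(as.numeric(res$fields$wheat$rainfed$monthly_gw[1, 1, ]),
                   want$monthly$gw)
})

test_that("uniform inputs give identical cells (translation invariance)", {
  x <- make_uniform_inputs(5, 5)
  res <- run_grid(x$forcing, x$soil, x$region_map, x$calendars, x$crops,
                  years = 2002, config = engine_config(seed = 4))
  for (rg in c("rainfed", "irrigated")) {
    gw <- res$fields$wheat[[rg]]$annual_gw
    expect_equal(max(gw) - min(gw), 0)
    bw <- res$fields$wheat[[rg]]$annual_bw
    expect_equal(max(bw) - min(bw), 0)
  }
})

test_that("grid run equals an independent per-cell loop of the point engine", {
  x <- seasonal_inputs()
  cfg <- engine_config(seed = 1)
  res <- seasonal_run()
  # independent loop over a sample of cells, crops and regimes
  cells <- list(c(1, 1), c(1, 10), c(6, 2), c(10, 10), c(3, 8))
  for (cell in cells) {
    r <- cell[1]; cc <- cell[2]
    cal <- x$cal$calendars[[as.character(x$cal$region_map[r, cc])]]
    fp <- point_forcing(x$forcing, r, cc)
    prof <- soil_profile(x$soil$theta_diff[r, cc], x$soil$f_max[r, cc])
    for (cr in names(x$crops)) for (rg in c("rainfed", "irrigated")) {
      seasons <- calendar_seasons(cal, cr, rg)
      if (length(seasons) == 0) next
      want <- simulate_cwr(fp, x$crops[[cr]], seasons, prof, rg, cfg,
                           production_years = 2004,
                           spin_years = res$spin_years)
      expect_identical(res$fields[[cr]][[rg]]$annual_gw[r, cc],
                       sum(want$monthly$gw))
      expect_identical(res$fields[[cr]][[rg]]$annual_bw[r, cc],
                       sum(want$monthly$bw))
      expect_identical(as.numeric(res$fields[[cr]][[rg]]$monthly_gw[r, cc, ]),
                       want$monthly$gw)
    }
  }
})

test_that("cells without a calendar entry stay masked", {
  x <- make_uniform_inputs(3, 3)
  rm2 <- x$region_map
  rm2[1, ] <- NA
  res <- run_grid(x$forcing, x$soil, rm2, x$calendars, x$crops,
                  years = 2002, config = engine_config(seed = 4))
  expect_true(all(is.na(res$fields$wheat$rainfed$annual_gw[1, ])))
  expect_true(all(!is.na(res$fields$wheat$rainfed$annual_gw[2:3, ])))
})

test_that("grid mismatches and missing crops are rejected by name", {
  x <- make_uniform_inputs(3, 3)
  bad_soil <- soil_grid(grid_spec(4, 3, 0.5), matrix(180, 4, 3),
                        matrix(15, 4, 3))
  expect_error(run_grid(x$forcing, bad_soil, x$region_map, x$calendars,
                        x$crops), "soil grid")
  expect_error(run_grid(x$forcing, x$soil, matrix(1L, 2, 2), x$calendars,
                        x$crops), "region map")
  expect_error(run_grid(x$forcing, x$soil, x$region_map, x$calendars,
                        x$crops, crops = c("wheat", "yam")), "yam")
})

test_that("forcing, soil and region layers round-trip through NetCDF", {
  x <- seasonal_inputs()
  dir <- withr::local_tempdir()
  write_forcing(x$forcing, file.path(dir, "p.nc"), file.path(dir, "e.nc"))
  back <- read_forcing(file.path(dir, "p.nc"), file.path(dir, "e.nc"),
                       x$spec)
  expect_equal(back$dates, x$forcing$dates)
  expect_equal(back$precip, x$forcing$precip)
  expect_equal(back$et0_monthly, x$forcing$et0_monthly)
  write_soil(x$soil, file.path(dir, "s.nc"))
  soil2 <- read_soil(file.path(dir, "s.nc"), x$spec)
  expect_equal(soil2$theta_diff, x$soil$theta_diff)
  expect_equal(soil2$f_max, x$soil$f_max)
  rm0 <- x$cal$region_map
  rm0[1, 1] <- NA
  write_region_map(rm0, x$spec, file.path(dir, "r.nc"))
  rm2 <- read_region_map(file.path(dir, "r.nc"), x$spec)
  expect_equal(rm2, rm0)
  # shape mismatch reports both shapes
  expect_error(read_soil(file.path(dir, "s.nc"), grid_spec(4, 4, 0.5)),
               "10 x 10.*expected 4 x 4")
  # unrecognised units are accepted with a warning, not an error
  nc <- ncdf4::nc_open(file.path(dir, "p.nc"), write = TRUE)
  ncdf4::ncatt_put(nc, "pr", "units", "furlongs/fortnight")
  ncdf4::nc_close(nc)
  expect_warning(
    back2 <- read_forcing(file.path(dir, "p.nc"), file.path(dir, "e.nc"),
                          x$spec),
    "furlongs")
  expect_equal(back2$precip, x$forcing$precip)
})

test_that("the full synthetic bundle round-trips through its files", {
  dir <- withr::local_tempdir()
  b <- synth_bundle(dir, preset = "seasonal", rows = 4, cols = 4,
                    years = 2001:2002, seed = 11)
  back <- read_bundle(dir)
  expect_equal(back$spec$n_rows, 4L)
  expect_equal(back$forcing$precip, b$forcing$precip)
  expect_equal(back$soil$theta_diff, b$soil$theta_diff)
  expect_equal(back$region_map, b$region_map)
  expect_equal(back$crops, b$crops)
})

test_that("annual product files follow the published layout", {
  res <- seasonal_run()
  dir <- withr::local_tempdir()
  files <- write_annual_outputs(res, dir, 2004)
  expect_setequal(basename(files),
                  c("BW_irrig_2004.nc", "GW_irrig_2004.nc",
                    "GW_rainf_2004.nc"))
  out <- read_cwr_output(file.path(dir, "GW_irrig_2004.nc"))
  expect_equal(dim(out$values), c(10, 10, 26))
  expect_equal(out$dim3_name, "crop")
  expect_equal(out$dim3, 1:26)
  expect_equal(out$units, "mm")
  # values land on the slice of their crop code and round-trip
  # (float storage in the file)
  for (cr in res$crops) {
    k <- crop_code(cr)
    expect_equal(out$values[, , k],
                 res$fields[[cr]]$irrigated$annual_gw,
                 tolerance = 1e-6)
  }
  # crops absent from the run are all-fill slices
  absent <- setdiff(1:26, crop_code(res$crops))
  expect_true(all(is.na(out$values[, , absent])))
})

test_that("monthly product files carry a 12-month dimension", {
  res <- seasonal_run()
  dir <- withr::local_tempdir()
  files <- write_monthly_outputs(res, dir, 2004, crops = "rice")
  expect_setequal(basename(files),
                  c("BW_rice_irr_2004.nc", "GW_rice_irr_2004.nc",
                    "GW_rice_rfc_2004.nc"))
  out <- read_cwr_output(file.path(dir, "BW_rice_irr_2004.nc"))
  expect_equal(dim(out$values)[3], 12)
  expect_equal(out$dim3_name, "month")
  expect_equal(out$values, res$fields$rice$irrigated$monthly_bw,
               tolerance = 1e-6)
  # masked cells never carry finite values
  expect_true(all(is.na(out$values[is.na(res$fields$rice$irrigated$monthly_bw)])))
})

test_that("nearest-neighbour regridding matches a brute-force lookup", {
  src_spec <- grid_spec(8, 8, 0.5, origin_lon = 0, origin_lat = 50)
  set.seed(31)
  v <- matrix(runif(64), 8, 8)
  mask <- matrix(runif(64) > 0.2, 8, 8)
  f <- gridded_field(src_spec, v, mask)
  # identity
  expect_equal(regrid_nearest(f, src_spec), f)
  # constant field stays constant under refinement
  fc <- gridded_field(src_spec, matrix(3.14, 8, 8))
  tgt <- grid_spec(24, 24, 0.5 / 3, origin_lon = 0, origin_lat = 50)
  expect_true(all(regrid_nearest(fc, tgt)$values == 3.14))
  # checkerboard downsample equals per-cell nearest lookup
  tgt2 <- grid_spec(4, 4, 1, origin_lon = 0, origin_lat = 50)
  got <- regrid_nearest(f, tgt2)
  for (i in 1:4) for (j in 1:4) {
    lon <- 0 + (j - 0.5) * 1
    lat <- 50 - (i - 0.5) * 1
    dlon <- abs(grid_lon(src_spec) - lon)
    dlat <- abs(grid_lat(src_spec) - lat)
    jj <- which.min(dlon)
    ii <- which.min(dlat)
    expect_identical(got$mask[i, j], f$mask[ii, jj])
    if (f$mask[ii, jj])
      expect_identical(got$values[i, j], f$values[ii, jj])
    else expect_true(is.na(got$values[i, j]))
  }
  # disjoint extents are rejected
  far <- grid_spec(4, 4, 0.5, origin_lon = 100, origin_lat = -40)
  expect_error(regrid_nearest(f, far), "overlap")
})

test_that("masked cells carry the fill value, never zero", {
  spec <- grid_spec(3, 3, 1)
  v <- matrix(1:9, 3, 3) * 1.0
  m <- matrix(TRUE, 3, 3)
  m[2, 2] <- FALSE
  f <- gridded_field(spec, v, m)
  expect_true(is.na(f$values[2, 2]))
  expect_equal(sum(!is.na(f$values)), 8)
})
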