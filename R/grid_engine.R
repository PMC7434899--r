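#' Grid specification
#'
#' Regular WGS84 latitude-longitude grid. Row 1 is the northernmost row;
#' columns run west to east; coordinates refer to cell centres. The
#' published global product uses 2160 rows by 4320 columns at 5 arcmin
#' (0.083333 degrees), see [grid_spec_global()].
#'
#' @param n_rows,n_cols grid dimensions.
#' @param cell_size cell size in degrees.
#' @param origin_lon,origin_lat longitude/latitude of the north-west grid
#'   corner (not the first cell centre).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size,
                      origin_lon = -180, origin_lat = 90) {
  if (n_rows < 1 || n_cols < 1) stop("grid dimensions must be >= 1")
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (n_rows * cell_size > 180 + 1e-9 || n_cols * cell_size > 360 + 1e-9)
    stop("grid exceeds the globe: check n_rows/n_cols * cell_size")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 cell_size = as.numeric(cell_size),
                 origin_lon = as.numeric(origin_lon),
                 origin_lat = as.numeric(origin_lat),
                 crs = "WGS84 (EPSG:4326)"),
            class = "grid_spec")
}

#' The global 5-arcminute grid of the published product
#'
#' @return A [grid_spec()] with 2160 rows, 4320 columns and 1/12 degree
#'   cells covering 180W..180E, 90S..90N.
#' @export
grid_spec_global <- function() grid_spec(2160L, 4320L, 1 / 12)

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d at %.6f deg, origin (%g, %g), %s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat,
              x$crs))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param spec a [grid_spec()].
#' @return For `grid_lon` the column-centre longitudes (west to east);
#'   for `grid_lat` the row-centre latitudes (north to south).
#' @export
grid_lon <- function(spec)
  spec$origin_lon + (seq_len(spec$n_cols) - 0.5) * spec$cell_size

#' @rdname grid_lon
#' @export
grid_lat <- function(spec)
  spec$origin_lat - (seq_len(spec$n_rows) - 0.5) * spec$cell_size

same_spec <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_rows", "n_cols", "cell_size",
                                "origin_lon", "origin_lat")],
                   unclass(b)[c("n_rows", "n_cols", "cell_size",
                                "origin_lon", "origin_lat")],
                   tolerance = 1e-9))
}

#' Gridded field
#'
#' A 2-D field on a [grid_spec()] with an explicit cropland mask.
#' Masked-out cells are set to `NA` (written to NetCDF as the fill
#' value), never to 0.
#'
#' @param spec a [grid_spec()].
#' @param values numeric matrix `n_rows x n_cols`.
#' @param mask logical matrix of the same shape; `FALSE` marks no-data
#'   cells. Defaults to the non-`NA` cells of `values`.
#' @return An object of class `gridded_field`.
#' @export
gridded_field <- function(spec, values, mask = NULL) {
  values <- as.matrix(values)
  if (!identical(dim(values), c(spec$n_rows, spec$n_cols)))
    stop("values shape ", paste(dim(values), collapse = "x"),
         " does not match grid ", spec$n_rows, "x", spec$n_cols)
  if (is.null(mask)) mask <- !is.na(values)
  if (!identical(dim(mask), dim(values)))
    stop("mask shape must match values")
  values[!mask] <- NA_real_
  structure(list(spec = spec, values = values, mask = mask),
            class = "gridded_field")
}

#' Nearest-neighbour regridding
#'
#' Resamples a field onto a target grid by nearest cell centre; the mask
#' is resampled identically. Both grids must be WGS84 and overlap.
#'
#' @param field a [gridded_field()].
#' @param target_spec a [grid_spec()].
#' @return A `gridded_field` on `target_spec`.
#' @export
regrid_nearest <- function(field, target_spec) {
  src <- field$spec
  if (same_spec(src, target_spec)) return(field)
  lon_t <- grid_lon(target_spec); lat_t <- grid_lat(target_spec)
  lon_s <- grid_lon(src); lat_s <- grid_lat(src)
  if (max(lon_t) < min(lon_s) - src$cell_size / 2 ||
      min(lon_t) > max(lon_s) + src$cell_size / 2 ||
      max(lat_t) < min(lat_s) - src$cell_size / 2 ||
      min(lat_t) > max(lat_s) + src$cell_size / 2)
    stop("source and target grids do not overlap")
  col <- pmin(pmax(round((lon_t - lon_s[1]) / src$cell_size) + 1, 1),
              src$n_cols)
  row <- pmin(pmax(round((lat_s[1] - lat_t) / src$cell_size) + 1, 1),
              src$n_rows)
  gridded_field(target_spec,
                field$values[row, col, drop = FALSE],
                field$mask[row, col, drop = FALSE])
}

# ---- NetCDF input layers -------------------------------------------------

nc_lonlat_dims <- function(spec) {
  list(ncdf4::ncdim_def("lon", "degrees_east", grid_lon(spec)),
       ncdf4::ncdim_def("lat", "degrees_north", grid_lat(spec)))
}

# values[r, c] with row 1 north  <->  nc array [lon, lat]
to_nc <- function(m) t(m)
from_nc <- function(a) t(a)

check_nc_shape <- function(nc, var, spec, path) {
  dims <- sapply(nc$var[[var]]$dim, function(d) d$len)
  if (dims[1] != spec$n_cols || dims[2] != spec$n_rows)
    stop(sprintf(
      "layer '%s' in %s has shape %d x %d (lon x lat); expected %d x %d",
      var, path, dims[1], dims[2], spec$n_cols, spec$n_rows))
}

check_units <- function(nc, var, expected, path) {
  u <- try(ncdf4::ncatt_get(nc, var, "units"), silent = TRUE)
  if (inherits(u, "try-error") || !isTRUE(u$hasatt)) return(invisible())
  if (!u$value %in% expected)
    warning(sprintf("layer '%s' in %s has units '%s'; expected one of %s",
                    var, path, u$value, paste(expected, collapse = ", ")))
}

#' Gridded daily forcing
#'
#' Container for the model's climate inputs on a grid: daily
#' precipitation and monthly reference evapotranspiration (disaggregated
#' to daily values per cell at simulation time).
#'
#' @param spec a [grid_spec()].
#' @param dates contiguous daily `Date` vector.
#' @param precip array `n_rows x n_cols x n_days`, mm/day.
#' @param et0_monthly array `n_rows x n_cols x n_months`, mm/month, one
#'   slice per calendar month of `dates`.
#' @return An object of class `gridded_forcing`.
#' @export
gridded_forcing <- function(spec, dates, precip, et0_monthly) {
  dates <- as.Date(dates)
  months <- unique(format(dates, "%Y-%m"))
  if (!identical(dim(precip),
                 c(spec$n_rows, spec$n_cols, length(dates))))
    stop("precip array must be n_rows x n_cols x n_days")
  if (!identical(dim(et0_monthly),
                 c(spec$n_rows, spec$n_cols, length(months))))
    stop("et0_monthly array must be n_rows x n_cols x n_months")
  if (any(precip < 0) || any(et0_monthly < 0))
    stop("forcing must be >= 0")
  structure(list(spec = spec, dates = dates, precip = precip,
                 et0_monthly = et0_monthly, months = months),
            class = "gridded_forcing")
}

#' Write gridded forcing to NetCDF
#'
#' Writes daily precipitation (`pr`, mm/day) and monthly reference
#' evapotranspiration (`et0`, mm/month) as NetCDF-4 with lon/lat/time
#' dimensions and WGS84 metadata.
#'
#' @param forcing a [gridded_forcing()].
#' @param precip_path,et0_path output file paths.
#' @return Invisibly, the two paths.
#' @export
write_forcing <- function(forcing, precip_path, et0_path) {
  spec <- forcing$spec
  ll <- nc_lonlat_dims(spec)
  tdim <- ncdf4::ncdim_def(
    "time", sprintf("days since %s", format(forcing$dates[1])),
    as.numeric(forcing$dates - forcing$dates[1]), unlim = FALSE)
  v <- ncdf4::ncvar_def("pr", "mm/day", c(ll, list(tdim)),
                        missval = NaN, prec = "double", compression = 4)
  nc <- ncdf4::nc_create(precip_path, v, force_v4 = TRUE)
  for (k in seq_along(forcing$dates))
    ncdf4::ncvar_put(nc, v, to_nc(forcing$precip[, , k]),
                     start = c(1, 1, k), count = c(-1, -1, 1))
  ncdf4::ncatt_put(nc, 0, "crs", spec$crs)
  ncdf4::nc_close(nc)

  mstart <- as.Date(paste0(forcing$months, "-01"))
  mdim <- ncdf4::ncdim_def(
    "time", sprintf("days since %s", format(forcing$dates[1])),
    as.numeric(mstart - forcing$dates[1]), unlim = FALSE)
  v2 <- ncdf4::ncvar_def("et0", "mm/month", c(ll, list(mdim)),
                         missval = NaN, prec = "double", compression = 4)
  nc <- ncdf4::nc_create(et0_path, v2, force_v4 = TRUE)
  for (k in seq_along(forcing$months))
    ncdf4::ncvar_put(nc, v2, to_nc(forcing$et0_monthly[, , k]),
                     start = c(1, 1, k), count = c(-1, -1, 1))
  ncdf4::ncatt_put(nc, 0, "crs", spec$crs)
  ncdf4::nc_close(nc)
  invisible(c(precip_path, et0_path))
}

#' Read gridded forcing from NetCDF
#'
#' Counterpart of [write_forcing()]. Shapes are validated against the
#' grid specification (mismatches are an error naming the layer and both
#' shapes); unknown units raise a warning, not an error.
#'
#' @param precip_path,et0_path NetCDF files as written by
#'   [write_forcing()].
#' @param spec the expected [grid_spec()].
#' @return A [gridded_forcing()].
#' @export
read_forcing <- function(precip_path, et0_path, spec) {
  nc <- ncdf4::nc_open(precip_path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  check_nc_shape(nc, "pr", spec, precip_path)
  check_units(nc, "pr", c("mm/day", "mm day-1", "mm"), precip_path)
  tunits <- nc$dim$time$units
  origin <- as.Date(sub("days since ", "", tunits))
  dates <- origin + as.numeric(nc$dim$time$vals)
  pr <- ncdf4::ncvar_get(nc, "pr", collapse_degen = FALSE)
  precip <- aperm(pr, c(2, 1, 3))

  nc2 <- ncdf4::nc_open(et0_path)
  on.exit(ncdf4::nc_close(nc2), add = TRUE)
  check_nc_shape(nc2, "et0", spec, et0_path)
  check_units(nc2, "et0", c("mm/month", "mm"), et0_path)
  e <- ncdf4::ncvar_get(nc2, "et0", collapse_degen = FALSE)
  et0 <- aperm(e, c(2, 1, 3))
  gridded_forcing(spec, dates, precip, et0)
}

#' Soil parameter grid
#'
#' @param spec a [grid_spec()].
#' @param theta_diff matrix of maximum soil moisture storage capacity,
#'   mm per metre of soil.
#' @param f_max matrix of maximum infiltration rate, mm/day.
#' @return An object of class `soil_grid`.
#' @export
soil_grid <- function(spec, theta_diff, f_max) {
  if (!identical(dim(theta_diff), c(spec$n_rows, spec$n_cols)) ||
      !identical(dim(f_max), c(spec$n_rows, spec$n_cols)))
    stop("soil layers must match the grid shape")
  structure(list(spec = spec, theta_diff = theta_diff, f_max = f_max),
            class = "soil_grid")
}

#' Write / read soil parameter grids (NetCDF)
#'
#' @param soil a [soil_grid()].
#' @param path NetCDF file path.
#' @return `write_soil` the path invisibly; `read_soil` a `soil_grid`.
#' @export
write_soil <- function(soil, path) {
  ll <- nc_lonlat_dims(soil$spec)
  v1 <- ncdf4::ncvar_def("theta_diff", "mm m-1", ll, missval = NaN,
                         prec = "double", compression = 4)
  v2 <- ncdf4::ncvar_def("f_max", "mm day-1", ll, missval = NaN,
                         prec = "double", compression = 4)
  nc <- ncdf4::nc_create(path, list(v1, v2), force_v4 = TRUE)
  ncdf4::ncvar_put(nc, v1, to_nc(soil$theta_diff))
  ncdf4::ncvar_put(nc, v2, to_nc(soil$f_max))
  ncdf4::ncatt_put(nc, 0, "crs", soil$spec$crs)
  ncdf4::nc_close(nc)
  invisible(path)
}

#' @rdname write_soil
#' @param spec the expected [grid_spec()].
#' @export
read_soil <- function(path, spec) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  check_nc_shape(nc, "theta_diff", spec, path)
  check_units(nc, "theta_diff", c("mm m-1", "mm/m"), path)
  soil_grid(spec,
            from_nc(ncdf4::ncvar_get(nc, "theta_diff",
                                     collapse_degen = FALSE)[, , drop = TRUE]),
            from_nc(ncdf4::ncvar_get(nc, "f_max",
                                     collapse_degen = FALSE)[, , drop = TRUE]))
}

#' Write / read the calendar-region map (NetCDF)
#'
#' The region map links each cell to the regional crop calendar that
#' governs it; cells without cropland carry the fill value.
#'
#' @param region_map integer matrix `n_rows x n_cols` of region ids
#'   (`NA` = no cropland).
#' @param spec a [grid_spec()].
#' @param path NetCDF file path.
#' @return `write_region_map` the path invisibly; `read_region_map` an
#'   integer matrix with `NA` for no-data cells.
#' @export
write_region_map <- function(region_map, spec, path) {
  ll <- nc_lonlat_dims(spec)
  v <- ncdf4::ncvar_def("region_id", "", ll, missval = -1L,
                        prec = "integer", compression = 4)
  m <- region_map
  m[is.na(m)] <- -1L
  nc <- ncdf4::nc_create(path, v, force_v4 = TRUE)
  ncdf4::ncvar_put(nc, v, to_nc(m))
  ncdf4::ncatt_put(nc, 0, "crs", spec$crs)
  ncdf4::nc_close(nc)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path, spec) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  check_nc_shape(nc, "region_id", spec, path)
  m <- from_nc(ncdf4::ncvar_get(nc, "region_id",
                                collapse_degen = FALSE)[, , drop = TRUE])
  m[m == -1L] <- NA_integer_
  storage.mode(m) <- "integer"
  m
}

# ---- the grid run --------------------------------------------------------

#' Run the model over a grid
#'
#' Runs the point pipeline ([simulate_cwr()]) for every cell with a
#' calendar entry, for each requested crop and regime. Cells are mutually
#' independent, so the result does not depend on iteration order; cells
#' whose region has no growing period for a combination are masked. The
#' spin-up year selection is drawn once (from the run seed) and shared by
#' every simulation of the run.
#'
#' @param forcing a [gridded_forcing()].
#' @param soil a [soil_grid()] on the same grid.
#' @param region_map integer matrix of calendar-region ids (`NA` = no
#'   cropland).
#' @param calendars named list of [crop_calendar()], keyed by region id
#'   as character.
#' @param crop_table named list of [crop_parameters()].
#' @param crops,regimes character vectors selecting what to simulate.
#' @param years production years to simulate (defaults to the last
#'   forcing year); multiple years are averaged into a climatological
#'   result.
#' @param config an [engine_config()].
#' @return An object of class `cwr_grid_results`: list with `spec`,
#'   `years`, `config`, `spin_years`, and `fields[[crop]][[regime]]`,
#'   each holding matrices `annual_gw`, `annual_bw` and arrays
#'   `monthly_gw`, `monthly_bw` (`n_rows x n_cols x 12`, mm), with `NA`
#'   outside the mask.
#' @export
run_grid <- function(forcing, soil, region_map, calendars, crop_table,
                     crops = names(crop_table),
                     regimes = c("rainfed", "irrigated"),
                     years = NULL, config = engine_config()) {
  spec <- forcing$spec
  if (!same_spec(spec, soil$spec))
    stop("grid mismatch: soil grid does not match the forcing grid")
  if (!identical(dim(region_map), c(spec$n_rows, spec$n_cols)))
    stop("grid mismatch: region map does not match the forcing grid")
  missing_crops <- setdiff(crops, names(crop_table))
  if (length(missing_crops) > 0)
    stop("missing crop parameters for: ",
         paste(missing_crops, collapse = ", "))
  yr <- as.integer(format(forcing$dates, "%Y"))
  avail <- sort(unique(yr))
  if (is.null(years)) years <- max(avail)
  spin_years <- select_spin_up_years(avail, config$spin_up_years,
                                     config$seed)
  mstart <- as.Date(paste0(forcing$months, "-01"))

  empty2 <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  empty3 <- array(NA_real_, c(spec$n_rows, spec$n_cols, 12L))
  fields <- stats::setNames(lapply(crops, function(cr)
    stats::setNames(lapply(regimes, function(rg)
      list(annual_gw = empty2, annual_bw = empty2,
           monthly_gw = empty3, monthly_bw = empty3)), regimes)), crops)

  for (r in seq_len(spec$n_rows)) for (cc in seq_len(spec$n_cols)) {
    reg <- region_map[r, cc]
    if (is.na(reg)) next
    cal <- calendars[[as.character(reg)]]
    if (is.null(cal)) next
    et0_daily <- disaggregate_et0(forcing$et0_monthly[r, cc, ],
                                  forcing$dates)
    fp <- daily_forcing(forcing$dates, forcing$precip[r, cc, ], et0_daily)
    prof <- soil_profile(soil$theta_diff[r, cc], soil$f_max[r, cc])
    for (cr in crops) for (rg in regimes) {
      seasons <- calendar_seasons(cal, cr, rg)
      if (length(seasons) == 0L) next
      res <- simulate_cwr(fp, crop_table[[cr]], seasons, prof, rg,
                          config, production_years = years,
                          spin_years = spin_years)
      if (length(years) > 1L) res <- multi_year_average(res)
      fields[[cr]][[rg]]$annual_gw[r, cc] <- sum(res$monthly$gw)
      fields[[cr]][[rg]]$annual_bw[r, cc] <- sum(res$monthly$bw)
      fields[[cr]][[rg]]$monthly_gw[r, cc, ] <- res$monthly$gw
      fields[[cr]][[rg]]$monthly_bw[r, cc, ] <- res$monthly$bw
    }
  }
  structure(list(spec = spec, years = years, config = config,
                 spin_years = spin_years, crops = crops,
                 regimes = regimes, fields = fields),
            class = "cwr_grid_results")
}

#' @export
print.cwr_grid_results <- function(x, ...) {
  cat(sprintf("<cwr_grid_results> %d x %d grid, year(s) %s\n",
              x$spec$n_rows, x$spec$n_cols,
              paste(x$years, collapse = ", ")))
  cat(sprintf("  crops: %s; regimes: %s\n",
              paste(x$crops, collapse = ", "),
              paste(x$regimes, collapse = ", ")))
  invisible(x)
}

# ---- published output layout ---------------------------------------------

#' Crop codes of the published product
#'
#' The fixed 26-class crop coding used on the annual product's crop
#' dimension: 23 individual crops plus the three crop groups.
#'
#' @return data.frame with columns `code` (1..26) and `crop`.
#' @export
crop_codes <- function() {
  data.frame(
    code = 1:26,
    crop = c("Wheat", "Maize", "Rice", "Barley", "Rye", "Millet",
             "Sorghum", "Soybeans", "Sunflower", "Potatoes", "Cassava",
             "Sugar cane", "Sugar beets", "Oil palm", "Rapeseed",
             "Groundnuts", "Pulses", "Citrus", "Date palm", "Grapes",
             "Cotton", "Cocoa", "Coffee", "Others perennial",
             "Fodder grasses", "Others annual"))
}

norm_crop <- function(x) gsub("[ _-]", "", tolower(x))

#' Crop code lookup
#'
#' @param crop_id crop identifier (matched case- and
#'   punctuation-insensitively against [crop_codes()]).
#' @return Integer code in 1..26.
#' @export
crop_code <- function(crop_id) {
  tab <- crop_codes()
  i <- match(norm_crop(crop_id), norm_crop(tab$crop))
  if (any(is.na(i)))
    stop("unknown crop id(s): ", paste(crop_id[is.na(i)], collapse = ", "))
  tab$code[i]
}

write_cwr_nc <- function(path, spec, dim3, dim3_name, dim3_units, slices,
                         year_label) {
  ll <- nc_lonlat_dims(spec)
  d3 <- ncdf4::ncdim_def(dim3_name, dim3_units, dim3,
                         create_dimvar = TRUE)
  v <- ncdf4::ncvar_def("cwr", "mm", c(ll, list(d3)), missval = NaN,
                        prec = "float", compression = 1,
                        chunksizes = c(spec$n_cols, spec$n_rows, 1))
  nc <- ncdf4::nc_create(path, v, force_v4 = TRUE)
  on.exit(ncdf4::nc_close(nc))
  for (k in seq_along(dim3))
    ncdf4::ncvar_put(nc, v, to_nc(slices(k)), start = c(1, 1, k),
                     count = c(-1, -1, 1))
  ncdf4::ncatt_put(nc, 0, "crs", spec$crs)
  ncdf4::ncatt_put(nc, 0, "year", as.character(year_label))
  if (dim3_name == "crop")
    ncdf4::ncatt_put(nc, 0, "crop_codes",
                     paste(sprintf("%d=%s", crop_codes()$code,
                                   crop_codes()$crop), collapse = "; "))
  invisible(path)
}

#' Write the annual product files
#'
#' Writes the three annual NetCDF-4 files of the published layout —
#' `BW_irrig_<YEAR>.nc`, `GW_irrig_<YEAR>.nc`, `GW_rainf_<YEAR>.nc` —
#' each with a 26-class crop dimension ordered by [crop_codes()]; crops
#' absent from `results` are written as all-fill slices. Units are mm;
#' the CRS and the crop coding are recorded as global attributes.
#'
#' @param results a `cwr_grid_results` from [run_grid()].
#' @param out_dir output directory (created if needed).
#' @param year_label label used in the file names.
#' @return Character vector of the three paths, invisibly.
#' @export
write_annual_outputs <- function(results, out_dir, year_label) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  spec <- results$spec
  codes <- crop_code(results$crops)
  empty <- matrix(NA_real_, spec$n_rows, spec$n_cols)
  slice_fun <- function(regime, what) function(k) {
    i <- match(k, codes)
    if (is.na(i)) return(empty)
    f <- results$fields[[results$crops[i]]][[regime]]
    if (is.null(f)) empty else f[[what]]
  }
  files <- c(BW_irrig = NA, GW_irrig = NA, GW_rainf = NA)
  jobs <- list(
    list(name = "BW_irrig", regime = "irrigated", what = "annual_bw"),
    list(name = "GW_irrig", regime = "irrigated", what = "annual_gw"),
    list(name = "GW_rainf", regime = "rainfed", what = "annual_gw"))
  for (j in jobs) {
    if (!j$regime %in% results$regimes) next
    path <- file.path(out_dir, sprintf("%s_%s.nc", j$name, year_label))
    write_cwr_nc(path, spec, 1:26, "crop", "crop_code",
                 slice_fun(j$regime, j$what), year_label)
    files[j$name] <- path
  }
  invisible(files[!is.na(files)])
}

#' Write the monthly product files for selected crops
#'
#' Writes, per crop, `BW_<crop>_irr_<YEAR>.nc`, `GW_<crop>_irr_<YEAR>.nc`
#' and `GW_<crop>_rfc_<YEAR>.nc` with a 12-month dimension, following the
#' published monthly layout.
#'
#' @param results a `cwr_grid_results` from [run_grid()].
#' @param out_dir output directory.
#' @param year_label label used in the file names.
#' @param crops crops to write (default: all in `results`).
#' @return Character vector of written paths, invisibly.
#' @export
write_monthly_outputs <- function(results, out_dir, year_label,
                                  crops = results$crops) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  spec <- results$spec
  paths <- character(0)
  for (cr in crops) {
    jobs <- list(
      list(tag = sprintf("BW_%s_irr", cr), regime = "irrigated",
           what = "monthly_bw"),
      list(tag = sprintf("GW_%s_irr", cr), regime = "irrigated",
           what = "monthly_gw"),
      list(tag = sprintf("GW_%s_rfc", cr), regime = "rainfed",
           what = "monthly_gw"))
    for (j in jobs) {
      if (!j$regime %in% results$regimes) next
      f <- results$fields[[cr]][[j$regime]][[j$what]]
      path <- file.path(out_dir, sprintf("%s_%s.nc", j$tag, year_label))
      write_cwr_nc(path, spec, 1:12, "month", "month",
                   function(k) f[, , k], year_label)
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}

#' Read a product file back
#'
#' Reads a NetCDF file written by [write_annual_outputs()] or
#' [write_monthly_outputs()].
#'
#' @param path NetCDF file.
#' @return List with `values` (array `n_rows x n_cols x n3`, row 1
#'   north), `dim3` (crop codes or months), `dim3_name`, `units`, `lon`,
#'   `lat`.
#' @export
read_cwr_output <- function(path) {
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  a <- ncdf4::ncvar_get(nc, "cwr", collapse_degen = FALSE)
  d3name <- nc$var$cwr$dim[[3]]$name
  list(values = aperm(a, c(2, 1, 3)),
       dim3 = as.numeric(nc$var$cwr$dim[[3]]$vals),
       dim3_name = d3name,
       units = ncdf4::ncatt_get(nc, "cwr", "units")$value,
       lon = as.numeric(nc$dim$lon$vals),
       lat = as.numeric(nc$dim$lat$vals))
}
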