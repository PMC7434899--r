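#' Pixel-by-pixel comparison of two gridded products
#'
#' Computes, per cell, the relative difference `|a - b| / b` against the
#' reference product `b` and reports the area-weighted fraction of the
#' common mask whose difference stays below a threshold, plus the
#' area-weighted mean relative difference. Cells where both products are
#' zero count as agreeing; cells where the reference is zero but the
#' candidate is not count as disagreeing. The statistic is scale
#' invariant: multiplying both fields by the same positive constant
#' leaves the report unchanged.
#'
#' @param a candidate [gridded_field()].
#' @param b reference `gridded_field` on the same grid and mask.
#' @param area_weights optional `gridded_field` of weights (e.g.
#'   harvested area); uniform weights when absent.
#' @param threshold relative-difference threshold (fraction, default
#'   0.2).
#' @return An object of class `comparison_report` with
#'   `fraction_within`, `mean_rel_diff` (over cells with a positive
#'   reference), `threshold` and `n_cells`.
#' @export
compare_fields <- function(a, b, area_weights = NULL, threshold = 0.2) {
  if (!same_spec(a$spec, b$spec))
    stop("grid specs of the two fields differ")
  if (!identical(a$mask, b$mask))
    stop("masks of the two fields differ")
  m <- a$mask
  if (!any(m)) stop("empty mask")
  w <- if (is.null(area_weights)) {
    matrix(1, nrow(m), ncol(m))
  } else {
    if (!same_spec(area_weights$spec, a$spec))
      stop("area-weight grid does not match the fields")
    aw <- area_weights$values
    aw[is.na(aw)] <- 0
    aw
  }
  av <- a$values[m]; bv <- b$values[m]; wv <- w[m]
  pos <- bv > 0
  rel <- rep(NA_real_, length(bv))
  rel[pos] <- abs(av[pos] - bv[pos]) / bv[pos]
  agree <- (pos & rel < threshold) | (!pos & av == 0)
  structure(list(
    fraction_within = sum(wv * agree) / sum(wv),
    mean_rel_diff = if (any(pos)) sum(wv[pos] * rel[pos]) / sum(wv[pos])
                    else NA_real_,
    threshold = threshold,
    n_cells = length(bv)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> %.1f%% of weighted area within %.0f%% of the reference (%d cells)\n",
    100 * x$fraction_within, 100 * x$threshold, x$n_cells))
  cat(sprintf("  area-weighted mean relative difference: %.3f\n",
              x$mean_rel_diff))
  invisible(x)
}

# Domain total of annual green + blue requirement over all simulated
# crops, regimes and cells (mm summed over cells), optionally split.
#' Domain totals of a grid result
#'
#' Sums the annual green and blue requirement fields of a
#' [run_grid()] result over all cells, crops and regimes.
#'
#' @param results a `cwr_grid_results`.
#' @return Named numeric vector with `gw`, `bw` and `total` (mm summed
#'   over cells).
#' @export
domain_total <- function(results) {
  gw <- 0; bw <- 0
  for (cr in results$crops) for (rg in results$regimes) {
    f <- results$fields[[cr]][[rg]]
    gw <- gw + sum(f$annual_gw, na.rm = TRUE)
    bw <- bw + sum(f$annual_bw, na.rm = TRUE)
  }
  c(gw = gw, bw = bw, total = gw + bw)
}

#' Sensitivity of the result to the initial soil moisture
#'
#' Repeats the full grid run with the initial moisture fraction
#' overridden (spin-up retained, all other configuration identical, the
#' same seeded spin-up years) and reports, per fraction, the domain-total
#' annual green + blue requirement and its relative change against the
#' 50% baseline, together with the maximum cell-level relative change.
#' With a multi-year spin-up the store forgets its initial condition and
#' the changes are expected to be well below 1%.
#'
#' @param forcing,soil,region_map,calendars,crop_table,crops,regimes,years
#'   inputs as for [run_grid()].
#' @param config an [engine_config()]; its
#'   `initial_moisture_fraction` is overridden per run.
#' @param fractions initial moisture fractions to test; must contain the
#'   0.5 baseline.
#' @return An object of class `sensitivity_report`: data.frame with
#'   columns `fraction`, `total` (mm), `rel_change` (vs baseline) and
#'   `max_cell_rel_change`, with the maximum domain-level change in
#'   attribute `max_rel_change`.
#' @export
sensitivity_initial_condition <- function(forcing, soil, region_map,
                                          calendars, crop_table,
                                          crops = names(crop_table),
                                          regimes = c("rainfed",
                                                      "irrigated"),
                                          years = NULL,
                                          config = engine_config(),
                                          fractions = c(0, 0.5, 1)) {
  if (!any(abs(fractions - 0.5) < 1e-12))
    stop("fractions must include the 0.5 baseline")
  runs <- lapply(fractions, function(f) {
    cfg <- config
    cfg$initial_moisture_fraction <- f
    run_grid(forcing, soil, region_map, calendars, crop_table, crops,
             regimes, years, cfg)
  })
  totals <- vapply(runs, function(r) domain_total(r)[["total"]],
                   numeric(1))
  base_i <- which.min(abs(fractions - 0.5))
  base <- runs[[base_i]]
  cell_change <- vapply(runs, function(r) {
    mx <- 0
    for (cr in r$crops) for (rg in r$regimes) {
      v <- r$fields[[cr]][[rg]]$annual_gw + r$fields[[cr]][[rg]]$annual_bw
      v0 <- base$fields[[cr]][[rg]]$annual_gw +
        base$fields[[cr]][[rg]]$annual_bw
      ok <- !is.na(v0) & v0 > 0
      if (any(ok)) mx <- max(mx, abs(v[ok] - v0[ok]) / v0[ok])
    }
    mx
  }, numeric(1))
  out <- data.frame(fraction = fractions, total = totals,
                    rel_change = abs(totals - totals[base_i]) /
                      totals[base_i],
                    max_cell_rel_change = cell_change)
  attr(out, "max_rel_change") <- max(out$rel_change)
  class(out) <- c("sensitivity_report", "data.frame")
  out
}

#' Sensitivity of the result to the off-season crop coefficient
#'
#' Repeats the full grid run with the off-season kc overridden and
#' tabulates, per crop and in total, the domain-total annual green and
#' blue requirements for each kc value. Off-season kc only acts through
#' soil-moisture carry-over into the growing season, so crops occupying
#' the whole year are insensitive to it by construction.
#'
#' @inheritParams sensitivity_initial_condition
#' @param kc_values off-season kc values to test, each in (0, 2\].
#' @return data.frame of class `kc_sensitivity_table` with columns
#'   `crop`, `kc`, `gw`, `bw` (mm summed over cells, both regimes for
#'   gw), including a `"total"` row per kc value.
#' @export
sensitivity_offseason_kc <- function(forcing, soil, region_map, calendars,
                                     crop_table,
                                     crops = names(crop_table),
                                     regimes = c("rainfed", "irrigated"),
                                     years = NULL,
                                     config = engine_config(),
                                     kc_values = c(0.1, 0.5, 1.0)) {
  if (any(kc_values <= 0 | kc_values > 2))
    stop("off-season kc values must lie in (0, 2]")
  rows <- list()
  for (k in kc_values) {
    cfg <- config
    cfg$off_season_kc <- k
    r <- run_grid(forcing, soil, region_map, calendars, crop_table,
                  crops, regimes, years, cfg)
    for (cr in crops) {
      gw <- 0; bw <- 0
      for (rg in regimes) {
        f <- r$fields[[cr]][[rg]]
        gw <- gw + sum(f$annual_gw, na.rm = TRUE)
        bw <- bw + sum(f$annual_bw, na.rm = TRUE)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(crop = cr, kc = k, gw = gw, bw = bw)
    }
    tot <- domain_total(r)
    rows[[length(rows) + 1L]] <-
      data.frame(crop = "total", kc = k, gw = tot[["gw"]],
                 bw = tot[["bw"]])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("kc_sensitivity_table", "data.frame")
  out
}
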