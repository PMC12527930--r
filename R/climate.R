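#' Monthly SST climatology and maximum monthly mean
#'
#' Computes the 12 monthly mean sea-surface temperatures over a fixed
#' 30-year baseline window (1982-01-01 to 2011-12-31 by convention) and the
#' maximum monthly mean (MMM), the warmest of the twelve. The MMM is the
#' anomaly threshold for degree-heating-week accumulation.
#'
#' @param dates Vector of `Date`s, strictly increasing and gap-free over the
#'   baseline window.
#' @param sst Daily SST in degrees C, same length as `dates`.
#' @param baseline Length-2 `Date` (or coercible) vector giving the window,
#'   default `c("1982-01-01", "2011-12-31")`.
#' @return List of class `thermal_climatology` with `monthly_means`
#'   (12 values), `mmm` and `baseline`.
#' @export
monthly_climatology <- function(dates, sst,
                                baseline = c("1982-01-01", "2011-12-31")) {
  dates <- as.Date(dates)
  baseline <- as.Date(baseline)
  if (length(dates) != length(sst)) stop("dates and sst lengths differ")
  if (any(!is.finite(sst))) stop("SST values must be finite")
  in_win <- dates >= baseline[1] & dates <= baseline[2]
  expected <- seq(baseline[1], baseline[2], by = "day")
  have <- dates[in_win]
  if (!identical(as.integer(have), as.integer(expected))) {
    miss <- setdiff(as.integer(expected), as.integer(have))
    if (length(miss)) {
      stop(sprintf("incomplete baseline coverage: %d missing day(s) starting %s",
                   length(miss), as.Date(miss[1], origin = "1970-01-01")))
    }
    stop("baseline days must be strictly increasing and gap-free")
  }
  mo <- as.integer(format(have, "%m"))
  monthly <- as.numeric(tapply(sst[in_win], mo, mean))
  structure(list(monthly_means = monthly, mmm = max(monthly),
                 baseline = baseline),
            class = "thermal_climatology")
}

#' @export
print.thermal_climatology <- function(x, ...) {
  cat(sprintf("Thermal climatology %s..%s, MMM = %.2f C\n",
              x$baseline[1], x$baseline[2], x$mmm))
  invisible(x)
}

#' Degree heating weeks from a daily SST series
#'
#' DHW on day t is the sum of positive SST anomalies above the maximum
#' monthly mean over the trailing 12-week (84-day, inclusive) window, in
#' C-weeks: `DHW(t) = sum_{d = t-83..t} max(SST(d) - (mmm + hotspot_floor), 0) / 7`.
#' The first 83 days use the available partial window. `block` mode instead
#' evaluates consecutive non-overlapping 84-day blocks (each block's total
#' assigned to every day in it), provided as a sensitivity alternative to the
#' daily trailing window.
#'
#' @param dates Gap-free increasing daily `Date`s.
#' @param sst Daily SST, degrees C.
#' @param mmm Maximum monthly mean from [monthly_climatology()].
#' @param window_days Accumulation window, default 84 (12 weeks).
#' @param hotspot_floor Additional anomaly floor above MMM before heat
#'   accumulates (0 by default; 1 reproduces the NOAA hotspot convention).
#' @param mode `"trailing"` (default) or `"block"`.
#' @return Data.frame with columns `date` and `dhw` (C-weeks).
#' @export
dhw_series <- function(dates, sst, mmm, window_days = 84, hotspot_floor = 0,
                       mode = c("trailing", "block")) {
  mode <- match.arg(mode)
  dates <- as.Date(dates)
  if (!length(sst)) stop("empty SST series")
  if (length(dates) != length(sst)) stop("dates and sst lengths differ")
  if (any(diff(as.integer(dates)) != 1)) stop("dates must be gap-free daily")
  hot <- pmax(sst - (mmm + hotspot_floor), 0)
  if (mode == "trailing") {
    cs <- cumsum(hot)
    lag <- c(rep(0, min(window_days, length(cs))),
             cs[seq_len(max(0, length(cs) - window_days))])
    dhw <- (cs - lag) / 7
  } else {
    blk <- (seq_along(hot) - 1) %/% window_days
    totals <- tapply(hot, blk, sum) / 7
    dhw <- as.numeric(totals[as.character(blk)])
  }
  data.frame(date = dates, dhw = dhw)
}

#' Annual maximum DHW
#'
#' @param dhw Data.frame from [dhw_series()] (`date`, `dhw`).
#' @return Data.frame `year`, `dhw_max`: the maximum DHW among days falling
#'   in each calendar year.
#' @export
annual_max_dhw <- function(dhw) {
  yr <- as.integer(format(dhw$date, "%Y"))
  mx <- tapply(dhw$dhw, yr, max)
  data.frame(year = as.integer(names(mx)), dhw_max = as.numeric(mx),
             row.names = NULL)
}

#' Multi-model ensemble mean of daily series
#'
#' Pointwise unweighted mean across climate models, on the intersection of
#' their time axes. A warning reports trimming; fully disjoint axes are an
#' error.
#'
#' @param series Long data.frame with columns `model_id`, `date`, `value`.
#' @return Data.frame `date`, `value` (ensemble mean), sorted by date.
#' @export
ensemble_mean <- function(series) {
  stopifnot(all(c("model_id", "date", "value") %in% names(series)))
  series$date <- as.Date(series$date)
  models <- split(series, series$model_id)
  if (!length(models)) stop("no models supplied")
  common <- Reduce(intersect, lapply(models, function(m) as.integer(m$date)))
  if (!length(common)) stop("models have disjoint time axes")
  n_all <- length(unique(as.integer(series$date)))
  if (length(common) < n_all) {
    warning(sprintf("time axes trimmed to %d common day(s) of %d",
                    length(common), n_all))
  }
  common <- sort(common)
  vals <- vapply(models, function(m) {
    m$value[match(common, as.integer(m$date))]
  }, numeric(length(common)))
  data.frame(date = as.Date(common, origin = "1970-01-01"),
             value = rowMeans(as.matrix(vals)))
}

#' Extract the nearest grid cell to a site
#'
#' Great-circle (haversine) nearest cell centre among the rows of a gridded
#' table; ties break deterministically toward the lower row index. Sites
#' outside the grid's bounding box are matched to the nearest edge cell with
#' a warning. Cells whose value column is entirely missing are treated as
#' land-masked: an error by default, or skipped when `widen = TRUE`.
#'
#' @param grid Data.frame with `lat`, `lon` columns (cell centres, degrees)
#'   plus any payload columns.
#' @param lat,lon Site coordinates in degrees.
#' @param value_col Optional payload column name checked for land masking.
#' @param widen If TRUE, a land-masked nearest cell is skipped in favour of
#'   the nearest non-missing cell.
#' @return The matched grid row (data.frame, one row) with an attached
#'   `distance_m` column.
#' @export
nearest_grid_extract <- function(grid, lat, lon, value_col = NULL, widen = FALSE) {
  stopifnot(all(c("lat", "lon") %in% names(grid)), nrow(grid) >= 1)
  if (lat < min(grid$lat) || lat > max(grid$lat) ||
      lon < min(grid$lon) || lon > max(grid$lon)) {
    warning("site outside grid bounding box; using nearest edge cell")
  }
  d <- geosphere::distHaversine(cbind(grid$lon, grid$lat), c(lon, lat))
  # near-equal distances (within 1 mm) are ties; lower index wins
  ord <- order(round(d, 3), seq_along(d))
  for (i in ord) {
    masked <- !is.null(value_col) && all(is.na(grid[[value_col]][i]))
    if (!masked) {
      out <- grid[i, , drop = FALSE]
      out$distance_m <- d[i]
      rownames(out) <- NULL
      return(out)
    }
    if (!widen) stop("land-masked nearest cell; set widen = TRUE to search further")
  }
  stop("all grid cells are land-masked")
}

#' Site-level climate forcing from a multi-model ensemble
#'
#' Builds the forcing a reef site experiences under one scenario: annual
#' maximum DHW, annual mean warming above the baseline-period mean
#' (`delta_t`), and annual pH change from the baseline-period mean
#' (`delta_ph`, negative under acidification). DHW is computed on the
#' multi-model mean SST series (not per model), matching the use of a single
#' multi-model annual mean as the forcing basis.
#'
#' @param sst Long data.frame `model_id`, `date`, `value` (daily SST, C) for
#'   one site/scenario.
#' @param ph Data.frame `model_id`, `year`, `value` (annual mean pH) for the
#'   same site/scenario.
#' @param baseline Baseline window passed to [monthly_climatology()].
#' @param hotspot_floor,window_days Passed to [dhw_series()].
#' @return Data.frame `year`, `dhw_max`, `delta_t`, `delta_ph` over the
#'   years covered by both inputs.
#' @export
site_forcing <- function(sst, ph, baseline = c("1982-01-01", "2011-12-31"),
                         hotspot_floor = 0, window_days = 84) {
  ens <- ensemble_mean(sst)
  clim <- monthly_climatology(ens$date, ens$value, baseline)
  dmax <- annual_max_dhw(dhw_series(ens$date, ens$value, clim$mmm,
                                    window_days, hotspot_floor))
  yr <- as.integer(format(ens$date, "%Y"))
  ann_t <- tapply(ens$value, yr, mean)
  base_years <- as.integer(format(as.Date(baseline[1]), "%Y")):
                as.integer(format(as.Date(baseline[2]), "%Y"))
  base_t <- mean(ann_t[as.character(base_years)])
  dt <- data.frame(year = as.integer(names(ann_t)),
                   delta_t = as.numeric(ann_t) - base_t)

  ph_by_year <- tapply(ph$value, ph$year, mean)  # model mean per year
  ph_base_years <- intersect(base_years, as.integer(names(ph_by_year)))
  if (!length(ph_base_years)) stop("pH series does not cover the baseline window")
  base_ph <- mean(ph_by_year[as.character(ph_base_years)])
  dph <- data.frame(year = as.integer(names(ph_by_year)),
                    delta_ph = as.numeric(ph_by_year) - base_ph)

  out <- merge(merge(dmax, dt, by = "year"), dph, by = "year")
  out[order(out$year), , drop = FALSE]
}
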