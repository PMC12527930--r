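baseline_days <- seq(as.Date("1982-01-01"), as.Date("2011-12-31"), by = "day")

test_that("monthly climatology and MMM come from baseline month means", {
  clim <- monthly_climatology(baseline_days, rep(27, length(baseline_days)))
  expect_equal(clim$monthly_means, rep(27, 12))
  expect_equal(clim$mmm, 27)

  # sinusoid peaking in September: oracle = independent per-month mean loop
  doy <- as.integer(format(baseline_days, "%j"))
  sst <- 27 + 3 * cos(2 * pi * (doy - 258) / 365.25)
  clim <- monthly_climatology(baseline_days, sst)
  oracle <- vapply(1:12, function(m) {
    keep <- as.integer(format(baseline_days, "%m")) == m
    mean(sst[keep])
  }, numeric(1))
  expect_equal(clim$monthly_means, oracle)
  expect_equal(clim$mmm, oracle[9])
  expect_equal(clim$mmm, max(oracle))

  # one missing day breaks the baseline precondition
  drop <- baseline_days != as.Date("1995-06-15")
  expect_error(monthly_climatology(baseline_days[drop], sst[drop]),
               "incomplete baseline coverage.*1995-06-15")
})

test_that("degree heating weeks accumulate positive anomalies over 12 weeks", {
  days <- seq(as.Date("2020-01-01"), by = "day", length.out = 365)
  expect_true(all(dhw_series(days, rep(29, 365), mmm = 29)$dhw == 0))

  # 28 consecutive days at +1 C is exactly 4 C-weeks at the window end
  sst <- rep(28, 365); sst[100:127] <- 30
  d <- dhw_series(days, sst, mmm = 29)
  expect_equal(max(d$dhw), 4)
  expect_equal(annual_max_dhw(d)$dhw_max, 4)
  expect_equal(d$dhw[127 + 84], 0)  # fully decays once the window passes

  expect_error(dhw_series(days, numeric(0), 29), "empty")
  expect_error(dhw_series(days[c(1:5, 7)], rep(28, 6), 29), "gap-free")
})

test_that("sliding-window DHW equals the brute-force trailing sum", {
  set.seed(3)
  days <- seq(as.Date("2019-06-01"), by = "day", length.out = 400)
  sst <- 28 + rnorm(400, 0, 1.2)
  mmm <- 28.4
  d <- dhw_series(days, sst, mmm)
  hot <- pmax(sst - mmm, 0)
  oracle <- vapply(seq_along(sst), function(t) {
    sum(hot[max(1, t - 83):t]) / 7
  }, numeric(1))
  expect_equal(d$dhw, oracle)

  # monotone under pointwise SST increase
  d_up <- dhw_series(days, sst + 0.5, mmm)
  expect_true(all(d_up$dhw >= d$dhw))

  # block mode: non-overlapping 84-day totals
  db <- dhw_series(days, sst, mmm, mode = "block")
  expect_equal(db$dhw[1], sum(hot[1:84]) / 7)
  expect_equal(db$dhw[85], sum(hot[85:168]) / 7)
})

test_that("ensemble mean is the pointwise unweighted model mean", {
  days <- seq(as.Date("2000-01-01"), by = "day", length.out = 50)
  one <- data.frame(model_id = "m1", date = days, value = sin(1:50))
  expect_equal(ensemble_mean(one)$value, sin(1:50))

  two <- rbind(data.frame(model_id = "m1", date = days, value = 26),
               data.frame(model_id = "m2", date = days, value = 28))
  expect_true(all(ensemble_mean(two)$value == 27))

  set.seed(44)
  five <- do.call(rbind, lapply(1:5, function(m) {
    data.frame(model_id = paste0("m", m), date = days, value = rnorm(50))
  }))
  em <- ensemble_mean(five)
  oracle <- vapply(seq_along(days), function(i) {
    mean(five$value[five$date == days[i]])
  }, numeric(1))
  expect_equal(em$value, oracle)

  short <- rbind(data.frame(model_id = "m1", date = days, value = 1),
                 data.frame(model_id = "m2", date = days[1:30], value = 3))
  expect_warning(tr <- ensemble_mean(short), "trimmed")
  expect_equal(nrow(tr), 30)

  disjoint <- rbind(data.frame(model_id = "m1", date = days[1:20], value = 1),
                    data.frame(model_id = "m2", date = days[31:50], value = 2))
  expect_error(ensemble_mean(disjoint), "disjoint")
})

test_that("nearest grid cell is the haversine argmin with a lower-index tie rule", {
  grid <- expand.grid(lon = seq(-82, -78, 1), lat = seq(24, 27, 1))
  grid$value <- seq_len(nrow(grid))

  hit <- nearest_grid_extract(grid, lat = 25, lon = -80)
  expect_equal(hit$lat, 25); expect_equal(hit$lon, -80)

  # equidistant pair east/west of the site: lower row index wins
  tie_grid <- data.frame(lon = c(-80.5, -79.5), lat = c(25, 25), value = 1:2)
  expect_equal(nearest_grid_extract(tie_grid, 25, -80)$value, 1)

  set.seed(11)
  for (k in 1:10) {
    site <- c(runif(1, 24, 27), runif(1, -82, -78))
    d <- geosphere::distHaversine(cbind(grid$lon, grid$lat), c(site[2], site[1]))
    expect_equal(nearest_grid_extract(grid, site[1], site[2])$value,
                 grid$value[which.min(d)])
  }

  expect_warning(nearest_grid_extract(grid, 30, -80), "bounding box")

  masked <- grid; masked$value[which.min(
    geosphere::distHaversine(cbind(grid$lon, grid$lat), c(-80, 25)))] <- NA
  expect_error(nearest_grid_extract(masked, 25, -80, value_col = "value"),
               "land-masked")
  widened <- nearest_grid_extract(masked, 25, -80, value_col = "value",
                                  widen = TRUE)
  expect_false(is.na(widened$value))
})

test_that("site forcing anchors DHW, warming and acidification to the baseline", {
  cfg <- synthetic_config(seed = 2, n_models = 2)
  ens <- gen_climate_ensemble(cfg, "ssp585")
  s <- ens$sst[ens$sst$location == "bonaire", ]
  p <- ens$ph[ens$ph$location == "bonaire", ]
  f <- site_forcing(
    data.frame(model_id = s$model_id, date = s$date, value = s$sst_c),
    data.frame(model_id = p$model_id, year = p$year, value = p$ph))
  expect_true(all(f$dhw_max >= 0))
  # baseline-period means of the anomalies are centred on zero
  base <- f$year %in% 1982:2011
  expect_lt(abs(mean(f$delta_t[base])), 1e-9)
  expect_lt(abs(mean(f$delta_ph[base])), 1e-9)
  # end-of-century warming and acidification approach the scenario ramps
  expect_gt(f$delta_t[f$year == 2100], 3.5)
  expect_lt(f$delta_ph[f$year == 2100], -0.3)
})
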