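test_that("accretion integrates trapezoidally between anchor rates", {
  expect_equal(integrate_accretion(c(2020, 2070), c(2, 2), 2070), 0.1)
  # rate falling linearly 2 -> 0 over 20 yr: triangle area 20 mm = 0.020 m
  expect_equal(integrate_accretion(c(2020, 2040), c(2, 0), 2040), 0.020)
  expect_equal(integrate_accretion(c(2020, 2040), c(2, 0), 2020), 0)

  # dense Riemann-sum oracle on random anchor rates
  set.seed(9)
  anchors <- c(2020, 2040, 2060, 2100)
  for (k in 1:5) {
    raps <- rnorm(4, 1, 2)
    for (to in c(2035, 2060, 2087, 2100)) {
      tt <- seq(2020, to, by = 0.01)
      dense <- approx(anchors, raps, xout = tt)$y
      oracle <- sum((head(dense, -1) + tail(dense, -1)) / 2 * 0.01) / 1000
      expect_equal(integrate_accretion(anchors, raps, to), oracle,
                   tolerance = 1e-9)
    }
  }

  # step mode holds the previous anchor's rate
  expect_equal(integrate_accretion(c(2020, 2040), c(2, 0), 2040, "step"), 0.040)
  expect_error(integrate_accretion(c(2020, 2040), c(1, 1), 2010), "before")
  expect_error(integrate_accretion(c(2020, 2040), c(1, 1), 2150), "beyond")
})

test_that("depth increase is sea-level displacement minus accretion", {
  slr <- data.frame(year = 2020:2100, sl_m = seq(0, 0.8, length.out = 81))
  # accretion tracking SLR exactly balances
  expect_equal(depth_increase(slr, 2020, 2100, 0.8), 0)
  expect_equal(depth_increase(slr, 2020, 2100, 0.10), 0.70)
  # an eroding reef adds its framework loss to the displacement
  expect_equal(depth_increase(slr, 2020, 2100, -0.05), 0.85)
  expect_error(depth_increase(slr, 2010, 2100, 0), "span")
})

test_that("confidence envelope pairs quantiles with cover variants coherently", {
  # degenerate quantiles and identical variants collapse onto the centre
  env <- ci_envelope(0.5, slr_q5 = 0.6, slr_q95 = 0.6,
                     accr_optimistic = 0.1, accr_pessimistic = 0.1)
  expect_equal(env$lower_m, 0.5); expect_equal(env$upper_m, 0.5)

  # four-combination enumeration oracle: paired extremes are the min/max
  slr_q <- c(0.5, 0.9); acc_v <- c(0.25, 0.05)   # optimistic, pessimistic
  combos <- as.vector(outer(slr_q, acc_v, `-`))
  env <- ci_envelope(0.7 - 0.15, slr_q[1], slr_q[2], acc_v[1], acc_v[2])
  expect_equal(env$lower_m, min(combos))
  expect_equal(env$upper_m, max(combos))

  # widening the SLR fan widens the envelope monotonically
  wide <- ci_envelope(0.55, 0.4, 1.0, acc_v[1], acc_v[2])
  expect_lt(wide$lower_m, env$lower_m)
  expect_gt(wide$upper_m, env$upper_m)

  expect_error(ci_envelope(0.5, 0.9, 0.6, 0.1, 0.1), "crossing")
})

test_that("restoration adds exactly rate times elapsed time", {
  w <- small_world()
  res <- small_pipeline()
  out <- res$outcomes
  # identity when nothing is added
  out0 <- depth_outcomes(res$projections, w$slr, restoration_rate = 0)
  expect_equal(out0$restored_depth_increase_m, out0$depth_increase_m)

  # 4.8 mm/yr over the elapsed census-to-anchor interval, every site/scenario
  census <- res$projections$year[match(paste(out$site_id, out$scenario),
              paste(res$projections$site_id, res$projections$scenario))]
  elapsed <- out$anchor_year - census
  expect_equal(out$depth_increase_m - out$restored_depth_increase_m,
               4.8e-3 * elapsed)

  # a reef censused in 2020: 0.288 m over 60 yr, 0.384 m over 80 yr
  sites <- make_sites(0.5, census_year = 2020)
  slr <- data.frame(subregion = "bonaire", scenario = "s0", year = 2010:2100)
  slr$q50_m <- 0.006 * (slr$year - 2010); slr$q5_m <- slr$q50_m; slr$q95_m <- slr$q50_m
  p <- project_budget(sites, data.frame(location = "bonaire", scenario = "s0",
                                        year = 2016:2100, dhw_max = 0,
                                        delta_t = 0, delta_ph = 0),
                      cover_model(0, 0, 0), anchors = c(2040, 2080, 2100))
  o <- depth_outcomes(p, slr)
  gain <- o$depth_increase_m - o$restored_depth_increase_m
  expect_equal(gain[o$anchor_year == 2080], 0.288)
  expect_equal(gain[o$anchor_year == 2100], 0.384)
})

test_that("threshold exceedance is strict with a first-exceedance year", {
  out <- data.frame(site_id = "s1", scenario = "x",
                    anchor_year = c(2040, 2060, 2100),
                    depth_increase_m = c(0.2, 0.48, 0.9))
  ex <- threshold_exceedance(out)
  expect_equal(ex$exceeds, c(FALSE, FALSE, TRUE))
  expect_true(all(ex$first_exceed_year == 2100))

  # exactly at the boundary counts as safe
  at <- out; at$depth_increase_m <- c(0.5, 0.5, 0.5)
  expect_true(all(!threshold_exceedance(at)$exceeds))
  expect_true(all(is.na(threshold_exceedance(at)$first_exceed_year)))

  # batch scan oracle over the synthetic world
  res <- small_pipeline()
  ex <- threshold_exceedance(res$outcomes, 0.3)
  expect_equal(ex$exceeds, res$outcomes$depth_increase_m > 0.3)
})

test_that("depth, accretion and sea level satisfy the conservation identity", {
  res <- small_pipeline()
  resid <- res$outcomes$depth_increase_m + res$outcomes$accretion_m -
    res$outcomes$slr_m
  expect_lt(max(abs(resid)), 1e-9)
  expect_true(all(res$outcomes$lower_m <= res$outcomes$depth_increase_m + 1e-12))
  expect_true(all(res$outcomes$upper_m >= res$outcomes$depth_increase_m - 1e-12))
})
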