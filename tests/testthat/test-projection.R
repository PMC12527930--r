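test_that("response regressions recover exact planes and reject bad designs", {
  tab <- expand.grid(delta_t = 0:3, delta_ph = c(0, -0.2, -0.4))
  tab$component <- "coral_calcification"
  tab$response <- -0.05 * tab$delta_t
  fit <- fit_response_model(tab)
  expect_equal(fit$coef_dt, -0.05)
  expect_equal(fit$coef_dph, 0)
  expect_equal(fit$r2, 1)

  # noiseless two-predictor plane: closed-form normal-equation oracle
  tab2 <- data.frame(component = "macro_bioerosion",
                     delta_t = c(0, 1, 2, 0, 1, 2),
                     delta_ph = c(0, 0, 0, -0.3, -0.3, -0.1))
  tab2$response <- 0.02 + 0.03 * tab2$delta_t - 1.2 * tab2$delta_ph
  X <- cbind(1, tab2$delta_t, tab2$delta_ph)
  beta <- solve(t(X) %*% X, t(X) %*% tab2$response)
  fit2 <- fit_response_model(tab2)
  expect_equal(c(fit2$intercept, fit2$coef_dt, fit2$coef_dph), as.numeric(beta))

  expect_error(fit_response_model(tab2[1:2, ]), ">= 3")
  coll <- tab2; coll$delta_ph <- coll$delta_t * 2
  expect_error(fit_response_model(coll), "collinear")
})

test_that("response modifiers are proportional changes floored at zero", {
  rm <- default_response_model()
  expect_equal(response_modifier(rm, "coral_calcification", 0, 0), 1)
  m <- response_modifier(rm, "coral_calcification", 2, -0.2)
  expect_equal(m, 1 - 0.06 * 2 + 0.9 * -0.2)
  expect_equal(response_modifier(rm, "coral_calcification", 100, -1), 0)
  expect_error(response_modifier(rm, "sponge_boring", 1, 0), "no response")
})

test_that("cover trajectories follow the annual recursion with clipping", {
  dhw0 <- data.frame(year = 2020:2039, dhw_max = 0)
  flat <- cover_trajectory(30, dhw0, cover_model(0, 0, 0), 2020, 2040)
  expect_true(all(flat$cover == 30))

  # 30 - 0.5 * 4 * 10 = 10
  dhw4 <- data.frame(year = 2020:2029, dhw_max = 4)
  tr <- cover_trajectory(30, dhw4, cover_model(0, -0.5, 0), 2020, 2030)
  expect_equal(tr$cover[tr$year == 2030], 10)

  # independent step-by-step recursion oracle on random stress
  set.seed(5)
  dhw <- data.frame(year = 2020:2059, dhw_max = pmax(0, rnorm(40, 4, 4)))
  m <- cover_model(0.3, -0.12, -0.01)
  got <- cover_trajectory(25, dhw, m, 2020, 2060)
  cc <- 25
  for (y in 2020:2059) {
    cc <- min(100, max(0, cc + 0.3 - 0.12 * dhw$dhw_max[dhw$year == y] - 0.01 * cc))
  }
  expect_equal(got$cover[got$year == 2060], cc)

  # clipping keeps cover inside [0, 100]
  heavy <- cover_trajectory(5, dhw4, cover_model(0, -10, 0), 2020, 2030)
  expect_true(all(heavy$cover >= 0))
  grow <- cover_trajectory(95, dhw0, cover_model(5, 0, 0), 2020, 2040)
  expect_true(all(grow$cover <= 100))

  expect_error(cover_trajectory(30, dhw4, m, 2020, 2040), "missing DHW")
  expect_error(cover_trajectory(120, dhw4, m, 2020, 2030), "\\[0, 100\\]")
})

neutral_forcing <- function(years, scenario = "s0", location = "bonaire") {
  data.frame(location = location, scenario = scenario, year = years,
             dhw_max = 0, delta_t = 0, delta_ph = 0)
}

test_that("zero forcing with a neutral cover model reproduces the census budget", {
  sites <- make_sites(c(1.2, -0.4))
  f <- neutral_forcing(2016:2100)
  p <- project_budget(sites, f, cover_model(0, 0, 0))
  present <- site_rap(sites)
  for (a in c(2040, 2060, 2100)) {
    at <- p[p$year == a, ]
    expect_equal(at$rap_max, present$rap_max)
    expect_equal(at$cover, rep(20, 2))
    expect_equal(at$g_net, present$g_net)
  }
})

test_that("cover collapse leaves a bioerosion-dominated budget", {
  sites <- make_sites(1.5)
  sites$cca_production <- 0.4
  sites$micro_bioerosion <- 0.1
  f <- neutral_forcing(2016:2100)
  f$dhw_max <- 40   # aggressive sustained stress
  p <- project_budget(sites, f, cover_model(0, -0.5, 0))
  at2100 <- p[p$year == 2100, ]
  expect_equal(at2100$cover, 0)
  expect_equal(at2100$coral_production, 0)
  # G collapses to CCA production minus erosion, all modifiers neutral
  expect_equal(at2100$g_net,
               0.4 - sites$micro_bioerosion - sites$external_bioerosion)
})

test_that("anchor budgets match a spreadsheet-style recomposition", {
  set.seed(77)
  sites <- make_sites(1.1, census_year = 2016)
  sites$cca_production <- 0.35
  sites$micro_bioerosion <- 0.12
  sites$macro_bioerosion <- 0.3
  years <- 2016:2100
  f <- data.frame(location = "bonaire", scenario = "s1", year = years,
                  dhw_max = pmax(0, rnorm(length(years), 3, 3)),
                  delta_t = pmax(0, (years - 2005) / 95 * 3),
                  delta_ph = -pmax(0, (years - 2005) / 95 * 0.3))
  cm <- cover_model(0.3, -0.12, -0.01)
  rm <- default_response_model()
  p <- project_budget(sites, f, cm, rm)

  # independent recomputation: evolve cover, then scale each component
  cc <- 20
  for (y in 2016:2099) {
    cc <- min(100, max(0, cc + 0.3 - 0.12 * f$dhw_max[f$year == y] - 0.01 * cc))
    if ((y + 1) %in% c(2040, 2060, 2100)) {
      dt <- f$delta_t[f$year == y + 1]; dph <- f$delta_ph[f$year == y + 1]
      coral <- sites$coral_production * (cc / 20) * max(0, 1 - 0.06 * dt + 0.9 * dph)
      cca <- 0.35 * max(0, 1 - 0.04 * dt + 1.1 * dph)
      micro <- 0.12 * max(0, 1 + 0.02 * dt - 1.6 * dph)
      macro <- 0.3 * max(0, 1 + 0.03 * dt - 1.2 * dph)
      g_oracle <- coral + cca - micro - macro - sites$external_bioerosion
      expect_equal(p$g_net[p$year == y + 1], g_oracle)
    }
  }
})

test_that("dominated forcing can only worsen projected accretion", {
  sites <- make_sites(c(2, 0.5, -0.2))
  years <- 2016:2100
  mild <- data.frame(location = "bonaire", scenario = "mild", year = years,
                     dhw_max = pmax(0, (years - 2030) * 0.1),
                     delta_t = pmax(0, (years - 2010) / 90 * 1.5),
                     delta_ph = -pmax(0, (years - 2010) / 90 * 0.1))
  severe <- mild
  severe$scenario <- "severe"
  severe$dhw_max <- mild$dhw_max * 2
  severe$delta_t <- mild$delta_t * 2
  severe$delta_ph <- mild$delta_ph * 2
  p <- project_budget(sites, rbind(mild, severe))
  for (a in c(2040, 2060, 2100)) {
    expect_true(all(p$rap_max[p$scenario == "severe" & p$year == a] <=
                    p$rap_max[p$scenario == "mild" & p$year == a] + 1e-12))
  }
})

test_that("projection rejects anchors before the census", {
  sites <- make_sites(1, census_year = 2050)
  expect_error(project_budget(sites, neutral_forcing(2016:2100)),
               "census_year after first projection anchor")
})
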