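#' Configuration for the synthetic reef world
#'
#' Defines a seeded synthetic study system emulating the structure of the
#' real inputs: three tropical western Atlantic subregions with site counts
#' matching a regional census compilation (Florida 113, Mexico 88, Bonaire
#' 228; 429 sites total), four SSP scenarios with warming, acidification and
#' sea-level ramps of SSP-like magnitude, a small multi-model climate
#' ensemble, and clast-mosaic quadrat images with known true porosity.
#'
#' Subregion profiles encode the qualitative contrasts of the region:
#' Florida sites have low cover, no surviving Acropora and low external
#' bioerosion; Mexico and Bonaire retain minority Acropora-bearing sites,
#' higher cover and higher external bioerosion. Coral production scales with
#' cover at an assemblage-specific rate, so cover-accretion regressions have
#' recoverable structure, and the noise levels place a realistic share of
#' sites in net-erosional states.
#'
#' @param seed Integer master seed; all generator substreams derive from it.
#' @param n_sites Named integer vector of sites per subregion.
#' @param n_models Climate-ensemble size per scenario (default 3).
#' @param scenarios Character vector of scenario labels, ordered by severity.
#' @param warming_2100,acidification_2100 Named per-scenario magnitudes:
#'   degrees C of warming and pH-unit decline by 2100 relative to baseline.
#' @param slr_2100 Named per-scenario median sea-level displacement at 2100
#'   relative to 2010, metres.
#' @param slr_fan Fractional half-width of the 5-95% SLR quantile fan at 2100.
#' @param image_size_px Quadrat raster side in pixels (a 0.5 m quadrat).
#' @param image_noise_sd Grey-rendering intensity noise s.d. (0-255 scale).
#' @param sst_noise_sd AR(1) daily SST innovation s.d., degrees C.
#' @param sst_ar AR(1) autocorrelation of the SST weather noise.
#' @param model_offset_sd S.d. of the fixed per-model SST bias, degrees C.
#' @param ph_noise_sd Annual pH noise s.d.
#' @param seasonal_scale Multiplier on the seasonal SST amplitude (0 removes
#'   the seasonal cycle, giving an analytically flat climatology).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(
    seed = 1,
    n_sites = c(florida = 113, mexico = 88, bonaire = 228),
    n_models = 3,
    scenarios = c("ssp126", "ssp245", "ssp370", "ssp585"),
    warming_2100 = c(ssp126 = 1.5, ssp245 = 2.5, ssp370 = 3.5, ssp585 = 4.5),
    acidification_2100 = c(ssp126 = 0.10, ssp245 = 0.20, ssp370 = 0.30, ssp585 = 0.40),
    slr_2100 = c(ssp126 = 0.50, ssp245 = 0.60, ssp370 = 0.75, ssp585 = 0.85),
    slr_fan = 0.45,
    image_size_px = 256,
    image_noise_sd = 18,
    sst_noise_sd = 0.25,
    sst_ar = 0.8,
    model_offset_sd = 0.25,
    ph_noise_sd = 0.005,
    seasonal_scale = 1) {
  stopifnot(all(n_sites >= 1), n_models >= 1,
            all(scenarios %in% names(warming_2100)),
            all(scenarios %in% names(acidification_2100)),
            all(scenarios %in% names(slr_2100)),
            slr_fan >= 0)
  profiles <- list(
    florida = list(
      mean_cover = 4, sd_cover = 2.5,
      class_probs = c(massive = 0.45, submassive = 0.30, encrusting = 0.25,
                      acropora_palmata = 0, acropora_cervicornis = 0,
                      porites_branching = 0, mixed_branching_massive = 0),
      cca = 0.35, external = 0.45, micro = 0.12, macro = 0.25,
      budget_noise = 0.35
    ),
    mexico = list(
      mean_cover = 8, sd_cover = 5,
      class_probs = c(massive = 0.45, submassive = 0.20, encrusting = 0.15,
                      acropora_palmata = 0.08, acropora_cervicornis = 0.02,
                      porites_branching = 0.05, mixed_branching_massive = 0.05),
      cca = 0.35, external = 0.95, micro = 0.15, macro = 0.40,
      budget_noise = 0.55
    ),
    bonaire = list(
      mean_cover = 12, sd_cover = 6,
      class_probs = c(massive = 0.40, submassive = 0.15, encrusting = 0.10,
                      acropora_palmata = 0.08, acropora_cervicornis = 0.07,
                      porites_branching = 0.10, mixed_branching_massive = 0.10),
      cca = 0.45, external = 0.75, micro = 0.15, macro = 0.35,
      budget_noise = 0.60
    )
  )
  # solid carbonate production per percent cover (kg m-2 yr-1 per %), by class:
  # branching acroporids produce fastest, head corals slower
  prod_per_cover <- c(acropora_palmata = 0.27, acropora_cervicornis = 0.24,
                      porites_branching = 0.17, massive = 0.15,
                      submassive = 0.15, encrusting = 0.14,
                      mixed_branching_massive = 0.16, mixed = 0.15)
  structure(list(
    seed = as.integer(seed), n_sites = n_sites, n_models = n_models,
    scenarios = scenarios, warming_2100 = warming_2100,
    acidification_2100 = acidification_2100, slr_2100 = slr_2100,
    slr_fan = slr_fan, image_size_px = image_size_px,
    image_noise_sd = image_noise_sd, sst_noise_sd = sst_noise_sd,
    sst_ar = sst_ar, model_offset_sd = model_offset_sd,
    ph_noise_sd = ph_noise_sd, seasonal_scale = seasonal_scale,
    profiles = profiles,
    prod_per_cover = prod_per_cover,
    census_years = 2016:2022,
    baseline = c("1982-01-01", "2011-12-31")
  ), class = "synthetic_config")
}

# deterministic substream seed; kept well below 2^31
.substream <- function(config, offset) (config$seed %% 1000000L) * 1000L + offset

# representative species used when a class dominates a synthetic site
.class_species <- function() {
  list(
    acropora_palmata = "Acropora palmata",
    acropora_cervicornis = "Acropora cervicornis",
    porites_branching = c("Porites porites", "Porites furcata"),
    massive = c("Orbicella annularis", "Pseudodiploria strigosa",
                "Colpophyllia natans"),
    submassive = c("Siderastrea siderea", "Porites astreoides"),
    encrusting = c("Agaricia agaricites", "Millepora complanata"),
    mixed_branching_massive = c("Madracis auretenra", "Favia fragum")
  )
}

#' Generate a synthetic site census table
#'
#' Draws, for each site: a subregion-profiled total coral cover, an
#' assemblage mixture (a dominant class with ~70% share for most sites and
#' an even mixture for the rest, so both dominance-classified and mixed
#' sites occur), and carbonate budget components in which coral production
#' scales with cover at the class's production rate while bioerosion follows
#' the subregion's intensity — yielding realistic cover-budget joint
#' structure including net-erosional sites.
#'
#' @param config A [synthetic_config()].
#' @return Site data.frame with identity columns, budget components and wide
#'   `cover_` species columns (see [cover_matrix()]).
#' @export
gen_sites <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(.substream(config, 1L))
  spp_by_class <- .class_species()
  all_species <- unlist(spp_by_class, use.names = FALSE)
  rows <- list()
  for (sub in names(config$n_sites)) {
    pr <- config$profiles[[sub]]
    n <- config$n_sites[[sub]]
    for (i in seq_len(n)) {
      total <- max(0.2, stats::rnorm(1, pr$mean_cover, pr$sd_cover))
      mixed_site <- stats::runif(1) < 0.30
      covers <- stats::setNames(numeric(length(all_species)), all_species)
      if (mixed_site) {
        # spread across several classes, none above the dominance threshold
        cls <- names(pr$class_probs)[pr$class_probs > 0]
        pick <- sample(cls, min(3, length(cls)))
        shares <- rep(1 / length(pick), length(pick))
        for (j in seq_along(pick)) {
          sp <- sample(spp_by_class[[pick[j]]], 1)
          covers[sp] <- covers[sp] + total * shares[j]
        }
        dom_class <- "mixed"
      } else {
        dom_class <- sample(names(pr$class_probs), 1, prob = pr$class_probs)
        dom_share <- stats::runif(1, 0.70, 0.92)
        sp <- sample(spp_by_class[[dom_class]], 1)
        covers[sp] <- total * dom_share
        other_cls <- setdiff(names(pr$class_probs)[pr$class_probs > 0], dom_class)
        if (length(other_cls)) {
          osp <- sample(spp_by_class[[sample(other_cls, 1)]], 1)
          covers[osp] <- covers[osp] + total * (1 - dom_share)
        }
      }
      prod_rate <- config$prod_per_cover[[dom_class]]
      coral <- max(0, prod_rate * total + stats::rnorm(1, 0, pr$budget_noise))
      cca <- max(0, stats::rnorm(1, pr$cca, pr$cca * 0.3))
      micro <- max(0, stats::rnorm(1, pr$micro, pr$micro * 0.3))
      macro <- max(0, stats::rnorm(1, pr$macro, pr$macro * 0.3))
      ext <- max(0, stats::rnorm(1, pr$external, pr$external * 0.3))
      row <- data.frame(
        site_id = sprintf("%s_%03d", sub, i), subregion = sub,
        sector = sprintf("%s_sector_%d", sub, 1 + (i - 1) %% 5),
        depth_zone = sample(c("shallow", "deep"), 1, prob = c(0.8, 0.2)),
        census_year = sample(config$census_years, 1),
        coral_production = coral, cca_production = cca,
        micro_bioerosion = micro, macro_bioerosion = macro,
        external_bioerosion = ext, stringsAsFactors = FALSE
      )
      cov_df <- as.data.frame(as.list(covers))
      names(cov_df) <- cover_column(all_species)
      rows[[length(rows) + 1]] <- cbind(row, cov_df)
    }
  }
  out <- do.call(rbind, rows)
  out$location <- out$subregion
  rownames(out) <- NULL
  out
}

#' Generate a clast-mosaic quadrat image with known porosity
#'
#' Draws random rotated ellipses (coral clasts, each at least ~5 cm
#' equivalent diameter) onto a 0.5 m virtual quadrat until the framework
#' fraction lies within 0.005 of `1 - true_porosity`; overshooting proposals
#' are rejected, and proposal size shrinks as the deficit closes. The truth
#' mask is returned alongside a greyscale rendering (bright framework, dark
#' pore space, Gaussian intensity noise).
#'
#' @param true_porosity Target stacking porosity, strictly in (0, 1).
#' @param config A [synthetic_config()] (image size and noise settings).
#' @param seed Optional seed overriding the config substream.
#' @return List: `grey` (greyscale [quadrat_image()]), `truth_mask` (binary
#'   [quadrat_image()]), `achieved_porosity`.
#' @export
gen_quadrat_image <- function(true_porosity, config = synthetic_config(),
                              seed = NULL) {
  if (true_porosity <= 0 || true_porosity >= 1) {
    stop("true_porosity must lie strictly in (0, 1)")
  }
  set.seed(if (is.null(seed)) .substream(config, 2L) else seed)
  n <- config$image_size_px
  target_f <- 1 - true_porosity
  tol <- 0.005
  min_r <- 0.05 * n / 0.5 / 2          # 5 cm equivalent clast radius in px
  max_r <- 0.18 * n / 0.5 / 2
  mask <- matrix(FALSE, n, n)
  xs <- matrix(rep(seq_len(n), each = n), n)   # column index
  ys <- matrix(rep(seq_len(n), times = n), n)  # row index
  f <- 0
  attempts <- 0
  while (target_f - f > tol) {
    attempts <- attempts + 1
    if (attempts > 5000) stop("unreachable target framework fraction")
    deficit <- target_f - f
    r_cap <- max(min_r, min(max_r, sqrt(deficit * n * n / pi)))
    a <- stats::runif(1, min_r, max(min_r + 1e-9, r_cap))
    b <- a * stats::runif(1, 0.5, 1)
    th <- stats::runif(1, 0, pi)
    # centring near existing framework allows arbitrarily small net additions
    cx <- stats::runif(1, 1, n); cy <- stats::runif(1, 1, n)
    dx <- xs - cx; dy <- ys - cy
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    cand <- (u / a)^2 + (v / b)^2 <= 1
    f_new <- mean(mask | cand)
    if (f_new <= target_f + tol) {
      mask <- mask | cand
      f <- f_new
    }
  }
  truth <- quadrat_image(mask + 0, class_label = "unclassified",
                         source_id = "synthetic_truth")
  grey_px <- ifelse(mask, 200, 60) +
    stats::rnorm(n * n, 0, config$image_noise_sd)
  grey <- quadrat_image(matrix(pmin(255, pmax(0, round(grey_px))), n, n),
                        class_label = "unclassified", source_id = "synthetic_grey")
  list(grey = grey, truth_mask = truth, achieved_porosity = 1 - f)
}

#' Generate a synthetic multi-model climate ensemble for one scenario
#'
#' Daily SST per location (subregion grid point) and model from 1982-01-01
#' to 2100-12-31: a seasonal sinusoid about the subregion's mean, a warming
#' ramp accelerating after 2005 and reaching the scenario's 2100 magnitude,
#' a fixed model offset and AR(1) weather noise. Annual mean pH declines
#' along the scenario's acidification ramp. The series fully covers the
#' 1982-2011 climatology baseline.
#'
#' @param config A [synthetic_config()].
#' @param scenario Scenario label from `config$scenarios`.
#' @return List: `sst` (data.frame `location`, `model_id`, `scenario`,
#'   `date`, `sst_c`) and `ph` (data.frame `location`, `model_id`,
#'   `scenario`, `year`, `ph`).
#' @export
gen_climate_ensemble <- function(config, scenario) {
  stopifnot(inherits(config, "synthetic_config"),
            scenario %in% config$scenarios)
  sc_i <- match(scenario, config$scenarios)
  set.seed(.substream(config, 10L + sc_i))
  dates <- seq(as.Date("1982-01-01"), as.Date("2100-12-31"), by = "day")
  yearfrac <- 1982 + (as.integer(dates) - as.integer(as.Date("1982-01-01"))) / 365.25
  doy <- as.integer(format(dates, "%j"))
  ramp_s <- pmax(0, (yearfrac - 2005) / (2100 - 2005))
  warm <- config$warming_2100[[scenario]] * ramp_s^1.5
  base_mean <- c(florida = 26.5, mexico = 27.5, bonaire = 27.8)
  seas_amp <- config$seasonal_scale * c(florida = 3.0, mexico = 2.2, bonaire = 1.6)
  years <- 1982:2100
  year_s <- pmax(0, (years - 2005) / (2100 - 2005))
  sst_rows <- list(); ph_rows <- list()
  for (loc in names(config$n_sites)) {
    for (m in seq_len(config$n_models)) {
      offset <- stats::rnorm(1, 0, config$model_offset_sd)
      ar <- stats::filter(stats::rnorm(length(dates), 0, config$sst_noise_sd),
                          config$sst_ar, method = "recursive")
      sst <- base_mean[[loc]] + offset +
        seas_amp[[loc]] * cos(2 * pi * (doy - 260) / 365.25) + warm + as.numeric(ar)
      sst_rows[[length(sst_rows) + 1]] <- data.frame(
        location = loc, model_id = sprintf("model_%02d", m),
        scenario = scenario, date = dates, sst_c = sst,
        stringsAsFactors = FALSE)
      ph <- 8.05 - config$acidification_2100[[scenario]] * year_s^1.2 +
        stats::rnorm(length(years), 0, config$ph_noise_sd)
      ph_rows[[length(ph_rows) + 1]] <- data.frame(
        location = loc, model_id = sprintf("model_%02d", m),
        scenario = scenario, year = years, ph = ph, stringsAsFactors = FALSE)
    }
  }
  list(sst = do.call(rbind, sst_rows), ph = do.call(rbind, ph_rows))
}

#' Generate a synthetic sea-level-rise quantile curve
#'
#' Median displacement relative to 2010 follows a monotone
#' linear-plus-quadratic ramp reaching the scenario's 2100 magnitude (with a
#' small fixed subregion multiplier); the 5-95% quantile fan widens linearly
#' in time to `slr_fan` of the median at 2100.
#'
#' @param config A [synthetic_config()].
#' @param scenario Scenario label.
#' @param subregion Subregion name.
#' @param linear_rate_mm_yr Optional constant rate (mm yr-1); when given, the
#'   median rises linearly at this rate instead of along the scenario ramp
#'   (useful as a recent-past reference line).
#' @return Data.frame `subregion`, `scenario`, `year` (2010-2100), `q5_m`,
#'   `q50_m`, `q95_m`.
#' @export
gen_slr_curve <- function(config, scenario, subregion,
                          linear_rate_mm_yr = NULL) {
  stopifnot(inherits(config, "synthetic_config"),
            scenario %in% config$scenarios)
  sub_mult <- c(florida = 1.05, mexico = 1.00, bonaire = 0.95)
  years <- 2010:2100
  t <- years - 2010
  if (!is.null(linear_rate_mm_yr)) {
    q50 <- linear_rate_mm_yr / 1000 * t
  } else {
    target <- config$slr_2100[[scenario]] * sub_mult[[subregion]]
    if (target <= 0) stop("2100 sea-level displacement must be positive")
    r0 <- 0.003                                 # ~3 mm/yr near-present rate
    a <- (target - r0 * 90) / 90^2
    q50 <- r0 * t + a * t^2
  }
  fan <- config$slr_fan * (t / 90)
  data.frame(subregion = subregion, scenario = scenario, year = years,
             q5_m = q50 * (1 - fan), q50_m = q50, q95_m = q50 * (1 + fan),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic warming/acidification experiment table
#'
#' Emulates a compilation of laboratory responses: a factorial grid of
#' warming and acidification treatments per budget component, with the
#' proportional response drawn around the true linear surface implied by a
#' response model.
#'
#' @param config A [synthetic_config()].
#' @param truth A `response_model` giving the true coefficients (default
#'   [default_response_model()]).
#' @param noise_sd Response noise s.d. (default 0.05).
#' @param seed Optional seed overriding the config substream.
#' @return Data.frame `component`, `delta_t`, `delta_ph`, `response`.
#' @export
gen_response_table <- function(config = synthetic_config(),
                               truth = default_response_model(),
                               noise_sd = 0.05, seed = NULL) {
  set.seed(if (is.null(seed)) .substream(config, 30L) else seed)
  grid <- expand.grid(delta_t = c(0, 1, 2, 3, 4),
                      delta_ph = c(0, -0.1, -0.2, -0.3, -0.4))
  out <- do.call(rbind, lapply(truth$component, function(cp) {
    i <- match(cp, truth$component)
    resp <- truth$intercept[i] + truth$coef_dt[i] * grid$delta_t +
      truth$coef_dph[i] * grid$delta_ph +
      stats::rnorm(nrow(grid), 0, noise_sd)
    data.frame(component = cp, grid, response = resp,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Generate the full synthetic world
#'
#' All four input kinds for every scenario, plus the ground truth needed by
#' recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return List: `sites`, `climate` (per-scenario list of `sst`/`ph`),
#'   `slr` (single data.frame over subregions x scenarios),
#'   `response_table`, `truth` (response model and config echo).
#' @export
gen_world <- function(config = synthetic_config()) {
  sites <- gen_sites(config)
  climate <- stats::setNames(
    lapply(config$scenarios, function(sc) gen_climate_ensemble(config, sc)),
    config$scenarios)
  slr <- do.call(rbind, lapply(config$scenarios, function(sc) {
    do.call(rbind, lapply(names(config$n_sites), function(sub) {
      gen_slr_curve(config, sc, sub)
    }))
  }))
  rownames(slr) <- NULL
  list(sites = sites, climate = climate, slr = slr,
       response_table = gen_response_table(config),
       truth = list(response_model = default_response_model(), config = config))
}
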