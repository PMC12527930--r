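#' Read and write site tables
#'
#' Plain-CSV I/O for site census tables: one row per site, budget component
#' columns in kg CaCO3 m-2 yr-1 and wide `cover_` percent-cover columns.
#'
#' @param path CSV path.
#' @return `read_sites_csv()`: site data.frame. `write_sites_csv()`: `path`,
#'   invisibly.
#' @export
read_sites_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "subregion", "census_year", "coral_production",
            "cca_production", "micro_bioerosion", "macro_bioerosion",
            "external_bioerosion")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("site table missing column(s): ",
                            paste(missing, collapse = ", "))
  if (!"location" %in% names(df)) df$location <- df$subregion
  df
}

#' @rdname read_sites_csv
#' @param sites Site data.frame.
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(sites, path, row.names = FALSE)
  invisible(path)
}

#' Forcing table for all locations and scenarios
#'
#' Applies [site_forcing()] to every location x scenario combination of a
#' long SST/pH input pair.
#'
#' @param sst Data.frame `location`, `model_id`, `scenario`, `date`, `sst_c`.
#' @param ph Data.frame `location`, `model_id`, `scenario`, `year`, `ph`.
#' @param baseline,hotspot_floor,window_days Passed to [site_forcing()].
#' @return Data.frame `location`, `scenario`, `year`, `dhw_max`, `delta_t`,
#'   `delta_ph`.
#' @export
forcing_table <- function(sst, ph, baseline = c("1982-01-01", "2011-12-31"),
                          hotspot_floor = 0, window_days = 84) {
  combos <- unique(sst[c("location", "scenario")])
  out <- lapply(seq_len(nrow(combos)), function(i) {
    loc <- combos$location[i]; sc <- combos$scenario[i]
    s <- sst[sst$location == loc & sst$scenario == sc, ]
    p <- ph[ph$location == loc & ph$scenario == sc, ]
    f <- site_forcing(
      data.frame(model_id = s$model_id, date = s$date, value = s$sst_c),
      data.frame(model_id = p$model_id, year = p$year, value = p$ph),
      baseline, hotspot_floor, window_days)
    cbind(location = loc, scenario = sc, f, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the full accretion-to-depth pipeline
#'
#' Composes the analysis stages in order: (1) convert census budgets to
#' present-day RAPmax under the assemblage porosity scheme; (2) compute
#' site-level climate forcing (annual maximum DHW, warming, acidification)
#' from the multi-model ensemble; (3) project cover, budgets and RAPmax to
#' the anchor years under each scenario, including optimistic/pessimistic
#' cover variants for the confidence envelope; (4) integrate accretion
#' against the SLR quantile curves into water-depth outcomes with the
#' restoration counterfactual and threshold flags; (5) fit cover-accretion
#' regressions on the present-day estimates.
#'
#' @param world Input bundle as produced by [gen_world()]: `sites`,
#'   `climate` (per-scenario `sst`/`ph`), `slr`, `response_table`.
#' @param scheme Porosity scheme (default [default_porosity_scheme()]).
#' @param cov_model Central [cover_model()].
#' @param resp_model Response model; when `NULL` (default) it is fitted from
#'   `world$response_table` with [fit_response_model()].
#' @param anchors Anchor years (default 2040, 2060, 2100).
#' @param restoration_rate,threshold Passed to [depth_outcomes()].
#' @param cover_variant_scale Multipliers on the cover model's DHW slope for
#'   the (optimistic, pessimistic) envelope variants; default `c(0.5, 1.5)`.
#' @param out_dir Optional directory: writes `present_rap.csv`,
#'   `forcing.csv`, `projections.csv`, `depth_outcomes.csv`,
#'   `cover_rap_fits.csv` and `summary.json`.
#' @return List: `present` (site RAPmax table), `forcing`, `projections`,
#'   `outcomes`, `fits`, `summary` (per subregion x scenario x anchor
#'   means), `resp_model`.
#' @export
run_pipeline <- function(world, scheme = default_porosity_scheme(),
                         cov_model = cover_model(), resp_model = NULL,
                         anchors = c(2040, 2060, 2100),
                         restoration_rate = 4.8, threshold = 0.5,
                         cover_variant_scale = c(0.5, 1.5),
                         out_dir = NULL) {
  stopifnot(all(c("sites", "climate", "slr") %in% names(world)))
  sites <- world$sites
  present <- site_rap(sites, scheme)
  if (is.null(resp_model)) {
    if (is.null(world$response_table)) stop("no response model or table supplied")
    resp_model <- fit_response_model(world$response_table)
  }
  sst <- do.call(rbind, lapply(world$climate, `[[`, "sst"))
  ph <- do.call(rbind, lapply(world$climate, `[[`, "ph"))
  forcing <- forcing_table(sst, ph)

  variant <- function(scale) {
    cover_model(cov_model$beta0, cov_model$beta_dhw * scale, cov_model$beta_c0)
  }
  proj <- project_budget(sites, forcing, cov_model, resp_model, scheme, anchors)
  proj_opt <- project_budget(sites, forcing, variant(cover_variant_scale[1]),
                             resp_model, scheme, anchors)
  proj_pes <- project_budget(sites, forcing, variant(cover_variant_scale[2]),
                             resp_model, scheme, anchors)
  outcomes <- depth_outcomes(proj, world$slr, proj_opt, proj_pes,
                             restoration_rate, threshold)
  groups <- regression_groups(sites, present)
  fits <- suppressMessages(fit_cover_rap(groups, drop_small = TRUE))

  sum_key <- interaction(outcomes$subregion, outcomes$scenario,
                         outcomes$anchor_year, drop = TRUE)
  summary_df <- do.call(rbind, lapply(split(outcomes, sum_key), function(g) {
    proj_g <- proj[proj$subregion == g$subregion[1] &
                   proj$scenario == g$scenario[1] &
                   proj$year == g$anchor_year[1], ]
    data.frame(subregion = g$subregion[1], scenario = g$scenario[1],
               anchor_year = g$anchor_year[1],
               mean_rap = mean(proj_g$rap_max),
               pct_eroding = erosional_fraction(proj_g$rap_max),
               mean_depth_increase_m = mean(g$depth_increase_m),
               mean_restored_depth_m = mean(g$restored_depth_increase_m),
               pct_exceeding = 100 * mean(g$exceeds_threshold),
               stringsAsFactors = FALSE)
  }))
  rownames(summary_df) <- NULL

  res <- list(present = present, forcing = forcing, projections = proj,
              outcomes = outcomes, fits = fits, summary = summary_df,
              resp_model = resp_model)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(present, file.path(out_dir, "present_rap.csv"), row.names = FALSE)
    utils::write.csv(forcing, file.path(out_dir, "forcing.csv"), row.names = FALSE)
    utils::write.csv(proj, file.path(out_dir, "projections.csv"), row.names = FALSE)
    utils::write.csv(outcomes, file.path(out_dir, "depth_outcomes.csv"),
                     row.names = FALSE)
    utils::write.csv(fits$fits, file.path(out_dir, "cover_rap_fits.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary_df, file.path(out_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  res
}
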