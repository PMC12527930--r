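#' Annual coral-cover change model
#'
#' Linear model of the annual change in absolute percent coral cover as a
#' function of thermal stress, with current cover as a covariate:
#' `C[y+1] = clip(C[y] + beta0 + beta_dhw * DHW_max[y] + beta_c0 * C[y], 0, 100)`.
#' `beta0` is a background recovery/decline rate (% yr-1), `beta_dhw` the
#' bleaching-mortality sensitivity (% yr-1 per C-week of annual maximum DHW),
#' and `beta_c0` a density-dependence term (yr-1). Coefficients are
#' configuration, not estimates: defaults produce near-zero cover by ~2080
#' under strong-warming forcing while allowing slow recovery when thermal
#' stress is absent.
#'
#' @param beta0 Intercept, % cover per year (default 0.3).
#' @param beta_dhw Slope on annual maximum DHW, % cover per year per C-week
#'   (default -0.12).
#' @param beta_c0 Coefficient on current cover, per year (default -0.01).
#' @return Object of class `cover_model`.
#' @export
cover_model <- function(beta0 = 0.3, beta_dhw = -0.12, beta_c0 = -0.01) {
  stopifnot(is.finite(beta0), is.finite(beta_dhw), is.finite(beta_c0))
  structure(list(beta0 = beta0, beta_dhw = beta_dhw, beta_c0 = beta_c0),
            class = "cover_model")
}

#' @export
print.cover_model <- function(x, ...) {
  cat(sprintf("Cover model: dC = %.3f %+.3f*DHW %+.4f*C  (%%/yr, clipped to [0,100])\n",
              x$beta0, x$beta_dhw, x$beta_c0))
  invisible(x)
}

#' Iterate a coral-cover trajectory under annual thermal stress
#'
#' @param c0 Initial percent cover in `[0, 100]`.
#' @param dhw_max Data.frame `year`, `dhw_max` (C-weeks) covering every year
#'   from `start_year` to `end_year - 1`.
#' @param model A [cover_model()].
#' @param start_year,end_year First and last calendar years of the trajectory.
#' @return Data.frame `year`, `cover` from `start_year` to `end_year`.
#' @export
cover_trajectory <- function(c0, dhw_max, model = cover_model(),
                             start_year, end_year) {
  if (c0 < 0 || c0 > 100) stop("initial cover must be in [0, 100]")
  if (end_year < start_year) stop("end_year before start_year")
  years <- start_year:end_year
  need <- years[-length(years)]
  dhw <- dhw_max$dhw_max[match(need, dhw_max$year)]
  if (anyNA(dhw) && length(need)) {
    stop("missing DHW for year(s): ",
         paste(need[is.na(dhw)], collapse = ", "))
  }
  cov <- numeric(length(years))
  cov[1] <- c0
  for (i in seq_along(need)) {
    step <- model$beta0 + model$beta_dhw * dhw[i] + model$beta_c0 * cov[i]
    cov[i + 1] <- min(100, max(0, cov[i] + step))
  }
  data.frame(year = years, cover = cov)
}

.response_components <- c("coral_calcification", "cca_calcification",
                          "micro_bioerosion", "macro_bioerosion")

#' Fit warming/acidification response regressions
#'
#' Ordinary least squares of the proportional response of each budget process
#' (relative to present, so 0 means no change) on temperature change and pH
#' change: `response ~ delta_t + delta_ph`, fitted per component from
#' laboratory-experiment tables.
#'
#' @param experimental_table Data.frame with columns `component` (one of
#'   coral_calcification, cca_calcification, micro_bioerosion,
#'   macro_bioerosion), `delta_t` (C), `delta_ph` (pH units, negative under
#'   acidification) and `response` (proportional change).
#' @return Object of class `response_model`: a data.frame with one row per
#'   component and columns `intercept`, `coef_dt`, `coef_dph`, `r2`, `n`.
#' @export
fit_response_model <- function(experimental_table) {
  need <- c("component", "delta_t", "delta_ph", "response")
  stopifnot(all(need %in% names(experimental_table)))
  rows <- lapply(split(experimental_table, experimental_table$component),
    function(tab) {
      if (nrow(tab) < 3) {
        stop("component ", tab$component[1], ": need >= 3 experimental rows")
      }
      X <- cbind(1, tab$delta_t, tab$delta_ph)
      if (qr(X)$rank < 3) {
        stop("component ", tab$component[1], ": collinear delta_t/delta_ph design")
      }
      fit <- stats::lm(response ~ delta_t + delta_ph, data = tab)
      data.frame(component = tab$component[1],
                 intercept = unname(stats::coef(fit)[1]),
                 coef_dt = unname(stats::coef(fit)[2]),
                 coef_dph = unname(stats::coef(fit)[3]),
                 r2 = summary(fit)$r.squared,
                 n = nrow(tab))
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("response_model", "data.frame")
  out
}

#' Construct a response model directly from coefficients
#'
#' @param coefs Data.frame with columns `component`, `intercept`, `coef_dt`,
#'   `coef_dph`.
#' @return A `response_model`.
#' @export
response_model <- function(coefs) {
  stopifnot(all(c("component", "intercept", "coef_dt", "coef_dph") %in% names(coefs)))
  coefs <- as.data.frame(coefs)
  class(coefs) <- c("response_model", "data.frame")
  coefs
}

#' Default warming/acidification response coefficients
#'
#' Proportional-change sensitivities per degree of warming and per pH unit:
#' calcification declines under both warming and acidification (positive
#' `coef_dph` times a negative pH change is a loss), while endolithic
#' bioerosion accelerates under acidification. Magnitudes are set to typical
#' laboratory-derived sensitivities for Caribbean calcifiers and borers and
#' are user-replaceable configuration.
#'
#' @return A `response_model`.
#' @export
default_response_model <- function() {
  response_model(data.frame(
    component = .response_components,
    intercept = c(0, 0, 0, 0),
    coef_dt   = c(-0.06, -0.04, 0.02, 0.03),
    coef_dph  = c(0.9, 1.1, -1.6, -1.2)
  ))
}

#' Multiplicative modifier for a budget component
#'
#' `modifier = 1 + intercept + coef_dt * delta_t + coef_dph * delta_ph`,
#' floored at 0: calcification cannot turn negative (dissolution is excluded
#' from the budget framework) and erosion cannot reverse sign.
#'
#' @param model A `response_model`.
#' @param component Component name.
#' @param delta_t Warming above baseline, C.
#' @param delta_ph pH change from baseline (negative = acidification).
#' @return Non-negative multiplier (vectorised over `delta_t`/`delta_ph`).
#' @export
response_modifier <- function(model, component, delta_t, delta_ph) {
  i <- match(component, model$component)
  if (is.na(i)) stop("no response coefficients for component ", component)
  pmax(0, 1 + model$intercept[i] + model$coef_dt[i] * delta_t +
            model$coef_dph[i] * delta_ph)
}

#' Project site budgets and RAPmax to anchor years
#'
#' For each site and scenario: coral cover is evolved annually from the
#' census year under the site's annual-maximum-DHW forcing; at each anchor
#' year the budget components are rescaled — coral production by the cover
#' ratio times the coral calcification modifier, CCA production by its
#' modifier, micro/macro bioerosion by theirs, external (grazer) bioerosion
#' held static — and reassembled into a net budget, which is converted to
#' RAPmax using the site's assemblage class frozen at census assignment.
#'
#' @param sites Site table (see [site_rap()]); needs a `location` column
#'   matching `forcing$location` (defaults to `subregion` when absent).
#' @param forcing Data.frame `location`, `scenario`, `year`, `dhw_max`,
#'   `delta_t`, `delta_ph` covering census year through the last anchor.
#' @param cov_model A [cover_model()].
#' @param resp_model A `response_model`.
#' @param scheme A [porosity_scheme()].
#' @param anchors Anchor years (default 2040, 2060, 2100).
#' @param class_map Passed to [site_rap()].
#' @param mineral_density Passed to [rap_max()].
#' @return Data.frame with one row per site x scenario x year (census year,
#'   labelled `"present"` in `period`, plus each anchor): columns `site_id`,
#'   `subregion`, `scenario`, `year`, `period`, `cover`, the five budget
#'   components, `g_net` and `rap_max`.
#' @export
project_budget <- function(sites, forcing, cov_model = cover_model(),
                           resp_model = default_response_model(),
                           scheme = default_porosity_scheme(),
                           anchors = c(2040, 2060, 2100),
                           class_map = default_species_classes(),
                           mineral_density = 2.9) {
  anchors <- sort(anchors)
  if (!"location" %in% names(sites)) sites$location <- sites$subregion
  if (any(sites$census_year > min(anchors))) {
    stop("census_year after first projection anchor")
  }
  base <- site_rap(sites, scheme, class_map, mineral_density = mineral_density)
  total_cover <- rowSums(cover_matrix(sites))
  scenarios <- unique(forcing$scenario)
  out <- vector("list", length(scenarios) * nrow(sites))
  k <- 0
  for (sc in scenarios) {
    fsc <- forcing[forcing$scenario == sc, , drop = FALSE]
    for (i in seq_len(nrow(sites))) {
      floc <- fsc[fsc$location == sites$location[i], , drop = FALSE]
      if (!nrow(floc)) stop("no forcing for location ", sites$location[i],
                            " scenario ", sc)
      yr0 <- sites$census_year[i]
      span <- yr0:max(anchors)
      if (!all(span[-length(span)] %in% floc$year)) {
        stop("forcing does not cover ", yr0, "..", max(anchors),
             " for location ", sites$location[i])
      }
      traj <- cover_trajectory(total_cover[i], floc, cov_model, yr0, max(anchors))
      yrs <- c(yr0, anchors)
      cov_t <- traj$cover[match(yrs, traj$year)]
      dt <- c(0, floc$delta_t[match(anchors, floc$year)])
      dph <- c(0, floc$delta_ph[match(anchors, floc$year)])
      cover_ratio <- if (total_cover[i] > 0) cov_t / total_cover[i] else rep(0, length(yrs))
      coral <- sites$coral_production[i] * cover_ratio *
        response_modifier(resp_model, "coral_calcification", dt, dph)
      cca <- sites$cca_production[i] *
        response_modifier(resp_model, "cca_calcification", dt, dph)
      micro <- sites$micro_bioerosion[i] *
        response_modifier(resp_model, "micro_bioerosion", dt, dph)
      macro <- sites$macro_bioerosion[i] *
        response_modifier(resp_model, "macro_bioerosion", dt, dph)
      ext <- rep(sites$external_bioerosion[i], length(yrs))
      g <- coral + cca - micro - macro - ext
      k <- k + 1
      out[[k]] <- data.frame(
        site_id = sites$site_id[i], subregion = sites$subregion[i],
        scenario = sc, year = yrs,
        period = c("present", paste0("anchor_", anchors)),
        cover = cov_t, coral_production = coral, cca_production = cca,
        micro_bioerosion = micro, macro_bioerosion = macro,
        external_bioerosion = ext, g_net = g,
        class_used = base$class_used[i], porosity_used = base$porosity_used[i],
        rap_max = rap_max(g, base$porosity_used[i], mineral_density),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
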