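#' Fit cover-to-accretion regressions per assemblage group
#'
#' Ordinary least squares of site RAPmax (mm yr-1) on percent coral cover,
#' fitted separately within assemblage groups (by default the three broad
#' groups: sites with A. palmata; massive-dominated sites; and sites of
#' submassive, encrusting and small-branched taxa). The reported confidence
#' band is the 95% CI of the mean regression line, not a prediction interval.
#'
#' @param data Data.frame with columns `group`, `cover` (percent) and `rap`
#'   (mm yr-1), typically built with [regression_groups()].
#' @param drop_small If TRUE, groups with fewer than 3 sites are dropped with
#'   a message instead of raising an error (used by the pipeline on small
#'   datasets).
#' @return Object of class `cover_rap_fits`: a list with `fits` (data.frame:
#'   `group`, `slope`, `intercept`, `r2`, `n`, `slope_se`) and `models`
#'   (the underlying `lm` objects, for CI bands via [predict_cover_rap()]).
#' @export
fit_cover_rap <- function(data, drop_small = FALSE) {
  stopifnot(all(c("group", "cover", "rap") %in% names(data)))
  data <- data[is.finite(data$cover) & is.finite(data$rap), , drop = FALSE]
  groups <- split(data, data$group)
  if (drop_small) {
    small <- names(groups)[vapply(groups, nrow, integer(1)) < 3]
    if (length(small)) {
      message("dropping group(s) with < 3 sites: ", paste(small, collapse = ", "))
      groups <- groups[setdiff(names(groups), small)]
    }
    if (!length(groups)) stop("no group has >= 3 sites")
  }
  models <- lapply(groups, function(g) {
    if (nrow(g) < 3) stop("group ", g$group[1], ": need >= 3 sites")
    if (stats::var(g$cover) == 0) stop("group ", g$group[1], ": constant cover, degenerate fit")
    stats::lm(rap ~ cover, data = g)
  })
  fits <- do.call(rbind, lapply(names(models), function(nm) {
    m <- models[[nm]]
    s <- summary(m)
    data.frame(group = nm, slope = unname(stats::coef(m)[2]),
               intercept = unname(stats::coef(m)[1]),
               r2 = s$r.squared, n = length(stats::fitted(m)),
               slope_se = s$coefficients["cover", "Std. Error"],
               stringsAsFactors = FALSE)
  }))
  structure(list(fits = fits, models = models), class = "cover_rap_fits")
}

#' @export
print.cover_rap_fits <- function(x, ...) {
  f <- x$fits
  for (i in seq_len(nrow(f))) {
    cat(sprintf("%s: rap = %.4f*cover %+.4f  (r2 = %.3f, n = %d)\n",
                f$group[i], f$slope[i], f$intercept[i], f$r2[i], f$n[i]))
  }
  invisible(x)
}

#' Mean regression line with 95% confidence band
#'
#' @param fits A [fit_cover_rap()] result.
#' @param group Group label.
#' @param cover Percent cover values at which to evaluate.
#' @return Data.frame `cover`, `fit`, `lwr`, `upr` (mm yr-1).
#' @export
predict_cover_rap <- function(fits, group, cover) {
  stopifnot(inherits(fits, "cover_rap_fits"))
  m <- fits$models[[group]]
  if (is.null(m)) stop("no fit for group ", group)
  p <- stats::predict(m, newdata = data.frame(cover = cover),
                      interval = "confidence", level = 0.95)
  data.frame(cover = cover, fit = p[, "fit"], lwr = p[, "lwr"], upr = p[, "upr"])
}

#' Invert a cover-accretion fit for a target accretion rate
#'
#' Solves `target = slope * cover + intercept` for the percent cover needed
#' to sustain a target RAPmax (for example, the cover needed to approach
#' region-typical long-term accretion of ~5 mm yr-1).
#'
#' @param fit Either a [fit_cover_rap()] result plus `group`, or a list/row
#'   with numeric `slope` and `intercept`.
#' @param target_rap Target accretion, mm yr-1.
#' @param group Group label when `fit` is a `cover_rap_fits`.
#' @return Percent cover (with a warning when outside `[0, 100]`).
#' @export
#' @examples
#' invert_for_target(list(slope = 0.1457, intercept = -0.3347), 5)
invert_for_target <- function(fit, target_rap, group = NULL) {
  if (inherits(fit, "cover_rap_fits")) {
    row <- fit$fits[fit$fits$group == group, ]
    if (!nrow(row)) stop("no fit for group ", group)
    slope <- row$slope; intercept <- row$intercept
  } else {
    slope <- fit$slope; intercept <- fit$intercept
  }
  if (!is.finite(slope) || slope == 0) stop("zero slope: cannot invert")
  cover <- (target_rap - intercept) / slope
  if (cover < 0 || cover > 100) {
    warning(sprintf("required cover %.1f%% lies outside [0, 100]", cover))
  }
  cover
}

#' Build regression groups from site classes
#'
#' Maps per-site assemblage classes to the three broad regression groups:
#' any site with A. palmata cover joins `"a_palmata"`; otherwise
#' massive-dominated sites join `"massive"`; all remaining sites join
#' `"submassive_encrusting_branched"`.
#'
#' @param sites Site table.
#' @param raps Output of [site_rap()] for the same sites.
#' @return Data.frame `site_id`, `group`, `cover` (total percent coral
#'   cover), `rap`.
#' @export
regression_groups <- function(sites, raps) {
  covers <- cover_matrix(sites)
  total <- rowSums(covers)
  apal <- if ("Acropora palmata" %in% colnames(covers)) {
    covers[, "Acropora palmata"] > 0
  } else rep(FALSE, nrow(sites))
  group <- ifelse(apal, "a_palmata",
                  ifelse(raps$class_used == "massive", "massive",
                         "submassive_encrusting_branched"))
  data.frame(site_id = sites$site_id, group = group, cover = total,
             rap = raps$rap_max, stringsAsFactors = FALSE)
}
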