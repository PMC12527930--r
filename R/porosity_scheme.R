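#' Coral-assemblage stacking-porosity scheme
#'
#' A porosity scheme maps coral-assemblage classes to framework stacking
#' porosity fractions. Stacking porosity is the void fraction added when the
#' skeletal carbonate produced by an assemblage accumulates post-mortem into
#' reef framework; it is the conversion factor between solid-equivalent
#' carbonate thickness and realised vertical accretion.
#'
#' @param class_porosity Named numeric vector of porosity fractions, each in
#'   `[0, 1)`. Must contain a `"mixed"` entry, used for sites with no single
#'   dominant assemblage.
#' @param scheme_name Single string identifying the scheme.
#'
#' @return An object of class `porosity_scheme`: a named numeric vector with a
#'   `scheme_name` attribute.
#' @seealso [default_porosity_scheme()], [assign_assemblage_class()], [rap_max()]
#' @export
#' @examples
#' porosity_scheme(c(acropora_palmata = 0.369, mixed = 0.383), "example")
porosity_scheme <- function(class_porosity, scheme_name = "unnamed") {
  if (!is.numeric(class_porosity) || is.null(names(class_porosity)) ||
      any(!nzchar(names(class_porosity)))) {
    stop("`class_porosity` must be a fully named numeric vector")
  }
  if (anyNA(class_porosity) || any(class_porosity < 0) || any(class_porosity >= 1)) {
    stop("porosities must lie in [0, 1)")
  }
  if (!"mixed" %in% names(class_porosity)) {
    stop("scheme must contain a \"mixed\" class entry")
  }
  structure(class_porosity, scheme_name = as.character(scheme_name)[1],
            class = "porosity_scheme")
}

#' @export
print.porosity_scheme <- function(x, ...) {
  cat("Porosity scheme:", attr(x, "scheme_name"), "\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Default tropical western Atlantic porosity scheme
#'
#' Assemblage-specific stacking porosities for the seven shallow-water coral
#' assemblage classes common on tropical western Atlantic reefs, plus the
#' pooled `"mixed"` class applied to highly mixed assemblages. The three
#' branching classes carry the fossil-outcrop image-derived values
#' (A. palmata 0.369, A. cervicornis 0.554, branching Porites 0.473); the
#' massive/submassive/encrusting head-coral classes default to values inside
#' the 0.25-0.35 band typical of denser head-coral framework, chosen so the
#' unweighted mean of the seven class means equals the pooled mixed value
#' 0.383. The head-coral defaults are synthetic placeholders and should be
#' overridden with measured values where available.
#'
#' @return A [porosity_scheme()] with eight entries.
#' @export
#' @examples
#' default_porosity_scheme()
default_porosity_scheme <- function() {
  porosity_scheme(c(
    acropora_palmata        = 0.369,
    acropora_cervicornis    = 0.554,
    porites_branching       = 0.473,
    massive                 = 0.260,
    submassive              = 0.310,
    encrusting              = 0.340,
    mixed_branching_massive = 0.375,
    mixed                   = 0.383
  ), scheme_name = "twa_assemblage_2024")
}

#' Uniform legacy porosity scheme
#'
#' The single-value 50% stacking porosity historically applied to all reef
#' assemblages before assemblage-specific values were available. Useful as the
#' comparison scheme in [compare_porosity_schemes()].
#'
#' @param porosity Porosity fraction applied to every class (default 0.5).
#' @return A [porosity_scheme()].
#' @export
uniform_porosity_scheme <- function(porosity = 0.5) {
  classes <- names(default_porosity_scheme())
  porosity_scheme(stats::setNames(rep(porosity, length(classes)), classes),
                  scheme_name = sprintf("uniform_%g", porosity))
}

#' Default species-to-assemblage-class map
#'
#' Maps common tropical western Atlantic shallow-water coral species and
#' morphotype groups to the assemblage classes of
#' [default_porosity_scheme()]. Any species name used in a site's cover vector
#' must appear here (or in a user-supplied map) before class assignment.
#'
#' @return A data.frame with columns `species` and `class_label`.
#' @export
default_species_classes <- function() {
  data.frame(
    species = c(
      "Acropora palmata",
      "Acropora cervicornis",
      "Porites porites", "Porites furcata",
      "Orbicella annularis", "Orbicella faveolata", "Montastraea cavernosa",
      "Colpophyllia natans", "Pseudodiploria strigosa", "Diploria labyrinthiformis",
      "Siderastrea siderea", "Porites astreoides", "Dichocoenia stokesii",
      "Agaricia agaricites", "Agaricia tenuifolia", "Millepora complanata",
      "Madracis auretenra", "Favia fragum"
    ),
    class_label = c(
      "acropora_palmata",
      "acropora_cervicornis",
      "porites_branching", "porites_branching",
      "massive", "massive", "massive",
      "massive", "massive", "massive",
      "submassive", "submassive", "submassive",
      "encrusting", "encrusting", "encrusting",
      "mixed_branching_massive", "mixed_branching_massive"
    ),
    stringsAsFactors = FALSE
  )
}

#' Read a porosity scheme from a YAML file
#'
#' Expects a mapping `scheme_name: <text>` plus `class_porosity: {class: value}`
#' with porosities either as fractions in `[0,1)` or percentages in `[1,100)`
#' (values > 1 are interpreted as percent and divided by 100).
#'
#' @param path Path to a YAML file.
#' @return A [porosity_scheme()].
#' @export
read_porosity_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$class_porosity)) stop("YAML must contain `class_porosity`")
  vals <- unlist(raw$class_porosity)
  vals <- ifelse(vals > 1, vals / 100, vals)
  porosity_scheme(vals, scheme_name = raw$scheme_name %||% basename(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
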