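# Shared fixtures, computed once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small synthetic world: quick module-level checks
small_world <- function() {
  fixture("small_world", function() {
    gen_world(synthetic_config(seed = 11,
                               n_sites = c(florida = 6, mexico = 5, bonaire = 8)))
  })
}

small_pipeline <- function() {
  fixture("small_pipeline", function() run_pipeline(small_world()))
}

# full-size synthetic world at the study's site counts, for the
# whole-system checks (conservation, restoration, scenario ordering)
full_pipeline <- function() {
  fixture("full_pipeline", function() {
    run_pipeline(gen_world(synthetic_config(seed = 42)))
  })
}

# a minimal hand-built site table with controllable budgets
make_sites <- function(g_targets, species = "Orbicella annularis",
                       subregion = "bonaire", census_year = 2020,
                       cover = 20) {
  n <- length(g_targets)
  df <- data.frame(
    site_id = sprintf("s%02d", seq_len(n)), subregion = subregion,
    sector = "sec1", depth_zone = "shallow", census_year = census_year,
    # put the whole signed budget in coral production vs external erosion
    coral_production = pmax(g_targets, 0) + 1,
    cca_production = 0, micro_bioerosion = 0, macro_bioerosion = 0,
    external_bioerosion = 1 - pmin(g_targets, 0),
    stringsAsFactors = FALSE
  )
  df[[cover_column(species)]] <- cover
  df$location <- df$subregion
  df
}
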