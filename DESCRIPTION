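Package: reefrap
Title: Coral Reef Carbonate Budgets, Accretion Potential and Sea-Level Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts coral-reef carbonate budgets (kg CaCO3 m-2 yr-1) into maximum
    vertical reef accretion potential (RAPmax, mm yr-1) using coral-assemblage-specific
    framework stacking porosities estimated from virtual-quadrat images of fossil reef
    outcrops. Projects coral cover, carbonate budget components and RAPmax to 2100
    under SSP climate scenarios via degree-heating-week thermal stress and
    warming/acidification response regressions, integrates projected accretion against
    sea-level-rise quantile curves to obtain above-reef water-depth increases with
    confidence envelopes, and evaluates a restoration counterfactual. Includes a
    seeded synthetic-data generator emulating all input kinds with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    geosphere,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0),
    tiff,
    knitr,
    ggplot2
Config/testthat/edition: 3
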