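Package: morp
Title: Enzyme-Constrained Metabolic Modeling with Minimal Proteome Reallocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constraint-based modeling of enzyme-constrained (GECKO-style)
    metabolic networks with a focus on proteome reallocation. Provides flux
    balance analysis with selectable objectives, minimization of total
    proteome, and MORP (minimization of reallocation of proteome, an L1
    objective on enzyme-usage fluxes relative to a reference condition);
    dynamic flux balance analysis by the static optimization approach with
    Monod substrate uptake and objective-switching phase schedules, including
    the dynamic variant dMORP with a rolling enzyme-usage reference;
    hit-and-run sampling of the flux polytope; SBML and JSON model I/O; and a
    synthetic lactic-acid-bacterium central-carbon model with competing
    homolactic and heterolactic fermentation routes for testing and
    demonstration. Results are returned as tidy tibbles with broom-style
    tidiers and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
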