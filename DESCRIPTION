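Package: pollinet
Title: Persistence of Plant-Pollinator Networks Under Habitat Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the population dynamics of bipartite plant-pollinator
    networks under a mutualistic Lotka-Volterra model with a type-II
    (saturating) functional response, and estimates species- and
    network-level persistence across stochastic parameter draws. Provides
    the network-structure and centrality metrics commonly used as
    persistence predictors (NODF nestedness, spin-glass modularity,
    weighted closeness, Bluethgen specialisation d'), data-preparation
    rules for monthly bipartite visitation networks (guild filtering,
    largest-component restriction, seasonal pooling), and a synthetic
    generator that emulates a restored/unrestored x early/late-season
    study design with a dominant invasive generalist plant. Results are
    returned as tidy tables ready for downstream mixed-model analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    igraph,
    vegan,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
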