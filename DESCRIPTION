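Package: larvforage
Title: Trait-Based Foraging and Growth Modelling for Marine Fish Larvae
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A deterministic, trait-based individual-based model of foraging
    and growth in young marine fish larvae. Larval types are defined by a
    short list of biological traits; prey are idealized as a normalized
    biomass size spectrum; foraging follows a mechanistic predation sequence
    (encounter, observation, pursuit, capture) with optimal diet selection
    under a Holling disk equation, including turbulence-mediated encounter
    and pursuit effects; growth is resolved as a 24-hour bioenergetic budget
    with Q10 temperature corrections. Ships parameterizations for young
    anchovy, cod, herring and sprat larvae, plus experiment drivers for
    growth potential, starvation/satiation points, prey requirements,
    parameter-perturbation sensitivity ranges and optimal foraging analyses.
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
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
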