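Package: marshstocks
Title: Blue Carbon and Nutrient Stock Accounting for Salt Marshes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stock accounting of carbon, nitrogen and phosphorus in salt-marsh
    ecosystems. Computes per-area element stocks in halophyte biomass and
    rhizosediment, annual production by the max-minus-min range of per-date
    replicate means, and coverage-weighted upscaling of per-area stocks to
    water-body and lagoon totals partitioned into low and mid-high marsh.
    Includes a from-scratch metric ordination toolkit (Euclidean distances,
    principal coordinates analysis, weighted-average variable scores and a
    one-way permutational MANOVA) for seasonal multivariate dynamics, and a
    seeded synthetic field-survey generator emulating a bimonthly replicated
    sampling design so every pipeline stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    dplyr,
    graphics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
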