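Package: invexpect
Title: Expected Versus Observed Nonindigenous Species from Shipping Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A null-model pipeline for ballast-water mediated biological
    invasions. Computes per-route, per-port-pair and per-region invasion
    probabilities from ship port-call logs (probability of being
    nonindigenous, of introduction, and of establishment), estimates donor
    region species richness from equal-area coastal grids, derives expected
    numbers of nonindigenous species (NIS) per donor-recipient region pair,
    and compares them with observed counts from curated NIS checklists using
    chi-square goodness-of-fit tests. Includes checklist analytics
    (fractional native-range attribution, taxonomic composition, subregion
    overlap) and a seed-reproducible synthetic-world generator for
    end-to-end testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
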