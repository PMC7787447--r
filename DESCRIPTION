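Package: geosift
Title: Extract, Filter and Geocode Relevant Locations from Scientific Articles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A fully automatic pipeline for mining the geographic information
    that matters in scientific full text: where field work was performed,
    where patients were treated, where samples were collected. Articles
    (JATS/NLM-style XML or plain text) are parsed into a common document
    model; methods and study-site sections are targeted via configurable
    heading patterns; named-entity output is chunked into location candidates
    with sentence context; rule-based filters remove company addresses,
    citations and other irrelevant mentions; cleaned location strings are
    geocoded against a pluggable backend, with a bundled deterministic
    offline gazetteer. Includes location-unit and article-unit
    precision/recall/F1 evaluation with an error taxonomy, GeoJSON and
    tabular outputs, and a seeded synthetic-corpus generator so the whole
    pipeline is testable offline.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stringi,
    stringr,
    tibble,
    tidyr,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
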