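Package: coral
Title: Promiscuous Enzyme Subpools in Protein-Constrained Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Restructures enzyme-constrained (GECKO-style) genome-scale
    metabolic models so that each promiscuous enzyme's resource pool is
    split into per-reaction subpools ordered by catalytic efficiency
    (MW/kcat), and runs the downstream optimization analyses: flux and
    subpool-usage variability analysis, parsimonious wild-type subpool
    allocation, single and pairwise blocking of main and side activities,
    conventional double gene knockouts, and metabolite-centric flux-sum
    analysis. Includes readers and writers for community JSON and SBML
    (level 3, FBC) models, TSV enzyme tables, underground-reaction tables
    and a documented YAML dialect for restructured models, plus a synthetic
    fixture generator and an independent dense-LP oracle so every analysis
    is testable on small models.
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
    stringr,
    tibble,
    tidyr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
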