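Package: ddinet
Title: Drug-Drug Interaction Burden and Network Analysis for Polypharmacy Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Profiles potential drug-drug interactions (DDIs) in patient
    cohorts against a severity-annotated interaction knowledge base, derives
    per-patient burden and risk strata, aggregates cohort-level severity and
    prevalence statistics with exact binomial confidence intervals, and
    builds a severity-weighted undirected drug-interaction network with a
    full graph-metric suite (degree, betweenness, closeness, eigenvector
    centrality, clustering, components, density) for hub-drug
    identification. Includes a seeded synthetic cohort generator emulating
    hospitalized cardiovascular polypharmacy so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
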