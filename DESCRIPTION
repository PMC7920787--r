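Package: sban
Title: Social-Behavioral Association Networks for Waterbird Communities
Version: 0.1.0
Authors@R:
    person("SBAN", "Developers", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Builds social-behavioral association networks (SBANs) from
    activity-based species abundance observations: daily selection events are
    filtered to the richest event per site and day, pivoted into per-stratum
    (regime x habitat) abundance matrices over a fixed universe of
    (species, behavior-class) nodes, and turned into undirected weighted
    networks by Pearson correlation with a sign policy and edge thresholding.
    Provides species (SIPS) and behavioral (BIPS) interaction preference
    scores, hub-centrality and PageRank keystone-species rankings on the
    cutoff-simplified network, a two-way fixed-effects ANOVA with Fisher's
    LSD post hoc to compare network attributes across management regimes and
    habitats, and a negative-binomial community simulator with plantable
    block-correlation structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
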