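Package: proxnet
Title: Social Network Analysis of Group-Scan Proximity Data
Version: 0.1.0
Authors@R:
    person("GRACE", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds weighted social networks from group-scan proximity
    records of animal groups and analyses their structure. Collapses
    repeated daily scans into visibility-aware dyadic states, computes
    simple-ratio association indices, weighted network statistics
    (density, strength, eigenvector centrality), rank-based matrix
    correlations with node-label permutation nulls (Dietz R), Newman
    modularity community detection by leading-eigenvector bisection,
    and a random-versus-scale-free network classification via AIC of
    linear and power regressions of centrality on reverse rank. Includes
    a seeded generator of synthetic scan datasets with known ground
    truth for end-to-end validation, and exporters for GraphML and
    weighted edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
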