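Package: mesendosim
Title: Cellular-Potts Simulation of Collective Mesendoderm Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-dimensional Cellular-Potts (Glazier-Graner-Hogeweg)
    agent-based model of collectively migrating Xenopus mesendoderm.
    Leader and follower cell agents carry elastic cell-cell and
    cell-substrate links and constant-tension lamellipodium links with
    Poisson extension-retraction turnover; a direction-agnostic
    cohesotaxis rule biases lamellipodial protrusion away from cell-cell
    contacts, and stochastic cell-cell link turnover permits passive
    radial intercalation. Provides builders for dorsal-marginal-zone
    (DMZ) and four-explant in-the-round (ITR) geometries, migration and
    gap-closure metrics, and seeded in-silico experiments (parameter
    sensitivity sweep, cohesotaxis sweep, intercalation sweep,
    lamellipodia-blocking retraction).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
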