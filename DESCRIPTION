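Package: hepasim
Title: Discrete-Event Monte Carlo Simulation of Hepatic Drug Disposition in
    Virtual Hepatocyte Cultures and Virtual Livers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Paired virtual systems for studying in vitro-to-in vivo
    extrapolation (IVIVE) of hepatic clearance: a virtual hepatocyte culture
    and a virtual human liver built from Monte Carlo-sampled lobule flow
    graphs of sinusoidal segments. Mobile compound objects move by biased
    random walks through concentric sinusoidal grids, enter and exit virtual
    hepatocytes stochastically, and may be bound and metabolized by enzyme
    objects. The package runs seeded discrete-event executions, averages
    experiments over Monte Carlo replicates, and derives per-hepatocyte entry
    rates, extraction ratios, periportal-to-pericentral exposure gradients,
    and cross-system (culture vs. liver) prediction fold-ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
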