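Package: fieldCA
Title: Hybrid Cellular-Automaton Simulation of the Cancer Field Effect
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates field cancerization in carcinogen-exposed epithelium
    with a hybrid cellular automaton: six cell classes on a toroidal lattice
    whose per-cell gene expressions evolve through a small multi-layer
    perceptron driven by carcinogen exposure and cell age, coupled to
    phenotype-probability dynamics, a cancer stem-cell hierarchy with
    transit-amplifying cells, tumor excision experiments, and clonal lineage
    tracking. Ships a 10-gene head-and-neck squamous cell carcinoma panel
    and supports user-defined gene panels, carcinogen fields and schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
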