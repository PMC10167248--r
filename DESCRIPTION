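Package: nrwatershed
Title: Watershed Reactive-Nitrogen Export, Hotspots, Drivers, and Land-Use Scenarios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for reactive-nitrogen (Nr) loss analysis in
    lowland watersheds. Implements a nutrient-delivery-ratio (NDR) mass-balance
    export model on D8-routed terrain (load partitioning, downslope retention,
    connectivity-modulated surface delivery, subsurface delivery, K calibration),
    Getis-Ord Gi* cold/hot-spot mapping on a coarse analysis lattice, driver
    attribution by the geographical-detector q-statistic with optimal
    discretization of continuous drivers, moving-window landscape metrics
    (SHDI, CONTAG, AI, MESH, class proportions, river density), and
    Markov-chain / cellular-automata land-use scenario projection with Nr
    re-evaluation. A seeded synthetic-watershed generator supplies complete
    inputs so every stage runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
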