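Package: stationopt
Title: Health Station Location Optimization by Random-Swap Clustering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Optimizes the placement of primary-care health stations over a
    set of geocoded patient locations, treating facility location as a
    clustering problem. Implements the random-swap clustering algorithm with
    three objective functions (Euclidean distance, squared Euclidean
    distance, and per-visit patient travel cost), an overhead-graph
    estimator that approximates road-network travel distance and time with a
    single table lookup, a rule-based travel-mode and travel-cost model
    (walk, taxi, bus, car), centroid-index cluster validation against known
    hub locations, and accessibility reports comparing station
    configurations. Includes a seeded synthetic-region generator producing
    patients, a road network with obstacles, bus stops and candidate
    buildings, so the whole pipeline runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
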