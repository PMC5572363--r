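Package: cosegmap
Title: Co-Segregating Markers and Map Inflation in High-Density Linkage Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify and predict the inflation of high-density
    genetic map length caused by co-segregating markers in doubled haploid
    (DH) biparental populations. Includes a DH genotype simulator with known
    ground truth, a linkage-mapping core (recombination-fraction estimation,
    linkage grouping, minimum-spanning-tree marker ordering with 2-opt
    refinement, Haldane/Kosambi distances, double-recombinant correction),
    skeleton-map construction from co-segregation clusters, sequential-map
    resampling experiments that measure the map inflation factor and
    marker-order collinearity, and a suite of regression learners that
    predict inflation from the proportion of co-segregating markers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    Rcpp,
    rpart,
    randomForest,
    e1071,
    caret,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
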