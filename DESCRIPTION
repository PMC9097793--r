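Package: divscape
Title: Multi-Species Genetic Diversity and Divergence Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Landscape genetics of plastid (cpDNA) haplotype data across
    many co-occurring plant species. Computes population genetic statistics
    (Nei's unbiased haplotype diversity, nucleotide diversity, AMOVA-based
    pairwise Phi-ST), interpolates per-species and multi-species genetic
    diversity and divergence surfaces by inverse-distance weighting on a
    geographic grid, delineates genetic-diversity hotspots and their overlap
    with protected areas, tests isolation by distance with Mantel
    permutation tests, and attributes diversity to climatic, topographic and
    anthropogenic variables via collinearity filtering, random-forest
    importance screening, generalized additive models and variation
    partitioning with adjusted R-squared. Includes a synthetic-study
    generator with planted spatial structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    igraph,
    jsonlite,
    mgcv,
    randomForest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
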