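Package: paravec
Title: Multivariate Vector Analysis of Gut Microbiota (Non)Parallelism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies parallelism and nonparallelism of host-associated
    microbial communities with multivariate vector analysis. From a feature
    abundance table, per-sample host metadata and an ultrametric host tree,
    the package filters samples and species, computes Bray-Curtis
    dissimilarities and principal coordinates, builds species-level
    divergence vectors in the retained ordination space, and measures the
    direction (angles between vectors) and magnitude (vector lengths) of
    community change between host-species pairs. Comparisons are classified
    by parallel versus nonparallel shifts in host trophic ecology,
    phylogenetically constrained quartets separate ecology- from
    phylogeny-driven parallelism, and a statistics layer provides the group
    tests and trend models used to relate parallelism to host divergence
    time. A synthetic-data generator simulates diet-structured,
    phylogenetically correlated communities so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    mgcv,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    biomformat
Config/testthat/edition: 3
RoxygenNote: 7.3.3
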