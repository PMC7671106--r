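Package: dietmorph
Title: Trait-Based Dietary Niche Categorization and Feeding Ecomorphology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for deriving "synthetic" dietary niche categories from
    functional traits of prey, classifying the primary diet of predator
    species from stomach-content importance data, computing functional jaw
    characters from linear cranial measurements, and relating diet to
    morphology on a phylogeny. Implements hierarchical clustering of prey
    items with within-groups sum-of-squares model selection, importance
    aggregation and argmax diet assignment with explicit tie handling,
    jaw-lever mechanical advantage ratios, principal component analysis with
    broken-stick axis retention, phylomorphospace projection, phylogenetic
    MANOVA with a Brownian-motion simulated Wilks null, single-rate Markov
    (Mk) ancestral state reconstruction, and discriminant re-classification
    of diet from morphology. Includes seeded generators for birth-death
    trees, Brownian traits with group shifts, Dirichlet diet profiles, and
    block-structured binary prey-trait matrices, so the full pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    MASS,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phytools,
    vegan,
    yaml,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
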