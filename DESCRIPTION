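Package: bioturb
Title: Reaction-Transport and Community Analysis of Bioturbated
    Intertidal Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying how burrowing macrofauna (lugworms)
    rework intertidal sands and restructure their microbial communities.
    Implements a one-dimensional finite-volume porewater model in which
    physical flushing and bioirrigation enter as depth-dependent nonlocal
    exchange terms, a solid-phase pigment tracer model with physical and
    biological biodiffusion, and inversion routines that attribute mixing
    to physics (defaunated plots) versus fauna (refaunated plots).  Also
    provides the derived geochemical indices (pigment freshness, domain
    rRNA gene ratios, functional-gene fractions, sediment zonation,
    feeding intensity from grain-size differences), community-structure
    statistics written from first principles (rarefaction, weighted and
    unweighted UniFrac, principal coordinates analysis, PERMANOVA, and
    canonical analysis of principal coordinates), class-level Spearman
    co-occurrence networks with hierarchical cluster extraction,
    interdomain distance-correlation tests, and a seeded synthetic-data
    generator that emulates the full study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    jsonlite,
    lhs,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    phyloseq,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
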