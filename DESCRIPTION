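Package: pksretro
Title: Retro-Biosynthetic Analysis of Modular Type I Polyketide Assembly Lines
Version: 0.1.0
Authors@R:
    person("pksretro", "maintainers", email = "pksretro@example.org",
           role = c("aut", "cre"))
Description: Tools for reasoning about modular type I polyketide synthase
    (PKS) gene clusters and stable-isotope feeding experiments. Predicts the
    linear polyketide product of a cluster from its module and domain
    organization (acyltransferase substrate signatures, ketoreductase
    stereochemistry fingerprints, dehydratase/enoylreductase activity),
    computes per-carbon 13C enrichment ratios from NMR intensity tables,
    infers the precursor-unit tiling of a compound's carbon skeleton from the
    labeling pattern, flags carbon-carbon bonds formed after chain assembly,
    and reconciles the gene-based prediction with the isotope-based
    inference. Includes seeded generators of synthetic clusters, products,
    carbon graphs and noisy enrichment tables for end-to-end testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
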