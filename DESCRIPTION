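Package: ibdlayers
Title: Dating Cultural Exchange from Ancestry-Layered Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes admixed hunter-gatherer genomes into ancestry layers of
    different antiquity (full genome, hunter-gatherer ancestry only, hunter-gatherer
    ancestry minus recently exchanged identity-by-descent segments, farmer ancestry
    only), computes layer-specific Hudson FST genetic distances, correlates them with
    cultural, ecological, geographic and linguistic distance matrices via permutation
    statistics (Mantel, multiple matrix regression, CADM), and classifies the timing
    of cultural exchange. Includes readers and writers for the standard file formats
    involved (phased VCF, PLINK-style genetic maps, local-ancestry and IBD segment
    tables, trait/biome/coordinate/cognate tables, NEXUS distance blocks), a
    synthetic-cohort generator with known ancestry tracts and implanted
    identity-by-descent segments for validation, and a zero-inflated Poisson
    framework for shared-lexicon counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    stats,
    utils,
    vcfR
Suggests:
    cluster,
    glmmTMB,
    jsonlite,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
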