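Package: knobscan
Title: Heterochromatic Knob Marker Association Mapping in Maize
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of small maize panels segregating for
    heterochromatic knob loci (K3L, K5L, K7S, K9S). Provides a selfing-pedigree
    genotype simulator with hybrid crosses, replicate-level phenotype simulation
    for male/female flowering time and flow-cytometry genome size, BLUE and
    entry-mean heritability estimation, an exact single-locus mixed linear model
    (EMMA-style REML with a VanRaden kinship) under additive and
    heterozygous-(dis)advantage marker encodings, and a phenotype-permutation
    significance threshold, together with a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    lme4,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
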