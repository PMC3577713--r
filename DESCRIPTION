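Package: trflptools
Title: T-RFLP Community Fingerprint Processing and Clone Library Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and statistical analysis of terminal-restriction
    fragment length polymorphism (T-RFLP) fingerprints of microbial
    communities: duplicate-run consensus, size gating, variable-percentage
    threshold normalization, multi-frame binning with best-frame selection,
    Dice distances, metric MDS ordination with k-means clusters and
    confidence ellipses, and per-group TRF richness contrasts. Companion
    tools dereplicate 16S rDNA clone libraries at 97% identity, estimate
    Chao1 richness and Shannon diversity, and predict terminal restriction
    fragments by in-silico digestion to link clones to fingerprint peaks.
    A seeded synthetic-data generator emulates host-associated communities
    dominated by a single ribotype with a transient regime shift, so every
    stage of the pipeline can be exercised without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    vegan,
    tools,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
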