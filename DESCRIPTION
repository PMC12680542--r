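Package: paleomito
Title: Damage-Aware Mitochondrial Consensus Reconstruction for Ancient DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs mitochondrial consensus genomes from aligned
    ancient-DNA reads produced by single-stranded library protocols, where
    post-mortem cytosine deamination appears as C-to-T substitutions on
    forward-mapping reads and G-to-A on reverse-mapping reads. Provides
    four consensus-calling modes (no correction, polarization-based damage
    silencing, polarization-free damage silencing, and polarization-free
    damage weighting), a position-specific damage-profile estimator, a
    circular-aware pileup engine, genetic sex inference from
    length-normalized chromosome read counts, and a single-stranded-library
    read simulator with known truth for validating every mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    jsonlite,
    optparse,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
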