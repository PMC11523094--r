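Package: lepWorigin
Title: Inferring the Evolutionary Origin of Lepidopteran W Chromosomes from Synteny
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer the evolutionary origin of the female-specific W
    chromosome in ZW sex-chromosome systems from whole-genome synteny. The
    package provides a seed-and-extend synteny-block detector with
    concordance chaining and local refinement, nonoverlapping interval
    coverage statistics with repeat filtering, chromosome homology
    assignment from shared single-copy markers and best protein hits,
    read-depth/GC/repeat-content confirmation of sex-chromosome identity,
    neo-Z fusion detection from split interleaved homology, and a
    classifier for competing W-origin hypotheses (shared autosomal pair,
    B-chromosome recruitment, Z-autosome fusion; single versus multiple
    origins). A synthetic clade simulator generates multi-species genomes
    under each hypothesis so the whole pipeline can be exercised and
    validated by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    IRanges,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
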