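Package: svpipe
Title: Structural Variant Detection and False-Positive Filtering for
    Paired-End Tumor Genomes
Version: 1.0.0
Authors@R:
    person("svpipe", "Maintainers", email = "svpipe@example.org",
           role = c("aut", "cre"))
Description: A self-contained pipeline for detecting large somatic structural
    variants (deletions, inversions, duplications, translocations) from
    discordant paired-end read alignments, together with the simulation
    machinery needed to validate it without external data.  Includes a
    rearranged-genome builder with truth sets and coordinate liftover, a
    Gaussian-insert paired-end read simulator with perfect and imperfect PCR
    duplicate injection, k-mer uniqueness (mappability) tracks, read-pair
    screening (mapping-quality filtering and duplicate removal), union-find
    clustering of discordant pairs into SV candidates, and a post-detection
    filter cascade: tumor/control comparison, low-mappability, simple-repeat
    and RepeatMasker overlap filters, and type-specific size cutoffs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
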