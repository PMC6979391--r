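Package: loopover
Title: Transposable-Element Mediated Turnover of CTCF Loop Anchors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative analysis of how transposable elements (TEs) supply
    and turn over CTCF chromatin-loop anchor sites between two genomes.
    Provides readers for the standard interchange formats (RepeatMasker .out
    and .align, BEDPE loop calls, narrowPeak, UCSC chain, bedGraph,
    contact-matrix triples), repeat-origin annotation of anchor CTCF sites
    with enrichment against a length-weighted genomic background, conserved
    loop calling by calibrated reciprocal chain lifting, detection of
    TE-mediated binding-site turnover with motif-orientation contingency
    statistics, contact-map statistics for anchor-deletion experiments
    (subsampling, VC-sqrt balancing, virtual 4C, cross-domain interaction
    percentages), TE substitution-spectrum profiling with a permutation
    background for the CpG-deamination methylation signature, and a fully
    synthetic two-species data generator with implanted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
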