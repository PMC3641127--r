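Package: tdscreen
Title: Genome-Wide Screen for Transdifferentiation Factors from
    Differential Expression and Polycomb Repression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate transcription factors that convert one
    adult cell type into another by combining two genome-wide criteria:
    higher expression in the target cell (Z-scored log(1+TPM) RNA-seq) and
    stronger Polycomb-associated H3K27me3 modification in the source cell
    (input-corrected Z-scored gene-body ChIP-seq signal). Provides gene-body
    read counting, input-library correction, isoform collapsing, promoter
    methylation differencing, Pareto-dominance ranking of candidates,
    recovery-curve evaluation against known transdifferentiation factors,
    fold-enrichment summaries, one-sided Kolmogorov-Smirnov group
    comparisons, and a synthetic paired two-cell-type data generator with
    planted factors for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    ggplot2,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
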