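Package: mirdiverge
Title: Lineage-Specific miRNA Repertoires and Target-Gene Expression Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how lineage-specific microRNAs shape
    target-gene expression divergence between species. Provides a three-step
    cross-species miRNA homolog screen (mismatch-tolerant genome scan, local
    hairpin alignment with Karlin-Altschul E-values, and a hairpin
    minimum-free-energy filter), canonical seed-site prediction (8mer, 7mer-m8,
    7mer-A1) on 3'UTRs, target-site conservation labelling and normalized
    divergence-rate statistics on multi-species UTR alignments, orthologue
    expression-ratio comparisons (Kolmogorov-Smirnov and Mann-Whitney tests),
    and hypergeometric gene-set enrichment. A synthetic-data module generates
    every input with known ground truth so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
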