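#!/usr/bin/env Rscript

# Step 5: pathway enrichment of the target genes of lineage-specific miRNAs
# (hypergeometric test, p < 0.05 and overlap >= 3 reporting filters).

source("analysis/00_config.R")

truth <- read_truth_json(file.path(SYN_DIR, "truth.json"))
gene_sets <- read_gene_sets(file.path(SYN_DIR, "gene_sets.tsv"))
universe <- utils::read.delim(file.path(SYN_DIR, "orthologs.tsv"),
                              colClasses = "character")$gene_a

res <- hypergeom_enrich(truth$target_genes, universe, gene_sets,
                        p_max = 0.05, min_count = 3)
utils::write.table(res, file.path(OUT_DIR, "enrichment.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d gene sets pass p < 0.05 with overlap >= 3", nrow(res)))
if (nrow(res)) {
  top <- res[1, ]
  message(sprintf("top set: %s (k = %d of K = %d, p = %.3g)%s",
                  top$set_id, top$k, top$K, top$p,
                  if (top$set_id == truth$enriched_set_id)
                    " - the planted pathway" else ""))
}
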