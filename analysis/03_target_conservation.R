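#!/usr/bin/env Rscript

# Step 3: predict seed sites on the reference UTRs, label their conservation
# on the multi-species alignments, and compare normalized divergence rates
# between targets of lineage-specific and conserved miRNAs.

source("analysis/00_config.R")

truth <- read_truth_json(file.path(SYN_DIR, "truth.json"))
matures <- read_fasta(file.path(SYN_DIR, "mature.fa"), type = "RNA")
blocks <- read_utr_alignments(file.path(SYN_DIR, "utr_alignments.tsv"),
                              ref_species = REF_SPECIES)
labels <- utils::read.delim(file.path(OUT_DIR, "homology_verdicts.tsv"))
mirna_labels <- setNames(labels$label, labels$mirna_id)

seeds <- vapply(matures, extract_seed, "")
calls <- predict_targets(seeds, blocks)
message(sprintf("%d candidate sites across %d genes", nrow(calls),
                length(unique(calls$gene_id))))

calls <- site_conservation_table(calls, blocks, PANEL)
calls <- site_divergence_table(calls, blocks, COMPARISON_SPECIES)
utils::write.table(calls, file.path(OUT_DIR, "target_sites.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

## conservation by miRNA specificity class
assessed <- calls[calls$conservation != "unassessed", ]
ct <- specificity_contingency(assessed, mirna_labels)
message(sprintf(
  "reference-specific site fraction: %.0f%% (specific miRNAs) vs %.0f%% (non-specific), chi-square p = %.3g",
  ct$proportions[1] * 100, ct$proportions[2] * 100, ct$p_value))
write_truth_json(list(table = as.data.frame(ct$table),
                      proportions = as.list(ct$proportions),
                      chisq_p = ct$p_value),
                 file.path(OUT_DIR, "site_contingency.json"))

## normalized divergence-rate distributions
spec_calls <- calls$mirna_id %in% names(mirna_labels)[mirna_labels == "specific"]
dtest <- divergence_distribution_test(calls$normalized[spec_calls],
                                      calls$normalized[!spec_calls])
message(sprintf(
  "divergence of sites of lineage-specific miRNAs: mean %.3f vs %.3f; KS D = %.3f, p = %.3g",
  mean(calls$normalized[spec_calls], na.rm = TRUE),
  mean(calls$normalized[!spec_calls], na.rm = TRUE), dtest$D, dtest$p_value))
write_truth_json(list(D = dtest$D, p = dtest$p_value),
                 file.path(OUT_DIR, "divergence_ks.json"))
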