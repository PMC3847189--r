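#!/usr/bin/env Rscript

# Step 1: generate the synthetic study inputs with known ground truth.
#
# The scenario emulated: a reference lineage ("cow") carrying an expanded
# miRNA repertoire, sister genomes in which only some miRNA families have
# homologs, multi-species 3'UTR alignments in which sites of
# lineage-specific miRNAs evolve faster than sites of conserved miRNAs,
# orthologue expression tables in which the targets of lineage-specific
# miRNAs are down-regulated, and gene sets containing one planted pathway.

source("analysis/00_config.R")

## miRNA catalog: 8 families x 3 members, diversified by seed shifting and
## point mutation (a miR-2284-like expansion)
cat_sim <- gen_mirna_catalog(n_families = 8, members_per_family = 3,
                             shift_prob = 0.3, point_mut_prob = 0.2,
                             rng_seed = STUDY_SEED)
catalog <- cat_sim$catalog
truth <- list(catalog = cat_sim$truth)
message(sprintf("catalog: %d miRNAs in 8 families", length(catalog)))

write_fasta(vapply(catalog, `[[`, "", "mature_seq"), # nolint
            file.path(SYN_DIR, "mature.fa"), type = "RNA")
write_fasta(vapply(catalog, `[[`, "", "hairpin_seq"),
            file.path(SYN_DIR, "hairpin.fa"), type = "RNA")
counts <- do.call(rbind, lapply(catalog, `[[`, "counts"))
rownames(counts) <- names(catalog)
totals <- c(s1 = 26e6, s2 = 26e6, s3 = 26e6)   # mapped-read totals per sample
write_counts(count_table(counts, totals), file.path(SYN_DIR, "mirna_counts.tsv"))

## genomes: families 1-4 have homologs in at least one sister species
## (with 0-2 mismatches); families 5-8 are lineage-specific. One species
## carries a destabilized copy of family 5, which must NOT rescue it.
fam <- cat_sim$truth$family
ids <- names(catalog)
carrier_fams <- list(sp_a = 1:2, sp_b = c(2:3), sp_c = 4)
specs <- list(
  list(species_id = "sp_a", carriers = ids[fam %in% carrier_fams$sp_a],
       mismatch_level = 0L, decoy_rate = 0.2),
  list(species_id = "sp_b", carriers = ids[fam %in% carrier_fams$sp_b],
       mismatch_level = 1L, decoy_rate = 0.2),
  list(species_id = "sp_c", carriers = ids[fam %in% carrier_fams$sp_c],
       mismatch_level = 2L, decoy_rate = 0.2),
  list(species_id = "sp_d", carriers = ids[fam == 5], mismatch_level = 0L,
       decoy_rate = 0.2, destabilize = TRUE))
gen <- gen_species_genomes(catalog, specs, genome_len = 30000,
                           rng_seed = STUDY_SEED + 1)
write_fasta(gen$genomes, file.path(SYN_DIR, "genomes.fa"), type = "DNA")
write_bed(gen$bed, file.path(SYN_DIR, "planted_hairpins.bed"))
truth$specific_families <- setdiff(1:8, unlist(carrier_fams))
truth$planted_homologs <- gen$truth$planted_homologs
message(sprintf("genomes: 4 sister species, %d planted homolog copies",
                nrow(gen$truth$planted_homologs)))

## UTR alignments: sites of lineage-specific miRNA families evolve fast
## (high site substitution, low retention); sites of conserved families
## evolve like their flanks and are usually retained
specific_ids <- ids[fam %in% truth$specific_families]
aln_species <- c(REF_SPECIES, PANEL)
u_fast <- gen_utr_alignment_set(300, aln_species, catalog[specific_ids],
                                site_frac = 0.8, retention_prob = 0.3,
                                site_sub_rate = 0.3, flank_sub_rate = 0.1,
                                indel_rate = 0.01, rng_seed = STUDY_SEED + 2)
u_slow <- gen_utr_alignment_set(300, aln_species,
                                catalog[setdiff(ids, specific_ids)],
                                site_frac = 0.8, retention_prob = 0.7,
                                site_sub_rate = 0.1, flank_sub_rate = 0.1,
                                indel_rate = 0.01, rng_seed = STUDY_SEED + 3)
# second half of genes renamed so the two sets concatenate
shift_gene <- function(g) sprintf("g%05d", as.integer(substring(g, 2)) + 300L)
u_slow$truth$planted_sites$gene_id <- shift_gene(u_slow$truth$planted_sites$gene_id)
u_slow$truth$site_conservation$gene_id <- shift_gene(u_slow$truth$site_conservation$gene_id)
for (i in seq_along(u_slow$blocks))
  u_slow$blocks[[i]]$gene_id <- shift_gene(u_slow$blocks[[i]]$gene_id)
blocks <- c(u_fast$blocks, u_slow$blocks)
write_utr_alignments(blocks, file.path(SYN_DIR, "utr_alignments.tsv"))
truth$planted_sites <- rbind(u_fast$truth$planted_sites,
                             u_slow$truth$planted_sites)
message(sprintf("UTR alignments: %d genes, %d planted sites",
                length(blocks), nrow(truth$planted_sites)))

## expression: genes carrying sites of lineage-specific miRNAs are
## down-regulated in the reference lineage
target_genes <- unique(u_fast$truth$planted_sites$gene_id)
expr <- gen_expression_tables(8000, target_genes, effect_log2 = 0.8,
                              dispersion = 0.1,
                              library_sizes = list(a = rep(3e7, 3),
                                                   b = rep(3e7, 3)),
                              rng_seed = STUDY_SEED + 4)
write_counts(expr$expr_a, file.path(SYN_DIR, "expr_cow.tsv"))
write_counts(expr$expr_b, file.path(SYN_DIR, "expr_sister.tsv"))
utils::write.table(expr$ortholog_map, file.path(SYN_DIR, "orthologs.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
truth$target_genes <- target_genes
truth$effect_log2 <- 0.8
message(sprintf("expression: 8000 orthologue pairs, %d true target genes",
                length(target_genes)))

## gene sets: one planted pathway among the targets
gs <- gen_gene_sets(sprintf("g%05d", 1:8000), n_sets = 25, set_size = 40,
                    planted_overlap = 20, target_ids = target_genes,
                    rng_seed = STUDY_SEED + 5)
write_gene_sets(gs$gene_sets, file.path(SYN_DIR, "gene_sets.tsv"))
truth$enriched_set_id <- gs$truth$enriched_set_id

write_truth_json(truth, file.path(SYN_DIR, "truth.json"))
message("wrote ", SYN_DIR, "/truth.json")
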