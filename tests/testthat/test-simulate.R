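test_that("generators are pure functions of their seed", {
  c1 <- gen_mirna_catalog(2, 3, 0.4, 0.3, rng_seed = 81)
  c2 <- gen_mirna_catalog(2, 3, 0.4, 0.3, rng_seed = 81)
  expect_identical(c1, c2)
  e1 <- gen_expression_tables(200, sprintf("g%05d", 1:20), rng_seed = 82)
  e2 <- gen_expression_tables(200, sprintf("g%05d", 1:20), rng_seed = 82)
  expect_identical(e1, e2)
  u1 <- gen_utr_alignment_set(30, c("cow", "human"), c1$catalog,
                              rng_seed = 83)
  u2 <- gen_utr_alignment_set(30, c("cow", "human"), c1$catalog,
                              rng_seed = 83)
  expect_identical(u1, u2)
})

test_that("without mutation processes a family shares one seed", {
  sim <- gen_mirna_catalog(1, 5, shift_prob = 0, point_mut_prob = 0,
                           rng_seed = 84)
  fam <- family_seed_analysis(sim$catalog)
  expect_equal(fam$n_distinct_seeds, 1L)
  expect_true(all(fam$relations$relation == "identical"))
  expect_true(all(sim$truth$relation == "identical"))
})

test_that("forced seed shifting diversifies seeds consistently with truth", {
  sim <- gen_mirna_catalog(1, 10, shift_prob = 1, point_mut_prob = 0,
                           rng_seed = 85)
  fam <- family_seed_analysis(sim$catalog)
  expect_gte(fam$n_distinct_seeds, 2L)
  expect_true(all(sim$truth$relation == "shifted"))
  expect_true(all(sim$truth$shift_k != 0))
  # pairwise: members shifted by k_i and k_j relate by a shift of k_j - k_i
  ks <- setNames(sim$truth$shift_k, sim$truth$mirna_id)
  rel <- fam$relations
  for (i in seq_len(nrow(rel))) {
    dk <- ks[rel$id_b[i]] - ks[rel$id_a[i]]
    if (dk == 0) {
      expect_equal(rel$relation[i], "identical")
    } else if (abs(dk) <= 3) {
      expect_equal(rel$relation[i], "shift")
      expect_equal(unname(rel$shift_k[i]), unname(dk))
    } else {
      expect_false(rel$relation[i] %in% c("identical", "shift"))
    }
  }
})

test_that("catalog records embed matures in hairpins with valid layout", {
  sim <- gen_mirna_catalog(3, 4, 0.5, 0.5, rng_seed = 86)
  for (rec in sim$catalog) {
    expect_true(grepl(rec$mature_seq, rec$hairpin_seq, fixed = TRUE))
    expect_gte(nchar(rec$mature_seq), 8L)
    expect_lte(nchar(rec$mature_seq), 30L)
  }
  expect_error(gen_mirna_catalog(0, 5), "positive")
  expect_error(gen_mirna_catalog(2, 5, shift_prob = 1.5), "\\[0, 1\\]")
})

test_that("genome generation validates inputs and plants at recorded spans", {
  sim <- gen_mirna_catalog(2, 1, 0, 0, rng_seed = 87)
  expect_error(gen_species_genomes(sim$catalog,
                                   list(list(species_id = "s",
                                             carriers = character(),
                                             mismatch_level = 0L,
                                             decoy_rate = 0)),
                                   genome_len = 30L), "genome_len")
  gg <- gen_species_genomes(sim$catalog,
                            list(list(species_id = "s1",
                                      carriers = names(sim$catalog),
                                      mismatch_level = 0L, decoy_rate = 0.5)),
                            genome_len = 6000, rng_seed = 88)
  ph <- gg$truth$planted_homologs
  for (i in seq_len(nrow(ph))) {
    span <- substr(gg$genomes[[ph$species_id[i]]], ph$start[i] + 1L,
                   ph$end[i])
    hp_dna <- chartr("U", "T", sim$catalog[[ph$mirna_id[i]]]$hairpin_seq)
    expect_equal(span, hp_dna)   # mismatch_level 0: byte-identical plant
  }
  # BED intervals cover plants and decoys, 0-based half-open
  expect_true(all(gg$bed$end > gg$bed$start))
  expect_true(all(ph$mirna_id %in% gg$bed$name))
})

test_that("generated alignments are rectangular with contiguous reference", {
  sim <- gen_mirna_catalog(2, 1, 0, 0, rng_seed = 89)
  u <- gen_utr_alignment_set(40, c("cow", "human", "mouse"), sim$catalog,
                             site_frac = 0.5, retention_prob = 0.5,
                             site_sub_rate = 0.3, flank_sub_rate = 0.1,
                             indel_rate = 0.05, rng_seed = 90)
  for (b in u$blocks) {
    expect_equal(length(unique(nchar(b$seqs))), 1L)
    expect_equal(length(b$ref_coord_map), nchar(b$seqs[1]))  # ref ungapped
  }
  # planted sites are exact seed matches on the reference row
  s <- u$truth$planted_sites
  seeds <- vapply(sim$catalog, function(x) extract_seed(x$mature_seq), "")
  for (i in seq_len(nrow(s))) {
    ref <- block_ref_seq(u$blocks[[s$gene_id[i]]])
    found <- find_seed_sites(seeds[[s$mirna_id[i]]], ref)
    expect_true(s$ref_start[i] %in% found$ref_start)
  }
  expect_error(gen_utr_alignment_set(10, c("a", "b"), sim$catalog,
                                     site_sub_rate = 2), "\\[0, 1\\]")
  expect_error(gen_utr_alignment_set(10, c("a", "b"), sim$catalog,
                                     utr_len = 50), "104")
})

test_that("zero mutation rates give identical rows and conserved sites", {
  sim <- gen_mirna_catalog(2, 1, 0, 0, rng_seed = 91)
  u <- gen_utr_alignment_set(30, c("cow", "human", "mouse"), sim$catalog,
                             site_frac = 1, retention_prob = 0,
                             site_sub_rate = 0, flank_sub_rate = 0,
                             indel_rate = 0, rng_seed = 92)
  for (b in u$blocks) expect_true(all(b$seqs == b$seqs[1]))
  cc <- site_conservation_table(u$truth$planted_sites, u$blocks,
                                c("human", "mouse"))
  expect_true(all(cc$conservation == "conserved"))
  expect_true(all(u$truth$site_conservation$conserved))
})

test_that("zero retention with saturating site mutation makes all sites lineage-specific", {
  sim <- gen_mirna_catalog(2, 1, 0, 0, rng_seed = 93)
  u <- gen_utr_alignment_set(40, c("cow", "human", "mouse"), sim$catalog,
                             site_frac = 1, retention_prob = 0,
                             site_sub_rate = 1, flank_sub_rate = 0.1,
                             indel_rate = 0, rng_seed = 94)
  cc <- site_conservation_table(u$truth$planted_sites, u$blocks,
                                c("human", "mouse"))
  expect_true(all(cc$conservation == "reference_specific"))
  expect_false(any(u$truth$site_conservation$conserved))
})

test_that("realized conservation truth matches the classifier labels", {
  sim <- gen_mirna_catalog(2, 1, 0, 0, rng_seed = 95)
  u <- gen_utr_alignment_set(200, c("cow", "human", "mouse"), sim$catalog,
                             site_frac = 1, retention_prob = 0.5,
                             site_sub_rate = 0.8, flank_sub_rate = 0.1,
                             indel_rate = 0.02, rng_seed = 96)
  cc <- site_conservation_table(u$truth$planted_sites, u$blocks,
                                c("human", "mouse"))
  tr <- u$truth$site_conservation
  truth_conserved <- tapply(tr$conserved, tr$gene_id, any)
  expect_equal(cc$conservation == "conserved",
               as.logical(truth_conserved[cc$gene_id]))
})

test_that("empirical substitution fractions converge to configured rates", {
  sim <- gen_mirna_catalog(1, 1, 0, 0, rng_seed = 97)
  u <- gen_utr_alignment_set(400, c("cow", "human"), sim$catalog,
                             site_frac = 1, retention_prob = 0,
                             site_sub_rate = 0.3, flank_sub_rate = 0.1,
                             indel_rate = 0, rng_seed = 98)
  d <- site_divergence_table(u$truth$planted_sites, u$blocks, "human")
  n_site <- sum(d$site_rate * 0 + ifelse(d$site_len == 8, 8, 7))
  # binomial 4-sigma bands around the configured per-base rates
  p_site <- sum(d$site_rate * ifelse(d$site_len == 8, 8, 7)) / n_site
  expect_lt(abs(p_site - 0.3), 4 * sqrt(0.3 * 0.7 / n_site))
  n_flank <- sum(d$flank_rate * 0 + ifelse(d$site_len == 8, 96, 84))
  p_flank <- sum(d$flank_rate * ifelse(d$site_len == 8, 96, 84)) / n_flank
  expect_lt(abs(p_flank - 0.1), 4 * sqrt(0.1 * 0.9 / n_flank))
})

test_that("expression tables plant the configured down-regulation", {
  targets <- sprintf("g%05d", 1:300)
  sim <- gen_expression_tables(4000, targets, effect_log2 = 1,
                               dispersion = 0.1, rng_seed = 99)
  rt <- build_ratio_table(sim$expr_a, sim$expr_b, sim$ortholog_map)
  sub <- rt$log2_ratio[rt$gene_a %in% targets]
  bg <- rt$log2_ratio[!rt$gene_a %in% targets]
  expect_lt(median(sub), median(bg))
  expect_equal(median(sub) - median(bg), -1, tolerance = 0.15)
  expect_error(gen_expression_tables(100, "not-a-gene"), "subset")
  expect_error(gen_expression_tables(100, character(), dispersion = 0),
               "dispersion")
})

test_that("gene-set generation respects overlap bounds", {
  universe <- sprintf("g%05d", 1:500)
  targets <- universe[1:50]
  gs <- gen_gene_sets(universe, 10, 25, 15, targets, rng_seed = 100)
  planted <- gs$gene_sets[[gs$truth$enriched_set_id]]
  expect_length(planted, 25L)
  expect_equal(length(intersect(planted, targets)), 15L)
  expect_error(gen_gene_sets(universe, 5, 600, 10, targets), "universe")
  expect_error(gen_gene_sets(universe, 5, 25, 60, targets), "overlap")
  empty <- gen_gene_sets(universe, 0, 25, 0, targets)
  expect_length(empty$gene_sets, 0L)
})
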