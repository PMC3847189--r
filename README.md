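# mirdiverge

How do miRNA genes gained along one lineage shape the expression divergence
of their target genes? `mirdiverge` is an R package plus analysis workflow
for comparative transcriptomics studies of exactly that question: a focal
species (e.g. a ruminant) is screened for miRNAs without homologs in sister
genomes, the conservation and evolutionary rate of their 3'UTR target sites
is measured on multi-species alignments, and the expression of their target
genes is compared against orthologues in a sister species. It is written
for bioinformaticians who want every step of such an analysis as a tested,
composable function — runnable end to end on synthetic data with known
ground truth, so each statistic can be validated before touching real data.

## What it computes

* **Catalog & seed diversification** — seed extraction (mature positions
  2–8), cpm normalization, expressed (> 5 reads in every sample) and
  highly-expressed (mean > 50 reads) filters, and pairwise seed relations
  within families: identical, shift(k) for |k| ≤ 3, point mutation.
* **Three-step homolog screen** — per comparison genome: (1) mature scan on
  both strands with ≤ 2 mismatches; (2) local hairpin alignment (match +1,
  mismatch −2, gap open −5, extend −2) with pass = E-value < 0.1 and
  identity > 60% of hairpin length; (3) hairpin minimum free energy
  < −25 kcal/mol under a nearest-neighbour DP folding model (pluggable).
  A miRNA with no species passing all three is *lineage-specific*; the net
  gain rate is n_specific / divergence time (Myr).
* **Target sites** — canonical 8mer / 7mer-m8 / 7mer-A1 sites; a site is
  *conserved* iff some panel species is character-identical over the site
  (indels count as divergence); the **normalized divergence rate** is
  d_site − d_flank, substitutions per site length (7 or 8) minus
  substitutions per flank length (84 or 96), gaps excluded from both.
  Specificity-by-conservation 2×2 tables are tested by Pearson chi-square;
  rate distributions by two-sample Kolmogorov–Smirnov.
* **Expression divergence** — orthologue pairs with cpm > 0.5 in both
  species, log2(A/B) ratios, KS CDF-shift test with direction, Mann–Whitney
  comparison of medians among genes changed > 1.2-fold, and the excess
  reduction percentage (|m_sub| − |m_bg|)/|m_bg| × 100.
* **Enrichment** — upper-tail hypergeometric gene-set test with p < 0.05
  and overlap ≥ 3 reporting filters (plus a BH-FDR column).
* **Synthetic data** — generators for every input above with planted,
  seed-deterministic ground truth.

## Worked example

```r
library(mirdiverge)

# a 4-member family diversified by seed shifting and point mutation
sim <- gen_mirna_catalog(n_families = 1, members_per_family = 4,
                         shift_prob = 0.5, point_mut_prob = 0.3, rng_seed = 8)
fam <- family_seed_analysis(sim$catalog)
fam$n_distinct_seeds
#> [1] 2
fam$relations
#>              id_a            id_b       relation shift_k
#> 1 syn-mir-f01-m01 syn-mir-f01-m02      identical       0
#> 2 syn-mir-f01-m01 syn-mir-f01-m03      identical       0
#> 3 syn-mir-f01-m01 syn-mir-f01-m04 point_mutation      NA
#> 4 syn-mir-f01-m02 syn-mir-f01-m03      identical       0
#> 5 syn-mir-f01-m02 syn-mir-f01-m04 point_mutation      NA
#> 6 syn-mir-f01-m03 syn-mir-f01-m04 point_mutation      NA

# precursor stability (step 3 of the homolog screen)
round(hairpin_mfe(sim$catalog[[1]]$hairpin_seq), 1)
#> [1] -55.2

# published-style 2x2 of site conservation by miRNA specificity
res <- contingency_test(matrix(c(6937, 13425, 4535, 13969), nrow = 2,
         dimnames = list(c("specific", "non_specific"),
                         c("reference_specific", "conserved"))))
round(100 * res$proportions)       # % lineage-specific sites per miRNA class
#>     specific non_specific
#>           60           49
res$p_value < 1e-4
#> [1] TRUE

net_gain_rate(46 + 25, 64.5)       # lineage-specific miRNAs per Myr
#> [1] 1.1
excess_reduction_percent(-1.73, -1.60)
#> [1] 8
```

The 60% vs 49% proportions say that target sites of lineage-specific miRNAs
are themselves lineage-specific far more often than sites of conserved
miRNAs; 1.1 is the estimated net gain of new miRNAs per million years; 8%
is how much deeper the median expression reduction of target genes is
compared with the genome-wide background.

## The analysis workflow

`analysis/01_simulate_inputs.R` … `05_enrichment.R` run one complete
synthetic study from the repository root (writing under `results/`):
generated inputs (FASTA/BED/TSV/JSON), catalog summary and homolog
verdicts, per-site conservation and divergence tables with the contingency
and KS tests, orthologue ratio statistics, and pathway enrichment. Each
script prints what it found; the planted truth is recovered at every stage.

```sh
Rscript analysis/01_simulate_inputs.R   # ... then 02..05 in order
```

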