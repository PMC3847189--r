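---
title: "Methods: lineage-specific miRNAs and target expression divergence"
author: "mirdiverge"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirdiverge)
```

# The question and the design

When a lineage gains miRNA genes that its sister lineages lack, three things
should be measurable. First, the new miRNAs exist as a repertoire: families
expanded by duplication and diversified by *seed shifting* (the dominant
mature isoform's 5' start moves by a few nucleotides, changing the seed and
therefore the target set) and by point mutation within the seed. Second,
their target sites in 3'UTRs are young: they are less often conserved across
other species, and the sites themselves evolve faster than their flanking
sequence. Third, if the miRNAs are functional repressors, their target genes
should sit lower in the expression distribution of the focal lineage than
their orthologues do in the sister lineage.

`mirdiverge` implements each measurement as a small set of composable
functions, plus generators that produce every input with known planted
truth. The package is organised as an analysis workflow: the numbered
scripts under `analysis/` narrate one synthetic study end to end, while all
computation lives in exported package functions so every step is unit-tested
and reusable.

# The three-step homolog screen

A miRNA is called *lineage-specific* when no comparison genome passes all
three of:

1. **Mature scan.** Every position on either strand of the genome where the
   mature sequence matches with at most 2 mismatches (Hamming distance; no
   indels). Implemented with `Biostrings::matchPattern`; an all-window
   brute-force scan serves as the test oracle.
2. **Hairpin alignment.** For each hit, the precursor hairpin is locally
   aligned (Smith–Waterman: match +1, mismatch −2, gap open −5, extension
   −2) against a window of the hit extended by (hairpin length + 100) nt per
   side, oriented to the hit strand. The pass requires E-value < 0.1 *and*
   identity > 60% of the hairpin length. The E-value is the Karlin–Altschul
   form `K·m·n·exp(−λS)` with λ = 1.28, K = 0.46 for this scoring scheme;
   both constants are arguments because alignment-statistics constants are
   implementation-dependent, and at these settings the identity rule does
   most of the filtering while the E-value removes only the weakest hits.
3. **Folding stability.** The genome-side aligned span must fold with
   minimum free energy strictly below −25 kcal/mol.

The window padding of 100 nt (beyond the hairpin length) is our choice: it
guarantees the full precursor is contained in the window for any hit inside
it, while keeping the E-value search space `m·n` small and explicit.
Evidence for every species is retained in the verdict object, including
failing steps, so screens can be audited.

The *net gain rate* divides the count of lineage-specific miRNAs by the
divergence time to the sister lineage (reported to one decimal, per Myr).

## The folding model

The default `fold_model` is a dynamic-programming fold over canonical
Watson–Crick plus G:U pairs with nearest-neighbour stack energies
(Turner-style values, kcal/mol at 37 °C), a hairpin-loop closure penalty
with a minimum loop of 3 nt, and interior/bulge loops up to 10 unpaired
bases with a flat-plus-size penalty (2.9 + 0.5 per base). Unpaired regions
are free, so the energy is ≤ 0 always and exactly 0 for sequences admitting
no pairs. This model is deliberately simple — no dangling ends, no
multibranch-loop terms, no coaxial stacking — because the screen only needs
to separate genuine precursor hairpins (typically −30 to −60 kcal/mol here)
from shuffled or arm-scrambled sequences (typically −20 to 0). It is not a
general structure predictor. Any external folder can be plugged in through
`fold_model()` / `external_fold_model()`, which accept any
sequence → kcal/mol function; the screen's contract is only the energy
threshold.

# Seed sites, conservation, and the divergence statistic

Seed-site prediction uses the three canonical site classes against the
reverse complement of the seed (mature positions 2–8): `8mer`
(rc(2–8) + A), `7mer-m8` (rc(2–8)) and `7mer-A1` (rc(2–7) + A). Overlapping
matches are reported once at the highest class. Only the major mature
sequence defines sites; star sequences are ignored. Site efficacy scoring
is a pluggable function — the default ranks site classes (8mer = 3,
7mer-m8 = 2, 7mer-A1 = 1) with a configurable cutoff — because published
context-style scores are not re-derivable and the analyses here depend only
on site identity, not on efficacy rank.

Two deliberately different divergence rules coexist:

* **Conservation label.** A site is *conserved* when at least one species
  of the comparison panel (default: human, dog, mouse, rat, chicken) is
  character-identical to the reference over the whole site — substitutions
  *and* indels count as divergence. Panel species missing from a block are
  skipped; if all are missing the site is *unassessed*.
* **Normalized divergence rate.** Against a single comparison species, the
  substitution rate within the site minus the substitution rate of its
  flanks, where flank totals are 84 nt for 7-mers and 96 nt for 8-mers.
  Gap columns are excluded from numerator *and* denominator here, because
  this statistic counts nucleotide substitutions only.

The flank totals are split 42/48 per side; when a site sits near a UTR end
the flanks truncate and the denominator adjusts. The statistic lies in
[−1, 1]; its expectation over many sites is the difference of the per-base
substitution probabilities, which is what the recovery tests assert.

The association between miRNA specificity and site conservation is tested
with a Pearson chi-square on the 2×2 table without continuity correction;
distributional comparisons of the normalized rate use the two-sample
two-sided Kolmogorov–Smirnov test. Because the normalized rate is discrete
(multiples of 1/7, 1/8, 1/84, 1/96), ties are unavoidable and the KS
p-value is asymptotic; this makes the test slightly conservative, which the
null-calibration check accounts for.

# Expression divergence

Orthologue count tables are collapsed to per-gene mean cpm
(count / mapped-read total × 10⁶). Pairs require cpm > 0.5 in both species;
ratios are log2(species A / species B), so *reduction in A* is negative.
The CDF-shift test is a two-sample KS with the direction taken from the
difference of medians. The magnitude comparison first restricts both groups
to genes changed more than 1.2-fold (|log2 ratio| > log2 1.2, symmetric in
both directions since direction of change is not part of the filter), then
compares with a two-sided Mann–Whitney U test, and summarises the excess
reduction as (|median_subset| − |median_background|)/|median_background|,
in percent.

Expression filters on miRNA counts use two independent thresholds: counts
strictly greater than 5 in every sample (*expressed*) and mean count across
samples strictly greater than 50 (*highly expressed*). The aggregation of
the high-expression rule across samples is our decision — a mean matches
the cpm ≈ 1.5 equivalence at sequencing depths of tens of millions of
reads per sample — and since per-sample counts are retained the rule can be
re-derived differently without touching the data.

# Enrichment

Over-representation uses the upper-tail hypergeometric probability
P(X ≥ k) for drawing k set genes in a query of n from a universe of N with
K set genes; gene sets are intersected with the universe before testing and
excluded set identifiers are never tested. Reporting keeps raw p < 0.05
with overlap ≥ 3 — no multiple-testing correction is applied to the filter,
matching the raw-p reporting convention this pipeline reproduces, but a
Benjamini–Hochberg FDR column is always emitted so the reader can judge.
The universe is an explicit argument, never inferred.

# What the generators emulate — and what they do not

* `gen_mirna_catalog`: families share one ancestral 28-nt arm; members are
  shifted (±1–3 nt) with probability `shift_prob` and seed-mutated with
  probability `point_mut_prob`; hairpins are arm + 8-nt loop + reverse
  complement. Real precursors have imperfect stems and asymmetric loops;
  perfect stems are used so that planted copies remain comfortably inside
  the stability threshold even after 2 planted mismatches.
* `gen_species_genomes`: carrier species receive the hairpin with exactly
  `mismatch_level` substitutions in the mature region, applied symmetrically
  to both arms so the variant precursor stays base-paired (and so a 3+
  mismatch copy is invisible to the ±-strand mature scan). Backgrounds and
  shuffled-hairpin decoys are verified to contain nothing within 2
  mismatches of any non-carrier mature. A `destabilize` flag scrambles
  every 4th base of the 3' arm, which keeps local alignment score-positive
  (identity ≈ 0.89) while destroying the stem — exercising the
  "passes sequence screens, fails folding" path. Because family members
  share near-identical matures, homolog truth is meaningful at the family
  level; truth-table tests use single-member families.
* `gen_utr_alignment_set`: per-base substitution with independent site and
  flank rates, per-base deletions in non-reference rows only (so reference
  coordinates stay contiguous and blocks rectangular; insertions relative
  to the reference are not simulated). A retained (gene, species) site is
  copied exactly; a non-retained site evolves freely under the site rate —
  divergence is *not* forced, so rate recovery stays unbiased binomial, and
  the truth records the realized conservation of every planted site.
  Planted 7-mer sites get a guarded boundary base so a chance flanking A
  cannot silently upgrade them to 8mers.
* `gen_expression_tables`: negative-binomial counts (variance
  μ + φμ², default φ = 0.1, a typical bulk RNA-seq value) around log-normal
  mean cpm (meanlog log 30, sdlog 1.2, giving a realistic dynamic range);
  targets are scaled by 2^(−effect) in species A. The background ratio
  distribution is centred near zero — unlike real cross-species data, where
  genome-wide medians can be offset — so passing tests show the statistics
  detect a planted shift, not that they reproduce any particular real-data
  median.
* `gen_gene_sets`: one set with exact planted overlap, others uniform.

All generators are pure functions of their seed. None of them simulates
reads, mapping error, multi-mapping smallRNA artefacts, 3'UTR annotation
error, or alignment error in the multi-species UTR alignments — so green
pipeline tests demonstrate correctness of the statistics and rules on their
stated inputs, not robustness to upstream noise.

# Numerical choices and problem sizes

* Tie-breaks: pair seed relations use priority identical > shift >
  point-mutation > other, with shift offsets tried in order
  +1, −1, +2, −2, +3, −3; site-class collisions at one locus keep the
  highest class.
* Degenerate inputs raise errors rather than returning silently: empty
  ratio tables after filtering, empty KS inputs, zero library totals,
  sites extending past the reference row, comparison species missing from
  a block.
* Divergence records whose compared region is entirely gapped are NA and
  dropped by the distribution test.
* Validation problem sizes were chosen to make Monte-Carlo bands tight at
  desk scale: 2000 sites for rate recovery (3-SE band), 30 replicates of
  n = 1000/group for KS power at a p < 10⁻⁶ criterion, 500 null replicates
  of n = 150/group for size at α = 0.01 (binomial band), 100 replicates of
  8000-gene tables for expression-shift detection, and a 4-species
  truth table for the homolog screen.

# Known limitations

* The folding model underestimates stability for structures relying on
  multibranch loops or long interior loops; it is a screen, not a
  predictor.
* E-value constants are nominal for the +1/−2 scheme and not calibrated
  against any aligner's empirical statistics; the identity cutoff is the
  operative filter.
* The KS test on discrete divergence rates is conservative under heavy
  ties.
* Homolog specificity truth is family-level whenever families share seeds
  and near-identical matures.
* The conservation label depends on which panel species are present in a
  block; `unassessed` sites must be excluded before contingency testing,
  and the package forces the caller to do so explicitly.
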