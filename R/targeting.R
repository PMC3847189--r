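# Seed-site prediction on 3'UTRs, conservation labelling on multi-species
# alignments, and the normalized divergence-rate statistic (site substitution
# rate minus flank substitution rate).

.all_starts <- function(utr, pattern) {
  L <- nchar(pattern)
  n <- nchar(utr)
  if (n < L) return(integer())
  p <- seq_len(n - L + 1L)
  p[substring(utr, p, p + L - 1L) == pattern]
}

#' Predict canonical seed-match target sites in a 3'UTR
#'
#' Site classes, scanned against the reverse complement of the seed (mature
#' positions 2-8):
#' * `8mer`: reverse complement of positions 2-8 followed by an A in the UTR;
#' * `7mer-m8`: reverse complement of positions 2-8;
#' * `7mer-A1`: reverse complement of positions 2-7 followed by an A.
#' Overlapping matches are reported once at the highest class
#' (8mer > 7mer-m8 > 7mer-A1).
#'
#' @param seed 7-mer seed (mature positions 2-8, RNA).
#' @param utr 3'UTR sequence (RNA; T accepted as U).
#' @return Data frame of target-site calls: `ref_start` (0-based on the
#'   ungapped UTR), `site_type`, `site_len`, `site_seq`.
#' @export
#' @examples
#' find_seed_sites("GAGGUAG", "AAACUACCUCAAA")  # one 8mer at ref_start 3
find_seed_sites <- function(seed, utr) {
  seed <- .rna(seed)
  if (nchar(seed) != 7L) stop("seed must be exactly 7 nt")
  utr <- .rna(utr)
  rc <- rna_revcomp(seed)
  site8 <- paste0(rc, "A")
  site7a1 <- paste0(substr(rc, 2L, 7L), "A")
  s8 <- .all_starts(utr, site8)
  s7m8 <- .all_starts(utr, rc)
  s7a1 <- .all_starts(utr, site7a1)
  # an 8mer at p subsumes the 7mer-m8 at p and the 7mer-A1 at p+1
  s7m8 <- setdiff(s7m8, s8)
  s7a1 <- setdiff(s7a1, s8 + 1L)
  out <- rbind(
    if (length(s8)) data.frame(ref_start = s8 - 1L, site_type = "8mer",
                               site_len = 8L),
    if (length(s7m8)) data.frame(ref_start = s7m8 - 1L, site_type = "7mer-m8",
                                 site_len = 7L),
    if (length(s7a1)) data.frame(ref_start = s7a1 - 1L, site_type = "7mer-A1",
                                 site_len = 7L))
  if (is.null(out))
    return(data.frame(ref_start = integer(), site_type = character(),
                      site_len = integer(), site_seq = character()))
  # same-start collisions (degenerate seeds) keep the highest class
  pri <- match(out$site_type, c("8mer", "7mer-m8", "7mer-A1"))
  out <- out[order(out$ref_start, pri), , drop = FALSE]
  out <- out[!duplicated(out$ref_start), , drop = FALSE]
  out$site_seq <- substring(utr, out$ref_start + 1L,
                            out$ref_start + out$site_len)
  rownames(out) <- NULL
  out
}

# Alignment columns of ungapped reference positions [ref_start, ref_start+len)
.site_columns <- function(block, ref_start, len) {
  idx <- (ref_start + 1L):(ref_start + len)
  if (ref_start < 0L || ref_start + len > length(block$ref_coord_map))
    stop(sprintf("site [%d,%d) extends past the reference row of gene '%s'",
                 ref_start, ref_start + len, block$gene_id))
  block$ref_coord_map[idx]
}

.row_chars <- function(block, species) {
  strsplit(block$seqs[match(species, block$species)], "")[[1]]
}

#' Conservation label of a target site on a multi-species alignment
#'
#' A site is `conserved` when at least one species of the panel has aligned
#' columns character-identical to the reference over the whole site (no
#' substitution and no gap: indels count as divergence). Panel species absent
#' from the block are skipped; if none is present the site is `unassessed`.
#' Otherwise the site is `reference_specific`.
#'
#' @param block A [utr_block()].
#' @param ref_start 0-based start of the site on the ungapped reference UTR.
#' @param site_len Site length (7 or 8).
#' @param species_panel Character vector of comparison species.
#' @return `"conserved"`, `"reference_specific"` or `"unassessed"`.
#' @export
classify_site_conservation <- function(block, ref_start, site_len,
                                       species_panel) {
  cols <- .site_columns(block, ref_start, site_len)
  ref <- .row_chars(block, block$ref_species)[cols]
  present <- intersect(species_panel, setdiff(block$species, block$ref_species))
  if (!length(present)) return("unassessed")
  for (sp in present) {
    other <- .row_chars(block, sp)[cols]
    if (all(other == ref)) return("conserved")
  }
  "reference_specific"
}

#' Normalized divergence rate of a target site against one species
#'
#' The site substitution rate is the number of substituted site columns
#' divided by the compared site length; the flank rate is computed the same
#' way over the upstream plus downstream flanks (42 nt per side for 7-mers,
#' 48 for 8-mers, i.e. totals 84 and 96; flanks running past the UTR ends are
#' truncated and the denominator adjusted). Columns where the comparison
#' species has a gap are excluded from both numerator and denominator.
#' The normalized rate is `site_rate - flank_rate`; positive values indicate
#' site-accelerated evolution.
#'
#' @param block A [utr_block()].
#' @param ref_start 0-based start of the site on the ungapped reference UTR.
#' @param site_len Site length (7 or 8).
#' @param comparison_species Species to compare the reference against.
#' @return List with `site_rate`, `flank_rate`, `normalized`,
#'   `comparison_species`, `n_site` and `n_flank` (compared column counts).
#'   Rates are `NA` when every column of the corresponding region is gapped.
#' @export
normalized_site_divergence <- function(block, ref_start, site_len,
                                       comparison_species) {
  if (!comparison_species %in% block$species)
    stop(sprintf("comparison species '%s' missing from gene '%s'",
                 comparison_species, block$gene_id))
  flank_side <- if (site_len == 8L) 48L else 42L
  L <- length(block$ref_coord_map)
  site_idx <- (ref_start + 1L):(ref_start + site_len)
  up_idx <- seq(max(1L, ref_start + 1L - flank_side), length.out = 0L)
  if (ref_start > 0L)
    up_idx <- max(1L, ref_start + 1L - flank_side):ref_start
  dn_from <- ref_start + site_len + 1L
  dn_idx <- integer()
  if (dn_from <= L)
    dn_idx <- dn_from:min(L, ref_start + site_len + flank_side)
  if (ref_start < 0L || ref_start + site_len > L)
    stop(sprintf("site [%d,%d) extends past the reference row of gene '%s'",
                 ref_start, ref_start + site_len, block$gene_id))
  ref <- .row_chars(block, block$ref_species)
  oth <- .row_chars(block, comparison_species)
  rate <- function(idx) {
    if (!length(idx)) return(c(NA_real_, 0))
    cols <- block$ref_coord_map[idx]
    keep <- oth[cols] != "-"
    n <- sum(keep)
    if (n == 0L) return(c(NA_real_, 0))
    c(sum(ref[cols][keep] != oth[cols][keep]) / n, n)
  }
  s <- rate(site_idx)
  f <- rate(c(up_idx, dn_idx))
  list(site_rate = s[1], flank_rate = f[1],
       normalized = s[1] - f[1],
       comparison_species = comparison_species,
       n_site = s[2], n_flank = f[2])
}

#' Predict target sites of many miRNAs across alignment blocks
#'
#' Scans the ungapped reference UTR of every block for canonical seed sites
#' of every seed, attaching gene and miRNA identifiers. An optional scorer
#' ranks calls; the default scores by site class (8mer = 3, 7mer-m8 = 2,
#' 7mer-A1 = 1), and `min_score` drops calls below the cutoff.
#'
#' @param seeds Named character vector of 7-mer seeds (names = miRNA ids).
#' @param blocks List of [utr_block()] objects.
#' @param scorer Function `data.frame -> numeric` returning one score per
#'   call; default ranks by site class.
#' @param min_score Minimum retained score (default `-Inf`, keep everything).
#' @return Data frame of calls: `gene_id`, `mirna_id`, `ref_start`,
#'   `site_type`, `site_len`, `site_seq`, `score`.
#' @export
predict_targets <- function(seeds, blocks,
                            scorer = site_class_scorer, min_score = -Inf) {
  stopifnot(length(seeds) > 0, !is.null(names(seeds)))
  out <- list()
  for (b in blocks) {
    ref <- block_ref_seq(b)
    for (m in names(seeds)) {
      calls <- find_seed_sites(seeds[[m]], ref)
      if (nrow(calls)) {
        calls$gene_id <- b$gene_id
        calls$mirna_id <- m
        out[[length(out) + 1L]] <- calls
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(), mirna_id = character(),
                      ref_start = integer(), site_type = character(),
                      site_len = integer(), site_seq = character(),
                      score = numeric()))
  df <- do.call(rbind, out)
  df <- df[, c("gene_id", "mirna_id", "ref_start", "site_type", "site_len",
               "site_seq")]
  df$score <- scorer(df)
  df <- df[df$score >= min_score, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Default site scorer: rank by site class
#' @param calls Data frame with a `site_type` column.
#' @return Numeric scores (8mer = 3, 7mer-m8 = 2, 7mer-A1 = 1).
#' @export
site_class_scorer <- function(calls) {
  unname(c(`8mer` = 3, `7mer-m8` = 2, `7mer-A1` = 1)[calls$site_type])
}

#' Conservation labels for a table of target-site calls
#'
#' @param calls Data frame from [predict_targets()] (needs `gene_id`,
#'   `ref_start`, `site_len`).
#' @param blocks List of [utr_block()] objects (matched to calls by gene id).
#' @param species_panel Comparison species for [classify_site_conservation()].
#' @return `calls` with an added `conservation` column.
#' @export
site_conservation_table <- function(calls, blocks, species_panel) {
  bl <- setNames(blocks, vapply(blocks, `[[`, "", "gene_id"))
  calls$conservation <- vapply(seq_len(nrow(calls)), function(i)
    classify_site_conservation(bl[[calls$gene_id[i]]], calls$ref_start[i],
                               calls$site_len[i], species_panel),
    character(1))
  calls
}

#' Divergence records for a table of target-site calls
#'
#' @param calls Data frame with `gene_id`, `ref_start`, `site_len`.
#' @param blocks List of [utr_block()] objects.
#' @param comparison_species Species against which divergence is measured.
#' @return `calls` with added `site_rate`, `flank_rate`, `normalized` columns.
#' @export
site_divergence_table <- function(calls, blocks, comparison_species) {
  bl <- setNames(blocks, vapply(blocks, `[[`, "", "gene_id"))
  recs <- lapply(seq_len(nrow(calls)), function(i)
    normalized_site_divergence(bl[[calls$gene_id[i]]], calls$ref_start[i],
                               calls$site_len[i], comparison_species))
  calls$site_rate <- vapply(recs, `[[`, numeric(1), "site_rate")
  calls$flank_rate <- vapply(recs, `[[`, numeric(1), "flank_rate")
  calls$normalized <- vapply(recs, `[[`, numeric(1), "normalized")
  calls
}

#' Chi-square test of site conservation against miRNA specificity
#'
#' Builds the 2x2 table of conservation labels (columns `reference_specific`,
#' `conserved`) by miRNA specificity class (rows `specific`, `non_specific`)
#' and applies [contingency_test()]. Calls labelled `unassessed` are not
#' allowed.
#'
#' @param calls Data frame with `mirna_id` and `conservation` columns.
#' @param mirna_labels Named character vector mapping miRNA ids to
#'   `"specific"` / `"non_specific"`.
#' @return See [contingency_test()].
#' @export
specificity_contingency <- function(calls, mirna_labels) {
  if (!nrow(calls)) stop("empty call table")
  if (any(calls$conservation == "unassessed"))
    stop("calls with 'unassessed' conservation must be removed first")
  cls <- mirna_labels[calls$mirna_id]
  if (anyNA(cls)) stop("some miRNAs lack a specificity label")
  tab <- table(factor(cls, levels = c("specific", "non_specific")),
               factor(calls$conservation,
                      levels = c("reference_specific", "conserved")))
  contingency_test(unclass(tab))
}

#' Proportions and chi-square test of a 2x2 specificity/conservation table
#'
#' Rows are miRNA specificity classes, columns are site conservation labels
#' (`reference_specific`, `conserved`). Reports the per-row proportion of
#' reference-specific sites and a Pearson chi-square test of independence
#' without continuity correction.
#'
#' @param tab 2x2 numeric matrix (rows: miRNA class; columns:
#'   reference-specific, conserved).
#' @return List with `table`, `proportions` (per-row fraction of
#'   reference-specific sites), `statistic` and `p_value`.
#' @export
contingency_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table")
  if (sum(tab) == 0) stop("empty contingency table")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(table = tab,
       proportions = tab[, 1] / rowSums(tab),
       statistic = unname(ct$statistic),
       p_value = ct$p.value)
}

#' Two-sample Kolmogorov-Smirnov test on normalized divergence rates
#'
#' @param rates_a,rates_b Numeric vectors of normalized divergence rates
#'   (non-empty; NAs dropped).
#' @return List with `D` and `p_value`. Normalized divergence is discrete, so
#'   the p-value uses the asymptotic distribution in the presence of ties.
#' @export
divergence_distribution_test <- function(rates_a, rates_b) {
  rates_a <- rates_a[!is.na(rates_a)]
  rates_b <- rates_b[!is.na(rates_b)]
  if (!length(rates_a) || !length(rates_b))
    stop("both groups must be non-empty")
  kt <- suppressWarnings(stats::ks.test(rates_a, rates_b))
  list(D = unname(kt$statistic), p_value = kt$p.value)
}
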