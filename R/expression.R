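# Orthologue expression-ratio construction and the CDF-shift / magnitude
# statistics comparing target genes with the genome-wide background.

#' Build an orthologue expression-ratio table
#'
#' Collapses each species' count table to per-gene mean cpm across samples,
#' joins the two species by the orthologue map, drops pairs failing the cpm
#' threshold in either species, and computes log2 ratios oriented as species A
#' over species B (so reduced expression in species A gives negative ratios).
#'
#' @param expr_a,expr_b [count_table()]s for species A and B.
#' @param ortholog_map Data frame with columns `gene_a`, `gene_b`.
#' @param min_cpm Both orthologues must exceed this cpm (default 0.5).
#' @return Data frame with `gene_a`, `gene_b`, `cpm_a`, `cpm_b`, `log2_ratio`.
#' @export
build_ratio_table <- function(expr_a, expr_b, ortholog_map, min_cpm = 0.5) {
  cpm_a <- rowMeans(cpm_normalize(expr_a))
  cpm_b <- rowMeans(cpm_normalize(expr_b))
  missing_a <- setdiff(ortholog_map$gene_a, names(cpm_a))
  missing_b <- setdiff(ortholog_map$gene_b, names(cpm_b))
  if (length(missing_a) || length(missing_b))
    stop(sprintf("orthologue map references absent genes (e.g. '%s')",
                 c(missing_a, missing_b)[1]))
  df <- data.frame(gene_a = ortholog_map$gene_a,
                   gene_b = ortholog_map$gene_b,
                   cpm_a = unname(cpm_a[ortholog_map$gene_a]),
                   cpm_b = unname(cpm_b[ortholog_map$gene_b]))
  df <- df[df$cpm_a > min_cpm & df$cpm_b > min_cpm, , drop = FALSE]
  if (!nrow(df)) stop("no orthologue pair survives the cpm filter")
  df$log2_ratio <- log2(df$cpm_a / df$cpm_b)
  rownames(df) <- NULL
  df
}

#' CDF-shift test of a ratio subset against the background
#'
#' Two-sample two-sided Kolmogorov-Smirnov test on log2 expression ratios;
#' the direction is the sign of median(subset) - median(background), so a
#' leftward shift (reduced expression of the subset in species A) gives
#' direction -1.
#'
#' @param subset_ratios,background_ratios Non-empty numeric vectors.
#' @return List with `D`, `p_value` and `direction` (-1, 0 or 1).
#' @export
cdf_shift_test <- function(subset_ratios, background_ratios) {
  if (!length(subset_ratios) || !length(background_ratios))
    stop("both ratio vectors must be non-empty")
  kt <- suppressWarnings(stats::ks.test(subset_ratios, background_ratios))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       direction = sign(stats::median(subset_ratios) -
                          stats::median(background_ratios)))
}

#' Magnitude of expression reduction among changed genes
#'
#' Restricts both groups to genes whose fold change exceeds `min_fold_change`
#' (|log2 ratio| > log2(min_fold_change), symmetric in both directions),
#' reports the group medians, and compares the groups with a two-sided
#' Mann-Whitney U test.
#'
#' @param subset_ratios,background_ratios Numeric log2-ratio vectors.
#' @param min_fold_change Fold-change cutoff (default 1.2).
#' @return List with `median_subset`, `median_background`, `p_value`,
#'   `n_subset`, `n_background`.
#' @export
magnitude_reduction <- function(subset_ratios, background_ratios,
                                min_fold_change = 1.2) {
  thr <- log2(min_fold_change)
  s <- subset_ratios[abs(subset_ratios) > thr]
  b <- background_ratios[abs(background_ratios) > thr]
  if (!length(s) || !length(b))
    stop("no ratios survive the fold-change filter")
  wt <- suppressWarnings(stats::wilcox.test(s, b, alternative = "two.sided"))
  list(median_subset = stats::median(s), median_background = stats::median(b),
       p_value = wt$p.value, n_subset = length(s), n_background = length(b))
}

#' Excess expression reduction of a subset relative to the background
#'
#' `(|median_subset| - |median_background|) / |median_background| * 100`,
#' rounded to the nearest integer percent.
#'
#' @param median_subset,median_background Median log2 ratios.
#' @return Integer percent.
#' @export
#' @examples
#' excess_reduction_percent(-1.73, -1.60)  # 8
excess_reduction_percent <- function(median_subset, median_background) {
  if (median_background == 0) stop("background median must be non-zero")
  round((abs(median_subset) - abs(median_background)) /
          abs(median_background) * 100)
}
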