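# miRNA records, seed extraction, expression normalization/filters, and
# seed-family diversification analysis.

#' Construct a miRNA record
#'
#' @param mirna_id Identifier.
#' @param mature_seq Dominant (major) mature sequence, RNA, length 8-30, and a
#'   substring of the hairpin.
#' @param hairpin_seq Precursor hairpin sequence, RNA.
#' @param star_seq Optional minor (star) sequence.
#' @param genome_pos Optional list `(chrom, start, end, strand)`, 0-based
#'   half-open.
#' @param counts Optional named vector of per-sample read counts.
#' @return An object of class `mirna_record`.
#' @export
mirna_record <- function(mirna_id, mature_seq, hairpin_seq, star_seq = NULL,
                         genome_pos = NULL, counts = NULL) {
  mature_seq <- .rna(mature_seq)
  hairpin_seq <- .rna(hairpin_seq)
  n <- nchar(mature_seq)
  if (n < 8L || n > 30L)
    stop(sprintf("mature sequence of '%s' must be 8-30 nt (got %d)",
                 mirna_id, n))
  if (!grepl(mature_seq, hairpin_seq, fixed = TRUE))
    stop(sprintf("mature sequence of '%s' is not a substring of its hairpin",
                 mirna_id))
  if (!is.null(counts) && any(counts < 0))
    stop("read counts must be non-negative")
  structure(
    list(mirna_id = mirna_id, mature_seq = mature_seq,
         star_seq = if (is.null(star_seq)) NULL else .rna(star_seq),
         hairpin_seq = hairpin_seq, genome_pos = genome_pos, counts = counts),
    class = "mirna_record")
}

#' @export
print.mirna_record <- function(x, ...) {
  cat(sprintf("<mirna_record> %s mature %s (hairpin %d nt)\n",
              x$mirna_id, x$mature_seq, nchar(x$hairpin_seq)))
  invisible(x)
}

#' Extract the seed region of a mature miRNA
#'
#' The seed is the 7-mer at positions 2-8 (1-based) of the mature sequence,
#' the primary determinant of target recognition.
#'
#' @param mature Mature miRNA sequence (RNA, length >= 8).
#' @return 7-character seed string.
#' @export
#' @examples
#' extract_seed("UGAGGUAGUAGGUUGUAUAGUU")  # "GAGGUAG"
extract_seed <- function(mature) {
  mature <- .rna(mature)
  if (nchar(mature) < 8L)
    stop("mature sequence shorter than 8 nt has no seed")
  substr(mature, 2L, 8L)
}

#' Counts-per-million normalization
#'
#' cpm[i, s] = count[i, s] / total[s] * 1e6, where total[s] is the per-sample
#' mapped-read total carried by the table.
#'
#' @param table A [count_table()].
#' @return Numeric matrix of cpm values with the table's dimnames.
#' @export
cpm_normalize <- function(table) {
  stopifnot(inherits(table, "count_table"))
  if (any(table$totals <= 0)) stop("per-sample totals must be positive")
  sweep(table$counts, 2L, table$totals, "/") * 1e6
}

#' Expression filters for miRNA read counts
#'
#' An entity is `expressed` when its read count exceeds 5 in every sample, and
#' `highly_expressed` when its mean read count across samples exceeds 50
#' (the two thresholds are independent; neither implies the other).
#'
#' @param table A [count_table()].
#' @param min_count Per-sample count that must be strictly exceeded for
#'   `expressed` (default 5).
#' @param high_count Mean count that must be strictly exceeded for
#'   `highly_expressed` (default 50).
#' @return Data frame with columns `id`, `expressed`, `highly_expressed`,
#'   `mean_count`.
#' @export
expression_filters <- function(table, min_count = 5, high_count = 50) {
  stopifnot(inherits(table, "count_table"))
  if (length(table$samples) < 1L) stop("need at least one sample")
  m <- rowMeans(table$counts)
  data.frame(id = table$ids,
             expressed = apply(table$counts > min_count, 1L, all),
             highly_expressed = m > high_count,
             mean_count = m,
             row.names = NULL)
}

# 7-mer window of a mature sequence at seed offset k (positions 2+k .. 8+k,
# 1-based); NA when the window falls outside the sequence.
.seed_at_offset <- function(mature, k) {
  a <- 2L + k; b <- 8L + k
  if (a < 1L || b > nchar(mature)) return(NA_character_)
  substr(mature, a, b)
}

#' Relation between the seeds of two family members
#'
#' Relations are assigned with priority identical > shift(k) > point_mutation >
#' other. `shift(k)` means one member's seed equals the 7-mer found at seed
#' offset `k` (|k| <= 3) on the other member's mature sequence, i.e. the
#' dominant mature start shifted by k nt; offsets are tried in order
#' +1, -1, +2, -2, +3, -3. `point_mutation` means the two seeds differ at
#' exactly one position. Matures too short to test a given offset simply skip
#' that offset.
#'
#' @param mature_a,mature_b Mature sequences (RNA, length >= 8).
#' @return List with `relation` (one of `"identical"`, `"shift"`,
#'   `"point_mutation"`, `"other"`) and `k` (shift offset, 0 for identical,
#'   NA otherwise).
#' @export
seed_relation <- function(mature_a, mature_b) {
  mature_a <- .rna(mature_a); mature_b <- .rna(mature_b)
  sa <- extract_seed(mature_a); sb <- extract_seed(mature_b)
  if (sa == sb) return(list(relation = "identical", k = 0L))
  for (k in c(1L, -1L, 2L, -2L, 3L, -3L)) {
    wa <- .seed_at_offset(mature_a, k)
    if (!is.na(wa) && wa == sb) return(list(relation = "shift", k = k))
    wb <- .seed_at_offset(mature_b, k)
    if (!is.na(wb) && wb == sa) return(list(relation = "shift", k = -k))
  }
  d <- sum(strsplit(sa, "")[[1]] != strsplit(sb, "")[[1]])
  if (d == 1L) return(list(relation = "point_mutation", k = NA_integer_))
  list(relation = "other", k = NA_integer_)
}

#' Seed diversification analysis of a miRNA family
#'
#' Counts distinct seeds across the members and classifies every member pair
#' by [seed_relation()], capturing diversification by seed shifting and point
#' mutation within an expanded family.
#'
#' @param members List of [mirna_record()] objects (>= 1).
#' @return List with `n_distinct_seeds`, `seeds` (named character vector) and
#'   `relations` (data frame: `id_a`, `id_b`, `relation`, `shift_k`).
#' @export
family_seed_analysis <- function(members) {
  if (length(members) < 1L) stop("need at least one family member")
  ids <- vapply(members, `[[`, "", "mirna_id")
  seeds <- setNames(vapply(members, function(m) extract_seed(m$mature_seq), ""),
                    ids)
  rel <- NULL
  if (length(members) >= 2L) {
    pairs <- utils::combn(length(members), 2L)
    rel <- do.call(rbind, apply(pairs, 2L, function(ij) {
      r <- seed_relation(members[[ij[1]]]$mature_seq,
                         members[[ij[2]]]$mature_seq)
      data.frame(id_a = ids[ij[1]], id_b = ids[ij[2]],
                 relation = r$relation, shift_k = r$k)
    }, simplify = FALSE))
  } else {
    rel <- data.frame(id_a = character(), id_b = character(),
                      relation = character(), shift_k = integer())
  }
  rownames(rel) <- NULL
  list(n_distinct_seeds = length(unique(seeds)), seeds = seeds,
       relations = rel)
}

#' Summarize a miRNA catalog with expression and seed information
#'
#' @param catalog List of [mirna_record()] objects carrying per-sample counts.
#' @param totals Named vector of per-sample mapped-read totals.
#' @return Data frame with `mirna_id`, `seed`, `expressed`, `highly_expressed`,
#'   `mean_cpm`.
#' @export
catalog_summary <- function(catalog, totals) {
  counts <- do.call(rbind, lapply(catalog, `[[`, "counts"))
  rownames(counts) <- vapply(catalog, `[[`, "", "mirna_id")
  tab <- count_table(counts, totals)
  flags <- expression_filters(tab)
  cpm <- cpm_normalize(tab)
  data.frame(mirna_id = flags$id,
             seed = vapply(catalog, function(m) extract_seed(m$mature_seq), ""),
             expressed = flags$expressed,
             highly_expressed = flags$highly_expressed,
             mean_cpm = rowMeans(cpm),
             row.names = NULL)
}
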