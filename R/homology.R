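# Three-step cross-species homolog screen for miRNAs:
#   step 1 - mismatch-tolerant scan of the mature sequence against each genome
#            (both strands, no indels);
#   step 2 - local alignment of the hairpin against a window around each hit,
#            with Karlin-Altschul E-value and identity cutoffs;
#   step 3 - minimum-free-energy filter on the genome-side aligned span.
# A miRNA with no species passing all three steps is lineage-specific.

#' Scan a genome for near-exact copies of a mature miRNA
#'
#' Reports every position on either strand where the Hamming distance between
#' the mature sequence (as DNA) and the genome window is at most
#' `max_mismatches`. No indels are considered.
#'
#' @param mature Mature miRNA sequence (RNA or DNA).
#' @param genome Genome sequence (character or `DNAString`).
#' @param max_mismatches Maximum Hamming distance (default 2).
#' @return Data frame with `start` (0-based), `end` (half-open), `strand`,
#'   `mismatches`, ordered by position. Coordinates are always on the forward
#'   strand.
#' @export
mature_match <- function(mature, genome, max_mismatches = 2L) {
  pat <- .dna(mature)
  g <- if (inherits(genome, "DNAString")) genome
       else Biostrings::DNAString(.dna(as.character(genome)))
  L <- nchar(pat)
  if (length(g) < L)
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  scan1 <- function(p, strand) {
    hits <- Biostrings::matchPattern(p, g, max.mismatch = max_mismatches,
                                     with.indels = FALSE)
    if (length(hits) == 0L)
      return(NULL)
    pc <- strsplit(as.character(p), "")[[1]]
    mm <- vapply(as.character(hits), function(w)
      sum(strsplit(w, "")[[1]] != pc), integer(1), USE.NAMES = FALSE)
    data.frame(start = Biostrings::start(hits) - 1L,
               end = Biostrings::end(hits),
               strand = strand, mismatches = mm)
  }
  fwd <- scan1(Biostrings::DNAString(pat), "+")
  rev <- scan1(Biostrings::reverseComplement(Biostrings::DNAString(pat)), "-")
  out <- rbind(fwd, rev)
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Local alignment of a hairpin against a genomic window
#'
#' Smith-Waterman local alignment with match +1, mismatch -2, gap open -5
#' (cost of a length-1 gap) and gap extension -2. The identity fraction is the
#' number of identical aligned columns divided by the full hairpin length, and
#' the E-value is `K * m * n * exp(-lambda * score)` with default constants
#' for this scoring scheme. The alignment passes when
#' `evalue < evalue_max` AND `identity_fraction > min_identity`.
#'
#' @param hairpin Hairpin (precursor) sequence, RNA or DNA.
#' @param genome_window Genomic window centred on a step-1 hit (character).
#' @param search_space Numeric `(m, n)`: effective query and search-space
#'   lengths for the E-value; defaults to the two sequence lengths.
#' @param evalue_max E-value cutoff (default 0.1).
#' @param min_identity Identity cutoff as a fraction of hairpin length
#'   (default 0.6).
#' @param lambda,K Karlin-Altschul constants for the +1/-2 scoring scheme.
#' @return List with `identity_fraction`, `score`, `evalue`, `pass`,
#'   `window_start`/`window_end` (1-based span of the alignment within the
#'   window) and `aligned_window_seq` (ungapped genome-side span).
#' @export
hairpin_align <- function(hairpin, genome_window,
                          search_space = NULL,
                          evalue_max = 0.1, min_identity = 0.6,
                          lambda = 1.28, K = 0.46) {
  hp <- .dna(hairpin)
  win <- .dna(as.character(genome_window))
  if (nchar(win) == 0L)
    return(list(identity_fraction = 0, score = -Inf, evalue = Inf,
                pass = FALSE, window_start = NA_integer_,
                window_end = NA_integer_, aligned_window_seq = ""))
  if (is.null(search_space)) search_space <- c(nchar(hp), nchar(win))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(hp), Biostrings::DNAString(win),
    type = "local", substitutionMatrix = mat,
    gapOpening = 3, gapExtension = 2)
  sc <- Biostrings::score(al)
  ident <- Biostrings::nmatch(al) / nchar(hp)
  ev <- K * search_space[1] * search_space[2] * exp(-lambda * sc)
  ws <- Biostrings::start(Biostrings::subject(al))
  we <- Biostrings::end(Biostrings::subject(al))
  list(identity_fraction = ident, score = sc, evalue = ev,
       pass = ev < evalue_max && ident > min_identity,
       window_start = ws, window_end = we,
       aligned_window_seq = substr(win, ws, we))
}

#' Classify a miRNA as lineage-specific or not by the three-step screen
#'
#' For each comparison genome: step 1 scans the mature sequence on both
#' strands allowing `max_mismatches`; for each hit, step 2 aligns the hairpin
#' against a window of the hit extended by (hairpin length + `window_pad`) nt
#' on each side, oriented to the hit strand; step 3 folds the genome-side
#' aligned span of any step-2 pass and requires MFE strictly below `mfe_max`.
#' The miRNA is `non_specific` iff some species has a hit passing all three
#' steps; evidence is recorded for every species, including failures.
#'
#' @param mirna A [mirna_record()].
#' @param genomes Named list (or `DNAStringSet`) of comparison-species genome
#'   sequences; must contain at least one species.
#' @param model Folding model for step 3 (default [nn_fold_model()]).
#' @param max_mismatches Step-1 mismatch allowance (default 2).
#' @param evalue_max,min_identity Step-2 cutoffs (defaults 0.1 and 0.6).
#' @param mfe_max Step-3 threshold in kcal/mol; pass requires MFE < `mfe_max`
#'   strictly (default -25).
#' @param window_pad Extra nt added beyond the hairpin length on each side of
#'   a step-1 hit when building the step-2 window (default 100).
#' @return An object of class `homology_verdict`: list with `mirna_id`,
#'   `label` (`"specific"` or `"non_specific"`) and `evidence` (per-species
#'   list of step-1 hits and per-hit step-2/3 records).
#' @export
classify_specificity <- function(mirna, genomes, model = nn_fold_model(),
                                 max_mismatches = 2L, evalue_max = 0.1,
                                 min_identity = 0.6, mfe_max = -25,
                                 window_pad = 100L) {
  stopifnot(inherits(mirna, "mirna_record"))
  if (length(genomes) < 1L) stop("need at least one comparison genome")
  if (is.null(names(genomes)) || any(!nzchar(names(genomes))))
    stop("genomes must be named by species")
  genomes <- lapply(as.list(genomes), function(g) .dna(as.character(g)))
  Lh <- nchar(mirna$hairpin_seq)
  pad <- Lh + window_pad
  evidence <- lapply(names(genomes), function(sp) {
    g <- genomes[[sp]]
    hits <- mature_match(mirna$mature_seq, g, max_mismatches)
    recs <- NULL
    if (nrow(hits)) {
      recs <- lapply(seq_len(nrow(hits)), function(h) {
        ws0 <- max(0L, hits$start[h] - pad)
        we0 <- min(nchar(g), hits$end[h] + pad)
        win <- substr(g, ws0 + 1L, we0)
        if (hits$strand[h] == "-") win <- .dna_revcomp(win)
        s2 <- hairpin_align(mirna$hairpin_seq, win,
                            evalue_max = evalue_max,
                            min_identity = min_identity)
        mfe <- NA_real_
        s3_pass <- FALSE
        if (s2$pass && nchar(s2$aligned_window_seq) >= 15L) {
          mfe <- hairpin_mfe(.rna(s2$aligned_window_seq), model)
          s3_pass <- mfe < mfe_max
        }
        list(start = hits$start[h], strand = hits$strand[h],
             mismatches = hits$mismatches[h],
             identity_fraction = s2$identity_fraction, evalue = s2$evalue,
             step2_pass = s2$pass, mfe_kcal_mol = mfe, step3_pass = s3_pass)
      })
    }
    list(species = sp, step1_hits = hits, hit_records = recs,
         homolog_found = any(vapply(recs, `[[`, FALSE, "step3_pass")))
  })
  names(evidence) <- names(genomes)
  any_homolog <- any(vapply(evidence, `[[`, FALSE, "homolog_found"))
  structure(
    list(mirna_id = mirna$mirna_id,
         label = if (any_homolog) "non_specific" else "specific",
         evidence = evidence),
    class = "homology_verdict")
}

#' @export
print.homology_verdict <- function(x, ...) {
  hit_sp <- names(Filter(function(e) e$homolog_found, x$evidence))
  cat(sprintf("<homology_verdict> %s: %s%s\n", x$mirna_id, x$label,
              if (length(hit_sp)) paste0(" (homolog in ",
                                         paste(hit_sp, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Net gain rate of lineage-specific miRNAs
#'
#' The count of lineage-specific miRNAs divided by the divergence time to the
#' sister lineage, reported to one decimal (miRNAs per million years).
#'
#' @param n_specific Number of lineage-specific miRNAs.
#' @param divergence_myr Divergence time in million years (> 0).
#' @return Rate in miRNAs per Myr, rounded to 1 decimal.
#' @export
#' @examples
#' net_gain_rate(71, 64.5)  # 1.1
net_gain_rate <- function(n_specific, divergence_myr) {
  if (divergence_myr <= 0) stop("divergence time must be positive")
  round(n_specific / divergence_myr, 1)
}
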