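#' @importFrom stats setNames
NULL

# Internal sequence helpers. Transcript-side sequences are canonically RNA
# (ACGU); genomes are DNA (ACGT). All genomic intervals are 0-based half-open.

.rna <- function(x) chartr("Tt", "Uu", toupper(x))
.dna <- function(x) chartr("Uu", "Tt", toupper(x))

.COMP_RNA <- c(A = "U", C = "G", G = "C", U = "A")

#' Reverse complement of an RNA string
#'
#' @param x RNA sequence (character scalar; T is accepted and treated as U).
#' @return Reverse complement as an RNA string.
#' @export
rna_revcomp <- function(x) {
  s <- strsplit(.rna(x), "")[[1]]
  paste(rev(unname(.COMP_RNA[s])), collapse = "")
}

.dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(.dna(x))))
}

#' Construct a multi-species 3'UTR alignment block
#'
#' A block holds the gapped alignment rows of one gene's 3'UTR across species,
#' together with a coordinate map from ungapped reference positions (0-based)
#' to alignment columns. All rows must have equal length; the reference row
#' must be present and contain only A/C/G/U/- characters.
#'
#' @param gene_id Gene identifier.
#' @param species Character vector of species identifiers, one per row.
#' @param seqs Character vector of gapped sequences (same order as `species`).
#' @param ref_species Identifier of the reference species.
#' @return An object of class `utr_block` with fields `gene_id`, `species`,
#'   `seqs`, `ref_species` and `ref_coord_map` (integer vector: entry `i` is
#'   the 1-based alignment column of ungapped reference base `i`; exported
#'   accessors report 0-based positions).
#' @export
utr_block <- function(gene_id, species, seqs, ref_species) {
  seqs <- unname(.rna(seqs))
  species <- unname(species)
  if (length(species) != length(seqs))
    stop("species and seqs must have equal length")
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop(sprintf("ragged alignment rows for gene '%s'", gene_id))
  if (!ref_species %in% species)
    stop(sprintf("missing reference species '%s' row for gene '%s'",
                 ref_species, gene_id))
  ref <- seqs[match(ref_species, species)]
  chars <- strsplit(ref, "")[[1]]
  if (!all(chars %in% c("A", "C", "G", "U", "-")))
    stop(sprintf("invalid characters in reference row of gene '%s'", gene_id))
  structure(
    list(gene_id = gene_id, species = species, seqs = seqs,
         ref_species = ref_species,
         ref_coord_map = which(chars != "-")),
    class = "utr_block")
}

#' @export
print.utr_block <- function(x, ...) {
  cat(sprintf("<utr_block> gene %s: %d species x %d columns (ref %s, %d bases)\n",
              x$gene_id, length(x$species), nchar(x$seqs[1]),
              x$ref_species, length(x$ref_coord_map)))
  invisible(x)
}

#' Ungapped reference sequence of an alignment block
#' @param block A `utr_block`.
#' @return RNA string of the reference row with gaps removed.
#' @export
block_ref_seq <- function(block) {
  gsub("-", "", block$seqs[match(block$ref_species, block$species)], fixed = TRUE)
}

#' Read TargetScan-style aligned-UTR TSV
#'
#' Each line is `gene_id<TAB>species_id<TAB>aligned_sequence`; lines are grouped
#' into one block per gene. T characters are transliterated to U.
#'
#' @param path Input file.
#' @param ref_species Reference species whose row anchors the coordinate map.
#' @return List of [utr_block()] objects, in file order of first appearance.
#' @export
read_utr_alignments <- function(path, ref_species) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character",
                          col.names = c("gene_id", "species", "seq"))
  if (nrow(df) == 0L) return(list())
  blocks <- split(df, factor(df$gene_id, levels = unique(df$gene_id)))
  lapply(blocks, function(b)
    utr_block(b$gene_id[1], b$species, b$seq, ref_species))
}

#' Write aligned-UTR blocks as TargetScan-style TSV
#' @param blocks List of `utr_block` objects.
#' @param path Output file.
#' @export
write_utr_alignments <- function(blocks, path) {
  df <- do.call(rbind, lapply(blocks, function(b)
    data.frame(gene_id = b$gene_id, species = b$species, seq = b$seqs)))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a count table
#'
#' Holds non-negative integer counts (entities x samples) together with
#' per-sample mapped-read totals. Totals are supplied independently of the
#' table: they are mapped-read totals, not column sums.
#'
#' @param counts Integer matrix with entity ids as rownames and sample ids as
#'   colnames.
#' @param totals Named numeric vector of per-sample mapped-read totals covering
#'   every sample in `counts`.
#' @return An object of class `count_table` (fields `ids`, `samples`, `counts`,
#'   `totals`).
#' @export
count_table <- function(counts, totals) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have entity rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate entity ids in count table")
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("counts must be integers")
  missing <- setdiff(colnames(counts), names(totals))
  if (length(missing))
    stop(sprintf("samples missing from totals: %s",
                 paste(missing, collapse = ", ")))
  structure(
    list(ids = rownames(counts), samples = colnames(counts),
         counts = matrix(as.numeric(counts), nrow(counts), ncol(counts),
                         dimnames = dimnames(counts)),
         totals = setNames(as.numeric(totals[colnames(counts)]),
                           colnames(counts))),
    class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d entities x %d samples (totals %s)\n",
              length(x$ids), length(x$samples),
              paste(format(x$totals, big.mark = ","), collapse = ", ")))
  invisible(x)
}

#' Read a count TSV into a count table
#'
#' Expects a header line of sample ids with the first column holding entity
#' ids. Counts must parse as non-negative integers; duplicate entity ids are
#' rejected.
#'
#' @param path Input TSV.
#' @param totals Named vector of per-sample mapped-read totals.
#' @return A [count_table()].
#' @export
read_counts <- function(path, totals) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (ncol(df) < 2L) stop("count table needs an id column plus >=1 sample")
  ids <- df[[1]]
  mat <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat), ncol(mat)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer or negative count at line %d ('%s')",
                 bad[1, 1] + 1L, mat[bad[1, 1], bad[1, 2]]))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate entity id '%s'", ids[anyDuplicated(ids)]))
  dimnames(num) <- list(ids, colnames(mat))
  count_table(num, totals)
}

#' Write a count table as TSV
#' @param table A [count_table()].
#' @param path Output file.
#' @export
write_counts <- function(table, path) {
  df <- data.frame(id = table$ids, table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @param type `"DNA"` or `"RNA"`; controls the alphabet written.
#' @export
write_fasta <- function(seqs, path, type = c("DNA", "RNA")) {
  type <- match.arg(type)
  set <- if (type == "DNA") Biostrings::DNAStringSet(.dna(seqs))
         else Biostrings::RNAStringSet(.rna(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path Input FASTA.
#' @param type `"DNA"` (canonical ACGT) or `"RNA"` (canonical ACGU).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("DNA", "RNA")) {
  type <- match.arg(type)
  set <- Biostrings::readBStringSet(path)
  x <- setNames(as.character(set), names(set))
  if (type == "DNA") .dna(x) else .rna(x)
}

#' Write genomic intervals as BED
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `name`, `strand`.
#' @param path Output BED file.
#' @export
write_bed <- function(df, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand)
  gr$name <- df$name
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file as a data frame of 0-based half-open intervals
#' @param path Input BED file.
#' @return Data frame with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else NA_character_,
             strand = as.character(GenomicRanges::strand(gr)))
}

#' Read a gene-set annotation TSV (set_id, gene_id) into a named list
#' @param path Input TSV (two columns, no header).
#' @return Named list of character vectors of gene ids.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character",
                          col.names = c("set_id", "gene_id"))
  if (nrow(df) == 0L) return(list())
  split(df$gene_id, factor(df$set_id, levels = unique(df$set_id)))
}

#' Write a gene-set annotation as TSV
#' @param sets Named list of character vectors of gene ids.
#' @param path Output file.
#' @export
write_gene_sets <- function(sets, path) {
  df <- data.frame(set_id = rep(names(sets), lengths(sets)),
                   gene_id = unlist(sets, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write simulation truth (or any result list) as JSON
#' @param x A list.
#' @param path Output JSON file.
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a JSON truth/result file
#' @param path Input JSON file.
#' @return A list.
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
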