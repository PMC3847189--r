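# Synthetic-data generators. Every downstream stage of the pipeline can be
# exercised on data produced here with known ground truth: miRNA families
# diversified by seed shifting and point mutation, genomes with planted
# homologs at controlled mismatch levels, multi-species UTR alignments with
# independently controlled site/flank substitution rates, overdispersed
# orthologue count tables with a planted down-regulated target set, and
# gene-set annotations with a planted enriched pathway.
#
# All generators are pure functions of their rng_seed: identical seeds give
# identical outputs.

.RNA_ALPHA <- c("A", "C", "G", "U")

.rand_rna <- function(n) paste(sample(.RNA_ALPHA, n, replace = TRUE),
                               collapse = "")

.check_prob <- function(x, what) {
  if (any(x < 0 | x > 1)) stop(sprintf("%s must lie in [0, 1]", what))
  invisible(x)
}

#' Generate a synthetic miRNA catalog with family diversification
#'
#' Each family derives from one ancestral 28-nt precursor-arm sequence whose
#' positions 4-25 form the base mature (22 nt). With probability `shift_prob`
#' a member's dominant mature start is offset by 1-3 nt (either direction);
#' with probability `point_mut_prob` one seed base (mature positions 2-8) is
#' substituted. Hairpins embed the member's arm followed by an 8-nt loop and
#' the arm's reverse complement, so every mature is a substring of its
#' hairpin. Per-sample read counts are drawn from a negative-binomial model
#' around a log-normal member mean.
#'
#' @param n_families Number of families (>= 1).
#' @param members_per_family Members per family (>= 1).
#' @param shift_prob Probability of a seed shift per member.
#' @param point_mut_prob Probability of a seed point mutation per member.
#' @param n_samples Number of count samples per member (default 3).
#' @param rng_seed Integer seed; identical seeds give identical catalogs.
#' @return List with `catalog` (list of [mirna_record()]) and `truth`
#'   (data frame: `mirna_id`, `family`, `relation` in
#'   identical/shifted/mutated/shifted_mutated, `shift_k`, `mut_seed_pos`,
#'   `seed`).
#' @export
gen_mirna_catalog <- function(n_families, members_per_family,
                              shift_prob = 0.3, point_mut_prob = 0.2,
                              n_samples = 3L, rng_seed = 1L) {
  if (n_families < 1L || members_per_family < 1L)
    stop("n_families and members_per_family must be positive")
  .check_prob(c(shift_prob, point_mut_prob), "probabilities")
  set.seed(rng_seed)
  catalog <- list()
  truth <- list()
  for (f in seq_len(n_families)) {
    locus <- .rand_rna(28L)
    loop <- .rand_rna(8L)
    for (m in seq_len(members_per_family)) {
      id <- sprintf("syn-mir-f%02d-m%02d", f, m)
      k <- 0L
      relation <- "identical"
      if (stats::runif(1) < shift_prob) {
        k <- sample(c(-3:-1, 1:3), 1L)
        relation <- "shifted"
      }
      locus_m <- locus
      mut_pos <- NA_integer_
      if (stats::runif(1) < point_mut_prob) {
        mut_pos <- sample(2:8, 1L)                 # seed position on the mature
        lp <- (3L + k) + mut_pos                   # locus coordinate
        old <- substr(locus_m, lp, lp)
        substr(locus_m, lp, lp) <- sample(setdiff(.RNA_ALPHA, old), 1L)
        relation <- if (relation == "shifted") "shifted_mutated" else "mutated"
      }
      mature <- substr(locus_m, 4L + k, 25L + k)
      hairpin <- paste0(locus_m, loop, rna_revcomp(locus_m))
      mu <- stats::rlnorm(1, log(60), 1.5)
      counts <- stats::setNames(stats::rnbinom(n_samples, mu = mu, size = 5),
                                paste0("s", seq_len(n_samples)))
      catalog[[id]] <- mirna_record(id, mature, hairpin,
                                    star_seq = rna_revcomp(mature),
                                    counts = counts)
      truth[[id]] <- data.frame(mirna_id = id, family = f,
                                relation = relation, shift_k = k,
                                mut_seed_pos = mut_pos,
                                seed = extract_seed(mature))
    }
  }
  list(catalog = catalog, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
}

# Symmetric substitution: change hairpin position p and keep its partner
# (n+1-p) complementary, so a variant precursor stays base-paired.
.variant_hairpin <- function(hairpin, mature, n_subs) {
  n <- nchar(hairpin)
  m0 <- regexpr(mature, hairpin, fixed = TRUE)[1]
  stopifnot(m0 > 0L)
  pos <- if (n_subs > 0L) sample(seq(m0, m0 + nchar(mature) - 1L), n_subs)
         else integer()
  for (p in pos) {
    old <- substr(hairpin, p, p)
    new <- sample(setdiff(.RNA_ALPHA, old), 1L)
    substr(hairpin, p, p) <- new
    q <- n + 1L - p
    if (q != p) substr(hairpin, q, q) <- unname(.COMP_RNA[new])
  }
  hairpin
}

# Scramble every 4th base of the 3' arm (mature left intact) so the copy
# still passes sequence screens (alignment extension stays score-positive)
# but no longer folds into a stable hairpin.
.destabilized_hairpin <- function(hairpin, mature) {
  n <- nchar(hairpin)
  m0 <- regexpr(mature, hairpin, fixed = TRUE)[1]
  m1 <- m0 + nchar(mature) - 1L
  arm3_from <- max(m1 + 1L, n - nchar(mature) - 5L)
  for (p in seq(arm3_from, n, by = 4L)) {
    old <- substr(hairpin, p, p)
    substr(hairpin, p, p) <- sample(setdiff(.RNA_ALPHA, old), 1L)
  }
  hairpin
}

#' Generate species genomes with planted miRNA homologs
#'
#' Each species receives a random background genome into which the hairpins
#' of its designated carrier miRNAs are planted with exactly `mismatch_level`
#' substitutions in the mature region (applied symmetrically to both arms, so
#' the variant precursor remains base-paired and stable). Shuffled-hairpin
#' decoys are added at `decoy_rate`. Backgrounds and decoys are verified to
#' contain no sequence within 2 mismatches of any non-carrier mature (on
#' either strand) outside planted carrier regions. A species spec may set
#' `destabilize = TRUE` to plant copies whose 3' arm is scrambled: such copies
#' pass sequence screens but fail a folding-stability filter.
#'
#' @param catalog List of [mirna_record()] objects.
#' @param species_specs List of specs, each a list with `species_id`,
#'   `carriers` (character vector of miRNA ids, may be empty),
#'   `mismatch_level` (>= 0), `decoy_rate` (probability) and optional
#'   `destabilize` (default `FALSE`).
#' @param genome_len Genome length per species; must host all planted
#'   hairpins without overlap.
#' @param rng_seed Integer seed.
#' @return List with `genomes` (named character vector, DNA), `truth`
#'   (data frame `planted_homologs`: species, miRNA, mismatch level, identity
#'   fraction over the hairpin, destabilized flag) and `bed` (data frame of
#'   planted intervals, 0-based half-open).
#' @export
gen_species_genomes <- function(catalog, species_specs, genome_len = 20000L,
                                rng_seed = 1L) {
  stopifnot(length(catalog) >= 1L, length(species_specs) >= 1L)
  ids <- vapply(catalog, `[[`, "", "mirna_id")
  names(catalog) <- ids
  hp_len <- max(vapply(catalog, function(x) nchar(x$hairpin_seq), integer(1)))
  if (hp_len > genome_len)
    stop("hairpin longer than genome_len")
  set.seed(rng_seed)
  genomes <- character()
  planted <- list()
  bed <- list()
  for (spec in species_specs) {
    if (spec$mismatch_level < 0L) stop("mismatch_level must be >= 0")
    .check_prob(spec$decoy_rate, "decoy_rate")
    destab <- isTRUE(spec$destabilize)
    carriers <- intersect(spec$carriers, ids)
    inserts <- list()
    for (mid in carriers) {
      rec <- catalog[[mid]]
      hp <- .variant_hairpin(rec$hairpin_seq, rec$mature_seq,
                             spec$mismatch_level)
      n_destab <- 0L
      if (destab) {
        before <- hp
        hp <- .destabilized_hairpin(hp, rec$mature_seq)
        n_destab <- sum(strsplit(hp, "")[[1]] != strsplit(before, "")[[1]])
      }
      inserts[[length(inserts) + 1L]] <-
        list(name = mid, seq = hp, planted = TRUE,
             identity = (nchar(hp) - 2L * spec$mismatch_level - n_destab) /
               nchar(hp))
    }
    n_decoys <- stats::rbinom(1L, length(catalog), spec$decoy_rate)
    non_carrier <- setdiff(ids, carriers)
    for (tries in seq_len(50L)) {
      ok <- TRUE
      decoys <- lapply(seq_len(n_decoys), function(d) {
        src <- catalog[[sample(length(catalog), 1L)]]$hairpin_seq
        list(name = sprintf("decoy%02d", d),
             seq = paste(sample(strsplit(src, "")[[1]]), collapse = ""),
             planted = FALSE, identity = NA_real_)
      })
      all_ins <- c(inserts, decoys)
      bg <- paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
                  collapse = "")
      slot <- genome_len %/% (length(all_ins) + 1L)
      if (length(all_ins) && slot <= hp_len + 10L)
        stop("genome_len too small to host all planted hairpins")
      g <- bg
      coords <- list()
      for (i in seq_along(all_ins)) {
        s0 <- i * slot                                  # 0-based insert start
        sq <- .dna(all_ins[[i]]$seq)
        substr(g, s0 + 1L, s0 + nchar(sq)) <- sq
        coords[[i]] <- c(s0, s0 + nchar(sq))
      }
      # planted-carrier regions are the only admissible near-matches of
      # non-carrier matures (family siblings); anything else forces a redraw
      planted_iv <- do.call(rbind, coords[vapply(all_ins, `[[`, FALSE,
                                                 "planted")])
      for (mid in non_carrier) {
        hits <- mature_match(catalog[[mid]]$mature_seq, g, 2L)
        if (nrow(hits)) {
          inside <- vapply(seq_len(nrow(hits)), function(h)
            !is.null(planted_iv) && nrow(planted_iv) > 0 &&
              any(hits$start[h] >= planted_iv[, 1] &
                    hits$end[h] <= planted_iv[, 2]), logical(1))
          if (!all(inside)) { ok <- FALSE; break }
        }
      }
      if (ok) break
    }
    if (!ok) stop("could not generate a clean background genome")
    genomes[[spec$species_id]] <- g
    for (i in seq_along(all_ins)) {
      ins <- all_ins[[i]]
      bed[[length(bed) + 1L]] <- data.frame(
        chrom = spec$species_id, start = coords[[i]][1], end = coords[[i]][2],
        name = ins$name, strand = "+")
      if (ins$planted)
        planted[[length(planted) + 1L]] <- data.frame(
          species_id = spec$species_id, mirna_id = ins$name,
          mismatch_level = spec$mismatch_level,
          identity_fraction = ins$identity, destabilized = destab,
          start = coords[[i]][1], end = coords[[i]][2])
    }
  }
  list(genomes = genomes,
       truth = list(planted_homologs =
                      if (length(planted)) do.call(rbind, planted)
                      else data.frame(species_id = character(),
                                      mirna_id = character(),
                                      mismatch_level = integer(),
                                      identity_fraction = numeric(),
                                      destabilized = logical(),
                                      start = integer(), end = integer())),
       bed = do.call(rbind, bed))
}

.SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1")

.site_pattern <- function(seed, type) {
  rc <- rna_revcomp(seed)
  switch(type,
         "8mer" = paste0(rc, "A"),
         "7mer-m8" = rc,
         "7mer-A1" = paste0(substr(rc, 2L, 7L), "A"))
}

#' Generate multi-species gapped UTR alignments with planted seed sites
#'
#' Reference (first species) UTRs are random; a fraction of genes receives
#' one planted exact seed site of a catalog miRNA (site class sampled
#' uniformly), positioned so that full flanks fit where possible. Every other
#' species' row derives from the reference by per-base substitution at
#' `site_sub_rate` inside planted site columns and `flank_sub_rate`
#' elsewhere, plus per-base deletions ('-') at `indel_rate` (non-reference
#' rows only, so reference coordinates stay contiguous and the alignment
#' rectangular). With probability `retention_prob` a (gene, species) site is
#' retained: its columns are copied exactly (no substitutions, no gaps);
#' otherwise site columns evolve freely under `site_sub_rate`. The truth
#' records the realized per-species conservation of every planted site.
#'
#' @param n_genes Number of genes.
#' @param species_list Character vector of species; the first is the
#'   reference.
#' @param catalog List of [mirna_record()] whose seeds are planted (cycled).
#' @param site_frac Fraction of genes receiving a planted site.
#' @param retention_prob Per-(gene, species) probability a planted site is
#'   retained exactly.
#' @param site_sub_rate,flank_sub_rate,indel_rate Per-base probabilities.
#' @param utr_len UTR length (>= site length + total flank length, i.e. 104).
#' @param rng_seed Integer seed.
#' @return List with `blocks` (list of [utr_block()]) and `truth` (list:
#'   `planted_sites` data frame with `gene_id`, `mirna_id`, `site_type`,
#'   `ref_start`, `site_len`; `site_conservation` long data frame with
#'   `gene_id`, `species_id`, `conserved`; and the configured rates).
#' @export
gen_utr_alignment_set <- function(n_genes, species_list, catalog,
                                  site_frac = 0.5, retention_prob = 0.5,
                                  site_sub_rate = 0.1, flank_sub_rate = 0.1,
                                  indel_rate = 0, utr_len = 120L,
                                  rng_seed = 1L) {
  stopifnot(n_genes >= 1L, length(species_list) >= 2L, length(catalog) >= 1L)
  .check_prob(c(site_frac, retention_prob, site_sub_rate, flank_sub_rate,
                indel_rate), "rates")
  if (utr_len < 8L + 96L)
    stop("utr_len must be at least 104 (site plus full flanks)")
  set.seed(rng_seed)
  ref_sp <- species_list[1]
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  L <- as.integer(utr_len)
  ref_idx <- matrix(sample.int(4L, n_genes * L, replace = TRUE), n_genes, L)
  n_plant <- round(site_frac * n_genes)
  planted_rows <- sort(sample.int(n_genes, n_plant))
  mirna_ids <- vapply(catalog, `[[`, "", "mirna_id")
  seeds <- vapply(catalog, function(x) extract_seed(x$mature_seq), "")
  sites <- NULL
  site_mask <- matrix(FALSE, n_genes, L)
  if (n_plant > 0L) {
    pick <- rep_len(seq_along(catalog), n_plant)
    type <- sample(.SITE_TYPES, n_plant, replace = TRUE)
    slen <- ifelse(type == "8mer", 8L, 7L)
    fps <- ifelse(slen == 8L, 48L, 42L)
    lo <- fps
    hi <- L - slen - fps
    ref_start <- lo + floor(stats::runif(n_plant) * (hi - lo + 1L))
    for (i in seq_len(n_plant)) {
      pat <- strsplit(.site_pattern(seeds[pick[i]], type[i]), "")[[1]]
      cols <- (ref_start[i] + 1L):(ref_start[i] + slen[i])
      ref_idx[planted_rows[i], cols] <- match(pat, .RNA_ALPHA)
      site_mask[planted_rows[i], cols] <- TRUE
      # keep the planted class exact: forbid the chance flanking bases that
      # would upgrade a 7mer to an overlapping 8mer call
      rc1 <- match(substr(rna_revcomp(seeds[pick[i]]), 1L, 1L), .RNA_ALPHA)
      if (type[i] == "7mer-A1" && ref_idx[planted_rows[i], cols[1] - 1L] == rc1)
        ref_idx[planted_rows[i], cols[1] - 1L] <-
          sample(setdiff(1:4, rc1), 1L)
      if (type[i] == "7mer-m8" &&
          ref_idx[planted_rows[i], cols[slen[i]] + 1L] == 1L)
        ref_idx[planted_rows[i], cols[slen[i]] + 1L] <- sample(2:4, 1L)
    }
    sites <- data.frame(gene_id = gene_ids[planted_rows],
                        mirna_id = mirna_ids[pick],
                        site_type = type, ref_start = ref_start,
                        site_len = slen)
  }
  rate_mat <- matrix(flank_sub_rate, n_genes, L)
  rate_mat[site_mask] <- site_sub_rate
  rows <- list()
  rows[[ref_sp]] <- list(idx = ref_idx, gap = matrix(FALSE, n_genes, L))
  cons <- list()
  for (sp in species_list[-1]) {
    exempt <- matrix(FALSE, n_genes, L)
    retained <- logical(n_plant)
    if (n_plant > 0L) {
      retained <- stats::runif(n_plant) < retention_prob
      for (i in which(retained))
        exempt[planted_rows[i],
               (sites$ref_start[i] + 1L):(sites$ref_start[i] +
                                            sites$site_len[i])] <- TRUE
    }
    sub_mask <- (matrix(stats::runif(n_genes * L), n_genes, L) < rate_mat) &
      !exempt
    gap_mask <- (matrix(stats::runif(n_genes * L), n_genes, L) < indel_rate) &
      !exempt
    idx <- ref_idx
    nm <- sum(sub_mask)
    if (nm > 0L)
      idx[sub_mask] <- ((idx[sub_mask] - 1L +
                           sample.int(3L, nm, replace = TRUE)) %% 4L) + 1L
    rows[[sp]] <- list(idx = idx, gap = gap_mask)
    if (n_plant > 0L) {
      changed <- vapply(seq_len(n_plant), function(i) {
        cols <- (sites$ref_start[i] + 1L):(sites$ref_start[i] +
                                             sites$site_len[i])
        any(sub_mask[planted_rows[i], cols] | gap_mask[planted_rows[i], cols])
      }, logical(1))
      cons[[sp]] <- data.frame(gene_id = sites$gene_id, species_id = sp,
                               conserved = !changed)
    }
  }
  to_strings <- function(r) {
    ch <- matrix(.RNA_ALPHA[r$idx], n_genes, L)
    ch[r$gap] <- "-"
    do.call(paste0, lapply(seq_len(L), function(j) ch[, j]))
  }
  mats <- lapply(rows, to_strings)
  blocks <- lapply(seq_len(n_genes), function(g)
    utr_block(gene_ids[g], species_list,
              vapply(species_list, function(sp) mats[[sp]][g], ""),
              ref_sp))
  names(blocks) <- gene_ids
  list(blocks = blocks,
       truth = list(
         planted_sites = if (is.null(sites))
           data.frame(gene_id = character(), mirna_id = character(),
                      site_type = character(), ref_start = integer(),
                      site_len = integer()) else sites,
         site_conservation = if (length(cons)) do.call(rbind, c(cons, make.row.names = FALSE))
           else data.frame(gene_id = character(), species_id = character(),
                           conserved = logical()),
         site_sub_rate = site_sub_rate, flank_sub_rate = flank_sub_rate,
         indel_rate = indel_rate))
}

#' Generate orthologue expression count tables with a planted target effect
#'
#' Counts for two species are drawn from a negative-binomial model around
#' gene-specific log-normal mean cpm values; the species-A means of the
#' designated target genes are scaled by `2^(-effect_log2)` (down-regulation
#' in species A). The orthologue map is the identity on gene ids.
#'
#' @param n_genes Number of genes (ids `g00001` ...).
#' @param target_ids Character vector of target gene ids (subset of the
#'   universe).
#' @param effect_log2 Log2 down-regulation applied to targets in species A.
#' @param dispersion Negative-binomial dispersion (> 0; variance =
#'   mu + dispersion * mu^2).
#' @param library_sizes List with numeric vectors `a` and `b` of per-sample
#'   mapped-read totals for the two species.
#' @param rng_seed Integer seed.
#' @return List with `expr_a`, `expr_b` ([count_table()]s), `ortholog_map`
#'   (data frame `gene_a`, `gene_b`) and `truth` (list: `target_ids`,
#'   `effect_log2`).
#' @export
gen_expression_tables <- function(n_genes, target_ids, effect_log2 = 1,
                                  dispersion = 0.1,
                                  library_sizes = list(a = rep(2e7, 3),
                                                       b = rep(2e7, 3)),
                                  rng_seed = 1L) {
  stopifnot(n_genes >= 1L)
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(unlist(library_sizes) <= 0)) stop("library sizes must be positive")
  if (!is.finite(effect_log2)) stop("effect_log2 must be finite")
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  if (length(setdiff(target_ids, gene_ids)))
    stop("target_ids must be a subset of the gene universe")
  set.seed(rng_seed)
  base_cpm <- stats::rlnorm(n_genes, meanlog = log(30), sdlog = 1.2)
  cpm_a <- base_cpm
  cpm_a[gene_ids %in% target_ids] <-
    cpm_a[gene_ids %in% target_ids] * 2^(-effect_log2)
  draw <- function(cpm, libs, prefix) {
    mu <- outer(cpm, libs / 1e6)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow(mu), ncol(mu))
    dimnames(counts) <- list(gene_ids,
                             paste0(prefix, seq_along(libs)))
    count_table(counts, stats::setNames(libs, colnames(counts)))
  }
  expr_a <- draw(cpm_a, library_sizes$a, "a")
  expr_b <- draw(base_cpm, library_sizes$b, "b")
  list(expr_a = expr_a, expr_b = expr_b,
       ortholog_map = data.frame(gene_a = gene_ids, gene_b = gene_ids),
       truth = list(target_ids = target_ids, effect_log2 = effect_log2))
}

#' Generate gene-set annotations with one planted enriched set
#'
#' The designated first set (`set001`) contains exactly `planted_overlap`
#' target genes plus fillers drawn from the non-target universe; all other
#' sets are sampled uniformly from the universe.
#'
#' @param universe Character vector of gene ids.
#' @param n_sets Number of sets (0 gives an empty annotation).
#' @param set_size Genes per set (<= universe size).
#' @param planted_overlap Target genes placed in the planted set
#'   (<= min(set_size, number of targets)).
#' @param target_ids Character vector of target gene ids.
#' @param rng_seed Integer seed.
#' @return List with `gene_sets` (named list) and `truth` (list:
#'   `enriched_set_id`, `planted_overlap`; `NULL` id when `n_sets` is 0).
#' @export
gen_gene_sets <- function(universe, n_sets, set_size, planted_overlap,
                          target_ids, rng_seed = 1L) {
  if (set_size > length(universe)) stop("set_size exceeds the universe")
  if (planted_overlap > min(set_size, length(target_ids)))
    stop("planted_overlap exceeds set_size or the number of targets")
  set.seed(rng_seed)
  if (n_sets == 0L)
    return(list(gene_sets = list(),
                truth = list(enriched_set_id = NULL, planted_overlap = 0L)))
  sets <- list()
  non_target <- setdiff(universe, target_ids)
  planted <- c(sample(target_ids, planted_overlap),
               sample(non_target, set_size - planted_overlap))
  sets[["set001"]] <- sample(planted)
  for (i in seq_len(n_sets - 1L))
    sets[[sprintf("set%03d", i + 1L)]] <- sample(universe, set_size)
  list(gene_sets = sets,
       truth = list(enriched_set_id = "set001",
                    planted_overlap = planted_overlap))
}
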