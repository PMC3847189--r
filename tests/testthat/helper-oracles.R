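# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

oracle_dna_comp <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp_dna <- function(x) {
  paste(rev(unname(oracle_dna_comp[strsplit(x, "")[[1]]])), collapse = "")
}

# All-window Hamming scan over both strands; coordinates 0-based half-open
# on the forward strand.
oracle_hamming_hits <- function(mature_dna, genome, max_mm) {
  L <- nchar(mature_dna)
  n <- nchar(genome)
  out <- NULL
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") mature_dna else oracle_revcomp_dna(mature_dna)
    pc <- strsplit(pat, "")[[1]]
    for (p in seq_len(n - L + 1L)) {
      w <- strsplit(substr(genome, p, p + L - 1L), "")[[1]]
      mm <- sum(w != pc)
      if (mm <= max_mm)
        out <- rbind(out, data.frame(start = p - 1L, end = p - 1L + L,
                                     strand = strand, mismatches = mm))
    }
  }
  if (is.null(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer()))
  out[order(out$start, out$strand), , drop = FALSE]
}

# Affine-gap Smith-Waterman best local score: match +1, mismatch -2,
# a gap of length k costs 5 + 2*(k-1).
oracle_sw_score <- function(a, b) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  NEG <- -1e9
  M <- matrix(0, m + 1L, n + 1L)
  Ix <- matrix(NEG, m + 1L, n + 1L)
  Iy <- matrix(NEG, m + 1L, n + 1L)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (a[i] == b[j]) 1 else -2
      M[i + 1L, j + 1L] <- max(0, max(M[i, j], Ix[i, j], Iy[i, j]) + s)
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - 5, Ix[i, j + 1L] - 2)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - 5, Iy[i + 1L, j] - 2)
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

# Maximum absolute gap between the two empirical CDFs.
oracle_ecdf_gap <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  fx <- vapply(pts, function(t) mean(x <= t), numeric(1))
  fy <- vapply(pts, function(t) mean(y <= t), numeric(1))
  max(abs(fx - fy))
}

# Exact hypergeometric upper tail P(X >= k) by combinatorial sum.
oracle_hyper_p <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Exhaustive enumeration of canonical seed sites with class priority
# 8mer > 7mer-m8 > 7mer-A1, reporting each start once.
oracle_rc_rna <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}

oracle_seed_sites <- function(seed, utr) {
  rc <- oracle_rc_rna(seed)
  site8 <- paste0(rc, "A")
  site7a1 <- paste0(substr(rc, 2L, 7L), "A")
  n <- nchar(utr)
  out <- NULL
  for (p in seq_len(max(0L, n - 7L + 1L))) {
    w8 <- if (p + 7L <= n) substr(utr, p, p + 7L) else ""
    w7 <- substr(utr, p, p + 6L)
    type <- NA_character_
    if (w8 == site8) type <- "8mer"
    else if (w7 == rc) {
      # not extendable to an 8mer at this start
      if (!(p + 7L <= n && substr(utr, p + 7L, p + 7L) == "A"))
        type <- "7mer-m8"
    } else if (w7 == site7a1) {
      # not the tail of an 8mer starting one base upstream
      if (!(p >= 2L && substr(utr, p - 1L, p + 6L) == site8))
        type <- "7mer-A1"
    }
    if (!is.na(type))
      out <- rbind(out, data.frame(ref_start = p - 1L, site_type = type))
  }
  if (is.null(out)) data.frame(ref_start = integer(), site_type = character())
  else out
}

rand_rna_str <- function(n) paste(sample(c("A","C","G","U"), n, TRUE),
                                  collapse = "")
rand_dna_str <- function(n) paste(sample(c("A","C","G","T"), n, TRUE),
                                  collapse = "")

# Crafted alignment block from explicit rows (character vectors of rows).
craft_block <- function(gene, species, rows, ref = species[1]) {
  utr_block(gene, species, rows, ref)
}
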