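# RNA secondary-structure folding: a self-contained nearest-neighbour
# dynamic-programming model used to screen candidate precursor hairpins by
# minimum free energy, plus a pluggable model hook so any external folder
# emitting "sequence -> kcal/mol" can be substituted.

.PAIR_NAMES <- c("AU", "UA", "CG", "GC", "GU", "UG")

# Nearest-neighbour stack free energies (kcal/mol, 37 C), outer pair in rows,
# inner (stacked) pair in columns. Values follow the standard Turner-style
# parameterization to ~0.1 kcal/mol; they are defaults of this model, exposed
# for inspection, not a re-derivation of any published table.
.STACK_E <- matrix(c(
  #  AU     UA     CG     GC     GU     UG
  -0.93, -1.10, -2.24, -2.08, -0.55, -1.36,  # AU
  -1.33, -0.93, -2.35, -2.11, -1.00, -1.27,  # UA
  -2.11, -2.08, -3.26, -2.36, -1.41, -2.11,  # CG
  -2.35, -2.24, -3.42, -3.26, -1.53, -2.51,  # GC
  -1.27, -1.36, -2.51, -2.11,  1.29, -0.50,  # GU
  -1.00, -0.55, -1.53, -1.41, -0.30,  1.29   # UG
), nrow = 6, byrow = TRUE, dimnames = list(.PAIR_NAMES, .PAIR_NAMES))

# Hairpin-loop closure penalty by loop size (>= 3 unpaired bases).
.hairpin_e <- function(u) {
  tab <- c(5.4, 5.6, 5.7, 5.4, 6.0, 5.5, 6.4)  # u = 3..9
  if (u <= 9L) tab[u - 2L] else 6.4 + 1.08 * log(u / 9)
}

# Interior/bulge loop penalty for u unpaired bases in total (1 <= u <= cap).
.interior_e <- function(u) 2.9 + 0.5 * u

#' Minimum free energy of an RNA sequence under the default folding model
#'
#' Dynamic-programming fold over canonical Watson-Crick plus G:U wobble pairs
#' with nearest-neighbour stack energies, a hairpin-loop closure penalty, a
#' minimum hairpin loop of 3 nt, and small interior/bulge loops (up to
#' `max_interior` unpaired bases, flat-plus-size penalty). Unpaired regions
#' cost nothing, so the energy is always <= 0 and equals 0 for sequences
#' admitting no pairs (e.g. homopolymers).
#'
#' @param seq RNA sequence (T accepted as U).
#' @param max_interior Largest total unpaired size of an interior/bulge loop.
#' @return Minimum free energy in kcal/mol (<= 0).
#' @export
rna_mfe <- function(seq, max_interior = 10L) {
  s <- strsplit(.rna(seq), "")[[1]]
  n <- length(s)
  if (n < 5L) return(0)
  pk <- outer(s, s, paste0)
  pairable <- matrix(pk %in% .PAIR_NAMES, n, n)
  V <- matrix(Inf, n, n)
  W <- matrix(0, n, n)
  for (d in 4:(n - 1L)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      if (pairable[i, j]) {
        best <- .hairpin_e(d - 1L)
        if (pairable[i + 1L, j - 1L] && is.finite(V[i + 1L, j - 1L]))
          best <- min(best, .STACK_E[pk[i, j], pk[i + 1L, j - 1L]] +
                        V[i + 1L, j - 1L])
        kmax <- min(i + 1L + max_interior, j - 5L)
        if (kmax > i + 1L || j - 1L > i + 5L) {
          for (k in (i + 1L):kmax) {
            lmin <- max(k + 4L, j - 1L - max_interior)
            if (lmin > j - 1L) next
            for (l in lmin:(j - 1L)) {
              u <- (k - i - 1L) + (j - l - 1L)
              if (u >= 1L && u <= max_interior && is.finite(V[k, l]))
                best <- min(best, .interior_e(u) + V[k, l])
            }
          }
        }
        V[i, j] <- best
      }
      w <- min(W[i + 1L, j], W[i, j - 1L], V[i, j])
      ks <- i:(j - 1L)
      w <- min(w, min(W[cbind(i, ks)] + W[cbind(ks + 1L, j)]))
      W[i, j] <- w
    }
  }
  min(0, W[1L, n])
}

#' Construct a folding model
#'
#' A folding model is a named energy function from an RNA string to kcal/mol.
#' The contract: energy <= 0 whenever at least one canonical pair stack is
#' admissible, and energy = 0 for sequences with no admissible pairs.
#'
#' @param name Model name.
#' @param energy_fn Function `character -> numeric` (kcal/mol).
#' @return An object of class `fold_model`.
#' @export
fold_model <- function(name, energy_fn) {
  stopifnot(is.function(energy_fn))
  structure(list(name = name, energy = energy_fn), class = "fold_model")
}

#' Default nearest-neighbour folding model
#' @return A [fold_model()] wrapping [rna_mfe()].
#' @export
nn_fold_model <- function() fold_model("nn_stack_dp", rna_mfe)

#' Folding model backed by an external command
#'
#' Runs `cmd` with the sequence on stdin and parses the trailing
#' `(<energy>)` of the last output line, the convention of RNAfold-style
#' folders. Provided as a hook for users who prefer an external
#' thermodynamic folder over the built-in model.
#'
#' @param cmd Command to run (default `"RNAfold"`).
#' @param args Character vector of extra arguments (default `"--noPS"`).
#' @return A [fold_model()].
#' @export
external_fold_model <- function(cmd = "RNAfold", args = "--noPS") {
  fold_model(paste0("external:", cmd), function(seq) {
    out <- system2(cmd, args, stdout = TRUE, input = .rna(seq))
    m <- regmatches(out, regexpr("\\(\\s*(-?[0-9.]+)\\)\\s*$", out))
    m <- m[lengths(m) > 0 | nzchar(m)]
    if (!length(m)) stop(sprintf("could not parse energy from '%s' output", cmd))
    as.numeric(gsub("[()\\s]", "", m[length(m)], perl = TRUE))
  })
}

#' Hairpin minimum free energy under a folding model
#'
#' @param seq Candidate precursor sequence (RNA, length >= 15).
#' @param model A [fold_model()]; default [nn_fold_model()].
#' @return Minimum free energy in kcal/mol.
#' @export
hairpin_mfe <- function(seq, model = nn_fold_model()) {
  if (nchar(seq) < 15L)
    stop("sequence shorter than 15 nt cannot be folded as a hairpin")
  stopifnot(inherits(model, "fold_model"))
  model$energy(seq)
}
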