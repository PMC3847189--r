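test_that("canonical seed sites are found and classed correctly", {
  s1 <- find_seed_sites("GAGGUAG", "AAACUACCUCAAA")
  expect_equal(nrow(s1), 1L)
  expect_equal(s1$ref_start, 3L)
  expect_equal(s1$site_type, "8mer")
  expect_equal(s1$site_len, 8L)

  s2 <- find_seed_sites("GAGGUAG", "GGCUACCUCGG")
  expect_equal(s2$site_type, "7mer-m8")

  s3 <- find_seed_sites("GAGGUAG", "GGUACCUCAGG")   # positions 2-7 match + A
  expect_equal(s3$site_type, "7mer-A1")

  expect_equal(nrow(find_seed_sites("GAGGUAG", "AAAAAAAA")), 0L)
  expect_error(find_seed_sites("GAGGUA", "AAAA"), "7 nt")
})

test_that("an 8mer subsumes its 7mer-m8 and 7mer-A1 sub-matches", {
  # UTR containing exactly one 8mer: no additional 7mer calls may appear at
  # the same locus
  sites <- find_seed_sites("GAGGUAG", "GGGCUACCUCAGGG")
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$site_type, "8mer")
})

test_that("site prediction equals exhaustive pattern enumeration", {
  set.seed(51)
  for (rep in 1:10) {
    seed <- rand_rna_str(7)
    utr <- rand_rna_str(300)
    # plant each site class once so matches exist
    rc <- oracle_rc_rna(seed)
    substr(utr, 20, 27) <- paste0(rc, "A")
    substr(utr, 60, 66) <- rc
    substr(utr, 100, 106) <- paste0(substr(rc, 2, 7), "A")
    got <- find_seed_sites(seed, utr)
    want <- oracle_seed_sites(seed, utr)
    expect_equal(got$ref_start, want$ref_start)
    expect_equal(got$site_type, want$site_type)
  }
})

test_that("conservation requires perfect identity with any panel species", {
  ref <- "AAACUACCUCAAAGGG"
  same <- ref
  sub <- ref; substr(sub, 5, 5) <- "G"                # substitution in site
  gap <- ref; substr(gap, 6, 6) <- "-"                # indel in site
  b <- craft_block("g1", c("cow", "human", "mouse"), c(ref, same, sub))
  expect_equal(classify_site_conservation(b, 3, 8, c("human", "mouse")),
               "conserved")
  b2 <- craft_block("g1", c("cow", "human", "mouse"), c(ref, sub, gap))
  expect_equal(classify_site_conservation(b2, 3, 8, c("human", "mouse")),
               "reference_specific")
  # one substitution vs human but identical to mouse: conserved (any species)
  b3 <- craft_block("g1", c("cow", "human", "mouse"), c(ref, sub, same))
  expect_equal(classify_site_conservation(b3, 3, 8, c("human", "mouse")),
               "conserved")
  # gaps in every panel species over a site column: reference-specific
  b4 <- craft_block("g1", c("cow", "human", "mouse"), c(ref, gap, gap))
  expect_equal(classify_site_conservation(b4, 3, 8, c("human", "mouse")),
               "reference_specific")
})

test_that("conservation labels ignore panel order and non-panel species", {
  ref <- "AAACUACCUCAAAGGG"
  sub <- ref; substr(sub, 5, 5) <- "G"
  b <- craft_block("g1", c("cow", "human", "mouse", "frog"),
                   c(ref, sub, ref, sub))
  expect_equal(classify_site_conservation(b, 3, 8, c("human", "mouse")),
               classify_site_conservation(b, 3, 8, c("mouse", "human")))
  # frog is identical-to-ref nowhere near: removing it changes nothing
  expect_equal(classify_site_conservation(b, 3, 8, c("human", "mouse")),
               "conserved")
  # all panel species absent from the block
  expect_equal(classify_site_conservation(b, 3, 8, c("dog", "rat")),
               "unassessed")
  expect_error(classify_site_conservation(b, 12, 8, c("human")), "extends")
})

test_that("normalized divergence counts site and flank substitutions", {
  # identical rows: zero everywhere
  set.seed(52)
  ref <- rand_rna_str(104)
  b <- craft_block("g1", c("cow", "human"), c(ref, ref))
  r <- normalized_site_divergence(b, 48, 8, "human")
  expect_equal(r$normalized, 0)
  expect_equal(r$n_flank, 96)

  # 7-mer with one site substitution and identical flanks: 1/7
  ref7 <- rand_rna_str(91)
  oth7 <- ref7
  p <- 43  # inside the site (0-based start 42, length 7)
  substr(oth7, p, p) <- setdiff(c("A","C","G","U"), substr(ref7, p, p))[1]
  b7 <- craft_block("g2", c("cow", "human"), c(ref7, oth7))
  r7 <- normalized_site_divergence(b7, 42, 7, "human")
  expect_equal(r7$site_rate, 1 / 7)
  expect_equal(r7$flank_rate, 0)
  expect_equal(r7$normalized, 1 / 7, tolerance = 1e-12)
  expect_equal(r7$n_flank, 84)

  # 8-mer with identical site and 12 substitutions across the 96 flanks
  ref8 <- rand_rna_str(104)
  oth8 <- ref8
  flank_pos <- c(5, 10, 15, 20, 25, 30, 60, 65, 70, 80, 90, 100)  # 1-based
  for (q in flank_pos) {
    substr(oth8, q, q) <- setdiff(c("A","C","G","U"), substr(ref8, q, q))[1]
  }
  b8 <- craft_block("g3", c("cow", "human"), c(ref8, oth8))
  r8 <- normalized_site_divergence(b8, 48, 8, "human")
  expect_equal(r8$site_rate, 0)
  expect_equal(r8$flank_rate, 12 / 96)
  expect_equal(r8$normalized, -0.125)
})

test_that("gap columns are excluded from divergence denominators", {
  set.seed(53)
  ref <- rand_rna_str(104)
  oth <- ref
  substr(oth, 5, 5) <- "-"
  substr(oth, 10, 10) <- "-"
  b <- craft_block("g1", c("cow", "human"), c(ref, oth))
  r <- normalized_site_divergence(b, 48, 8, "human")
  expect_equal(r$n_flank, 94)
  expect_equal(r$flank_rate, 0)
  expect_error(normalized_site_divergence(b, 48, 8, "dog"), "dog")
})

test_that("flanks truncate at the UTR ends with adjusted denominators", {
  set.seed(54)
  ref <- rand_rna_str(110)
  b <- craft_block("g1", c("cow", "human"), c(ref, ref))
  # site at the very start: no upstream flank at all
  r <- normalized_site_divergence(b, 0, 7, "human")
  expect_equal(r$n_flank, 42)
  # site near the end: downstream flank truncated
  r2 <- normalized_site_divergence(b, 100, 7, "human")
  expect_equal(r2$n_flank, 42 + 3)
})

test_that("normalized divergence stays within [-1, 1] on simulated sites", {
  sim <- gen_mirna_catalog(2, 1, 0, 0, rng_seed = 55)
  u <- gen_utr_alignment_set(150, c("cow", "human"), sim$catalog,
                             site_frac = 1, retention_prob = 0,
                             site_sub_rate = 0.5, flank_sub_rate = 0.2,
                             indel_rate = 0.05, rng_seed = 56)
  d <- site_divergence_table(u$truth$planted_sites, u$blocks, "human")
  ok <- !is.na(d$normalized)
  expect_true(all(d$normalized[ok] >= -1 & d$normalized[ok] <= 1))
  expect_equal(d$normalized[ok], (d$site_rate - d$flank_rate)[ok])
})

test_that("the specificity-by-conservation table reproduces printed proportions", {
  tab <- matrix(c(6937, 13425, 4535, 13969), nrow = 2,
                dimnames = list(c("specific", "non_specific"),
                                c("reference_specific", "conserved")))
  res <- contingency_test(tab)
  expect_equal(round(res$proportions * 100), c(specific = 60,
                                               non_specific = 49))
  expect_lt(res$p_value, 1e-4)

  sym <- contingency_test(matrix(c(50, 50, 50, 50), 2))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  diag <- contingency_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag$statistic, 20)
  expect_lt(diag$p_value, 0.01)
})

test_that("specificity contingency is built from call labels", {
  calls <- data.frame(
    mirna_id = c(rep("mA", 4), rep("mB", 4)),
    conservation = c("reference_specific", "reference_specific", "conserved",
                     "reference_specific",
                     "conserved", "conserved", "reference_specific",
                     "conserved"))
  labels <- c(mA = "specific", mB = "non_specific")
  res <- specificity_contingency(calls, labels)
  expect_equal(unname(res$table[1, ]), c(3, 1))
  expect_equal(unname(res$table[2, ]), c(1, 3))
  calls$conservation[1] <- "unassessed"
  expect_error(specificity_contingency(calls, labels), "unassessed")
  expect_error(specificity_contingency(calls[0, ], labels), "empty")
})

test_that("the divergence KS statistic equals the brute-force ECDF gap", {
  set.seed(57)
  for (rep in 1:5) {
    a <- round(runif(10), 2)
    b <- round(runif(10), 2)
    got <- divergence_distribution_test(a, b)
    expect_equal(got$D, oracle_ecdf_gap(a, b))
  }
  same <- divergence_distribution_test(1:10 / 10, 1:10 / 10)
  expect_equal(same$D, 0)
  expect_equal(same$p_value, 1)
  expect_error(divergence_distribution_test(numeric(), 1:3), "non-empty")
})
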