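make_random_proteome <- function(id, n, len, seed) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  proteome_record(id, setNames(
    vapply(seq_len(n), function(i)
      paste(sample(aa, len, TRUE), collapse = ""), character(1)),
    paste0("p", seq_len(n))))
}

test_that("ANI is 100 on self and tracks simulated identity", {
  g <- genome_record("self", c(c1 = random_genome_seq(15000, 61)))
  expect_equal(ani(g, g), 100)

  pp <- evolve_pair(divergence_spec(100000, d = 0.05, seed = 8))
  a <- ani(pp$a, pp$b)
  expect_lt(abs(a - pp$truth$true_identity), 0.5)
})

test_that("ANI errors explicitly when nothing aligns", {
  g <- genome_record("short", c(c1 = strrep("ACGT", 100)))
  expect_error(ani(g, g, frag_len = 100000), "fragment")
})

test_that("AAI: identity, constructed divergence, and RBH filtering", {
  A <- make_random_proteome("A", 4, 250, 71)
  expect_equal(aai(A, A), 100)

  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
  set.seed(72)
  mut <- vapply(A$proteins, function(p) {
    v <- strsplit(p, "")[[1]]
    for (i in seq(10, length(v), by = 10))
      v[i] <- sample(setdiff(aa, v[i]), 1)
    paste(v, collapse = "")
  }, character(1))
  B <- proteome_record("B", setNames(mut, paste0("q", seq_along(mut))))
  expect_lt(abs(aai(A, B) - 90), 1.5)

  # a pair of unrelated random proteins must not enter the mean:
  # hand-check the RBH table of a 3 x 3 toy
  C <- proteome_record("C", c(A$proteins[1:2], x = make_random_proteome(
    "t", 1, 250, 99)$proteins[[1]]))
  D <- proteome_record("D", c(setNames(mut[1:2], c("m1", "m2")),
                              y = make_random_proteome(
                                "u", 1, 250, 98)$proteins[[1]]))
  val <- aai(C, D)
  h <- phylodelim:::.protein_hits(C, D, 10, 0.5)
  rbh_ids <- c()
  for (i in 1:3) {
    j <- which.max(h$score[i, ])
    if (which.max(h$score[, j]) == i && h$pid[i, j] > 30 &&
        h$frac_short[i, j] > 0.7)
      rbh_ids <- c(rbh_ids, h$pid[i, j])
  }
  expect_equal(val, mean(rbh_ids))
  # the unrelated pair is below the identity filter
  expect_lt(h$pid[3, 3], 30)
})

test_that("POCP matches the closed formula on constructed proteomes", {
  A <- make_random_proteome("A", 10, 200, 81)
  expect_equal(pocp(A, A), 100)

  # A has 3 proteins, B has 4; 2 of A conserved in B and 2 of B in A
  A3 <- proteome_record("A3", A$proteins[1:3])
  B4 <- proteome_record("B4", c(
    setNames(A$proteins[1:2], c("c1", "c2")),
    u1 = make_random_proteome("x", 1, 200, 90)$proteins[[1]],
    u2 = make_random_proteome("y", 1, 200, 91)$proteins[[1]]))
  expect_equal(pocp(A3, B4), 100 * 4 / 7, tolerance = 1e-9)
})

test_that("coherence verdict applies the 95/98 bands", {
  expect_equal(coherence_verdict(list(ani = 94.43, D = 0.038))$verdict,
               "distinct")
  expect_true(coherence_verdict(list(ani = 94.43,
                                     D = 0.038))$high_coherence_flag)
  expect_equal(coherence_verdict(list(ani = 100, D = 0))$verdict,
               "conspecific")
  expect_equal(coherence_verdict(list(ani = 96.0))$verdict, "borderline")
  expect_error(coherence_verdict(list(D = 0.01)), "ANI")
})

test_that("indices stay in [0, 100] and hit 100 on self-comparison", {
  set.seed(83)
  for (i in 1:5) {
    p <- make_random_proteome("p", 3, 120, 830 + i)
    expect_equal(aai(p, p), 100)
    expect_equal(pocp(p, p), 100)
  }
  for (i in 1:3) {
    g <- genome_record("g", c(c1 = random_genome_seq(8000, 840 + i)))
    expect_equal(ani(g, g), 100)
  }
})
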