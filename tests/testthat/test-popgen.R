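test_that("marker concatenation is additive and policy-aware", {
  m1 <- marker_alignment("ITS", c(a = "ACGTA", b = "ACGTT", c = "ACGAA"))
  m2 <- marker_alignment("TEF1", c(a = "GGGGGGG", b = "GGGGGGT",
                                   c = "GGGGGTT"))
  cc <- concatenate(list(m1, m2))
  expect_equal(nchar(cc$rows[["a"]]), 12L)
  expect_equal(cc$rows[["b"]], "ACGTTGGGGGGT")
  # single marker is the identity
  expect_equal(concatenate(list(m1))$rows, m1$rows)
  # missing strain: strict errors, gap_fill pads
  m3 <- marker_alignment("RPB2", c(a = "TTT", b = "TTA"))
  expect_error(concatenate(list(m1, m3)), "missing")
  gf <- concatenate(list(m1, m3), missing_policy = "gap_fill")
  expect_equal(gf$rows[["c"]], "ACGAA---")
})

test_that("the Tajima's D worked example evaluates exactly", {
  # 4 sequences, 3 variable columns each with a singleton T, 4 invariant
  rows <- c(s1 = "AAAAAAA", s2 = "TAAAAAA", s3 = "ATAAAAA",
            s4 = "AATAAAA")
  ps <- popgen_summary(marker_alignment("toy", rows))
  expect_equal(ps$S, 3L)
  expect_equal(ps$pihat, 1.5)
  # hand evaluation of the 1989 constants at n = 4:
  # a1 = 11/6, a2 = 49/36, b1 = 5/9, b2 = 46/108, ...
  expect_equal(ps$tajimas_d, -0.754, tolerance = 1e-3)
  expect_equal(ps$parsimony_informative, 0L)
  expect_equal(ps$n_haplotypes, 4L)
})

test_that("monomorphic alignments degrade explicitly", {
  ps <- popgen_summary(marker_alignment("m",
                                        c(a = "AAA", b = "AAA",
                                          c = "AAA", d = "AAA")))
  expect_equal(ps$S, 0L)
  expect_equal(ps$pi_per_site, 0)
  expect_equal(ps$n_haplotypes, 1L)
  expect_equal(ps$hd, 0)
  expect_false(ps$tajima_defined)
  expect_true(is.na(ps$tajimas_d))
})

test_that("haplotype diversity follows the small-sample formula", {
  ps <- popgen_summary(marker_alignment("m",
                                        c(a = "AC", b = "AC",
                                          c = "GT", d = "GT")))
  expect_equal(ps$n_haplotypes, 2L)
  expect_equal(ps$hd, (4 / 3) * (1 - 0.5))
})

test_that("gap/ambiguity columns are excluded and invariant columns inert", {
  rows <- c(a = "ACGT-A", b = "ACGTNA", c = "ACTTCA", d = "ACGTYA")
  ps <- popgen_summary(marker_alignment("m", rows))
  expect_equal(ps$L, 5L)  # column 5 dropped (gap, N, Y)
  # adding an invariant column changes nothing but L
  rows2 <- setNames(paste0(rows, "G"), names(rows))
  ps2 <- popgen_summary(marker_alignment("m", rows2))
  expect_equal(ps2$S, ps$S)
  expect_equal(ps2$pihat, ps$pihat)
  expect_equal(ps2$tajimas_d, ps$tajimas_d)
  expect_equal(ps2$L, ps$L + 1L)
})

test_that("pi matches the brute-force pairwise oracle", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(4:8, 1); L <- sample(20:60, 1)
    rows <- setNames(vapply(seq_len(n), function(j)
      paste(sample(c("A", "C", "G", "T"), L, TRUE,
                   prob = c(0.4, 0.3, 0.2, 0.1)), collapse = ""),
      character(1)), paste0("s", 1:n))
    ps <- popgen_summary(marker_alignment("r", rows))
    or <- oracle_pairwise_pi(rows)
    expect_equal(ps$pihat, or$pihat)
    expect_equal(ps$pi_per_site, or$pi_per_site)
  }
})

test_that("parsimony-informative sites need two states in two sequences", {
  rows <- c(a = "AAT", b = "AAT", c = "ATA", d = "ATA")
  ps <- popgen_summary(marker_alignment("m", rows))
  expect_equal(ps$S, 2L)
  expect_equal(ps$parsimony_informative, 2L)
  rows2 <- c(a = "AT", b = "AA", c = "AA", d = "AA")
  expect_equal(popgen_summary(
    marker_alignment("m", rows2))$parsimony_informative, 0L)
})

test_that("neutral coalescent simulations give near-zero Tajima's D", {
  ds <- vapply(1:40, function(sd) {
    sim <- simulate_species_markers(species_sim_spec(
      1, tips_per_species = 20, within_theta = 5,
      marker_lengths = 1000L, seed = 7000 + sd))
    popgen_summary(sim$markers[[1]])$tajimas_d
  }, numeric(1))
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.35)
})
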