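test_that("variant classification is definitional", {
  expect_equal(classify_variant(variant_record("c", 1, "C", "CAGT")),
               "insertion")
  expect_equal(classify_variant(variant_record("c", 1, "A", "T")), "snv")
  expect_equal(classify_variant(variant_record("c", 1, "AC", "GT")),
               "complex")
  expect_equal(classify_variant(variant_record("c", 1, "ACGT", "A")),
               "deletion")
  # case-insensitive prefix test
  expect_equal(classify_variant(variant_record("c", 1, "t", "TTCG")),
               "insertion")
  expect_error(variant_record("c", 1, "A", "AZ"), "IUPAC")
  expect_error(variant_record("c", 0, "A", "T"), "pos")
})

test_that("the printed insertion table passes the k = 31 ALT-length screen", {
  path <- system.file("extdata", "table4_insertions.tsv",
                      package = "phylodelim")
  vs <- read_variant_table(path)
  expect_equal(length(vs), 14L)
  expect_true(all(vapply(vs, classify_variant, "") == "insertion"))
  kept <- filter_insertions(vs, k = 31, criterion = "alt_length")
  expect_equal(length(kept), 14L)
  # net-length reading excludes the 31-character ALT with net 30
  net <- filter_insertions(vs, k = 31, criterion = "net_length")
  alt31 <- vs[[which(vapply(vs, function(v) v$pos, 1L) == 1014012L)]]
  expect_equal(nchar(alt31$alt), 31L)
  expect_false(alt31$pos %in% vapply(net, function(v) v$pos, 1L))
  expect_equal(length(filter_insertions(list())), 0L)
})

test_that("filter matches a direct length comparison on simulated tables", {
  sim <- simulate_variant_table(
    100, class_probs = c(snv = 0, insertion = 1, deletion = 0),
    indel_len_sampler = function(m) c(rep(40L, 40), rep(5L, 60))[1:m],
    seed = 5)
  expect_equal(sum(sim$truth$alt_length >= 31), 40L)
  kept <- filter_insertions(sim$variants, k = 31)
  expect_equal(length(kept), 40L)
  mixed <- simulate_variant_table(200, seed = 6)
  kept2 <- filter_insertions(mixed$variants, k = 31)
  expect_equal(length(kept2),
               sum(mixed$truth$class == "insertion" &
                     mixed$truth$alt_length >= 31))
  # everything below k drops out
  small <- simulate_variant_table(
    50, class_probs = c(snv = 0, insertion = 1, deletion = 0),
    indel_len_sampler = function(m) rep(3L, m), seed = 7)
  expect_equal(length(filter_insertions(small$variants, k = 31)), 0L)
})

test_that("VCF-style input parses through the same reader", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tACCGT\t.\tPASS\tTYPE=INSERT",
               "chr1\t200\t.\tG\tT\t.\tPASS\t."), f)
  vs <- read_variant_table(f)
  expect_equal(length(vs), 2L)
  expect_equal(classify_variant(vs[[1]]), "insertion")
  expect_equal(classify_variant(vs[[2]]), "snv")
})

test_that("growth rate is the OLS slope of diameter on time", {
  expect_equal(growth_rate(c(0, 24, 48), c(0.5, 3.3, 6.1)),
               0.11667, tolerance = 1e-4)
  expect_equal(growth_rate(c(0, 10, 20), c(2, 2, 2)), 0)
  expect_equal(growth_rate(c(0, 48), c(0, 7.3)), 7.3 / 48)
  expect_error(growth_rate(c(0), c(1)), "2 time points")
  expect_error(growth_rate(c(0, 0), c(1, 2)), "strictly increasing")
})

test_that("PIRG follows its formula, is scale-invariant, flags reversals", {
  expect_equal(pirg(3.5, 0), 100)
  expect_equal(pirg(3.5, 3.5), 0)
  expect_equal(pirg(4, 1), 75)
  set.seed(1)
  for (i in 1:20) {
    r1 <- runif(1, 1, 5); r2 <- runif(1, 0, r1); cc <- runif(1, 0.1, 10)
    expect_equal(pirg(cc * r1, cc * r2), pirg(r1, r2))
  }
  expect_warning(pirg(2, 3), "negative")
  expect_error(pirg(0, 1), "r1")
  dm <- dual_culture_measure("F. oxysporum", 4, 0.5)
  expect_equal(dm$pirg, 87.5)
  expect_false(dm$flagged)
})

test_that("PIRG group comparison reproduces textbook ANOVA", {
  same <- list(a = c(50, 52, 48), b = c(50, 52, 48))
  res <- compare_pirg_groups(same)
  expect_lt(res$anova_f, 1e-10)
  expect_false(any(res$tukey$significant))

  sep <- list(a = c(100, 100, 100), b = c(0, 0, 0))
  res2 <- compare_pirg_groups(sep)
  expect_true(res2$tukey$significant[1])

  # closed-form F for three groups
  g <- list(x = c(1, 2, 3), y = c(4, 5, 6), z = c(7, 8, 9))
  res3 <- compare_pirg_groups(g)
  grand <- mean(unlist(g))
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, 1))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 1))
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(res3$anova_f, f_hand)
  expect_error(compare_pirg_groups(list(a = 1:3)), "2 groups")
  expect_error(compare_pirg_groups(list(a = 1:3, b = 5)), "replicates")
})
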