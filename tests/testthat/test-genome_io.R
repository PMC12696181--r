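test_that("FASTA read/write round-trips and rejects malformed input", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">s1 extra words", "ACGTA", "CGTAC", ">s2", "ggttaacc"), f)
  g <- read_fasta(f, id = "toy")
  expect_equal(length(g$scaffolds), 2L)
  expect_equal(unname(g$scaffolds["s1"]), "ACGTACGTAC")
  expect_equal(unname(g$scaffolds["s2"]), "ggttaacc")  # case preserved

  f2 <- tempfile(fileext = ".fa")
  write_fasta(g, f2, width = 4)
  g2 <- read_fasta(f2)
  expect_identical(unname(g2$scaffolds), unname(g$scaffolds))
  expect_identical(names(g2$scaffolds), names(g$scaffolds))

  fdup <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), fdup)
  expect_error(read_fasta(fdup), "duplicate")
  fempty <- tempfile(fileext = ".fa")
  file.create(fempty)
  expect_error(read_fasta(fempty), "empty")
})

test_that("assembly statistics match hand-enumerated N50/L50 and GC", {
  lens <- c(5, 4, 3, 2, 1)
  g <- genome_record("n50", setNames(
    vapply(lens, function(n) strrep("A", n), character(1)),
    paste0("s", seq_along(lens))))
  st <- assembly_stats(g)
  expect_equal(st$total_length, 15)
  expect_equal(unname(st$n50), 4)
  expect_equal(unname(st$l50), 2L)

  st2 <- assembly_stats(genome_record("gc", c(s1 = "GGCC")))
  expect_equal(st2$gc_percent, 100)
  expect_equal(unname(st2$n50), 4)
  expect_equal(unname(st2$l50), 1L)

  expect_error(assembly_stats(genome_record("nn", c(s1 = "NNNN"))),
               "GC undefined")
})

test_that("N50/L50 agree with a brute-force oracle and are order-invariant", {
  set.seed(11)
  for (i in 1:1000) {
    lens <- sample.int(5000, sample(1:12, 1), replace = TRUE)
    g <- genome_record("r", setNames(
      vapply(lens, function(n) strrep("A", n), character(1)),
      paste0("s", seq_along(lens))))
    st <- assembly_stats(g)
    or <- oracle_n50(lens)
    expect_equal(unname(st$n50), or$n50)
    expect_equal(unname(st$l50), or$l50)
  }
  # permutation invariance of scaffold order
  set.seed(12)
  seqs <- setNames(
    vapply(c(100, 37, 880, 12), function(n)
      paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = ""),
      character(1)), paste0("s", 1:4))
  s_a <- assembly_stats(genome_record("a", seqs))
  perm <- sample(names(seqs))
  s_b <- assembly_stats(genome_record("b", seqs[perm]))
  for (fld in c("total_length", "n50", "l50", "gc_percent"))
    expect_equal(unname(s_a[[fld]]), unname(s_b[[fld]]))
})

test_that("organelle detection is a size heuristic with inclusive bound", {
  g <- genome_record("mt", c(chr1 = strrep("A", 2000), mt = strrep("C", 500)))
  expect_equal(detect_organelle(g, max_len = 1000)$name, "mt")
  expect_equal(detect_organelle(g, max_len = 1000)$length, 500)
  expect_null(detect_organelle(g, max_len = 100)$name)
  # boundary is inclusive
  g2 <- genome_record("b", c(only = strrep("G", 99)))
  expect_equal(detect_organelle(g2, max_len = 99)$name, "only")
})

test_that("telomere scan flags repeat arrays at either end", {
  set.seed(3)
  mid <- paste(sample(c("A", "C"), 1000, TRUE), collapse = "")
  s <- paste0(strrep("CCCTAA", 5), mid, strrep("TTAGGG", 5))
  tel <- telomere_scan(genome_record("t", c(chr = s)))
  expect_true(tel[1, "p5"] && tel[1, "p3"])

  bare <- paste(sample(c("A", "C"), 2000, TRUE), collapse = "")
  tel2 <- telomere_scan(genome_record("t", c(chr = bare)))
  expect_false(any(tel2))

  # two copies below the min_copies = 3 default
  s3 <- paste0(strrep("TTAGGG", 2), bare)
  tel3 <- telomere_scan(genome_record("t", c(chr = s3)))
  expect_false(tel3[1, "p5"])
  expect_error(telomere_scan(genome_record("t", c(chr = s)), window = 3),
               "window")
})
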