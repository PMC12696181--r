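test_that("sketches are deterministic and bounded by the sketch size", {
  g <- genome_record("acgt", c(c1 = strrep("ACGT", 100)))
  sk <- make_sketch(g, k = 3, s = 100)
  # tiny alphabet: the sketch is the full distinct canonical 3-mer set
  expect_lte(length(sk$hashes), 100)
  expect_true(all(diff(sk$hashes) > 0))
  expect_identical(make_sketch(g, k = 3, s = 100)$hashes, sk$hashes)

  big <- genome_record("big", c(c1 = random_genome_seq(1000000, 77)))
  skb <- make_sketch(big, k = 21, s = 1000)
  expect_identical(length(skb$hashes), 1000L)

  expect_error(make_sketch(genome_record("n", c(c1 = "NNNNNNNN")), k = 5),
               "no valid k-mer")
})

test_that("Mash distance: identity, cap, closed form, parameter guards", {
  g <- genome_record("g", c(c1 = random_genome_seq(20000, 5)))
  sk <- make_sketch(g)
  expect_identical(mash_distance(sk, sk), 0)

  # disjoint hash sets hit the J = 0 cap
  a <- structure(list(genome_id = "a", k = 21L, s = 4L, seed = 42L,
                      hashes = c(1, 2, 3, 4)), class = "Sketch")
  b <- structure(list(genome_id = "b", k = 21L, s = 4L, seed = 42L,
                      hashes = c(5, 6, 7, 8)), class = "Sketch")
  expect_identical(mash_distance(a, b), 1.0)

  expect_equal(mash_d_from_jaccard(0.9, 21), -(1 / 21) * log(1.8 / 1.9))
  expect_equal(mash_d_from_jaccard(0.9, 21), 0.002575, tolerance = 1e-3)

  bk <- b; bk$k <- 15L
  expect_error(mash_distance(a, bk), "different k")
  bs <- b; bs$seed <- 7L
  expect_error(mash_distance(a, bs), "seed")
})

test_that("Mash distance is symmetric and zero on identity for random sketches", {
  set.seed(21)
  for (i in 1:200) {
    h <- sort(sample.int(1e6, 50))
    ha <- sort(sample(h, 30))
    hb <- sort(sample(h, 30))
    a <- structure(list(genome_id = "a", k = 21L, s = 30L, seed = 42L,
                        hashes = ha), class = "Sketch")
    b <- structure(list(genome_id = "b", k = 21L, s = 30L, seed = 42L,
                        hashes = hb), class = "Sketch")
    expect_identical(mash_distance(a, b), mash_distance(b, a))
    expect_identical(mash_distance(a, a), 0)
  }
})

test_that("sketch Jaccard tracks the exact k-mer Jaccard", {
  hits <- 0
  for (i in 1:20) {
    pair <- diverged_pair_seq(30000, 0.03, seed = 100 + i)
    ga <- genome_record("a", c(c1 = pair$a))
    gb <- genome_record("b", c(c1 = pair$b))
    ja <- phylodelim:::.sketch_jaccard(make_sketch(ga, s = 1000),
                                       make_sketch(gb, s = 1000))
    jx <- oracle_jaccard(pair$a, pair$b, 21)
    tol <- 3 * sqrt(jx * (1 - jx) / 1000)
    if (abs(ja - jx) <= tol) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("neighbor selection orders by distance with stable tie-breaks", {
  set.seed(9)
  anc <- random_genome_seq(20000, 41)
  mk <- function(id, d, seed) {
    p <- diverged_pair_seq(20000, d, seed)
    genome_record(id, c(c1 = p$b))
  }
  query <- genome_record("q", c(c1 = anc))
  refs <- c(list(genome_record("q_copy", c(c1 = anc))),
            lapply(1:6, function(i) mk(paste0("r", i), 0.02 * i, 200 + i)))
  sks <- lapply(refs, make_sketch)
  skq <- make_sketch(query)
  nb <- select_neighbors(skq, sks, n = 20)
  expect_equal(nrow(nb), 7L)
  expect_equal(nb$genome_id[1], "q_copy")
  expect_identical(nb$D[1], 0)
  expect_true(!is.unsorted(nb$D))
  # matches an exhaustive sort of all pairwise distances
  dd <- vapply(sks, function(s) mash_distance(skq, s), numeric(1))
  ids <- vapply(sks, function(s) s$genome_id, character(1))
  expect_equal(nb$genome_id, ids[order(dd, ids)])
  # truncation
  expect_equal(nrow(select_neighbors(skq, sks[1:2], n = 3)), 2L)
  expect_equal(nrow(select_neighbors(skq, list(), n = 3)), 0L)
})

test_that("sketch JSON-lines serialization round-trips exactly", {
  g <- genome_record("ser", c(c1 = random_genome_seq(5000, 13)))
  sk <- make_sketch(g, s = 50)
  f <- tempfile(fileext = ".jsonl")
  write_sketches(list(sk), f)
  back <- read_sketches(f)[[1]]
  expect_identical(back$hashes, sk$hashes)
  expect_identical(back$k, sk$k)
  expect_identical(back$genome_id, sk$genome_id)
})
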