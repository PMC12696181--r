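random_dist_matrix <- function(n, seed) {
  set.seed(seed)
  pts <- matrix(rnorm(n * 3), n)
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(paste0("t", 1:n), paste0("t", 1:n))
  dist_matrix(m)
}

test_that("dist_matrix validates its invariants", {
  m <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_s3_class(dist_matrix(m), "dist_matrix")
  bad <- m; bad[1, 2] <- 2
  expect_error(dist_matrix(bad), "symmetric")
  bad2 <- m; diag(bad2) <- 0.1
  expect_error(dist_matrix(bad2), "diagonal")
  expect_error(dist_matrix(matrix(0, 2, 2)), "labeled")
})

test_that("Ward clustering joins the closest pair first and is monotone", {
  m <- as.matrix(dist(c(a = 0, b = 1, c = 10)))
  h <- ward_cluster(dist_matrix(m))
  expect_equal(h$merge[1, ], c(-1, -2))       # {0, 1} merge first
  expect_equal(h$height[1], 1)
  expect_true(!is.unsorted(h$height))

  # identical labels merge first at height 0
  m2 <- matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  h2 <- ward_cluster(dist_matrix(m2))
  expect_equal(sort(abs(h2$merge[1, ])), c(1, 2))
  expect_equal(h2$height[1], 0)
})

test_that("Ward merge heights equal the Lance-Williams oracle", {
  for (i in 1:20) {
    m <- random_dist_matrix(sample(4:8, 1), 300 + i)
    h <- ward_cluster(m)
    expect_equal(h$height, oracle_ward_heights(unclass(m)),
                 tolerance = 1e-9)
  }
})

test_that("NJ reconstructs additive matrices exactly", {
  for (i in 1:20) {
    set.seed(400 + i)
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(tr)
    dm <- dm[order(rownames(dm)), order(rownames(dm))]
    rec <- nj_tree(dist_matrix(dm), "nj")
    expect_equal(ape::dist.topo(ape::unroot(tr), rec), 0,
                 ignore_attr = TRUE)
    expect_equal(max(abs(ape::cophenetic.phylo(rec)[rownames(dm),
                                                    colnames(dm)] - dm)),
                 0, tolerance = 1e-8)
  }
})

test_that("3-taxon NJ solves the three-point formulas", {
  m <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dist_matrix(m), "nj")
  len <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(len["a"]), (3 + 5 - 6) / 2)
  expect_equal(unname(len["b"]), (3 + 6 - 5) / 2)
  expect_equal(unname(len["c"]), (5 + 6 - 3) / 2)
  expect_error(nj_tree(dist_matrix(m[1:2, 1:2])), "at least 3")
})

test_that("branch lengths are never negative after clamping", {
  for (i in 1:10) {
    m <- unclass(random_dist_matrix(7, 500 + i))
    set.seed(i)
    noise <- matrix(runif(49, 0, 0.3), 7)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    tr <- nj_tree(dist_matrix(m + noise))
    expect_true(all(tr$edge.length >= 0))
  }
})

test_that("NJ and Ward agree on ultrametric matrices", {
  # ultrametric heights separated by factor 3 so both methods reduce to
  # the single-linkage merge order (Ward's size-weighted updates can
  # reorder near-tie heights, which is out of scope here)
  for (i in 1:5) {
    set.seed(600 + i)
    tr <- ape::rcoal(6)
    mrca <- ape::mrca(tr)
    h_rank <- rank(ape::node.depth.edgelength(tr)[7:11])
    dm <- matrix(0, 6, 6, dimnames = dimnames(mrca))
    for (a in 1:6) for (b in 1:6) if (a != b)
      dm[a, b] <- 2 * 3^(-h_rank[mrca[a, b] - 6])
    dm <- dm[order(rownames(dm)), order(rownames(dm))]
    njt <- nj_tree(dist_matrix(dm), "nj")
    wrd <- ape::as.phylo(ward_cluster(dist_matrix(dm)))
    expect_equal(ape::dist.topo(njt, ape::unroot(wrd)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("Newick and PHYLIP round-trips are lossless", {
  set.seed(700)
  tr <- ape::rtree(8)
  tr$node.label <- round(runif(tr$Nnode), 3)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)), 0,
               ignore_attr = TRUE)
  o <- order(tr$tip.label)
  expect_equal(ape::cophenetic.phylo(tr2)[tr$tip.label[o], tr$tip.label[o]],
               ape::cophenetic.phylo(tr)[tr$tip.label[o], tr$tip.label[o]],
               tolerance = 1e-9)
  expect_equal(as.numeric(tr2$node.label), as.numeric(tr$node.label))

  m <- random_dist_matrix(5, 701)
  fp <- tempfile(fileext = ".phy")
  write_phylip_matrix(m, fp)
  m2 <- read_phylip_matrix(fp)
  expect_equal(unclass(m2), unclass(m), tolerance = 1e-8,
               ignore_attr = FALSE)
})

test_that("sketch-resampling bootstrap gives full support for clean clades", {
  genomes <- list()
  for (i in 1:3) {
    p <- diverged_pair_seq(20000, 0.02, 810 + i)  # one clean pair per clade
    genomes[[2 * i - 1]] <- genome_record(paste0("sp", i, "_1"),
                                          c(c1 = p$a))
    genomes[[2 * i]] <- genome_record(paste0("sp", i, "_2"),
                                      c(c1 = p$b))
  }
  sks <- lapply(genomes, make_sketch, s = 500)
  bt <- bootstrap_support(sks, reps = 20, seed = 4)
  sup <- as.numeric(bt$node.label)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 1))
  # the three clean two-tip clades are recovered in every replicate
  expect_gte(sum(sup == 1, na.rm = TRUE), 2)

  bt1 <- bootstrap_support(sks, reps = 1, seed = 4)
  expect_true(all(as.numeric(bt1$node.label) %in% c(0, 1, NA)))
})
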