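groups_of <- function(assign) {
  unname(sort(vapply(split(names(assign), assign),
                     function(g) paste(sort(g), collapse = ","), "")))
}

# well-separated two-rate trees per the delimitation model's assumptions
well_separated_tree <- function(seed, n_species = 3, tips = 5) {
  sim <- simulate_delimitation_tree(n_species, tips_per_species = tips,
                                    within_mean = 0.001,
                                    between_mean = 0.5, seed = seed)
  list(true_tree = sim$tree, true_partition = sim$true_partition)
}

test_that("two-tip PTP likelihoods match the closed form", {
  tr <- ape::read.tree(text = "(a:0.4,b:0.9);")
  part <- ptp_ml(tr)
  # both partitions are one-class fits over the same two branches:
  # n log(n/L) - n with n = 2, L = 1.3
  expect_equal(part$null_loglik, 2 * log(2 / 1.3) - 2)
  expect_true(part$n_species %in% c(1L, 2L))
  expect_equal(part$n_species, 1L)  # no rate signal in two branches
})

test_that("PTP two-class likelihood equals exhaustive enumeration", {
  for (i in 1:10) {
    set.seed(900 + i)
    tr <- ape::rtree(sample(5:7, 1))
    idx <- phylodelim:::.tree_index(tr)
    best <- phylodelim:::.ptp_search(idx)
    expect_equal(best$ll, oracle_ptp_best(tr), tolerance = 1e-9)
  }
})

test_that("PTP recovers well-separated clades and collapses star trees", {
  for (sd in 1:5) {
    sim <- well_separated_tree(sd)
    p <- ptp_ml(sim$true_tree)
    expect_equal(p$n_species, 3L)
    # delimited groups match the generating partition
    expect_equal(groups_of(p$assignment),
                 groups_of(sim$true_partition$assignment))
  }
  star <- ape::stree(6, "star")
  star$edge.length <- rep(1, 6)
  p <- ptp_ml(star)
  expect_equal(p$n_species, 1L)
  expect_gt(p$p_value, 0.05)

  zero <- ape::stree(4, "star")
  zero$edge.length <- rep(0, 4)
  expect_error(ptp_ml(zero), "degenerate")
})

test_that("bPTP is seed-reproducible and matches ML PTP on clean trees", {
  sim <- well_separated_tree(2)
  cfg <- mcmc_config(iterations = 30000L, seeds = c(1L, 2L))
  b1 <- bptp(sim$true_tree, cfg)
  b2 <- bptp(sim$true_tree, cfg)
  expect_identical(b1$traces, b2$traces)
  expect_identical(b1$assignment, b2$assignment)

  modal <- as.integer(names(which.max(b1$species_count_posterior)))
  expect_equal(modal, 3L)
  expect_true(all(b1$support >= 0 & b1$support <= 1))
  true_groups <- split(names(sim$true_partition$assignment),
                       sim$true_partition$assignment)
  for (grp in true_groups) {
    key <- paste(sort(match(grp, sim$true_tree$tip.label)),
                 collapse = ",")
    expect_gt(b1$support[[key]], 0.5)
  }
})

test_that("bPTP does not confidently split a single-rate tree", {
  set.seed(33)
  tr <- ape::rphylo(10, birth = 1, death = 0)
  b <- bptp(tr, mcmc_config(iterations = 30000L, seeds = 1L))
  multi <- b$support[grepl(",", names(b$support))]
  if (length(multi) > 0) expect_lt(max(multi), 0.95)
  expect_error(bptp(tr, mcmc_config(iterations = 0L)), "iterations")
})

test_that("GMYC recovers clusters, respects the null, and is idempotent", {
  for (sd in 1:3) {
    sim <- well_separated_tree(sd)
    g <- gmyc(sim$true_tree)
    expect_equal(g$n_species, 3L)
    expect_lt(g$p_value, 0.05)
    expect_true(all(g$support >= 0 & g$support <= 1))
  }
  # ultrametricize is idempotent on an ultrametric tree
  set.seed(41)
  u <- ape::rcoal(8)
  expect_equal(ultrametricize_mpl(u), u)
  u2 <- ultrametricize_mpl(well_separated_tree(1)$true_tree)
  expect_true(ape::is.ultrametric(u2, tol = 1e-8))

  # a pure-Yule tree carries no threshold signal: the null should be
  # preferred in the clear majority of replicates, and a retained null
  # reports the all-singleton convention
  nulls <- 0L
  for (sd in 1:5) {
    set.seed(sd)
    y <- ape::rphylo(12, birth = 1, death = 0)
    gy <- gmyc(y)
    if (gy$p_value > 0.05) {
      nulls <- nulls + 1L
      expect_true(gy$no_significant_clustering)
      expect_equal(gy$n_species, 12L)
    }
  }
  expect_gte(nulls, 4L)

  expect_error(gmyc(ape::read.tree(text = "(a:1,b:1);")), "3 tips")
})

test_that("GMYC threshold search is invariant to tip order", {
  sim <- well_separated_tree(4)
  tr <- sim$true_tree
  g1 <- gmyc(tr)
  set.seed(10)
  tr2 <- ape::rotateConstr(tr, sample(tr$tip.label))
  g2 <- gmyc(tr2)
  expect_equal(g1$threshold, g2$threshold, tolerance = 1e-9)
  expect_equal(groups_of(g1$assignment), groups_of(g2$assignment))
})

test_that("every delimitation returns a true partition of the tips", {
  sim <- well_separated_tree(6)
  for (part in list(ptp_ml(sim$true_tree),
                    gmyc(sim$true_tree),
                    bptp(sim$true_tree,
                         mcmc_config(iterations = 10000L, seeds = 1L)))) {
    expect_setequal(names(part$assignment), sim$true_tree$tip.label)
    expect_true(all(!is.na(part$assignment)))
    expect_gte(part$n_species, 1L)
    expect_lte(part$n_species, length(sim$true_tree$tip.label))
    if (!is.null(part$support))
      expect_true(all(part$support >= 0 & part$support <= 1))
  }
})
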