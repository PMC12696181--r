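#' Synthetic data with known truth
#'
#' Generators that emulate the statistical structure of the real inputs —
#' genome pairs at controlled divergence, multi-species neutral-coalescent
#' marker alignments, and variant tables with a known indel-size spectrum
#' — so every analysis stage can be validated against construction truth
#' without any download. All generators are bitwise reproducible under a
#' fixed seed.
#'
#' @name synthetic_data
NULL

#' Specification for a diverged genome pair
#'
#' @param ancestor_length ancestor length in bp.
#' @param gc GC fraction of the ancestor (default 0.48, a typical
#'   filamentous-fungus value).
#' @param d total substitution divergence between the two descendants
#'   (each receives Poisson substitutions at rate `d/2`); `0 <= d < 0.75`.
#' @param indel_rate total indel rate per base (split evenly, geometric
#'   lengths).
#' @param mean_indel_len mean indel length in bp (default 5).
#' @param seed RNG seed.
#' @return A list of class `DivergenceSpec`.
#' @export
divergence_spec <- function(ancestor_length, gc = 0.48, d = 0.05,
                            indel_rate = 0, mean_indel_len = 5,
                            seed = 1L) {
  stopifnot(d >= 0, d < 0.75, indel_rate >= 0, ancestor_length >= 1)
  structure(list(ancestor_length = as.integer(ancestor_length), gc = gc,
                 d = d, indel_rate = indel_rate,
                 mean_indel_len = mean_indel_len, seed = as.integer(seed)),
            class = "DivergenceSpec")
}

#' Evolve a genome pair from a common ancestor
#'
#' Draws a random ancestor at the requested GC, then evolves two
#' descendants independently: Poisson-distributed substitutions at rate
#' `d/2` per base (uniform over the three alternative bases) and indels
#' at rate `indel_rate/2` with geometric lengths. The truth record
#' carries the realized per-base identity measured on the substituted
#' sequences before indels are applied.
#'
#' @param spec a [divergence_spec()].
#' @return List with `a`, `b` ([genome_record()]s) and `truth`
#'   (`true_identity` in percent, `true_d` realized divergence).
#' @export
evolve_pair <- function(spec) {
  stopifnot(inherits(spec, "DivergenceSpec"))
  set.seed(spec$seed)
  L <- spec$ancestor_length
  probs <- c(A = (1 - spec$gc) / 2, C = spec$gc / 2, G = spec$gc / 2,
             T = (1 - spec$gc) / 2)
  anc <- sample(names(probs), L, replace = TRUE, prob = probs)
  d1 <- .substitute(anc, spec$d / 2)
  d2 <- .substitute(anc, spec$d / 2)
  true_identity <- 100 * mean(d1 == d2)
  g1 <- .apply_indels(d1, spec$indel_rate / 2, spec$mean_indel_len)
  g2 <- .apply_indels(d2, spec$indel_rate / 2, spec$mean_indel_len)
  list(
    a = genome_record("sim_a", c(chr1 = paste(g1, collapse = ""))),
    b = genome_record("sim_b", c(chr1 = paste(g2, collapse = ""))),
    truth = list(true_identity = true_identity,
                 true_d = 1 - true_identity / 100)
  )
}

.substitute <- function(seq, rate) {
  L <- length(seq)
  n_sub <- stats::rpois(1, L * rate)
  if (n_sub == 0) return(seq)
  pos <- sample.int(L, min(n_sub, L))
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    seq[p] <- sample(setdiff(bases, seq[p]), 1)
  }
  seq
}

.apply_indels <- function(seq, rate, mean_len) {
  L <- length(seq)
  n_ind <- stats::rpois(1, L * rate)
  if (n_ind == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  for (z in seq_len(n_ind)) {
    len <- 1L + stats::rgeom(1, 1 / mean_len)
    p <- sample.int(length(seq), 1)
    if (stats::runif(1) < 0.5) {
      ins <- sample(bases, len, replace = TRUE)
      seq <- append(seq, ins, after = p)
    } else {
      drop <- seq(p, min(p + len - 1L, length(seq)))
      if (length(drop) < length(seq)) seq <- seq[-drop]
    }
  }
  seq
}

#' Specification for a multi-species marker simulation
#'
#' @param n_species number of species (>= 1).
#' @param tips_per_species sampled individuals per species.
#' @param between_depth expected inter-species branch length
#'   (substitutions per site).
#' @param within_theta per-locus coalescent theta within species.
#' @param marker_lengths integer vector of marker lengths (bp).
#' @param seed RNG seed.
#' @return A list of class `SpeciesSimSpec`.
#' @export
species_sim_spec <- function(n_species, tips_per_species = 4L,
                             between_depth = 0.1, within_theta = 5,
                             marker_lengths = c(600L, 900L, 1200L),
                             seed = 1L) {
  stopifnot(n_species >= 1, tips_per_species >= 1, between_depth > 0)
  structure(list(n_species = as.integer(n_species),
                 tips_per_species = as.integer(tips_per_species),
                 between_depth = between_depth,
                 within_theta = within_theta,
                 marker_lengths = as.integer(marker_lengths),
                 seed = as.integer(seed)),
            class = "SpeciesSimSpec")
}

#' Simulate neutral-coalescent marker alignments for several species
#'
#' Builds a species tree with exponential inter-species branch lengths
#' (mean `between_depth`), attaches a standard neutral coalescent
#' genealogy (scaled by `within_theta / 2` per locus) at each species tip,
#' and evolves each marker under Jukes-Cantor on the composite genealogy
#' (branch lengths converted to per-site scale by each marker's length).
#' All markers share one genealogy (no recombination).
#'
#' @param spec a [species_sim_spec()].
#' @return List with `markers` (list of [marker_alignment()]),
#'   `true_tree` (composite genealogy, per-site units of the first
#'   marker), and `true_partition` (a [species_partition()] with the
#'   generating assignment).
#' @export
simulate_species_markers <- function(spec) {
  stopifnot(inherits(spec, "SpeciesSimSpec"))
  set.seed(spec$seed)
  ns <- spec$n_species
  tps <- spec$tips_per_species
  labels <- unlist(lapply(seq_len(ns), function(i)
    paste0("sp", i, "_t", seq_len(tps))))

  build_tree <- function(theta_per_site) {
    if (ns == 1) {
      if (tps < 2) stop("single species needs >= 2 tips")
      tr <- ape::rcoal(tps, tip.label = labels)
      tr$edge.length <- tr$edge.length * theta_per_site / 2
      return(tr)
    }
    sp_tree <- ape::rtree(ns, tip.label = paste0("sp", seq_len(ns)),
                          br = NULL)
    sp_tree$edge.length <- stats::rexp(nrow(sp_tree$edge),
                                       rate = 1 / spec$between_depth)
    if (tps == 1) {
      sp_tree$tip.label <- paste0(sp_tree$tip.label, "_t1")
      return(sp_tree)
    }
    tr <- sp_tree
    for (i in seq_len(ns)) {
      sub <- ape::rcoal(tps, tip.label = paste0("sp", i, "_t",
                                                seq_len(tps)))
      sub$edge.length <- sub$edge.length * theta_per_site / 2
      sub$root.edge <- 0
      tr <- ape::bind.tree(tr, sub,
                           where = which(tr$tip.label == paste0("sp", i)))
    }
    tr
  }

  # one genealogy shared by all markers; per-site scale set by marker 1
  L1 <- spec$marker_lengths[1]
  genealogy <- build_tree(spec$within_theta / L1)

  markers <- vector("list", length(spec$marker_lengths))
  for (mi in seq_along(spec$marker_lengths)) {
    Lm <- spec$marker_lengths[mi]
    dat <- phangorn::simSeq(genealogy, l = Lm, type = "DNA")
    mat <- toupper(as.character(dat))
    rows <- apply(mat, 1, paste, collapse = "")
    markers[[mi]] <- marker_alignment(paste0("marker", mi),
                                      rows[labels])
  }

  assignment <- stats::setNames(rep(seq_len(ns), each = tps), labels)
  part <- species_partition(assignment, method = "ptp_ml",
                            log_likelihood = NA_real_)
  part$method <- "truth"
  list(markers = markers, true_tree = genealogy, true_partition = part)
}

#' Simulate a rate-separated tree for delimitation testing
#'
#' Builds the canonical two-rate test tree for PTP-style delimitation:
#' a backbone over `n_species` clades with exponential branch lengths of
#' mean `between_mean`, and random clade topologies whose branch lengths
#' are iid exponential with mean `within_mean`. Unlike the coalescent
#' genealogies of [simulate_species_markers()], the within-clade branch
#' lengths here follow the exponential law the two-class model assumes,
#' so recovery failures indicate implementation errors rather than model
#' misspecification.
#'
#' @param n_species number of clades (>= 2).
#' @param tips_per_species tips per clade (>= 2).
#' @param within_mean mean within-clade branch length.
#' @param between_mean mean backbone branch length.
#' @param seed RNG seed.
#' @return List with `tree` (rooted `phylo`) and `true_partition`.
#' @export
simulate_delimitation_tree <- function(n_species, tips_per_species = 5L,
                                       within_mean = 0.001,
                                       between_mean = 0.5, seed = 1L) {
  stopifnot(n_species >= 2, tips_per_species >= 2,
            within_mean > 0, between_mean > 0)
  set.seed(seed)
  backbone <- ape::rtree(n_species, tip.label = paste0("sp",
                                                       seq_len(n_species)),
                         br = NULL)
  backbone$edge.length <- stats::rexp(nrow(backbone$edge),
                                      rate = 1 / between_mean)
  tr <- backbone
  for (i in seq_len(n_species)) {
    clade <- ape::rtree(tips_per_species,
                        tip.label = paste0("sp", i, "_t",
                                           seq_len(tips_per_species)),
                        br = NULL)
    clade$edge.length <- stats::rexp(nrow(clade$edge),
                                     rate = 1 / within_mean)
    clade$root.edge <- 0
    tr <- ape::bind.tree(tr, clade,
                         where = which(tr$tip.label == paste0("sp", i)))
  }
  labels <- tr$tip.label
  assignment <- stats::setNames(
    as.integer(sub("^sp(\\d+)_.*$", "\\1", labels)), labels)
  part <- species_partition(assignment, method = "ptp_ml")
  part$method <- "truth"
  list(tree = tr, true_partition = part)
}

#' Simulate a variant table with a known class and size spectrum
#'
#' @param n number of records.
#' @param class_probs probabilities for `snv`, `insertion`, `deletion`.
#' @param indel_len_sampler function(m) returning m indel net lengths
#'   (default geometric with mean 8, shifted to >= 1).
#' @param seed RNG seed.
#' @return List with `variants` (list of [variant_record()]) and `truth`
#'   (data.frame: class, alt_length, net_length).
#' @export
simulate_variant_table <- function(n,
                                   class_probs = c(snv = 0.8,
                                                   insertion = 0.1,
                                                   deletion = 0.1),
                                   indel_len_sampler = NULL,
                                   seed = 1L) {
  stopifnot(n >= 0)
  set.seed(seed)
  if (is.null(indel_len_sampler))
    indel_len_sampler <- function(m) 1L + stats::rgeom(m, 1 / 8)
  bases <- c("A", "C", "G", "T")
  if (n == 0)
    return(list(variants = list(),
                truth = data.frame(class = character(),
                                   alt_length = integer(),
                                   net_length = integer())))
  classes <- sample(names(class_probs), n, replace = TRUE,
                    prob = class_probs)
  lens <- indel_len_sampler(n)
  variants <- vector("list", n)
  truth <- data.frame(class = classes, alt_length = NA_integer_,
                      net_length = NA_integer_)
  for (i in seq_len(n)) {
    anchor <- sample(bases, 1)
    if (classes[i] == "snv") {
      alt <- sample(setdiff(bases, anchor), 1)
      variants[[i]] <- variant_record("chr1", i * 100L, anchor, alt)
      truth$alt_length[i] <- 1L
      truth$net_length[i] <- 0L
    } else if (classes[i] == "insertion") {
      ins <- paste(sample(bases, lens[i], replace = TRUE), collapse = "")
      variants[[i]] <- variant_record("chr1", i * 100L, anchor,
                                      paste0(anchor, ins))
      truth$alt_length[i] <- 1L + lens[i]
      truth$net_length[i] <- lens[i]
    } else {
      del <- paste(sample(bases, lens[i], replace = TRUE), collapse = "")
      variants[[i]] <- variant_record("chr1", i * 100L,
                                      paste0(anchor, del), anchor)
      truth$alt_length[i] <- 1L
      truth$net_length[i] <- -lens[i]
    }
  }
  list(variants = variants, truth = truth)
}
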