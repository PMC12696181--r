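#' Species delimitation on phylogenetic trees
#'
#' Three delimitation tests over a tree whose tips are candidate
#' conspecifics:
#'
#' * [ptp_ml()] — maximum-likelihood Poisson tree processes: branches are
#'   classified into a speciation class and a coalescent class, each with
#'   its own exponential branch-length rate; the partition of tips implied
#'   by the coalescent subtrees is optimized.
#' * [bptp()] — Bayesian PTP: Metropolis-Hastings over the same partition
#'   space, giving posterior support per delimited species.
#' * [gmyc()] — single-threshold generalized mixed Yule coalescent on an
#'   (optionally ultrametricized) tree: a time threshold separates Yule
#'   branching between species from coalescent branching within species.
#'
#' All three return a `SpeciesPartition`.
#'
#' @name delimitation
NULL

# ---- tree bookkeeping -------------------------------------------------

# Index a rooted tree: parents, children, tips below each node, and the
# count/total length of edges inside each node's subtree.
.tree_index <- function(tr) {
  n <- length(tr$tip.label)
  m <- tr$Nnode
  nnode <- n + m
  pa <- integer(nnode)                     # 0 for root
  elen_above <- numeric(nnode)             # length of edge above node
  children <- vector("list", nnode)
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    pa[ch] <- p
    elen_above[ch] <- tr$edge.length[e]
    children[[p]] <- c(children[[p]], ch)
  }
  root <- which(pa == 0 & seq_len(nnode) > n)
  post <- rev(.preorder_nodes(root, children))
  tips_below <- vector("list", nnode)
  sub_n <- integer(nnode)
  sub_len <- numeric(nnode)
  desc_int <- vector("list", nnode)
  for (v in post) {
    if (v <= n) {
      tips_below[[v]] <- v
    } else {
      for (ch in children[[v]]) {
        tips_below[[v]] <- c(tips_below[[v]], tips_below[[ch]])
        sub_n[v] <- sub_n[v] + 1L + sub_n[ch]
        sub_len[v] <- sub_len[v] + elen_above[ch] + sub_len[ch]
        if (ch > n) desc_int[[v]] <- c(desc_int[[v]], ch, desc_int[[ch]])
      }
    }
  }
  list(n = n, m = m, root = root, pa = pa, children = children,
       elen_above = elen_above, tips_below = tips_below, sub_n = sub_n,
       sub_len = sub_len, desc_int = desc_int,
       internal = seq(n + 1L, n + m),
       total_n = nrow(tr$edge), total_len = sum(tr$edge.length))
}

.preorder_nodes <- function(root, children) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, children[[v]])
  }
  out
}

# Ensure a rooted tree with branch lengths; midpoint-root when unrooted.
.ensure_rooted <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  tree
}

# profile log-likelihood of one exponential branch-length class
.class_ll <- function(n, L) {
  if (n == 0) return(0)
  if (L <= 0) return(-Inf)
  n * log(n / L) - n
}

# two-class PTP profile log-likelihood for a cut set (vector of node ids
# whose subtrees are coalescent); idx from .tree_index
.ptp_ll <- function(cuts, idx) {
  coal_n <- sum(idx$sub_n[cuts])
  coal_len <- sum(idx$sub_len[cuts])
  .class_ll(idx$total_n - coal_n, idx$total_len - coal_len) +
    .class_ll(coal_n, coal_len)
}

# tip assignment implied by a cut set
.partition_from_cuts <- function(cuts, idx, tip_labels) {
  assignment <- integer(idx$n)
  sp <- 0L
  for (v in cuts) {
    sp <- sp + 1L
    assignment[idx$tips_below[[v]]] <- sp
  }
  for (t in which(assignment == 0L)) {
    sp <- sp + 1L
    assignment[t] <- sp
  }
  stats::setNames(assignment, tip_labels)
}

.species_keys <- function(cuts, idx) {
  groups <- lapply(cuts, function(v) sort(idx$tips_below[[v]]))
  singles <- setdiff(seq_len(idx$n), unlist(groups))
  keys <- c(vapply(groups, paste, character(1), collapse = ","),
            as.character(singles))
  sort(keys)
}

#' Construct a SpeciesPartition
#'
#' @param assignment named integer vector, tip label -> species index.
#' @param support numeric vector in `[0,1]`, named by comma-separated tip
#'   groups (one entry per delimited species).
#' @param method one of `"ptp_ml"`, `"bptp"`, `"gmyc"`.
#' @param log_likelihood model log-likelihood of the partition.
#' @param ... extra fields stored verbatim (p-values, traces, flags).
#' @return Object of class `SpeciesPartition`.
#' @export
species_partition <- function(assignment, support = NULL, method,
                              log_likelihood = NA_real_, ...) {
  stopifnot(!is.null(names(assignment)))
  structure(
    c(list(assignment = assignment,
           n_species = length(unique(assignment)),
           support = support, method = method,
           log_likelihood = log_likelihood),
      list(...)),
    class = "SpeciesPartition"
  )
}

#' @export
print.SpeciesPartition <- function(x, ...) {
  cat(sprintf("SpeciesPartition (%s): %d species over %d tips; logLik %.3f\n",
              x$method, x$n_species, length(x$assignment),
              x$log_likelihood))
  if (!is.null(x$p_value))
    cat(sprintf("  LRT vs one-class null: p = %.4g\n", x$p_value))
  invisible(x)
}

# ---- ML PTP -----------------------------------------------------------

#' Maximum-likelihood Poisson tree processes delimitation
#'
#' Branch lengths are modeled as exponential with a speciation-class rate
#' and a pooled coalescent-class rate (rate = 1 / mean class branch
#' length). A partition is encoded by a set of subtree cut points: edges
#' inside cut subtrees are coalescent, all others speciation; each cut
#' subtree is one species and every tip attached to the speciation
#' backbone is a singleton. A greedy hill-climb over cut-set moves
#' maximizes the two-class profile likelihood, and a likelihood-ratio test
#' against the one-class null (all branches one rate) decides whether any
#' delimitation is supported at all; when the null is not rejected a
#' single species is returned.
#'
#' @param tree rooted tree with branch lengths (`phylo`); unrooted input
#'   is midpoint-rooted.
#' @param alpha significance level of the LRT (default 0.05).
#' @return A [species_partition()] with fields `p_value`, `null_loglik`
#'   and `cut_nodes`.
#' @export
ptp_ml <- function(tree, alpha = 0.05) {
  tree <- .ensure_rooted(tree)
  if (sum(tree$edge.length) <= 0)
    stop("degenerate tree: total branch length is zero")
  idx <- .tree_index(tree)
  best <- .ptp_search(idx)
  ll0 <- .class_ll(idx$total_n, idx$total_len)
  lrt <- 2 * (best$ll - ll0)
  p <- stats::pchisq(max(lrt, 0), df = 1, lower.tail = FALSE)
  if (p > alpha) {
    assignment <- stats::setNames(rep(1L, idx$n), tree$tip.label)
    return(species_partition(assignment,
                             support = NULL, method = "ptp_ml",
                             log_likelihood = ll0, p_value = p,
                             null_loglik = ll0, cut_nodes = idx$root,
                             null_preferred = TRUE))
  }
  assignment <- .partition_from_cuts(best$cuts, idx, tree$tip.label)
  species_partition(assignment, support = NULL, method = "ptp_ml",
                    log_likelihood = best$ll, p_value = p,
                    null_loglik = ll0, cut_nodes = best$cuts,
                    null_preferred = FALSE)
}

# exact search for small trees, greedy hill-climb otherwise
.ptp_search <- function(idx) {
  if (idx$m <= 15) return(.ptp_exhaustive(idx))
  starts <- list(integer(0), idx$root)
  root_int_children <- idx$children[[idx$root]]
  root_int_children <- root_int_children[root_int_children > idx$n]
  if (length(root_int_children)) starts <- c(starts, list(root_int_children))
  best <- NULL
  for (cuts in starts) {
    res <- .ptp_climb(cuts, idx)
    if (is.null(best) || res$ll > best$ll) best <- res
  }
  best
}

# enumerate every antichain of internal nodes (valid cut set)
.ptp_exhaustive <- function(idx) {
  internal <- idx$internal
  m <- idx$m
  best <- list(cuts = integer(0), ll = .ptp_ll(integer(0), idx))
  for (mask in seq_len(2^m - 1)) {
    cuts <- internal[bitwAnd(bitwShiftR(mask, seq_len(m) - 1L), 1L) == 1L]
    ok <- TRUE
    for (v in cuts) {
      if (any(idx$desc_int[[v]] %in% cuts)) { ok <- FALSE; break }
    }
    if (!ok) next
    ll <- .ptp_ll(cuts, idx)
    if (ll > best$ll) best <- list(cuts = cuts, ll = ll)
  }
  best
}

.ptp_climb <- function(cuts, idx) {
  ll <- .ptp_ll(cuts, idx)
  repeat {
    improved <- FALSE
    for (v in idx$internal) {
      cand <- .ptp_moves(v, cuts, idx)
      for (cc in cand) {
        ll2 <- .ptp_ll(cc, idx)
        if (ll2 > ll + 1e-12) {
          cuts <- cc; ll <- ll2; improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(cuts = cuts, ll = ll)
}

# candidate cut sets reachable from `cuts` by changing node v's status
.ptp_moves <- function(v, cuts, idx) {
  out <- list()
  if (v %in% cuts) {
    out <- c(out, list(setdiff(cuts, v)))                   # dissolve
    ch <- idx$children[[v]]
    ch <- ch[ch > idx$n]
    if (length(ch)) out <- c(out, list(c(setdiff(cuts, v), ch)))  # push down
  } else {
    anc_in <- .has_ancestor_in(v, cuts, idx)
    if (!anc_in) {
      absorbed <- intersect(cuts, idx$desc_int[[v]])
      out <- c(out, list(c(setdiff(cuts, absorbed), v)))    # add / absorb
    }
  }
  out
}

.has_ancestor_in <- function(v, cuts, idx) {
  p <- idx$pa[v]
  while (p != 0) {
    if (p %in% cuts) return(TRUE)
    p <- idx$pa[p]
  }
  FALSE
}

# ---- Bayesian PTP -----------------------------------------------------

#' MCMC configuration for [bptp()]
#'
#' @param iterations MCMC iterations per chain (default 1e6).
#' @param burn_in_fraction fraction discarded as burn-in (default 0.1).
#' @param seeds integer seeds, one independent chain each
#'   (default `c(1, 2, 3, 4)`).
#' @param thinning keep every `thinning`-th sample (default 100).
#' @return A list of class `MCMCConfig`.
#' @export
mcmc_config <- function(iterations = 1000000L, burn_in_fraction = 0.1,
                        seeds = c(1L, 2L, 3L, 4L), thinning = 100L) {
  stopifnot(iterations >= 1, burn_in_fraction >= 0, burn_in_fraction < 1,
            length(seeds) >= 1, thinning >= 1)
  structure(list(iterations = as.integer(iterations),
                 burn_in_fraction = burn_in_fraction,
                 seeds = as.integer(seeds),
                 thinning = as.integer(thinning)),
            class = "MCMCConfig")
}

#' Bayesian Poisson tree processes delimitation
#'
#' Metropolis-Hastings sampling over the PTP cut-set space under a
#' uniform prior. Moves: dissolve a cut (its tips become singletons),
#' push a cut down to its internal children, add a cut (absorbing any
#' cut subtrees below it); proposals are uniform over the current move
#' set with the usual Hastings correction, accepted with the
#' profile-likelihood ratio.
#' Posterior support of a species is the fraction of post-burn-in samples
#' in which exactly that tip set forms a species. Chains for each seed run
#' independently; the convergence report is the largest absolute
#' difference in species support across seeds.
#'
#' @param tree rooted tree with branch lengths; unrooted input is
#'   midpoint-rooted.
#' @param cfg an [mcmc_config()].
#' @return A [species_partition()] for the modal (most-sampled) partition,
#'   with `support` (posterior per species), `species_count_posterior`
#'   (table over sampled species counts), `convergence_max_diff`,
#'   and per-seed traces in `traces` (iteration, log-likelihood,
#'   n_species).
#' @export
bptp <- function(tree, cfg = mcmc_config()) {
  stopifnot(inherits(cfg, "MCMCConfig"))
  tree <- .ensure_rooted(tree)
  idx <- .tree_index(tree)
  chains <- lapply(cfg$seeds, function(sd) .bptp_chain(idx, cfg, sd))

  # pooled posterior over species groups and species counts
  all_keys <- unlist(lapply(chains, function(ch) ch$partition_keys))
  n_samples <- sum(vapply(chains, function(ch) length(ch$partition_keys),
                          integer(1)))
  modal_key <- names(sort(table(all_keys), decreasing = TRUE))[1]
  modal_cuts <- as.integer(strsplit(modal_key, "|", fixed = TRUE)[[1]])
  modal_cuts <- modal_cuts[!is.na(modal_cuts)]

  group_counts <- table(unlist(lapply(chains, function(ch) ch$group_keys)))
  assignment <- .partition_from_cuts(modal_cuts, idx, tree$tip.label)
  keys <- .species_keys(modal_cuts, idx)
  support <- stats::setNames(numeric(length(keys)), keys)
  for (k in keys)
    support[k] <- if (k %in% names(group_counts))
      group_counts[[k]] / n_samples else 0

  # per-seed supports of the modal partition's groups, for convergence
  per_seed <- vapply(chains, function(ch) {
    tab <- table(ch$group_keys)
    vapply(keys, function(k) {
      if (k %in% names(tab)) tab[[k]] / length(ch$partition_keys) else 0
    }, numeric(1))
  }, numeric(length(keys)))
  conv <- if (length(cfg$seeds) > 1)
    max(apply(matrix(per_seed, nrow = length(keys)), 1,
              function(x) diff(range(x))))
  else 0

  counts <- unlist(lapply(chains, function(ch) ch$n_species_samples))
  species_post <- table(counts) / length(counts)

  species_partition(
    assignment, support = support, method = "bptp",
    log_likelihood = .ptp_ll(modal_cuts, idx),
    species_count_posterior = species_post,
    convergence_max_diff = conv,
    traces = lapply(chains, function(ch) ch$trace),
    cut_nodes = modal_cuts)
}

# enumerate the reversible move set from a cut state:
#   remove v     (v is a cut)                <-> add v
#   push-down v  (v is a cut, has internal children; replace v by them)
#                                            <-> absorb v
#   add v        (v not cut, no cut ancestor, no cut descendant)
#   absorb v     (v not cut, no cut ancestor, cut descendants replaced)
# moves encoded as (node, type): 1 = remove, 2 = push-down, 3 = add/absorb
.bptp_moves <- function(cuts, idx) {
  nodes <- integer(0); types <- integer(0)
  for (v in idx$internal) {
    if (cuts[v]) {
      nodes <- c(nodes, v); types <- c(types, 1L)
      ch <- idx$children[[v]]
      if (any(ch > idx$n)) {
        nodes <- c(nodes, v); types <- c(types, 2L)
      }
    } else if (!.has_ancestor_in_logical(v, cuts, idx)) {
      nodes <- c(nodes, v); types <- c(types, 3L)
    }
  }
  list(nodes = nodes, types = types)
}

.bptp_chain <- function(idx, cfg, seed) {
  set.seed(seed)
  iters <- cfg$iterations
  burn <- floor(iters * cfg$burn_in_fraction)
  thin <- cfg$thinning
  cuts <- logical(idx$n + idx$m)     # state: is node a cut?
  cuts[idx$root] <- TRUE             # start from the one-species state
  coal_n <- idx$sub_n[idx$root]
  coal_len <- idx$sub_len[idx$root]
  ll <- .class_ll(idx$total_n - coal_n, idx$total_len - coal_len) +
    .class_ll(coal_n, coal_len)
  n_cut_tips <- idx$n
  n_cuts <- 1L

  keep_n <- max(0L, (iters - burn) %/% thin)
  partition_keys <- character(keep_n)
  group_keys <- vector("list", keep_n)
  n_species_samples <- integer(keep_n)
  trace <- matrix(NA_real_, nrow = keep_n, ncol = 3,
                  dimnames = list(NULL, c("iteration", "log_likelihood",
                                          "n_species")))
  ki <- 0L
  us <- stats::runif(iters)
  moves <- .bptp_moves(cuts, idx)
  for (it in seq_len(iters)) {
    n_from <- length(moves$nodes)
    mi <- sample.int(n_from, 1L)
    v <- moves$nodes[mi]; ty <- moves$types[mi]
    cuts2 <- cuts
    if (ty == 1L) {                      # remove
      cuts2[v] <- FALSE
      d_n <- -idx$sub_n[v]; d_len <- -idx$sub_len[v]
      d_tips <- -length(idx$tips_below[[v]]); d_cuts <- -1L
    } else if (ty == 2L) {               # push-down to internal children
      ch <- idx$children[[v]]
      ch <- ch[ch > idx$n]
      cuts2[v] <- FALSE
      cuts2[ch] <- TRUE
      d_n <- sum(idx$sub_n[ch]) - idx$sub_n[v]
      d_len <- sum(idx$sub_len[ch]) - idx$sub_len[v]
      d_tips <- sum(lengths(idx$tips_below[ch])) -
        length(idx$tips_below[[v]])
      d_cuts <- length(ch) - 1L
    } else {                             # add (absorbing cut descendants)
      absorbed <- idx$desc_int[[v]][cuts[idx$desc_int[[v]]]]
      cuts2[absorbed] <- FALSE
      cuts2[v] <- TRUE
      d_n <- idx$sub_n[v] - sum(idx$sub_n[absorbed])
      d_len <- idx$sub_len[v] - sum(idx$sub_len[absorbed])
      d_tips <- length(idx$tips_below[[v]]) -
        sum(lengths(idx$tips_below[absorbed]))
      d_cuts <- 1L - length(absorbed)
    }
    coal_n2 <- coal_n + d_n; coal_len2 <- coal_len + d_len
    ll2 <- .class_ll(idx$total_n - coal_n2, idx$total_len - coal_len2) +
      .class_ll(coal_n2, coal_len2)
    moves2 <- .bptp_moves(cuts2, idx)
    log_alpha <- ll2 - ll + log(n_from) - log(length(moves2$nodes))
    if (log(us[it]) < log_alpha) {
      cuts <- cuts2
      coal_n <- coal_n2; coal_len <- coal_len2
      n_cut_tips <- n_cut_tips + d_tips
      n_cuts <- n_cuts + d_cuts
      ll <- ll2
      moves <- moves2
    }
    if (it > burn && (it - burn) %% thin == 0) {
      ki <- ki + 1L
      cc <- which(cuts)
      partition_keys[ki] <- paste(cc, collapse = "|")
      group_keys[[ki]] <- .species_keys(cc, idx)
      ns <- n_cuts + (idx$n - n_cut_tips)
      n_species_samples[ki] <- ns
      trace[ki, ] <- c(it, ll, ns)
    }
  }
  list(partition_keys = partition_keys[seq_len(ki)],
       group_keys = unlist(group_keys[seq_len(ki)]),
       n_species_samples = n_species_samples[seq_len(ki)],
       trace = as.data.frame(trace[seq_len(ki), , drop = FALSE]))
}

.has_ancestor_in_logical <- function(v, cuts, idx) {
  p <- idx$pa[v]
  while (p != 0) {
    if (cuts[p]) return(TRUE)
    p <- idx$pa[p]
  }
  FALSE
}

# ---- GMYC -------------------------------------------------------------

#' Mean-path-length ultrametric smoothing
#'
#' Sets each internal node's height to the mean path length from that node
#' to its descendant tips, clamped so children are never higher than their
#' parents; tips sit at height zero. Idempotent on ultrametric trees.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return An ultrametric `phylo` with the same topology.
#' @export
ultrametricize_mpl <- function(tree) {
  tree <- .ensure_rooted(tree)
  if (ape::is.ultrametric(tree, tol = 1e-8)) return(tree)
  idx <- .tree_index(tree)
  nnode <- idx$n + idx$m
  h <- numeric(nnode)
  post <- rev(.preorder_nodes(idx$root, idx$children))
  for (v in post) {
    if (v > idx$n) {
      paths <- unlist(lapply(idx$children[[v]], function(ch) {
        # mean path to tips through child ch, weighted by tip count
        rep(h[ch] + idx$elen_above[ch], length(idx$tips_below[[ch]]))
      }))
      h[v] <- mean(paths)
    }
  }
  for (v in .preorder_nodes(idx$root, idx$children)) {
    if (v != idx$root) h[v] <- min(h[v], h[idx$pa[v]])
  }
  for (e in seq_len(nrow(tree$edge)))
    tree$edge.length[e] <- h[tree$edge[e, 1]] - h[tree$edge[e, 2]]
  tree
}

#' Single-threshold GMYC delimitation
#'
#' Fits a single-threshold mixed Yule coalescent on an ultrametric tree:
#' a time threshold T separates speciation branching deeper than T
#' (Yule, per-lineage rate) from independent within-species coalescents
#' shallower than T (per-pair rate, exposure restricted to pairs in the
#' same cluster); the lineages crossing T define the species clusters.
#' Both rates have closed-form MLEs per candidate threshold (candidates
#' are midpoints between consecutive node heights plus the all-singleton
#' and single-cluster extremes). The ML threshold is tested against the
#' single-process null (the better of the two extreme thresholds, i.e. a
#' single branching process over the whole tree); because the threshold
#' model shrinks coalescent exposure on any tree, the chi-square
#' reference for this LRT is badly anticonservative, so the p-value is
#' obtained by parametric bootstrap from the fitted single-process null.
#' Per-cluster support is the Akaike weight summed over candidate
#' thresholds whose partition contains the cluster.
#'
#' @param tree `phylo` with branch lengths (>= 3 tips); non-ultrametric
#'   input is smoothed with [ultrametricize_mpl()] when
#'   `ultrametricize = TRUE`, otherwise rejected.
#' @param ultrametricize apply mean-path-length smoothing when needed.
#' @param alpha LRT significance level (default 0.05).
#' @param n_null_sims parametric-bootstrap replicates for the LRT
#'   p-value (default 99).
#' @param seed RNG seed for the bootstrap.
#' @return A [species_partition()] with `p_value`, `threshold`,
#'   `null_loglik` and `no_significant_clustering` flag (when the null is
#'   preferred the assignment is the all-singleton GMYC null convention).
#' @export
gmyc <- function(tree, ultrametricize = TRUE, alpha = 0.05,
                 n_null_sims = 99L, seed = 1L) {
  if (length(tree$tip.label) < 3) stop("GMYC needs at least 3 tips")
  tree <- .ensure_rooted(tree)
  if (!ape::is.ultrametric(tree, tol = 1e-8)) {
    if (!ultrametricize) stop("tree is not ultrametric")
    tree <- ultrametricize_mpl(tree)
  }
  scan <- .gmyc_scan(tree)
  idx <- scan$idx
  fits <- scan$fits
  lls <- scan$lls
  cands <- scan$cands
  best_i <- which.max(lls)
  best <- fits[[best_i]]
  ll0 <- scan$ll0
  lrt <- 2 * (best$ll - ll0)
  p <- .gmyc_null_p(lrt, tree, scan, n_null_sims, seed)

  # Akaike weights over thresholds for per-cluster support
  aic <- -2 * lls + 2 * 3
  w <- exp(-(aic - min(aic)) / 2)
  w <- w / sum(w)
  keys <- .gmyc_partition_keys(best, idx)
  support <- stats::setNames(numeric(length(keys)), keys)
  for (i in seq_along(fits)) {
    ki <- .gmyc_partition_keys(fits[[i]], idx)
    hit <- keys %in% ki
    support[hit] <- support[hit] + w[i]
  }

  if (p > alpha) {
    assignment <- stats::setNames(seq_len(idx$n), tree$tip.label)
    return(species_partition(assignment, support = support,
                             method = "gmyc", log_likelihood = ll0,
                             p_value = p, threshold = NA_real_,
                             null_loglik = ll0,
                             no_significant_clustering = TRUE))
  }
  assignment <- .gmyc_assignment(best, idx, tree$tip.label)
  species_partition(assignment, support = support, method = "gmyc",
                    log_likelihood = best$ll, p_value = p,
                    threshold = cands[best_i], null_loglik = ll0,
                    no_significant_clustering = FALSE)
}

# scan all candidate thresholds of an ultrametric tree
.gmyc_scan <- function(tree) {
  idx <- .tree_index(tree)
  depth <- ape::node.depth.edgelength(tree)
  maxd <- max(depth[seq_len(idx$n)])
  height <- maxd - depth                 # time before present
  height[height < 0] <- 0
  int_h <- sort(unique(round(height[idx$internal], 12)), decreasing = TRUE)
  # candidates: above the root, between consecutive events, below the last
  cands <- c(int_h[1] * 1.5 + 1e-9,
             if (length(int_h) > 1)
               (int_h[-length(int_h)] + int_h[-1]) / 2,
             int_h[length(int_h)] / 2)
  fits <- lapply(cands, function(T) .gmyc_fit(T, tree, idx, height))
  lls <- vapply(fits, function(f) f$ll, numeric(1))
  # null: a single branching process over the whole tree = the better of
  # the two extreme thresholds (all-coalescent / all-Yule)
  list(idx = idx, height = height, cands = cands, fits = fits, lls = lls,
       ll0 = max(lls[1], lls[length(lls)]),
       lrt = 2 * (max(lls) - max(lls[1], lls[length(lls)])))
}

# parametric-bootstrap p-value for the GMYC LRT: simulate trees from the
# fitted single-process null (Yule or coalescent, whichever fits better)
# and compare the observed LRT to the simulated LRT distribution. The
# naive chi-square reference is badly anticonservative here because the
# threshold model shrinks coalescent exposure on any tree.
.gmyc_null_p <- function(lrt_obs, tree, scan, n_null_sims, seed) {
  if (n_null_sims < 1) return(NA_real_)
  n <- scan$idx$n
  m_ev <- n - 2                     # events excluding the root split
  yule_better <- scan$lls[length(scan$lls)] >= scan$lls[1]
  # the LRT is invariant to rescaling all branch lengths, so the null
  # trees can be simulated at unit rate
  set.seed(seed)
  lrt_sim <- vapply(seq_len(n_null_sims), function(i) {
    sim <- if (yule_better) {
      ape::rphylo(n, birth = 1, death = 0)
    } else {
      ape::rcoal(n)
    }
    .gmyc_scan(sim)$lrt
  }, numeric(1))
  (1 + sum(lrt_sim >= lrt_obs - 1e-12)) / (n_null_sims + 1)
}

# fit the two-process likelihood for one threshold T
# clusters = edges crossing T (parent height > T >= child height);
# the root counts as crossing when T is above the root height.
.gmyc_fit <- function(T, tree, idx, height) {
  n <- idx$n
  root_h <- height[idx$root]
  hp <- rep(-Inf, n + idx$m)            # height of each node's parent
  has_pa <- idx$pa != 0
  hp[has_pa] <- height[idx$pa[has_pa]]
  # crossing edges identified by their child node; each defines a cluster
  crossing <- which(hp > T & height <= T)
  if (T >= root_h) crossing <- idx$root
  # map every node to its cluster (its crossing ancestor)
  cluster <- integer(n + idx$m)
  for (ci in seq_along(crossing)) {
    v <- crossing[ci]
    cluster[v] <- ci
    if (v > n) cluster[idx$desc_int[[v]]] <- ci
    cluster[idx$tips_below[[v]]] <- ci
  }
  # events: every internal node except the root (whose split is
  # conditioned on); classified directly by node height
  ev_h <- height[setdiff(idx$internal, idx$root)]
  n_spec <- sum(ev_h > T)
  n_coal <- sum(ev_h <= T)
  # exposure: walk intervals between breakpoints, root -> present;
  # below T only pairs within the same cluster can coalesce
  bps <- sort(unique(c(root_h, height[idx$internal],
                       if (T < root_h && T > 0) T, 0)),
              decreasing = TRUE)
  A_spec <- 0; A_coal <- 0
  for (j in seq_len(length(bps) - 1)) {
    top <- bps[j]; bot <- bps[j + 1]
    wdt <- top - bot
    # active edges: parent height >= top and child height <= bot
    act <- which(hp >= top - 1e-12 & height <= bot + 1e-12)
    if (top <= T + 1e-12) {
      nk <- tabulate(cluster[act])
      A_coal <- A_coal + sum(nk * (nk - 1) / 2) * wdt
    } else {
      A_spec <- A_spec + length(act) * wdt
    }
  }
  ll <- .class_ll(n_spec, A_spec) + .class_ll(n_coal, A_coal)
  list(ll = ll, T = T, crossing = crossing,
       n_spec = n_spec, n_coal = n_coal)
}

.gmyc_partition_keys <- function(fit, idx) {
  keys <- vapply(fit$crossing, function(v) {
    paste(sort(if (v <= idx$n) v else idx$tips_below[[v]]), collapse = ",")
  }, character(1))
  sort(keys)
}

.gmyc_assignment <- function(fit, idx, tip_labels) {
  assignment <- integer(idx$n)
  for (ci in seq_along(fit$crossing)) {
    v <- fit$crossing[ci]
    tips <- if (v <= idx$n) v else idx$tips_below[[v]]
    assignment[tips] <- ci
  }
  stats::setNames(assignment, tip_labels)
}

#' Write a SpeciesPartition as TSV plus a JSON support report
#'
#' @param part a [species_partition()].
#' @param tsv_path two-column TSV (tip, species) output path.
#' @param json_path optional JSON support-report path.
#' @return `tsv_path`, invisibly.
#' @export
write_partition <- function(part, tsv_path, json_path = NULL) {
  utils::write.table(
    data.frame(tip = names(part$assignment),
               species = unname(part$assignment)),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(method = part$method, n_species = part$n_species,
           log_likelihood = part$log_likelihood,
           p_value = part$p_value,
           support = as.list(part$support)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tsv_path)
}
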