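#' Labeled symmetric distance matrix
#'
#' Validates and wraps a square matrix for the clustering and tree
#' builders: symmetric within 1e-12, zero diagonal, non-negative entries,
#' unique labels.
#'
#' @param m square numeric matrix with identical row/column names.
#' @return The validated matrix with class `dist_matrix`.
#' @export
dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("distance matrix must be labeled")
  if (!identical(rownames(m), colnames(m)))
    stop("row and column labels differ")
  if (anyDuplicated(rownames(m))) stop("duplicate labels")
  if (any(m < 0)) stop("negative distances")
  if (max(abs(m - t(m))) > 1e-12) stop("matrix not symmetric")
  if (any(diag(m) != 0)) stop("diagonal must be exactly zero")
  class(m) <- c("dist_matrix", "matrix")
  m
}

#' Ward agglomerative clustering of a distance matrix
#'
#' Ward linkage via the Lance-Williams recurrence on squared distances
#' (the `ward.D2` convention: input distances are treated as Euclidean,
#' merge heights are on the original scale). Merge heights are
#' non-decreasing.
#'
#' @param m a [dist_matrix()].
#' @return An `hclust` object (a rooted dendrogram).
#' @export
ward_cluster <- function(m) {
  m <- dist_matrix(unclass(m))
  if (nrow(m) < 2) stop("need at least 2 labels")
  stats::hclust(stats::as.dist(m), method = "ward.D2")
}

#' Distance-based phylogeny by (BIO)NJ
#'
#' Builds an unrooted tree by neighbor joining. BIONJ's variance-weighted
#' update is the default; plain NJ is available. Negative branch lengths
#' (a known NJ artifact on non-additive matrices) are clamped to zero with
#' the deficit moved to the adjacent sister branch so path lengths are
#' approximately preserved.
#'
#' @param m a [dist_matrix()] with at least 3 labels.
#' @param method `"bionj"` (default) or `"nj"`.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(m, method = c("bionj", "nj")) {
  method <- match.arg(method)
  m <- dist_matrix(unclass(m))
  if (nrow(m) < 3) stop("need at least 3 labels for NJ")
  tr <- if (method == "bionj") ape::bionj(stats::as.dist(m))
        else ape::nj(stats::as.dist(m))
  .clamp_negative_branches(tr)
}

# move each negative branch's deficit onto its sister edge(s)
.clamp_negative_branches <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[1]
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sisters <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sisters) > 0)
      tr$edge.length[sisters] <- tr$edge.length[sisters] + deficit /
        length(sisters)
    else break
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Sketch-resampling bootstrap supports for a distance phylogeny
#'
#' Resamples (with replacement) the hash set of each genome's sketch,
#' recomputes the Mash distance matrix and the NJ tree per replicate, and
#' reports bipartition frequencies in `[0, 1]` on the full-data tree.
#' These supports measure the stability of the distance signal, not a
#' model-based support.
#'
#' @param sketches list of `Sketch` objects (>= 4 for internal edges).
#' @param reps number of replicates (>= 1).
#' @param seed RNG seed.
#' @param method tree method passed to [nj_tree()].
#' @return The full-data [nj_tree()] with `node.label` set to supports.
#' @export
bootstrap_support <- function(sketches, reps = 100L, seed = 1L,
                              method = "bionj") {
  stopifnot(reps >= 1)
  main <- nj_tree(mash_distance_matrix(sketches), method)
  set.seed(seed)
  boots <- vector("list", reps)
  for (r in seq_len(reps)) {
    res <- lapply(sketches, function(sk) {
      sk$hashes <- sort(unique(sample(sk$hashes, length(sk$hashes),
                                      replace = TRUE)))
      sk
    })
    boots[[r]] <- nj_tree(mash_distance_matrix(res), method)
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  main$node.label <- counts / reps
  main
}

#' Newick and PHYLIP matrix I/O
#'
#' Thin wrappers kept for a uniform surface: trees round-trip losslessly
#' for topology, branch lengths and support labels.
#'
#' @param tree an [ape::phylo] object.
#' @param path file path.
#' @name tree_io
#' @return `read_newick` returns a `phylo`; writers return `path`
#'   invisibly.
NULL

#' @rdname tree_io
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' @rdname tree_io
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' @rdname tree_io
#' @param m a [dist_matrix()].
#' @export
write_phylip_matrix <- function(m, path) {
  m <- unclass(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i],
                       sprintf("%.9f", m[i, ])), collapse = "  "), con)
  invisible(path)
}

#' @rdname tree_io
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  parts <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  labels <- vapply(parts, `[`, character(1), 1)
  m <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(m) <- list(labels, labels)
  m[abs(m) < 1e-15] <- 0
  dist_matrix(m)
}
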