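#' Canonical k-mer frequency profiles
#'
#' A compositional signature of a genome: the normalized frequency vector
#' of canonical k-mers (each word pooled with its reverse complement; at
#' k = 6 there are 2,080 canonical words). Hexamer composition separates
#' coding-rich from non-coding-rich genomes and is used here as an
#' alignment-free complement to identity-based indices.
#'
#' @param g a [genome_record()].
#' @param k word size (default 6; capped at 12 to keep the dense vector
#'   bounded).
#' @param canonical collapse each word with its reverse complement
#'   (default `TRUE`).
#' @return Object of class `KmerProfile`: `genome_id`, `k`, `freqs`
#'   (named numeric, sums to 1), `total_kmers`.
#' @export
hexamer_profile <- function(g, k = 6L, canonical = TRUE) {
  stopifnot(inherits(g, "GenomeRecord"))
  if (k > 12) stop("k > 12 not supported for dense profiles")
  seqs <- Biostrings::DNAStringSet(toupper(g$scaffolds))
  counts <- colSums(Biostrings::oligonucleotideFrequency(seqs, width = k))
  if (canonical) {
    words <- names(counts)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(words)))
    canon <- pmin(words, rc)
    counts <- vapply(split(counts, canon), sum, numeric(1))
  }
  total <- sum(counts)
  if (total == 0) stop("no valid k-mer in genome '", g$id, "' at k = ", k)
  structure(
    list(genome_id = g$id, k = as.integer(k), freqs = counts / total,
         total_kmers = total),
    class = "KmerProfile"
  )
}

#' @export
print.KmerProfile <- function(x, ...) {
  cat(sprintf("KmerProfile '%s': k=%d, %d bins, %d k-mers counted\n",
              x$genome_id, x$k, length(x$freqs), x$total_kmers))
  invisible(x)
}

#' Compositional similarity between two k-mer profiles
#'
#' Four indices on the normalized frequency vectors:
#' * `weighted_jaccard`: sum(min(x, y)) / sum(max(x, y)), in `[0, 1]`;
#' * `containment`: sum(min(x, y)) / sum(x) — asymmetric, `x` is the query;
#' * `euclidean`: L2 distance of the two vectors;
#' * `pearson`: Pearson correlation of the two vectors.
#'
#' @param x,y `KmerProfile` objects with equal `k`.
#' @param index one of `"weighted_jaccard"`, `"containment"`,
#'   `"euclidean"`, `"pearson"`.
#' @return A single numeric value.
#' @export
profile_similarity <- function(x, y,
                               index = c("weighted_jaccard", "containment",
                                         "euclidean", "pearson")) {
  stopifnot(inherits(x, "KmerProfile"), inherits(y, "KmerProfile"))
  if (x$k != y$k) stop("profiles have different k (", x$k, " vs ", y$k, ")")
  index <- match.arg(index)
  a <- .align_bins(x$freqs, y$freqs)
  switch(index,
    weighted_jaccard = {
      denom <- sum(pmax(a$x, a$y))
      if (denom == 0) 0 else sum(pmin(a$x, a$y)) / denom
    },
    containment = sum(pmin(a$x, a$y)) / sum(a$x),
    euclidean = sqrt(sum((a$x - a$y)^2)),
    pearson = stats::cor(a$x, a$y)
  )
}

# union the named bins of two profiles, missing bins as 0
.align_bins <- function(x, y) {
  bins <- union(names(x), names(y))
  xx <- stats::setNames(numeric(length(bins)), bins)
  yy <- xx
  xx[names(x)] <- x
  yy[names(y)] <- y
  list(x = xx, y = yy)
}

#' Binary (presence/absence) Jaccard of two profiles
#'
#' Proportion of the union of observed k-mers shared by both genomes.
#' Reported alongside the weighted index because "shared k-mers" can be
#' read either way.
#'
#' @inheritParams profile_similarity
#' @return Numeric in `[0, 1]`.
#' @export
binary_jaccard <- function(x, y) {
  stopifnot(inherits(x, "KmerProfile"), inherits(y, "KmerProfile"))
  if (x$k != y$k) stop("profiles have different k")
  sx <- names(x$freqs)[x$freqs > 0]
  sy <- names(y$freqs)[y$freqs > 0]
  length(intersect(sx, sy)) / length(union(sx, sy))
}

#' Pairwise compositional distance matrix over profiles
#'
#' @param profiles list of `KmerProfile` objects.
#' @param index similarity index; the matrix holds `1 - similarity` for
#'   `weighted_jaccard`/`containment`/`pearson`, the distance itself for
#'   `euclidean`. Default `weighted_jaccard`.
#' @return A [dist_matrix()] labeled by genome ids.
#' @export
profile_distance_matrix <- function(profiles, index = "weighted_jaccard") {
  ids <- vapply(profiles, function(p) p$genome_id, character(1))
  n <- length(profiles)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        v <- profile_similarity(profiles[[i]], profiles[[j]], index)
        d <- if (index == "euclidean") v else 1 - v
        m[i, j] <- m[j, i] <- d
      }
    }
  }
  dist_matrix(m)
}

#' Write / read a profile as two-column TSV (kmer, frequency)
#'
#' @param p a `KmerProfile`.
#' @param path TSV path.
#' @param genome_id id for the reader's reconstructed profile.
#' @return `path` (writer, invisibly) or a `KmerProfile` (reader).
#' @export
write_profile <- function(p, path) {
  utils::write.table(
    data.frame(kmer = names(p$freqs), frequency = unname(p$freqs)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path, genome_id = basename(path)) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  structure(
    list(genome_id = genome_id, k = nchar(tab$kmer[1]),
         freqs = stats::setNames(tab$frequency, tab$kmer),
         total_kmers = NA_integer_),
    class = "KmerProfile")
}
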