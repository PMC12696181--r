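#' MinHash genome sketches and the Mash distance
#'
#' A `Sketch` is the bottom-s MinHash signature of a genome: the `s`
#' smallest 64-bit hash values over the set of canonical k-mers (the
#' lexicographic minimum of each k-mer and its reverse complement). Two
#' sketches estimate the k-mer Jaccard index J, and the Mash distance
#' D = -(1/k) * log(2J / (1 + J)) approximates per-base divergence.
#'
#' @param g a [genome_record()].
#' @param k k-mer size (default 21).
#' @param s sketch size (default 1000).
#' @param seed hash seed (default 42).
#' @return An object of class `Sketch` with fields `genome_id`, `k`, `s`,
#'   `seed` and `hashes` (strictly increasing numeric vector, length <= s).
#' @export
make_sketch <- function(g, k = 21L, s = 1000L, seed = 42L) {
  stopifnot(inherits(g, "GenomeRecord"))
  hashes <- cpp_sketch_hashes(unname(g$scaffolds), as.integer(k),
                              as.integer(s), as.integer(seed))
  if (length(hashes) == 0)
    stop("no valid k-mer in genome '", g$id, "' at k = ", k)
  structure(
    list(genome_id = g$id, k = as.integer(k), s = as.integer(s),
         seed = as.integer(seed), hashes = hashes),
    class = "Sketch"
  )
}

#' @export
print.Sketch <- function(x, ...) {
  cat(sprintf("Sketch '%s': k=%d, s=%d, seed=%d, %d hashes\n",
              x$genome_id, x$k, x$s, x$seed, length(x$hashes)))
  invisible(x)
}

#' Mash distance between two sketches
#'
#' The Jaccard index is estimated from the merged bottom-s union: with
#' X the s smallest hashes of the union of the two hash sets,
#' J = |X intersect A intersect B| / |X|. The distance is
#' D = -(1/k) * log(2J/(1+J)), capped at 1 when J = 0 (the closed form
#' diverges there).
#'
#' @param a,b `Sketch` objects with identical `k` and `seed`.
#' @return Non-negative numeric distance; 0 on identical sketches.
#' @export
mash_distance <- function(a, b) {
  stopifnot(inherits(a, "Sketch"), inherits(b, "Sketch"))
  if (a$k != b$k) stop("sketches have different k (", a$k, " vs ", b$k, ")")
  if (a$seed != b$seed) stop("sketches have different hash seeds")
  j <- .sketch_jaccard(a, b)
  mash_d_from_jaccard(j, a$k)
}

#' @rdname mash_distance
#' @param j Jaccard index estimate in `[0, 1]`.
#' @param k k-mer size used for the sketches.
#' @export
mash_d_from_jaccard <- function(j, k) {
  if (j <= 0) return(1.0)
  if (j >= 1) return(0.0)
  min(1.0, -(1 / k) * log(2 * j / (1 + j)))
}

.sketch_jaccard <- function(a, b) {
  s <- min(a$s, b$s)
  u <- sort(unique(c(a$hashes, b$hashes)))
  x <- u[seq_len(min(s, length(u)))]
  shared <- x[x %in% a$hashes & x %in% b$hashes]
  length(shared) / length(x)
}

#' Rank reference sketches by Mash distance to a query
#'
#' @param query a `Sketch`.
#' @param refs list of `Sketch` objects sharing `k` and `seed` with `query`.
#' @param n number of neighbors to keep (default 20).
#' @return `data.frame` with columns `genome_id` and `D`, ascending by `D`,
#'   ties broken by `genome_id`; `min(n, length(refs))` rows.
#' @export
select_neighbors <- function(query, refs, n = 20L) {
  stopifnot(inherits(query, "Sketch"))
  if (length(refs) == 0)
    return(data.frame(genome_id = character(), D = numeric()))
  d <- vapply(refs, function(r) mash_distance(query, r), numeric(1))
  ids <- vapply(refs, function(r) r$genome_id, character(1))
  ord <- order(d, ids)
  out <- data.frame(genome_id = ids[ord], D = d[ord],
                    stringsAsFactors = FALSE)
  utils::head(out, n)
}

#' Pairwise Mash distance matrix over a set of sketches
#'
#' @param sketches list of `Sketch` objects (shared `k`, `seed`).
#' @return A symmetric [dist_matrix()] labeled by genome ids.
#' @export
mash_distance_matrix <- function(sketches) {
  ids <- vapply(sketches, function(s) s$genome_id, character(1))
  n <- length(sketches)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        m[i, j] <- m[j, i] <- mash_distance(sketches[[i]], sketches[[j]])
      }
    }
  }
  dist_matrix(m)
}

#' Serialize sketches as JSON lines
#'
#' One JSON object per line: `genome_id`, `k`, `s`, `seed` and the hash
#' values hex-encoded.
#'
#' @param sketches list of `Sketch` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sketches <- function(sketches, path) {
  lines <- vapply(sketches, function(sk) {
    jsonlite::toJSON(list(
      genome_id = sk$genome_id, k = sk$k, s = sk$s, seed = sk$seed,
      hashes = vapply(sk$hashes, .num_to_hex, character(1))),
      auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sketches
#' @export
read_sketches <- function(path) {
  lapply(readLines(path), function(ln) {
    obj <- jsonlite::fromJSON(ln)
    structure(
      list(genome_id = obj$genome_id, k = as.integer(obj$k),
           s = as.integer(obj$s), seed = as.integer(obj$seed),
           hashes = vapply(obj$hashes, .hex_to_num, numeric(1),
                           USE.NAMES = FALSE)),
      class = "Sketch")
  })
}

# double -> hex string; values fit in 53 bits so doubles are exact
.num_to_hex <- function(x) {
  digits <- character(0)
  repeat {
    digits <- c(format.hexmode(as.integer(x %% 16)), digits)
    x <- x %/% 16
    if (x == 0) break
  }
  paste(digits, collapse = "")
}

# hex string -> double; values fit in 53 bits so doubles are exact
.hex_to_num <- function(h) {
  digits <- as.numeric(strtoi(strsplit(tolower(h), "")[[1]], 16L))
  Reduce(function(acc, d) acc * 16 + d, digits)
}
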