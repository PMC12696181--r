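#' Categorical geographic distance matrix
#'
#' Encodes geographic origin as a binary distance: 0 for pairs from the
#' same origin (country), 1 otherwise.
#'
#' @param origin named character vector, label -> country.
#' @return A list of class `GeoMatrix` with `labels`, `origin` and `d_geo`
#'   (a [dist_matrix()]).
#' @export
geo_matrix <- function(origin) {
  stopifnot(!is.null(names(origin)))
  labels <- names(origin)
  d <- outer(origin, origin, FUN = function(a, b) as.numeric(a != b))
  dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, origin = origin, d_geo = dist_matrix(d)),
            class = "GeoMatrix")
}

#' Subset a distance matrix to a focal label's coherence neighborhood
#'
#' Keeps the focal label plus every label within `max_d` of it; used to
#' restrict geographic-differentiation testing to genomes of high
#' coherence.
#'
#' @param m a [dist_matrix()].
#' @param focal focal label (must be present).
#' @param max_d inclusive distance ceiling (default 0.1).
#' @return The extracted [dist_matrix()].
#' @export
subset_by_distance <- function(m, focal, max_d = 0.1) {
  m <- dist_matrix(unclass(m))
  if (!focal %in% rownames(m)) stop("focal label not in matrix: ", focal)
  keep <- rownames(m)[m[focal, ] <= max_d | rownames(m) == focal]
  dist_matrix(m[keep, keep, drop = FALSE])
}

#' Mantel test between a genomic and a geographic distance matrix
#'
#' Rank correlation (Spearman's rho or Kendall's tau-b) between the
#' upper-triangle entries of the two matrices, with a permutation null
#' obtained by simultaneously permuting rows and columns of the second
#' matrix. With `exact = TRUE` (feasible for n <= 7) all `n!` label
#' permutations are enumerated and the p-value is the exact proportion
#' with a statistic at least as extreme; otherwise
#' `p = (count + 1) / (n_permutations + 1)`.
#'
#' @param d1 a [dist_matrix()] (e.g. Mash distances).
#' @param d2 a `GeoMatrix` or [dist_matrix()] with the same labels.
#' @param method `"spearman"` (default) or `"kendall"`.
#' @param n_permutations random permutations (default 9999).
#' @param seed RNG seed for the permutations.
#' @param tail `"one_sided_greater"` (default; tests positive association)
#'   or `"two_sided"`.
#' @param exact enumerate all permutations instead of sampling.
#' @return A list of class `MantelResult`: `r`, `p`, `method`,
#'   `n_permutations`, `seed`, `tail`.
#' @export
mantel <- function(d1, d2, method = c("spearman", "kendall"),
                   n_permutations = 9999L, seed = 1L,
                   tail = c("one_sided_greater", "two_sided"),
                   exact = FALSE) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  m1 <- dist_matrix(unclass(d1))
  m2 <- if (inherits(d2, "GeoMatrix")) unclass(d2$d_geo) else unclass(d2)
  if (!setequal(rownames(m1), rownames(m2)))
    stop("label sets of the two matrices differ")
  m2 <- m2[rownames(m1), rownames(m1)]
  n <- nrow(m1)
  if (n < 4) stop("need at least 4 labels for a Mantel test")
  ut <- upper.tri(m1)
  x <- m1[ut]
  if (stats::sd(x) == 0 || stats::sd(m2[ut]) == 0)
    stop("constant distance matrix: correlation undefined")

  stat <- function(perm) {
    mp <- m2[perm, perm]
    .rank_cor(x, mp[ut], method)
  }
  r_obs <- stat(seq_len(n))

  if (exact) {
    perms <- .all_permutations(n)
    r_perm <- vapply(perms, stat, numeric(1))
    p <- if (tail == "two_sided") mean(abs(r_perm) >= abs(r_obs) - 1e-12)
         else mean(r_perm >= r_obs - 1e-12)
    n_used <- length(perms)
  } else {
    set.seed(seed)
    r_perm <- vapply(seq_len(n_permutations),
                     function(i) stat(sample.int(n)), numeric(1))
    hits <- if (tail == "two_sided") sum(abs(r_perm) >= abs(r_obs) - 1e-12)
            else sum(r_perm >= r_obs - 1e-12)
    p <- (hits + 1) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(list(r = r_obs, p = p, method = method,
                 n_permutations = n_used, seed = seed, tail = tail,
                 exact = exact),
            class = "MantelResult")
}

#' @export
print.MantelResult <- function(x, ...) {
  cat(sprintf("Mantel test (%s, %s): r = %.4f, p = %.4g (%s permutations)\n",
              x$method, x$tail, x$r, x$p,
              if (x$exact) "all" else format(x$n_permutations)))
  invisible(x)
}

# Spearman rho / Kendall tau-b without cor.test overhead
.rank_cor <- function(x, y, method) {
  if (method == "spearman") stats::cor(rank(x), rank(y))
  else stats::cor(x, y, method = "kendall")
}

.all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

#' Read origins from a two-column TSV (label, country)
#'
#' @param path TSV path with header columns `label` and `country`.
#' @return A [geo_matrix()].
#' @export
read_origins <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, quote = "")
  geo_matrix(stats::setNames(tab$country, tab$label))
}
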