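#' Marker alignments and multilocus concatenation
#'
#' A `MarkerAlignment` holds one aligned locus: equal-length rows keyed by
#' strain label, gaps as `-`. [concatenate()] joins several loci row-wise
#' into the multilocus alignment the diversity statistics run on.
#'
#' @param marker_name locus name (e.g. `"ITS"`, `"RPB2"`, `"TEF1"`).
#' @param rows named character vector of aligned sequences.
#' @return Object of class `MarkerAlignment`.
#' @export
marker_alignment <- function(marker_name, rows) {
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("rows must be uniquely named by strain label")
  if (length(unique(nchar(rows))) != 1)
    stop("aligned rows must have equal length")
  structure(list(marker_name = marker_name,
                 rows = vapply(rows, toupper, character(1))),
            class = "MarkerAlignment")
}

#' @export
print.MarkerAlignment <- function(x, ...) {
  cat(sprintf("MarkerAlignment '%s': %d sequences x %d sites\n",
              x$marker_name, length(x$rows), nchar(x$rows[1])))
  invisible(x)
}

#' Read / write an aligned multi-FASTA as a MarkerAlignment
#'
#' @param path FASTA path.
#' @param marker_name locus name; defaults to the file basename.
#' @return A [marker_alignment()].
#' @export
read_marker_alignment <- function(path, marker_name = NULL) {
  g <- read_fasta(path)
  if (is.null(marker_name)) marker_name <- g$id
  marker_alignment(marker_name, g$scaffolds)
}

#' Concatenate marker alignments row-wise
#'
#' @param markers list of [marker_alignment()] objects.
#' @param missing_policy `"strict"` (error when a strain is absent from a
#'   marker) or `"gap_fill"` (pad missing strains with gaps).
#' @return A [marker_alignment()] whose length is the sum of the marker
#'   lengths.
#' @export
concatenate <- function(markers, missing_policy = c("strict", "gap_fill")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(length(markers) >= 1)
  strains <- unique(unlist(lapply(markers, function(m) names(m$rows))))
  pieces <- lapply(markers, function(m) {
    len <- nchar(m$rows[1])
    absent <- setdiff(strains, names(m$rows))
    if (length(absent) && missing_policy == "strict")
      stop("strain(s) missing from marker '", m$marker_name, "': ",
           paste(absent, collapse = ", "))
    fill <- stats::setNames(rep(strrep("-", len), length(absent)), absent)
    c(m$rows, fill)[strains]
  })
  rows <- do.call(paste0, pieces)
  names(rows) <- strains
  marker_alignment(paste(vapply(markers, function(m) m$marker_name,
                                character(1)), collapse = "+"), rows)
}

#' Population-genetic summary of an alignment
#'
#' Computes, over the analyzed sites of a (concatenated) alignment:
#' number of sequences `n`, analyzed length `L`, segregating sites `S`,
#' parsimony-informative sites, nucleotide diversity per site (pi),
#' Tajima's D, haplotype count and haplotype diversity
#' `Hd = n/(n-1) * (1 - sum p_i^2)`.
#'
#' Under the default `complete_columns` policy, any column containing a
#' gap or an IUPAC ambiguity code is excluded from the analysis entirely
#' (listwise deletion); under `pairwise`, each sequence pair uses the
#' columns where both have unambiguous bases (pi only; S and D still use
#' complete columns).
#'
#' Tajima's D follows the 1989 formulation:
#' `a1 = sum 1/i`, `a2 = sum 1/i^2` (i = 1..n-1),
#' `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`,
#' `c1 = b1 - 1/a1`, `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`,
#' `e1 = c1/a1`, `e2 = c2/(a2 + a1^2)`, and
#' `D = (pihat - S/a1) / sqrt(e1 S + e2 S (S-1))` with `pihat` the mean
#' pairwise difference count. When `S = 0`, D is undefined and returned
#' as `NA` with `tajima_defined = FALSE`.
#'
#' @param a a [marker_alignment()].
#' @param site_policy `"complete_columns"` (default) or `"pairwise"`.
#' @return A list of class `PopgenSummary`.
#' @export
popgen_summary <- function(a, site_policy = c("complete_columns",
                                              "pairwise")) {
  site_policy <- match.arg(site_policy)
  stopifnot(inherits(a, "MarkerAlignment"))
  mat <- do.call(rbind, strsplit(unname(a$rows), ""))
  rownames(mat) <- names(a$rows)
  n <- nrow(mat)
  good <- mat %in% c("A", "C", "G", "T")
  dim(good) <- dim(mat)
  complete <- colSums(good) == n
  sub <- mat[, complete, drop = FALSE]
  L <- ncol(sub)

  n_states <- vapply(seq_len(L), function(j) length(unique(sub[, j])),
                     integer(1))
  S <- sum(n_states >= 2)
  pars_inf <- sum(vapply(seq_len(L), function(j) {
    tab <- table(sub[, j])
    sum(tab >= 2) >= 2 && length(tab) >= 2
  }, logical(1)))

  # mean pairwise difference count over analyzed sites
  if (site_policy == "complete_columns") {
    pihat <- .mean_pairwise_diff(sub)
    pi_per_site <- if (L > 0) pihat / L else 0
  } else {
    pp <- .pairwise_deletion_pi(mat, good)
    pi_per_site <- pp$pi
    pihat <- .mean_pairwise_diff(sub)   # count scale still on complete cols
  }

  haps <- apply(sub, 1, paste, collapse = "")
  n_h <- length(unique(haps))
  p <- as.numeric(table(haps)) / n
  hd <- if (n > 1) n / (n - 1) * (1 - sum(p^2)) else 0

  taj <- .tajimas_d(n, S, pihat)

  structure(
    list(n = n, L = L, S = S, pi_per_site = pi_per_site,
         parsimony_informative = pars_inf, tajimas_d = taj$D,
         tajima_defined = taj$defined, n_haplotypes = n_h, hd = hd,
         pihat = pihat, site_policy = site_policy),
    class = "PopgenSummary"
  )
}

#' @export
print.PopgenSummary <- function(x, ...) {
  cat(sprintf(
    paste0("PopgenSummary: n=%d, L=%d, S=%d (%d parsimony-informative), ",
           "pi=%.4f, D=%s, %d haplotypes, Hd=%.4f\n"),
    x$n, x$L, x$S, x$parsimony_informative, x$pi_per_site,
    if (x$tajima_defined) sprintf("%.3f", x$tajimas_d) else "undefined",
    x$n_haplotypes, x$hd))
  invisible(x)
}

.mean_pairwise_diff <- function(sub) {
  n <- nrow(sub)
  if (n < 2 || ncol(sub) == 0) return(0)
  total <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      total <- total + sum(sub[i, ] != sub[j, ])
    }
  }
  total / choose(n, 2)
}

.pairwise_deletion_pi <- function(mat, good) {
  n <- nrow(mat)
  vals <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ok <- good[i, ] & good[j, ]
      if (any(ok))
        vals <- c(vals, sum(mat[i, ok] != mat[j, ok]) / sum(ok))
    }
  }
  list(pi = mean(vals))
}

# Tajima (1989) constants and statistic
.tajimas_d <- function(n, S, pihat) {
  if (n < 4 || S == 0)
    return(list(D = NA_real_, defined = FALSE))
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a2 + a1^2)
  D <- (pihat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(D = D, defined = TRUE)
}

#' Write a PopgenSummary as JSON and/or TSV
#'
#' @param x a `PopgenSummary`.
#' @param json_path optional JSON output path.
#' @param tsv_path optional TSV output path.
#' @return `x`, invisibly.
#' @export
write_popgen_summary <- function(x, json_path = NULL, tsv_path = NULL) {
  fields <- x[c("n", "L", "S", "pi_per_site", "parsimony_informative",
                "tajimas_d", "n_haplotypes", "hd")]
  if (!is.null(json_path))
    jsonlite::write_json(fields, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(tsv_path))
    utils::write.table(
      data.frame(statistic = names(fields),
                 value = unlist(lapply(fields, as.character))),
      tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
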