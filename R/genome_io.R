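#' Genome records and assembly statistics
#'
#' A `GenomeRecord` is a named set of scaffold sequences with free-form
#' metadata; it is the unit every downstream analysis (sketching, coherence
#' indices, composition profiles) consumes.
#'
#' @param id accession or label for the assembly.
#' @param scaffolds named character vector of nucleotide sequences
#'   (`A,C,G,T,N`; lowercase allowed and preserved).
#' @param metadata optional named list of free-form annotations.
#' @return An object of class `GenomeRecord`.
#' @export
genome_record <- function(id, scaffolds, metadata = list()) {
  if (is.null(names(scaffolds)) || any(names(scaffolds) == ""))
    stop("every scaffold must be named")
  if (anyDuplicated(names(scaffolds)))
    stop("scaffold names must be unique within a record")
  if (any(nchar(scaffolds) == 0L))
    stop("scaffold sequences must be non-empty")
  structure(
    list(id = as.character(id),
         scaffolds = vapply(scaffolds, as.character, character(1)),
         metadata = metadata),
    class = "GenomeRecord"
  )
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord '%s': %d scaffold(s), %s bp total\n",
              x$id, length(x$scaffolds),
              format(sum(nchar(x$scaffolds)), big.mark = ",")))
  invisible(x)
}

#' Read a (multi-)FASTA file into a GenomeRecord
#'
#' Sequence case is preserved and whitespace inside records is stripped.
#' The record id defaults to the file name without extension.
#'
#' @param path path to a FASTA file.
#' @param id optional record id; defaults to the basename of `path`.
#' @return A [genome_record()].
#' @export
read_fasta <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("no FASTA records in: ", path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))  # header word before space
  if (anyDuplicated(names(seqs)))
    stop("duplicate FASTA header in: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  genome_record(id, seqs)
}

#' Write a GenomeRecord as multi-FASTA
#'
#' @param g a [genome_record()].
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "GenomeRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(g$scaffolds)) {
    writeLines(paste0(">", nm), con)
    s <- g$scaffolds[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Assembly-level descriptive statistics
#'
#' Computes total length, N50/L50, GC content and telomere flags for a
#' genome record. N50 is the length of the scaffold at which the descending
#' cumulative length first reaches at least half the total; L50 is its
#' 1-based rank. GC is computed over unambiguous bases only (N and IUPAC
#' ambiguity codes are excluded from numerator and denominator).
#'
#' @param g a [genome_record()].
#' @param organelle_max_len size ceiling (bp) for organelle detection,
#'   passed to [detect_organelle()].
#' @return A list of class `AssemblyStats` with fields `total_length`,
#'   `n_scaffolds`, `n50`, `l50`, `gc_percent`, `organelle_scaffold`,
#'   `organelle_length`, `nuclear_length` (total minus organelle) and
#'   `telomere_status` (per-scaffold logical matrix, columns `p5`/`p3`).
#' @export
assembly_stats <- function(g, organelle_max_len = 100000L) {
  stopifnot(inherits(g, "GenomeRecord"))
  lens <- nchar(g$scaffolds)
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  cum <- cumsum(sorted)
  l50 <- which(cum >= total / 2)[1]
  n50 <- sorted[l50]

  counts <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(toupper(g$scaffolds))))
  acgt <- counts[c("A", "C", "G", "T")]
  if (sum(acgt) == 0)
    stop("GC undefined: record contains no unambiguous A/C/G/T bases")
  gc <- 100 * sum(acgt[c("C", "G")]) / sum(acgt)

  org <- detect_organelle(g, max_len = organelle_max_len)
  tel <- telomere_scan(g)

  structure(
    list(total_length = total,
         n_scaffolds = length(lens),
         n50 = n50,
         l50 = l50,
         gc_percent = gc,
         organelle_scaffold = org$name,
         organelle_length = org$length,
         nuclear_length = total - if (is.null(org$length)) 0L else org$length,
         telomere_status = tel),
    class = "AssemblyStats"
  )
}

#' @export
print.AssemblyStats <- function(x, ...) {
  cat(sprintf(
    "AssemblyStats: %s bp in %d scaffolds; N50 %s bp (L50 %d); GC %.2f%%\n",
    format(x$total_length, big.mark = ","), x$n_scaffolds,
    format(x$n50, big.mark = ","), x$l50, x$gc_percent))
  if (!is.null(x$organelle_scaffold))
    cat(sprintf("  putative organelle: %s (%s bp)\n", x$organelle_scaffold,
                format(x$organelle_length, big.mark = ",")))
  invisible(x)
}

#' Detect a putative organelle scaffold by size
#'
#' Fungal mitochondrial genomes are far smaller than nuclear chromosomes;
#' the shortest scaffold is reported as the organelle candidate when it
#' falls at or under `max_len`. This is a size heuristic, not a homology
#' search.
#'
#' @param g a [genome_record()].
#' @param max_len inclusive size ceiling in bp (default 100 kb).
#' @return A list with `name` and `length`, both `NULL` when no scaffold
#'   qualifies.
#' @export
detect_organelle <- function(g, max_len = 100000L) {
  stopifnot(inherits(g, "GenomeRecord"))
  lens <- nchar(g$scaffolds)
  i <- which.min(lens)
  if (lens[i] <= max_len)
    list(name = names(g$scaffolds)[i], length = unname(lens[i]))
  else
    list(name = NULL, length = NULL)
}

#' Scan scaffold ends for telomeric repeat arrays
#'
#' An end is flagged when the motif or its reverse complement occurs at
#' least `min_copies` times (case-insensitively, overlaps allowed) within
#' `window` bp of that end. The default motif TTAGGG / CCCTAA is the
#' telomeric repeat of filamentous ascomycetes.
#'
#' @param g a [genome_record()].
#' @param motif repeat unit (default `"TTAGGG"`).
#' @param window bp scanned at each end (default 500).
#' @param min_copies occurrences needed to flag an end (default 3).
#' @return Logical matrix, one row per scaffold, columns `p5` and `p3`.
#' @export
telomere_scan <- function(g, motif = "TTAGGG", window = 500L,
                          min_copies = 3L) {
  stopifnot(inherits(g, "GenomeRecord"))
  if (nchar(motif) == 0) stop("motif must be non-empty")
  if (window < nchar(motif)) stop("window smaller than motif length")
  motif <- toupper(motif)
  rc <- .revcomp(motif)
  count_hits <- function(s) {
    n <- .count_overlapping(s, motif)
    if (rc != motif) n <- n + .count_overlapping(s, rc)
    n
  }
  res <- t(vapply(g$scaffolds, function(s) {
    s <- toupper(s)
    n <- nchar(s)
    head_s <- substr(s, 1L, min(window, n))
    tail_s <- substr(s, max(1L, n - window + 1L), n)
    c(p5 = count_hits(head_s) >= min_copies,
      p3 = count_hits(tail_s) >= min_copies)
  }, logical(2)))
  rownames(res) <- names(g$scaffolds)
  res
}

.count_overlapping <- function(s, pat) {
  hits <- gregexpr(paste0("(?=", pat, ")"), s, perl = TRUE)[[1]]
  if (hits[1] == -1L) 0L else length(hits)
}

.revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Emit assembly statistics as a two-column TSV
#'
#' @param stats an `AssemblyStats` object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_assembly_stats <- function(stats, path) {
  tel_ends <- sum(stats$telomere_status)
  rows <- rbind(
    c("Genome size", sprintf("%d bp", stats$total_length)),
    c("Number of scaffolds", as.character(stats$n_scaffolds)),
    c("Contig N50", sprintf("%d bp", stats$n50)),
    c("Contig L50", as.character(stats$l50)),
    c("GC percent", sprintf("%.2f", stats$gc_percent)),
    c("Non-nuclear (Mitochondrion MT) size",
      if (is.null(stats$organelle_length)) "NA"
      else sprintf("%d bp", stats$organelle_length)),
    c("Nuclear genome size", sprintf("%d bp", stats$nuclear_length)),
    c("Telomere-bearing scaffold ends", as.character(tel_ends))
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
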