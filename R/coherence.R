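#' Overall genome relatedness indices
#'
#' Identity-based coherence metrics between a query genome and a
#' reference: [ani()] (average nucleotide identity over reciprocal
#' best-hit genome fragments), [aai()] (average amino-acid identity over
#' reciprocal best-hit proteins) and [pocp()] (percentage of conserved
#' proteins). The conventional species boundary is 95% ANI;
#' [coherence_verdict()] applies it with a borderline band up to 98%.
#'
#' @name coherence
NULL

#' Proteome record
#'
#' @param id proteome label.
#' @param proteins named character vector of amino-acid sequences
#'   (20-letter alphabet plus X and `*`).
#' @return Object of class `ProteomeRecord`.
#' @export
proteome_record <- function(id, proteins) {
  if (is.null(names(proteins)) || anyDuplicated(names(proteins)))
    stop("proteins must be uniquely named")
  if (length(proteins) == 0) stop("empty proteome")
  structure(list(id = id, proteins = vapply(proteins, as.character,
                                            character(1))),
            class = "ProteomeRecord")
}

#' @export
print.ProteomeRecord <- function(x, ...) {
  cat(sprintf("ProteomeRecord '%s': %d proteins\n", x$id,
              length(x$proteins)))
  invisible(x)
}

#' Read / write a proteome FASTA
#'
#' @param path FASTA path.
#' @param id proteome id; defaults to the file basename.
#' @return A [proteome_record()].
#' @export
read_proteome <- function(path, id = NULL) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))
  proteome_record(id, seqs)
}

#' @rdname read_proteome
#' @param p a [proteome_record()].
#' @export
write_proteome <- function(p, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(p$proteins), path)
  invisible(path)
}

#' Naive proteome from six-frame longest ORFs
#'
#' A convenience when no gene predictions are available: translates all
#' six frames, splits at stop codons and keeps open reading frames of at
#' least `min_aa` residues. Not a gene predictor.
#'
#' @param g a [genome_record()].
#' @param min_aa minimum ORF length in residues (default 100).
#' @return A [proteome_record()].
#' @export
proteome_from_orfs <- function(g, min_aa = 100L) {
  peps <- character(0)
  for (nm in names(g$scaffolds)) {
    s <- Biostrings::DNAString(gsub("[^ACGTacgt]", "N",
                                    toupper(g$scaffolds[[nm]])))
    for (strand in 1:2) {
      seq <- if (strand == 1) s else Biostrings::reverseComplement(s)
      for (off in 0:2) {
        sub <- Biostrings::subseq(seq, off + 1,
                                  length(seq) - (length(seq) - off) %% 3)
        if (length(sub) < 3) next
        aa <- suppressWarnings(as.character(
          Biostrings::translate(sub, if.fuzzy.codon = "X")))
        orfs <- strsplit(aa, "\\*")[[1]]
        orfs <- orfs[nchar(orfs) >= min_aa]
        if (length(orfs))
          peps <- c(peps, stats::setNames(
            orfs, sprintf("%s_f%d%s_%d", nm, off + 1,
                          c("+", "-")[strand], seq_along(orfs))))
      }
    }
  }
  if (length(peps) == 0) stop("no ORF of >= ", min_aa, " aa found")
  proteome_record(g$id, peps)
}

# ---- ANI --------------------------------------------------------------

#' Average nucleotide identity over reciprocal best-hit fragments
#'
#' Both genomes are cut into non-overlapping `frag_len` windows (the
#' OrthoANI-style granularity); fragments are matched across genomes by
#' shared seed k-mers (orientation-aware) and the best candidates aligned
#' globally. Only reciprocal best-hit fragment pairs whose identity
#' reaches `min_frag_identity` contribute; ANI is the mean percent
#' identity over contributing pairs (both directions averaged), so
#' self-comparison gives exactly 100.
#'
#' @param a,b [genome_record()] objects, each >= `frag_len` bp.
#' @param frag_len fragment window (default 1020 bp).
#' @param min_frag_identity identity floor for a fragment pair to count
#'   (fraction, default 0.3).
#' @param seed_k seed k-mer size for candidate matching (default 15).
#' @return ANI in percent. Errors with an explicit undefined-ANI message
#'   when no reciprocal fragment pair passes the floor.
#' @export
ani <- function(a, b, frag_len = 1020L, min_frag_identity = 0.3,
                seed_k = 15L) {
  fa <- .fragments(a, frag_len)
  fb <- .fragments(b, frag_len)
  if (length(fa) == 0 || length(fb) == 0)
    stop("genome shorter than one fragment (", frag_len, " bp)")
  hits_ab <- .best_fragment_hits(fa, fb, seed_k)
  hits_ba <- .best_fragment_hits(fb, fa, seed_k)
  ids <- numeric(0)
  for (i in seq_along(fa)) {
    j <- hits_ab$best[i]
    if (is.na(j)) next
    if (!is.na(hits_ba$best[j]) && hits_ba$best[j] == i) {
      id <- (hits_ab$pid[i] + hits_ba$pid[j]) / 2
      if (id >= min_frag_identity * 100) ids <- c(ids, id)
    }
  }
  if (length(ids) == 0)
    stop("undefined ANI: no reciprocal fragment pair above the identity ",
         "floor")
  mean(ids)
}

.fragments <- function(g, frag_len) {
  out <- character(0)
  for (s in g$scaffolds) {
    n <- nchar(s)
    if (n < frag_len) next
    starts <- seq(1L, n - frag_len + 1L, by = frag_len)
    out <- c(out, substring(toupper(s), starts, starts + frag_len - 1L))
  }
  out[!grepl("[^ACGT]", out)]
}

# fixed +1/-1 DNA scoring matrix, built once (avoids the costly
# quality-based matrix construction inside pairwiseAlignment)
.dna_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat))
      mat <<- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1)
    mat
  }
})

# seed-and-align: for each query fragment pick the subject fragment
# sharing the most seed k-mers (forward or reverse orientation), then
# align globally and record percent identity
.best_fragment_hits <- function(q, s, seed_k) {
  step <- max(1L, seed_k)
  seed_of <- function(frag) {
    starts <- seq(1L, nchar(frag) - seed_k + 1L, by = step)
    substring(frag, starts, starts + seed_k - 1L)
  }
  s_index <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(s)) {
    for (km in unique(seed_of(s[j]))) {
      assign(km, c(get0(km, envir = s_index, ifnotfound = integer(0)), j),
             envir = s_index)
    }
  }
  lookup <- function(seeds) {
    hits <- unlist(lapply(unique(seeds), get0, envir = s_index,
                          ifnotfound = integer(0)))
    if (length(hits) == 0) return(NA_integer_)
    tab <- tabulate(hits, nbins = length(s))
    which.max(tab)
  }
  best <- integer(length(q)); pid <- numeric(length(q))
  subj_set <- Biostrings::DNAStringSet(s)
  for (i in seq_along(q)) {
    fw <- seed_of(q[i])
    rv <- seed_of(.revcomp(q[i]))
    jf <- lookup(fw); jr <- lookup(rv)
    # orientation by stronger seed support
    cand <- c(jf, jr)
    use_rc <- c(FALSE, TRUE)
    scores <- c(-Inf, -Inf)
    for (z in 1:2) {
      if (!is.na(cand[z])) {
        seeds <- if (z == 1) fw else rv
        scores[z] <- sum(seeds %in% seed_of(s[cand[z]]))
      }
    }
    z <- which.max(scores)
    if (is.infinite(scores[z])) { best[i] <- NA_integer_; next }
    pat <- if (use_rc[z]) .revcomp(q[i]) else q[i]
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(pat), subj_set[[cand[z]]], type = "global",
      substitutionMatrix = .dna_submat(), gapOpening = 4,
      gapExtension = 1)
    best[i] <- cand[z]
    pid[i] <- Biostrings::pid(aln, type = "PID1")
  }
  list(best = best, pid = pid)
}

# ---- AAI / POCP -------------------------------------------------------

# all-vs-all local alignments between two proteomes; returns per-pair
# score, percent identity and alignable fraction of the shorter protein
.protein_hits <- function(a, b, gap_open, gap_ext) {
  pa <- Biostrings::AAStringSet(a$proteins)
  pb <- Biostrings::AAStringSet(b$proteins)
  na <- length(pa); nb <- length(pb)
  score <- matrix(-Inf, na, nb)
  pid <- matrix(0, na, nb)
  alen <- matrix(0, na, nb)
  for (i in seq_len(na)) {
    a_i <- Biostrings::pairwiseAlignment(
      rep(pa[i], nb), pb, type = "local",
      substitutionMatrix = "BLOSUM62",
      gapOpening = gap_open, gapExtension = gap_ext)
    score[i, ] <- Biostrings::score(a_i)
    pid[i, ] <- Biostrings::pid(a_i, type = "PID1")
    alen[i, ] <- Biostrings::nchar(a_i)
  }
  len_a <- Biostrings::nchar(pa)
  len_b <- Biostrings::nchar(pb)
  list(score = score, pid = pid, alen = alen,
       frac_short = alen / outer(len_a, len_b, pmin),
       len_a = len_a, len_b = len_b)
}

#' Average amino-acid identity over reciprocal best hits
#'
#' Proteins are paired by reciprocal best local-alignment hits (BLOSUM62);
#' pairs with identity above `min_identity` percent and an aligned region
#' covering more than `min_frac` of the shorter protein contribute, and
#' AAI is their mean percent identity.
#'
#' @param a,b [proteome_record()] objects.
#' @param min_identity identity floor in percent (default 30).
#' @param min_frac alignable-fraction floor on the shorter protein
#'   (default 0.7).
#' @return AAI in percent; errors when no reciprocal pair qualifies.
#' @export
aai <- function(a, b, min_identity = 30, min_frac = 0.7) {
  stopifnot(inherits(a, "ProteomeRecord"), inherits(b, "ProteomeRecord"))
  h <- .protein_hits(a, b, gap_open = 10, gap_ext = 0.5)
  best_ab <- apply(h$score, 1, which.max)
  best_ba <- apply(h$score, 2, which.max)
  ids <- numeric(0)
  for (i in seq_along(best_ab)) {
    j <- best_ab[i]
    if (best_ba[j] == i &&
        h$pid[i, j] > min_identity && h$frac_short[i, j] > min_frac)
      ids <- c(ids, h$pid[i, j])
  }
  if (length(ids) == 0)
    stop("undefined AAI: no reciprocal best-hit pair passes the filters")
  mean(ids)
}

#' Percentage of conserved proteins
#'
#' A protein of one proteome is conserved in the other when it has a hit
#' with E-value below `max_evalue`, identity above `min_identity` percent
#' and an aligned region covering more than `min_frac` of the query
#' length. `POCP = 100 * (C1 + C2) / (T1 + T2)` with C the conserved
#' counts in each direction and T the proteome sizes. E-values use the
#' Karlin-Altschul formula `E = K m n exp(-lambda S)` with conventional
#' gapped BLOSUM62 parameters (lambda = 0.267, K = 0.041).
#'
#' @param a,b [proteome_record()] objects.
#' @param max_evalue E-value ceiling (default 1e-5).
#' @param min_identity identity floor in percent (default 40).
#' @param min_frac aligned-fraction floor on the query length
#'   (default 0.5).
#' @return POCP in percent.
#' @export
pocp <- function(a, b, max_evalue = 1e-5, min_identity = 40,
                 min_frac = 0.5) {
  stopifnot(inherits(a, "ProteomeRecord"), inherits(b, "ProteomeRecord"))
  h <- .protein_hits(a, b, gap_open = 11, gap_ext = 1)
  lambda <- 0.267; K <- 0.041
  conserved <- function(score, pid, frac_query, len_q, len_db_total) {
    e <- K * len_q * len_db_total * exp(-lambda * score)
    any(e < max_evalue & pid > min_identity & frac_query > min_frac)
  }
  db_b <- sum(h$len_b); db_a <- sum(h$len_a)
  c1 <- sum(vapply(seq_along(h$len_a), function(i)
    conserved(h$score[i, ], h$pid[i, ], h$alen[i, ] / h$len_a[i],
              h$len_a[i], db_b), logical(1)))
  c2 <- sum(vapply(seq_along(h$len_b), function(j)
    conserved(h$score[, j], h$pid[, j], h$alen[, j] / h$len_b[j],
              h$len_b[j], db_a), logical(1)))
  100 * (c1 + c2) / (length(h$len_a) + length(h$len_b))
}

#' Three-way coherence verdict against the species threshold
#'
#' `distinct` when ANI is below `ani_threshold` (the 95% species
#' boundary); `conspecific` when ANI is at least 98; `borderline` in
#' between. The Mash-distance flag (D at or below `d_threshold` marks
#' "high genomic coherence") is contextual and never classifies on its
#' own.
#'
#' @param panel a one-row coherence panel (list or data.frame row) with
#'   at least `ani`; `D` optional.
#' @param ani_threshold species boundary in percent (default 95).
#' @param d_threshold Mash coherence flag threshold (default 0.05).
#' @return List with `verdict` (`"distinct"`, `"borderline"` or
#'   `"conspecific"`) and `high_coherence_flag` (logical or NA).
#' @export
coherence_verdict <- function(panel, ani_threshold = 95.0,
                              d_threshold = 0.05) {
  ani_val <- panel$ani
  if (is.null(ani_val) || is.na(ani_val))
    stop("panel must have ANI populated")
  verdict <- if (ani_val < ani_threshold) "distinct"
             else if (ani_val >= 98) "conspecific"
             else "borderline"
  flag <- if (!is.null(panel$D) && !is.na(panel$D)) panel$D <= d_threshold
          else NA
  list(verdict = verdict, high_coherence_flag = flag)
}

#' Assemble and write a coherence panel table
#'
#' One row per query/reference pair in the column order used for
#' genome-relatedness reporting: Strain, Assembly accession, D, ANI, AAI,
#' POCP, Hexamer frequency, Country of origin.
#'
#' @param rows data.frame with columns `strain`, `accession`, `D`, `ani`,
#'   `aai`, `pocp`, `hexamer`, `country` (missing metrics as NA).
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_coherence_panel <- function(rows, path) {
  out <- data.frame(
    "Strain" = rows$strain,
    "Assembly accession" = rows$accession,
    "D" = rows$D, "ANI" = rows$ani, "AAI" = rows$aai,
    "POCP" = rows$pocp, "Hexamer frequency" = rows$hexamer,
    "Country of origin" = rows$country,
    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
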