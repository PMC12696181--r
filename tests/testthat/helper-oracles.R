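# Independent brute-force oracles used across tests. These deliberately
# re-derive quantities from first principles rather than calling package
# internals.

oracle_n50 <- function(lens) {
  sorted <- sort(lens, decreasing = TRUE)
  total <- sum(sorted)
  cum <- cumsum(sorted)
  i <- which(cum >= total / 2)[1]
  list(n50 = sorted[i], l50 = i)
}

revcomp_str <- function(s) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# exact canonical k-mer set of a sequence (uppercase, ACGT only)
oracle_canonical_kmers <- function(s, k) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < k) return(character(0))
  fw <- substring(s, 1:(n - k + 1), k:n)
  rc_full <- revcomp_str(s)
  rc <- substring(rc_full, (n - k + 1):1, n:k)
  ok <- !grepl("[^ACGT]", fw)
  unique(pmin(fw[ok], rc[ok]))
}

oracle_jaccard <- function(s1, s2, k) {
  a <- oracle_canonical_kmers(s1, k)
  b <- oracle_canonical_kmers(s2, k)
  length(intersect(a, b)) / length(union(a, b))
}

# Lance-Williams ward.D2 agglomeration: returns the sorted merge heights
oracle_ward_heights <- function(m) {
  d2 <- m^2
  n <- nrow(d2)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        v <- d2[active[ii], active[jj]]
        if (v < bestv - 1e-15) { bestv <- v; best <- c(ii, jj) }
      }
    }
    i <- active[best[1]]; j <- active[best[2]]
    heights <- c(heights, sqrt(bestv))
    ni <- sizes[i]; nj <- sizes[j]
    for (kk in active) {
      if (kk == i || kk == j) next
      nk <- sizes[kk]
      v <- ((ni + nk) * d2[i, kk] + (nj + nk) * d2[j, kk] -
              nk * d2[i, j]) / (ni + nj + nk)
      d2[i, kk] <- d2[kk, i] <- v
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# exhaustive PTP: enumerate every antichain of internal nodes (cut sets),
# evaluate the two-class exponential profile likelihood from scratch
oracle_ptp_best <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  pa <- integer(nnode); elen <- numeric(nnode)
  for (e in seq_len(nrow(tree$edge))) {
    pa[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  internal <- (n + 1):nnode
  desc <- lapply(seq_len(nnode), function(v) {
    which(vapply(seq_len(nnode), function(w) {
      p <- pa[w]
      while (p != 0) { if (p == v) return(TRUE); p <- pa[p] }
      FALSE
    }, logical(1)))
  })
  cls <- function(k, L) if (k == 0) 0 else if (L <= 0) -Inf else
    k * log(k / L) - k
  total_n <- nrow(tree$edge); total_len <- sum(tree$edge.length)
  best_ll <- -Inf
  m <- length(internal)
  for (mask in 0:(2^m - 1)) {
    cuts <- internal[bitwAnd(bitwShiftR(mask, seq_len(m) - 1), 1L) == 1L]
    # antichain check
    ok <- TRUE
    for (v in cuts) if (any(desc[[v]] %in% cuts)) { ok <- FALSE; break }
    if (!ok) next
    coal <- unlist(lapply(cuts, function(v) desc[[v]]))
    coal_n <- length(coal); coal_len <- sum(elen[coal])
    ll <- cls(total_n - coal_n, total_len - coal_len) +
      cls(coal_n, coal_len)
    if (ll > best_ll) best_ll <- ll
  }
  best_ll
}

# all permutations of 1..n (for exact Mantel enumeration)
oracle_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

oracle_pairwise_pi <- function(rows) {
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  keep <- apply(mat, 2, function(col) all(col %in% c("A", "C", "G", "T")))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    tot <- tot + sum(mat[i, ] != mat[j, ])
  list(pihat = tot / choose(n, 2),
       pi_per_site = tot / choose(n, 2) / ncol(mat), L = ncol(mat))
}

random_genome_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a pair of sequences at substitution divergence d (no indels)
diverged_pair_seq <- function(n, d, seed) {
  set.seed(seed)
  anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  mutate <- function(x, rate) {
    nmut <- rpois(1, rate * length(x))
    pos <- sample.int(length(x), min(nmut, length(x)))
    for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
    x
  }
  a <- mutate(anc, d / 2); b <- mutate(anc, d / 2)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""),
       realized_d = mean(a != b))
}
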