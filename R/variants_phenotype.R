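#' Variant records and the insertion-size screen
#'
#' Minimal variant records (CHROM, POS, REF, ALT, INFO) as produced by a
#' whole-genome aligner's variant output, with a classifier and the
#' k-mer-size insertion filter: insertions whose ALT allele reaches the
#' assembly k-mer size (k = 31 by default) are the ones most likely to
#' disrupt k-mer-based analyses and gene structure, and are prioritized.
#'
#' @param chrom chromosome / scaffold name.
#' @param pos 1-based position.
#' @param ref,alt reference and alternate alleles (non-empty).
#' @param info free-form key/value string.
#' @return A list of class `VariantRecord`.
#' @export
variant_record <- function(chrom, pos, ref, alt, info = "") {
  if (pos < 1) stop("pos must be >= 1")
  if (nchar(ref) == 0 || nchar(alt) == 0)
    stop("ref and alt must be non-empty")
  ok <- grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$", c(ref, alt))
  if (!all(ok)) stop("non-IUPAC characters in ref/alt")
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 alt = alt, info = info),
            class = "VariantRecord")
}

#' Classify a variant record
#'
#' `snv` when both alleles are single differing bases; `insertion` when
#' ALT extends REF as a prefix; `deletion` when REF extends ALT as a
#' prefix; `complex` otherwise. Case-insensitive.
#'
#' @param v a [variant_record()].
#' @return One of `"snv"`, `"insertion"`, `"deletion"`, `"complex"`.
#' @export
classify_variant <- function(v) {
  stopifnot(inherits(v, "VariantRecord"))
  ref <- toupper(v$ref); alt <- toupper(v$alt)
  if (nchar(ref) == 1 && nchar(alt) == 1)
    return(if (ref != alt) "snv" else "complex")
  if (nchar(alt) > nchar(ref) && startsWith(alt, ref)) return("insertion")
  if (nchar(ref) > nchar(alt) && startsWith(ref, alt)) return("deletion")
  "complex"
}

#' Filter insertion records by size threshold
#'
#' Keeps insertion-class records whose ALT allele length (default
#' `criterion = "alt_length"`) or net inserted length
#' (`|alt| - |ref|`, `criterion = "net_length"`) reaches `k`. Input order
#' is preserved. Length counting is case-insensitive.
#'
#' @param vs list of [variant_record()] objects.
#' @param k size threshold in bp (default 31, the conventional assembly
#'   k-mer size).
#' @param criterion `"alt_length"` (default) or `"net_length"`.
#' @return The retained subset of `vs`.
#' @export
filter_insertions <- function(vs, k = 31L,
                              criterion = c("alt_length", "net_length")) {
  criterion <- match.arg(criterion)
  stopifnot(k >= 1)
  keep <- vapply(vs, function(v) {
    if (classify_variant(v) != "insertion") return(FALSE)
    len <- if (criterion == "alt_length") nchar(v$alt)
           else nchar(v$alt) - nchar(v$ref)
    len >= k
  }, logical(1))
  vs[keep]
}

#' Read a variant table (VCF subset or tab-separated)
#'
#' Accepts either a VCF v4.x file (only CHROM, POS, REF, ALT, INFO are
#' used; `##` meta lines skipped) or a plain TSV whose header contains
#' `CHROM`/`#CHROM`, `POS`, `REF`, an ALT column (`ALT` or
#' `ALT-INSERTION`) and optionally `INFO`.
#'
#' @param path input path.
#' @return List of [variant_record()] objects.
#' @export
read_variant_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  body <- lines[-1]
  body <- body[nzchar(body)]
  cols <- strsplit(body, "\t")
  idx <- function(nm) {
    i <- which(toupper(header) %in% nm)
    if (length(i) == 0) stop("missing column: ", paste(nm, collapse = "/"))
    i[1]
  }
  i_chrom <- idx(c("CHROM", "#CHROM"))
  i_pos <- idx("POS")
  i_ref <- idx("REF")
  i_alt <- idx(c("ALT", "ALT-INSERTION"))
  i_info <- which(toupper(header) == "INFO")
  lapply(cols, function(f) {
    variant_record(f[i_chrom], as.integer(f[i_pos]), f[i_ref], f[i_alt],
                   if (length(i_info)) f[i_info[1]] else "")
  })
}

#' Colony radial growth rate
#'
#' Ordinary least-squares slope of colony diameter against time.
#'
#' @param times hours, strictly increasing, length >= 2.
#' @param diameters cm, same length as `times`.
#' @return Growth rate in cm/h.
#' @export
growth_rate <- function(times, diameters) {
  if (length(times) < 2) stop("need at least 2 time points")
  if (length(times) != length(diameters))
    stop("times and diameters differ in length")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  unname(stats::coef(stats::lm(diameters ~ times))[2])
}

#' Percentage inhibition of radial growth (PIRG)
#'
#' `PIRG = (R1 - R2) / R1 * 100`, where R1 is the pathogen's radius grown
#' alone and R2 its radius in dual culture with the antagonist. Negative
#' values (pathogen grew more with the antagonist) are allowed and
#' carry a warning.
#'
#' @param r1 pathogen-alone radius (cm), > 0.
#' @param r2 dual-culture pathogen radius (cm), >= 0.
#' @return PIRG in percent.
#' @export
pirg <- function(r1, r2) {
  if (any(r1 <= 0)) stop("r1 must be > 0")
  if (any(r2 < 0)) stop("r2 must be >= 0")
  out <- (r1 - r2) / r1 * 100
  if (any(out < 0))
    warning("negative PIRG: pathogen grew more with the antagonist")
  out
}

#' Compare PIRG across antagonists: one-way ANOVA + Tukey HSD
#'
#' @param groups named list, antagonist -> numeric vector of PIRG
#'   replicates (>= 2 groups, >= 2 replicates each).
#' @param alpha significance level for flagging pairs (default 0.05).
#' @return List with `anova_f`, `anova_p`, `tukey` (data.frame of pairwise
#'   comparisons: diff, lwr, upr, p_adj, significant) and `group_means`.
#' @export
compare_pirg_groups <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2)) stop("every group needs >= 2 replicates")
  df <- data.frame(
    pirg = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), sizes)))
  fit <- stats::aov(pirg ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] <= alpha,
                      row.names = NULL)
  list(anova_f = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1],
       tukey = tukey,
       group_means = vapply(groups, mean, numeric(1)))
}

#' Dual-culture measurement row
#'
#' @param pathogen pathogen name.
#' @param r1,r2 radii in cm (pathogen alone / with antagonist).
#' @return A list of class `DualCultureMeasure` including the computed
#'   `pirg` and a `flagged` field when `r2 > r1`.
#' @export
dual_culture_measure <- function(pathogen, r1, r2) {
  flagged <- r2 > r1
  p <- suppressWarnings(pirg(r1, r2))
  structure(list(pathogen = pathogen, r1 = r1, r2 = r2, pirg = p,
                 flagged = flagged),
            class = "DualCultureMeasure")
}
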