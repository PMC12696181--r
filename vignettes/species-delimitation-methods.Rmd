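---
title: "Integrative genome-based species delimitation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrative genome-based species delimitation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylodelim)
```

## The problem

Deciding whether a newly sequenced fungal isolate is a known species or a
new one is no longer settled by morphology or a single marker. The modern
argument is integrative: several independent lines of genomic evidence —
alignment-free whole-genome distance, identity-based relatedness indices,
genome composition, phylogenetic placement, coalescent delimitation
models, and population-genetic structure — are computed against the
isolate's nearest sequenced relatives, and the species hypothesis stands
only if they agree. `phylodelim` implements that whole chain as testable
functions, together with simulators that generate inputs with known
truth, so each stage can be validated without touching public archives.

The package is organized as an analysis: the numbered scripts under
`analysis/` walk through simulation, coherence screening, delimitation,
diversity statistics, geography and phenotype, writing their tables under
`results/`. Every computation in those scripts is a package function.

## Genome screening: MinHash sketches and the Mash distance

Candidate relatives are found by alignment-free screening. A genome is
reduced to a bottom-$s$ MinHash sketch: every canonical $k$-mer (the
lexicographic minimum of a $k$-mer and its reverse complement, so
strandedness does not matter) is hashed with a 64-bit MurmurHash3-style
function, and the $s$ smallest distinct hash values are kept. Defaults
are $k = 21$, $s = 1000$, hash seed 42 — the conventional parameters of
genome sketching tools; hash values are masked to 53 bits so they are
exactly representable as R doubles, which changes nothing statistically
at these sketch sizes.

Two sketches estimate the Jaccard index $J$ of the underlying $k$-mer
sets by the merged-union bottom-$s$ estimator: with $X$ the $s$ smallest
hashes of the union, $\hat J = |X \cap A \cap B| / |X|$. The Mash
distance is

$$D = -\tfrac{1}{k}\,\ln\!\frac{2J}{1+J},$$

which under a Poisson substitution model approximates per-base
divergence. $J = 0$ makes the closed form diverge; $D$ is capped at 1
and the cap is visible in output. $D \le 0.05$ is reported as a "high
genomic coherence" flag but never classifies on its own — the package's
verdict logic treats ANI as primary, because compositional and identity
signals can disagree inside the $D \le 0.05$ neighborhood.

## Relatedness indices: ANI, AAI, POCP

ANI is computed OrthoANI-style: both genomes are cut into
non-overlapping 1020 bp fragments, fragments are matched across genomes
by shared seed $k$-mers (orientation-aware, seed $k = 15$), candidate
pairs are aligned globally, and only reciprocal best-hit fragment pairs
with at least 30% identity contribute; ANI is their mean percent
identity with both directions averaged, so self-ANI is exactly 100.
Fragment granularity (1020 bp) follows the cited convention; the seed
size trades sensitivity for speed and is configurable. When no
fragment pair passes the floor the function signals an explicit
undefined-ANI error instead of returning 0.

AAI pairs proteins by reciprocal best local-alignment hits under
BLOSUM62 (identity > 30%, aligned region > 70% of the shorter protein);
POCP counts a protein as conserved when it has a hit with E-value
< 1e-5, identity > 40% and aligned region > 50% of the query, and is
$100\,(C_1+C_2)/(T_1+T_2)$. E-values use the Karlin–Altschul formula
with conventional gapped BLOSUM62 parameters ($\lambda = 0.267$,
$K = 0.041$). Proteomes are explicit inputs; a six-frame longest-ORF
extractor is provided as a convenience, clearly not a gene predictor.
At the proteome sizes this package targets, the reciprocal-best-hit
search is an exact all-vs-all alignment rather than a seeded heuristic.

The three-way verdict classifies a pair as *distinct* below 95% ANI
(the conventional species boundary), *conspecific* at or above 98%, and
*borderline* between — reflecting the observation that distinct fungal
species can share up to ~98% ANI. Both thresholds are arguments.

## Composition profiles

The canonical hexamer frequency profile (2,080 bins at $k = 6$) is a
content signature sensitive to coding density and genome architecture.
Four indices compare normalized profiles: weighted Jaccard
$\sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)$, containment
(asymmetric, query in the denominator), Euclidean distance, and Pearson
correlation. Frequencies, not raw counts, are compared because genomes
differ in length. The dendrogram distance used by the workflow defaults
to $1 -$ weighted Jaccard; which index drives a published figure is
often unstated, so the choice is a flag, and a binary
(presence/absence) Jaccard is also available because "proportion of
shared hexamers" admits both readings.

## Trees

Distance phylogenies use BIONJ by default (plain NJ available) on the
Mash distance matrix directly; no internal distance transformation is
applied, since published branch lengths in this workflow are on the $D$
scale. Negative NJ branches — an artifact on non-additive matrices —
are clamped to zero with the deficit moved to the sister edges so path
lengths are approximately preserved. Ward clustering uses the
`ward.D2` convention (Lance–Williams on squared distances, heights on
the original scale) with deterministic tie-breaking. Bootstrap supports
for the distance phylogeny are computed by resampling sketch hashes and
recording bipartition frequencies; these measure stability of the
distance signal, not model-based support, and are labeled as such.

## Species delimitation

Three tests run on trees whose tips are candidate conspecifics.

**ML PTP.** Branches belong to a speciation class or a coalescent
class, each exponential with its own rate (MLE $=$ 1/mean class branch
length). A partition is a set of subtree "cuts": edges inside cut
subtrees are coalescent, each cut subtree is one species, tips on the
speciation backbone are singletons. The original formulation allows
per-species coalescent rates; this implementation pools them into one
class, which keeps the likelihood enumerable by brute force on small
trees (the test suite exploits exactly that). The search is exhaustive
over antichains up to 15 internal nodes and greedy hill-climbing with
absorb/push-down moves beyond. A likelihood-ratio test against the
one-class null (all branches one rate, $\chi^2_1$) gates the result:
when the null is not rejected a single species is returned.

**Bayesian PTP.** Metropolis–Hastings over the same cut-set space under
a uniform prior, with dissolve / push-down / absorb moves proposed
uniformly from the current move set and a Hastings correction for the
changing neighborhood size. Support of a species is the fraction of
post-burn-in samples containing exactly that tip set; chains run
independently per seed and the convergence report is the largest
cross-seed support difference. Defaults: $10^6$ iterations, 10%
burn-in, thinning 100, seeds 1–4 (burn-in and thinning are
conventional choices, not taken from any publication). The sampler uses
the profile likelihood (plug-in rate MLEs) rather than integrating the
rates; both partitions under comparison always carry the same two rate
parameters, so no dimension penalty is being skipped.

**GMYC.** The single-threshold mixed Yule coalescent on an ultrametric
tree: nodes deeper than a threshold $T$ are speciation events (Yule,
per-lineage rate), nodes shallower are within-species coalescences
(per-pair rate, exposure restricted to pairs within the same cluster —
lineages crossing $T$ define the clusters). Both rate MLEs are closed
form per threshold; candidates are midpoints between consecutive node
heights plus the two extremes. Non-ultrametric input is smoothed by
mean path length: each node's height becomes the mean distance to its
descendant tips, clamped so a child never exceeds its parent — an
idempotent transformation chosen because tools that "accept
non-ultrametric trees" rarely say how. The threshold model shrinks
coalescent exposure on *any* tree, so the naive $\chi^2$ reference for
its LRT rejects far too often (a well-documented pathology of this
model class). The p-value is therefore computed by parametric
bootstrap: trees are simulated from the fitted single-process null
(Yule or coalescent, whichever extreme fits better; the LRT is
invariant to overall rate scaling, so unit-rate simulations suffice)
and the observed LRT is ranked among the simulated ones (99 replicates
by default). When the null is retained the all-singleton convention is
reported with a "no significant clustering" flag. Per-cluster support
is the Akaike weight mass of the thresholds whose partition contains
the cluster. Whether published support values are node-level or
partition-level is often ambiguous — this package emits both the
per-species supports and the partition-level statistics.

Unrooted input trees are midpoint-rooted before PTP; the rooting choice
is documented in output rather than silently applied.

## Population genetics

The multilocus panel runs on a row-wise concatenation of pre-aligned
markers (alignment and trimming are upstream, out of scope). Under the
default listwise (`complete_columns`) policy any column containing a
gap or IUPAC ambiguity is dropped entirely — the convention of the
popular haplotype-network tools; pairwise deletion is available for
$\pi$. Reported are segregating sites $S$, parsimony-informative sites
(≥ 2 states each in ≥ 2 sequences), per-site nucleotide diversity
$\pi$, haplotype count and haplotype diversity
$H_d = \frac{n}{n-1}(1 - \sum_i p_i^2)$, and Tajima's D per the 1989
formulas, with $\hat\pi$ on the count scale inside D and $\pi$ per
analyzed site in the report. $S = 0$ yields an explicit undefined flag
for D, never a silent zero. The worked example in the test suite
($n = 4$, $S = 3$, $\hat\pi = 1.5$, $D \approx -0.754$) is evaluated
from the constants by hand. No p-value for D is computed beyond the
tests' simulation checks; outgroup inclusion is the caller's choice via
ordinary subsetting of the alignment.

## Geographic differentiation

The Mantel test correlates the genomic distance matrix (restricted to a
focal strain's coherence neighborhood, $D \le 0.1$) with a binary
same/different-country matrix — "categorical" geographic distance is
encoded 0/1 since no finer encoding is published. Spearman or Kendall
tau-b rank correlations run on the upper triangles, the null permutes
rows and columns of the geographic matrix simultaneously, and
$p = (\text{count} + 1)/(n_\text{perm} + 1)$; at $n \le 7$ complete
enumeration is available and the tests verify the permutation p equals
it. The default tail is one-sided (greater), matching the hypothesis
that geographic separation accompanies divergence; published r/p values
for this test depend on unstated permutation counts and tails, so they
are checked only for sign and rough magnitude, not reproduced exactly.

## Variants and phenotype

The variant screen classifies records by the prefix rule (SNV /
insertion / deletion / complex) and retains insertions whose ALT allele
reaches the assembly $k$-mer size, $k = 31$. The printed table of major
insertions contains an ALT of exactly 31 letters whose net inserted
length is 30, so "larger than 31 bp" is ambiguous between ALT length
and net length; the ALT-length reading reproduces the printed set of 14
and is the default, with `net_length` available.

Growth rate is the OLS slope of colony diameter on time (cm/h); PIRG is
$(R_1 - R_2)/R_1 \times 100$ with negative values allowed but flagged;
group comparisons use one-way ANOVA with Tukey HSD at $\alpha = 0.05$.

## The synthetic-data module

Three generators provide inputs with known truth. `evolve_pair`
produces a genome pair from a random ancestor (default GC 0.48, typical
for these fungi) with Poisson substitutions at $d/2$ per descendant and
geometric-length indels; the truth records realized identity measured
before indels. `simulate_species_markers` builds a species tree with
exponential inter-species branches, attaches neutral-coalescent
genealogies scaled by $\theta/2$, and evolves markers under
Jukes–Cantor (the simplest model that exercises $\pi$, $S$, D and
delimitation; richer models are out of scope); all markers share one
genealogy — no recombination. `simulate_delimitation_tree` builds the
two-rate tree the PTP model assumes: iid exponential within-clade
branches (mean 0.001) against an exponential backbone (mean 0.5), the
canonical "well-separated" condition. The distinction matters: on
coalescent genealogies the exact-ML PTP occasionally splits off a
deep-coalescing tip — correct ML behavior under model
misspecification — so recovery rates are benchmarked on the two-rate
trees where failures would indicate implementation errors.
`simulate_variant_table` emits records with a known class and
length spectrum (geometric lengths by default, chosen to straddle
$k = 31$ when configured with mean ≈ 20).

What the simulations do not emulate: repeats and mobile elements,
GC heterogeneity along chromosomes, sequencing error, recombination,
gene gain/loss. Passing tests therefore demonstrate correctness of the
statistics and search procedures, not robustness to every property of
real assemblies.

## Numerical choices and problem sizes

Simulated genomes are 200 kb where divergence recovery is measured
(large enough that binomial noise on identity is ≈ 0.05 pp) and 15–30 kb
where only correctness of plumbing is at stake. Delimitation benchmarks
use 3 species × 5 tips over 20 replicate trees; the Bayesian sampler
runs $10^5$ iterations per chain in the benchmarks, which its
convergence diagnostic shows is ample at this tree size. Mantel null
calibration uses 500 datasets at $n = 10$ with 199 permutations each.
Ties in clustering are broken deterministically; distance matrices are
validated to 1e-12 symmetry; Newick round-trips are exact to 1e-9.

## Known limitations

ANI here is not bit-compatible with any particular published binary
(explicitly out of scope); its absolute values agree with simulated
truth to < 0.1 pp but can differ from other implementations by a few
tenths on real, repeat-rich genomes. The PTP search is exact only up to
15 internal nodes. GMYC supports are Akaike-weight heuristics, not
posterior probabilities. The six-frame ORF extractor is a stopgap for
demonstration, not a substitute for gene prediction.
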