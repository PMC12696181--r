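Package: phylodelim
Title: Integrative Genome-Based Species Delimitation for Fungal Isolates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative workflow for deciding whether a newly sequenced
    fungal isolate is a distinct species. Combines alignment-free genome
    screening (bottom-s MinHash sketches and the Mash distance), overall
    genome relatedness indices (ANI, AAI, POCP) against the conventional 95
    percent species boundary, canonical hexamer composition profiles with
    weighted Jaccard, containment, Euclidean and Pearson similarity,
    distance-based phylogenomics (BIONJ/NJ, Ward clustering), coalescent
    species-delimitation tests (ML and Bayesian Poisson tree processes,
    single-threshold GMYC), multilocus population-genetic summaries
    (nucleotide diversity, segregating sites, Tajima's D, haplotype
    diversity), a Mantel test of geographic differentiation, an
    insertion-size variant screen, and dual-culture phenotype statistics
    (growth rates, PIRG). A synthetic-data module generates genomes, marker
    alignments and variant tables with known truth so every stage is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
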