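#!/usr/bin/env Rscript
# Stage 1: generate every synthetic input the downstream analyses
# consume — genome pairs across the divergence range observed among the
# focal strain's neighbors (Mash D roughly 0.04-0.13), multi-species
# marker alignments, two-rate delimitation trees, and a variant table —
# and record the construction truth beside each artifact.

suppressPackageStartupMessages(library(phylodelim))
out <- "results/01_inputs"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260922L

message("simulating genome pairs at divergences 1-8% ...")
truth <- do.call(rbind, lapply(c(0.01, 0.03, 0.05, 0.08), function(d) {
  pp <- evolve_pair(divergence_spec(200000, d = d,
                                    seed = seed + round(1000 * d)))
  tag <- sprintf("d%03d", round(1000 * d))
  write_fasta(pp$a, file.path(out, paste0(tag, "_a.fa")))
  write_fasta(pp$b, file.path(out, paste0(tag, "_b.fa")))
  data.frame(pair = tag, nominal_d = d,
             true_identity = pp$truth$true_identity)
}))
write.table(truth, file.path(out, "genome_pair_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

message("simulating 3-species marker alignments ...")
sim <- simulate_species_markers(species_sim_spec(
  3, tips_per_species = 5, between_depth = 0.5, within_theta = 0.5,
  marker_lengths = c(600L, 900L, 1200L), seed = seed))
for (m in sim$markers) {
  write_fasta(genome_record(m$marker_name, m$rows),
              file.path(out, paste0(m$marker_name, ".fa")))
}
write_newick(sim$true_tree, file.path(out, "true_genealogy.nwk"))
write_partition(sim$true_partition,
                file.path(out, "true_partition.tsv"))

message("simulating a delimitation test tree ...")
dl <- simulate_delimitation_tree(3, tips_per_species = 5, seed = seed)
write_newick(dl$tree, file.path(out, "delimitation_tree.nwk"))

message("simulating a variant table ...")
vt <- simulate_variant_table(
  500, indel_len_sampler = function(m) 1L + stats::rgeom(m, 1 / 20),
  seed = seed)
lines <- vapply(vt$variants, function(v)
  paste(v$chrom, v$pos, v$ref, v$alt, v$info, sep = "\t"), character(1))
writeLines(c("#CHROM\tPOS\tREF\tALT\tINFO", lines),
           file.path(out, "variants.tsv"))
write.table(vt$truth, file.path(out, "variants_truth.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

message("stage 1 complete; inputs under ", out)
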