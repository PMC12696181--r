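#!/usr/bin/env Rscript
# Stage 6: phenotype statistics — colony growth rates from diameter time
# series and PIRG (percentage inhibition of radial growth) comparisons
# across antagonists with one-way ANOVA + Tukey HSD. The input values
# reproduce the geometry of the reported dual-culture assays (9 cm PDA
# plates, pathogen radius measured alone and against each antagonist).

suppressPackageStartupMessages(library(phylodelim))
out <- "results/06_phenotype"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
set.seed(20260922)

## growth rates at three temperatures (diameter cm vs hours)
times <- c(0, 24, 48, 72, 96, 120)
series <- list(
  `18C` = 0.5 + 0.067 * times,
  `25C` = pmin(0.5 + 0.117 * times, 9),
  `28C` = pmin(0.5 + 0.113 * times, 9)
)
rates <- vapply(series, function(dia) {
  keep <- dia < 9           # plate edge censors later points
  growth_rate(times[keep], dia[keep])
}, numeric(1))
print(round(rates, 3))
write.table(data.frame(temperature = names(rates),
                       rate_cm_per_h = rates),
            file.path(out, "growth_rates.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

## PIRG for dual-culture assays: three replicate radii per antagonist
r1 <- 4.0    # pathogen alone reaches ~4 cm radius
groups <- list(
  BMH_0061     = pirg(r1, c(0.45, 0.55, 0.50)),
  T_virens     = pirg(r1, c(0.15, 0.25, 0.20)),
  T_asperellum = pirg(r1, c(1.25, 1.40, 1.30)),
  T_reesei     = pirg(r1, c(2.40, 2.55, 2.50))
)
print(lapply(groups, round, 1))
cmp <- compare_pirg_groups(groups)
cat(sprintf("ANOVA: F = %.2f, p = %.3g\n", cmp$anova_f, cmp$anova_p))
print(cmp$tukey, digits = 3)
write.table(cmp$tukey, file.path(out, "pirg_tukey.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(data.frame(antagonist = names(cmp$group_means),
                       mean_pirg = cmp$group_means),
            file.path(out, "pirg_means.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
message("stage 6 complete; outputs under ", out)
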