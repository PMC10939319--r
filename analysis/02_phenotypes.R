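#!/usr/bin/env Rscript
# Family-level sex-reversal statistics: male ratios and survival per arm,
# inversion rate (IR) and relative survival rate (RSR) per family, exact
# Fisher and binomial tests, population summaries with group letters, and
# the Spearman correlation between RSR and IR.

library(thermosex)

out <- "results/phenotypes"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

batches <- read_phenotypes("results/data/phenotypes.csv")
pairs <- family_pairs(batches)
write_tsv(pairs, file.path(out, "family_pairs.tsv"))

summ <- summarize_population(pairs, batches)
write_tsv(summ$summary, file.path(out, "population_summary.tsv"))
write_tsv(summ$ir_rsr, file.path(out, "population_ir_rsr.tsv"))

rs <- spearman_correlation(pairs$rsr, pairs$ir)
write_tsv(data.frame(statistic = "spearman_rsr_vs_ir",
                     rho = rs$rho, p = rs$p, n = rs$n, method = rs$method),
          file.path(out, "rsr_ir_correlation.tsv"))

cat(sprintf("%d families; IR range %.1f..%.1f%%, mean %.1f%%\n",
            nrow(pairs), min(pairs$ir), max(pairs$ir), mean(pairs$ir)))
cat(sprintf("families with a significant treated/control sex-ratio shift (Fisher p<=0.05): %d\n",
            sum(pairs$fisher_p <= 0.05)))
cat(sprintf("RSR vs IR Spearman rho = %.2f (p = %.3f, %s)\n",
            rs$rho, rs$p, rs$method))
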