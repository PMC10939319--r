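#!/usr/bin/env Rscript
# Per-stratum differential expression between treated (Ltherm) and
# control libraries: CPM normalization, mean-variance precision weights,
# family-paired linear model, empirical-Bayes moderated t.

library(thermosex)

out <- "results/diffexp"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sheet <- read_sample_sheet("results/data/sample_sheet.csv")
counts <- read_counts("results/data/gene_counts.tsv", "gene", sheet)

strata <- unique(sheet[, c("tissue", "stage_dpf")])
for (i in seq_len(nrow(strata))) {
  tis <- strata$tissue[i]; stg <- strata$stage_dpf[i]
  ss <- sheet[sheet$tissue == tis & sheet$stage_dpf == stg, ]
  de <- de_stratum(counts[, ss$sample_id], ss)
  tag <- sprintf("%s_%ddpf", tis, stg)
  write_tsv(de, file.path(out, paste0("de_", tag, ".tsv")))
  cat(sprintf("%s: %d genes tested (%d filtered), %d up, %d down (BH p<=0.05)\n",
              tag, nrow(de), attr(de, "n_filtered"),
              sum(de$direction == "up"), sum(de$direction == "down")))
}
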