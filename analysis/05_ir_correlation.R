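#!/usr/bin/env Rscript
# IR-correlation screen: per-family log2(Ltherm/Control) fold changes per
# stratum, correlated per gene against the family reversal-rate trait.

library(thermosex)

out <- "results/ir_correlation"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sheet <- read_sample_sheet("results/data/sample_sheet.csv")
counts <- read_counts("results/data/gene_counts.tsv", "gene", sheet)
trait <- unlist(jsonlite::read_json("results/data/truth.json")$trait)

strata <- unique(sheet[, c("tissue", "stage_dpf")])
for (i in seq_len(nrow(strata))) {
  tis <- strata$tissue[i]; stg <- strata$stage_dpf[i]
  ss <- sheet[sheet$tissue == tis & sheet$stage_dpf == stg, ]
  cs <- counts[, ss$sample_id]
  lc <- cpm(cs[filter_expressed(cs), ], log = TRUE)
  fcm <- family_fold_changes(lc, ss)
  res <- trait_correlation(fcm, trait)
  tag <- sprintf("%s_%ddpf", tis, stg)
  write_tsv(res, file.path(out, paste0("corr_", tag, ".tsv")))
  write_tsv(data.frame(gene = rownames(fcm), fcm, check.names = FALSE),
            file.path(out, paste0("fold_changes_", tag, ".tsv")))
  cat(sprintf("%s: %d genes screened, %d +Corr, %d -Corr (raw p<=0.05)\n",
              tag, nrow(res), sum(res$sign == "+"), sum(res$sign == "-")))
}
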