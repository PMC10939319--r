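#!/usr/bin/env Rscript
# Evidence integration and set enrichment: per-gene DEG/DSG/Corr status
# strings, Venn partitions per stratum, curated-gene cross-referencing,
# majority-vote identifier resolution, and hypergeometric
# over-representation of the five reporting categories.

library(thermosex)

out <- "results/integration"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sheet <- read_sample_sheet("results/data/sample_sheet.csv")
gmt <- read_gmt("results/data/gene_sets.gmt")
mapping <- read_mapping("results/data/id_mapping.tsv")

resolved <- resolve_ids(mapping)
cat(sprintf("identifier resolution: %d of %d ids kept after majority vote\n",
            length(resolved), length(unique(mapping$from_id))))

strata <- unique(sheet[, c("tissue", "stage_dpf")])
for (i in seq_len(nrow(strata))) {
  tag <- sprintf("%s_%ddpf", strata$tissue[i], strata$stage_dpf[i])
  de <- utils::read.delim(sprintf("results/diffexp/de_%s.tsv", tag))
  ds <- utils::read.delim(sprintf("results/splicing/ds_%s.tsv", tag))
  corr <- utils::read.delim(sprintf("results/ir_correlation/corr_%s.tsv", tag))
  ev <- evidence_table(de, ds, corr)
  write_tsv(ev, file.path(out, paste0("evidence_", tag, ".tsv")))

  v <- venn_counts(ev$gene[ev$deg_direction != "none"], ev$gene[ev$dsg],
                   ev$gene[ev$corr_sign != "none"])
  jsonlite::write_json(v, file.path(out, paste0("venn_", tag, ".json")),
                       auto_unbox = TRUE)
  cat(sprintf("%s: |DEG|=%d |DSG|=%d |Corr|=%d, union %d, all-three %d\n",
              tag, v$n_deg, v$n_dsg, v$n_corr, v$union_size, v$all_three))

  both <- filter_by_status(ev, function(e)
    e$deg_direction != "none" && e$corr_sign != "none")
  cat(sprintf("  DEG-and-Corr genes: %d%s\n", length(both),
              if (length(both)) paste0(" (top: ",
                                       paste(utils::head(both, 3),
                                             collapse = ", "), ")") else ""))

  enr <- run_categorized(ev, gmt$gene_sets, term_names = gmt$term_names)
  if (length(enr)) {
    tab <- do.call(rbind, enr)
    write_tsv(tab, file.path(out, paste0("enrichment_", tag, ".tsv")))
    top <- tab[which.min(tab$p), ]
    cat(sprintf("  top enrichment: %s in %s (k=%d/%d, p=%.2g)\n",
                top$term, top$category, top$k, top$K, top$p))
  }
}
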