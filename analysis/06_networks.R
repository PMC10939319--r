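#!/usr/bin/env Rscript
# Co-expression networks over the fold-change profiles: unsigned
# soft-threshold adjacency (|cor|^6) and 20-node networks (seed + the 19
# strongest partners) around seed genes. On simulated ids the seeds are
# the strongest planted IR-linked genes per stratum, standing in for the
# curated gonad/brain seed panel used on real data.

library(thermosex)

out <- "results/networks"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sheet <- read_sample_sheet("results/data/sample_sheet.csv")
counts <- read_counts("results/data/gene_counts.tsv", "gene", sheet)
truth <- jsonlite::read_json("results/data/truth.json")
trait <- unlist(truth$trait)

strata <- unique(sheet[, c("tissue", "stage_dpf")])
for (i in seq_len(nrow(strata))) {
  tis <- strata$tissue[i]; stg <- strata$stage_dpf[i]
  tag <- sprintf("%s_%ddpf", tis, stg)
  ss <- sheet[sheet$tissue == tis & sheet$stage_dpf == stg, ]
  cs <- counts[, ss$sample_id]
  lc <- cpm(cs[filter_expressed(cs), ], log = TRUE)
  fcm <- family_fold_changes(lc, ss)
  adj <- adjacency_matrix(fcm, beta = 6)

  de <- utils::read.delim(sprintf("results/diffexp/de_%s.tsv", tag))
  corr <- utils::read.delim(sprintf("results/ir_correlation/corr_%s.tsv", tag))
  ev <- evidence_table(de, NULL, corr)

  seeds <- intersect(names(truth$ir_linked_genes), rownames(adj))[1:2]
  seeds <- seeds[!is.na(seeds)]
  for (sg in seeds) {
    net <- seed_network(adj, sg, k = 19, evidence = ev)
    write_network(net, file.path(out, sprintf("net_%s_%s.graphml", tag, sg)),
                  "graphml")
    cat(sprintf("%s seed %s: %d nodes, %d edges, strongest partner weight %.3f\n",
                tag, sg, igraph::vcount(net), igraph::ecount(net),
                max(igraph::E(net)$weight)))
  }
}
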