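#!/usr/bin/env Rscript
# Generate the synthetic study dataset: 6 full-sib families, each split
# into a 30 degC control and a 36.5 degC treated batch; gene- and
# exon-level RNA-seq counts for 48 libraries (2 tissues x 2 stages), with
# planted differential-expression, IR-linked and splicing effects; plus
# the family-level phenotype records and a synthetic gene-set annotation.

library(thermosex)

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 1L)   # defaults emulate the 6-family design
ph <- simulate_phenotypes(cfg)
sim <- simulate_counts(cfg)
ann <- simulate_annotation(cfg$n_genes, n_terms = 50, sources = 3,
                           conflict_frac = 0.1, seed = cfg$seed)

write_phenotypes(ph$batches, file.path(out, "phenotypes.csv"))
write_sample_sheet(sim$sample_sheet, file.path(out, "sample_sheet.csv"))
write_counts(sim$gene_counts, file.path(out, "gene_counts.tsv"), "gene")
write_counts(sim$exon_counts, file.path(out, "exon_counts.tsv"), "exon")
write_gmt(ann$gene_sets, file.path(out, "gene_sets.gmt"),
          setNames(ann$terms$term_name, ann$terms$term_id))
write_mapping(ann$mapping, file.path(out, "id_mapping.tsv"))
jsonlite::write_json(
  list(de_genes = as.list(sim$truth$de_genes),
       ir_linked_genes = as.list(sim$truth$ir_linked_genes),
       ds_genes = sim$truth$ds_genes,
       trait = as.list(setNames(cfg$ir_values,
                                unique(sim$sample_sheet$family)))),
  file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d genes x %d libraries (%d families), %d phenotype batches\n",
            nrow(sim$gene_counts), ncol(sim$gene_counts),
            cfg$n_families, nrow(ph$batches)))
cat(sprintf("planted: %d DE, %d IR-linked, %d spliced genes\n",
            length(sim$truth$de_genes), length(sim$truth$ir_linked_genes),
            length(sim$truth$ds_genes)))
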