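# thermosex

Statistics and transcriptome screens for temperature-induced sex reversal
in Nile tilapia (*Oreochromis niloticus*).

High temperature (36.5 °C) applied during the thermosensitive larval
window (10–30 dpf) masculinizes a fraction of XX females into neo-males.
Experiments that probe this effect split each full-sib family into a
control and a heat-treated ("Ltherm") batch, score survival and sex
ratios, and sequence paired treated/control gonad and brain transcriptomes
at 15 and 40 dpf — one library per condition, so every inference must run
through family pairing. This package implements that analysis chain for
geneticists and aquaculture researchers working with such designs:

* **Phenotype statistics** — per-family male ratios and survival, the
  inversion rate `IR = 100·(SR_t − SR_c)/(1 − SR_c)` and its survival
  analogue RSR, exact Fisher and binomial tests, Spearman correlations
  (exact permutation null for n ≤ 7), logistic-regression group
  comparisons with compact letter displays.
* **Differential expression** — CPM normalization with proportional prior
  counts, mean–variance precision weights, family-paired linear models,
  empirical-Bayes moderated t (scaled-F moment matching with trigamma
  inversion), BH-controlled DEG calls.
* **Differential splicing** — per-exon treatment fold changes expressed
  as deviations from the gene's other exons, moderated tests, Simes
  aggregation to gene-level p, FDR ≤ 0.05 DSG calls.
* **IR-correlation screen** — per-family log2(Ltherm/Control) fold
  changes correlated per gene against the family reversal rate.
* **Co-expression networks** — unsigned soft-threshold adjacency
  (|cor|^6) over fold-change profiles, 20-node networks (seed + 19
  strongest partners) around seed genes, GraphML/edge-list export.
* **Evidence integration & enrichment** — ↑Exp/↓Exp/±Corr/DSG status
  strings, three-set Venn partitions, curated-gene cross-referencing,
  majority-vote identifier resolution, ortholog-augmented annotation,
  hypergeometric over-representation.
* **Synthetic data** — a generator that emulates the 6-family ×
  2-treatment × 2-tissue × 2-stage design (family reversal rates 18, 34,
  73, 26, 100, 12 %) with planted DE, IR-linked and splicing effects and
  full ground truth, used by the parameter-recovery tests.

## Worked example

The numbered scripts under `analysis/` run the whole chain on the
simulated study design and narrate what they find:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_phenotypes.R
Rscript analysis/03_diffexp.R
```

```
simulated 2000 genes x 48 libraries (6 families), 12 phenotype batches
planted: 100 DE, 100 IR-linked, 100 spliced genes

6 families; IR range 38.6..51.3%, mean 44.1%
families with a significant treated/control sex-ratio shift (Fisher p<=0.05): 6
RSR vs IR Spearman rho = 0.60 (p = 0.242, exact permutation)

gonad_40dpf: 2000 genes tested (0 filtered), 183 up, 152 down (BH p<=0.05)
```

The simulated reversal probability is 0.44, so per-family IR estimates
cluster around 44%; the ~335 DEG calls in the 40 dpf gonads comprise the
100 planted treatment-shifted genes plus genes carrying the planted
IR-linked and exon-level effects, which are genuine expression shifts too.
Scripts `04`–`07` add splicing, the IR-correlation screen, seed networks
(20 nodes each) and integration/enrichment, e.g.:

```
gonad_40dpf: |DEG|=335 |DSG|=102 |Corr|=195, union 454, all-three 4
  DEG-and-Corr genes: 80 (top: G00647, G01320, G01846)
```

Equivalently, one call runs everything: see `?run_pipeline`.

In an interactive session the individual statistics are direct:

```r
library(thermosex)
inversion_rate(1.00, 0.50)        # 100  — an all-male treated batch
inversion_rate(0.88, 0.65)        # 65.7 — partial reversal
fisher_exact_2x2(81, 9, 40, 40)   # treated vs control sex ratio
spearman_correlation(c(18, 34, 73, 26), c(55, 30, -10, 40))$rho
```

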