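---
title: "Methods: temperature-induced sex reversal statistics and transcriptome screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temperature-induced sex reversal statistics and transcriptome screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The experimental system

Nile tilapia (*Oreochromis niloticus*) has genotypic sex determination
(XX/XY) that can be overridden by temperature: exposing XX larvae to high
water temperature (36.5 °C) during the thermosensitive window (10–30 days
post-fertilization, dpf) masculinizes a fraction of genetic females into
functional "neo-males". The design this package analyses splits each
full-sib family into a control batch reared at 30 °C and a treated
("Ltherm") batch reared at 36.5 °C, records survival at 31 dpf and the sex
ratio at 90 dpf, and profiles the transcriptome of gonads and brains at 15
and 40 dpf in paired treated/control libraries — one library per
family × treatment × tissue × stage, with no within-condition replicates.

`thermosex` implements the full inference chain on such data: phenotype
statistics, differential expression, exon-level splicing, a fold-change
versus reversal-rate correlation screen, co-expression networks, evidence
integration, and set enrichment, plus a synthetic-data module that
emulates the design with planted ground truth.

## Phenotype statistics

The masculinization effect in a family is summarized by the inversion
rate, the estimated fraction of presumptive females that were reversed:

$$IR = 100\,\frac{SR_t - SR_c}{1 - SR_c},$$

where $SR_t$ and $SR_c$ are the male proportions of the treated and
control batch. The relative survival rate (RSR) applies the same
normalized difference to the 31-dpf survival proportions. Both are
undefined when the control proportion is 1 (an all-male control leaves no
presumptive females to reverse) and may legitimately be negative; negative
values are reported, not clamped.

Supporting tests follow the conventions of the statistical environment
the field uses (R): the two-sided Fisher exact and binomial p-values sum
the probabilities of outcomes no more probable than the observed one, and
quartiles use type-7 linear interpolation. `spearman_correlation()`
mid-ranks ties and enumerates all permutations for $n \le 7$ (exact null),
switching to the $t$ approximation above that; the rank correlation of a
4-family panel is thus exact. Population-level male-rate comparisons use a
binomial-logit model per pair of groups with likelihood-ratio tests,
Benjamini–Hochberg adjustment, and an insert-and-absorb compact letter
display; complete separation (a group at 0 or 1) triggers an exact-Fisher
fallback for that pair, recorded in the output. The post-hoc adjustment
(BH) and the pairwise-model structure were design choices: the source
experiment reports group letters without naming its procedure, and the
letter display here is defined by the invariant that two groups share a
letter exactly when their adjusted p exceeds the significance level.

## Normalization and differential expression

Counts are normalized to counts per million (CPM). For log2-CPM a prior
count (default 0.5) is added, scaled proportionally to each library's
size, with the library size inflated by twice the scaled prior, keeping
zero counts finite and fold-change estimates shrunk at low counts.

With one library per family and arm, treatment effects are estimable only
through family pairing: each tissue × stage stratum (12 libraries for 6
families) is fitted with an intercept + family-blocks + treatment linear
model (5 residual degrees of freedom). Because count noise is strongly
mean-dependent, per-observation precision weights are estimated from the
data: the square root of each gene's residual standard deviation is
regressed on its mean log2 count with lowess (span 0.5), the trend is
evaluated at each observation's fitted log2 count, and the weight is the
inverse fourth power of the prediction. Below 50 genes the trend is
considered unstable and unit weights are used with a warning.

Variance moderation follows the empirical-Bayes scaled-F model: the first
two moments of $\log s_g^2$ are matched by digamma/trigamma inversion to
obtain a prior variance $s_0^2$ with prior degrees of freedom $d_0$
(Newton iteration for the trigamma inverse; $d_0$ is capped at $10^6$ and
treated as fully pooled when the inversion indicates no excess
dispersion), and each gene's posterior variance is the convex combination
$(d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$. The moderated
$t = \hat\beta/(\mathrm{se}_u \tilde s_g)$ has $d_0 + d_g$ degrees of
freedom. DEGs are called at BH-adjusted $p \le 0.05$ by default; the raw-p
variant is available via `use_adjusted = FALSE`, because headline DEG
counts in this literature are sometimes quoted on raw p while volcano
plots show adjusted p.

A low-expression filter (CPM ≥ 1 in at least half of the stratum's
libraries) precedes modelling; with no filter stated in the source
protocols, this common default guards the variance trend against
all-zero rows and is configurable.

## Differential splicing

Exon-level counts are fitted with the same weighted, moderated model.
Each exon's treatment log2 fold change is then re-expressed as its
deviation from the mean fold change of the gene's other exons, so a shift
common to the whole gene cancels exactly — the statistic responds only to
relative exon usage. The deviation is tested with a moderated $t$ (its
variance combines the exon's own moderated variance with that of the
other-exon mean), exon p-values are aggregated per gene with Simes' rule
($\min_i p_{(i)} m / i$), and gene-level p-values are BH-adjusted with a
DSG call at FDR ≤ 0.05. Per-exon testing with Simes aggregation was
chosen over a gene-level F-test because it both localizes the affected
exon (reported as `best_exon`) and matches the "at least one exon"
phrasing of the question; single-exon genes are skipped and counted.

## The IR-correlation screen

For each stratum, a fold-change matrix holds each gene's per-family
log2(Ltherm/Control) ratio, computed as the difference of prior-counted
log2-CPM values (finiteness at zero counts; families missing an arm are
dropped and logged). Each gene's profile is correlated against the family
reversal rates with the Pearson coefficient — at $n = 6$ families rank
correlation is nearly degenerate, and the correlation machinery this
screen descends from is Pearson-based — with the two-sided p from
$t = r\sqrt{(n-2)/(1-r^2)}$. A gene is `+Corr`/`-Corr` at raw
$p \le 0.05$; no FDR is applied by default, matching the large Corr list
sizes typical of this screen relative to DEG lists, and the threshold is
configurable. Zero-variance profiles are reported as undefined rather
than silently dropped.

## Co-expression networks

The same fold-change profiles feed an unsigned soft-threshold adjacency
$a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$ with $\beta = 6$ (the standard
unsigned default; the power is configurable and recorded). Unsigned is
deliberate: co-regulation in opposite directions counts as co-expression.
Around each seed gene the $k = 19$ strongest partners (ties broken
lexicographically by gene id, making results independent of row order)
form a 20-node network; partner–partner edges are included above an
adjacency floor of 0.1 to convey neighborhood structure. Raw adjacency,
not topological overlap, defines "degree of co-expression"; module
detection and eigengenes are out of scope. On real data the default seed
panel is the ten sex-differentiation genes of interest (*amh*, *cyp11c1*,
*cyp19a1a*, *cyp19a1b*, *dmrt1*, *hsd11b1la*, *hsd11b1lac(2)*, *dax1*,
*sf1*, *hsd11b2*, see `default_seed_genes()`).

## Evidence integration and enrichment

Per gene and stratum, the DEG direction, DSG flag and Corr sign are
joined into a status string using the field's compact notation — `↑Exp`
/ `↓Exp` for significant regulation, `↑exp` / `↓exp` for a
non-significant fold-change direction, `+Corr` / `-Corr`, `DSG` — with a
round-trippable parser. Venn partitions report both conventions
(inclusive list sizes and the seven exclusive regions) because published
counts in this area mix the two. A curated panel of sex-differentiation
genes (`curated_sex_genes()`) is cross-referenced through a synonym map;
ambiguous resolution is an error, not a guess.

Enrichment uses the upper-tail hypergeometric test per term with BH
adjustment, term-size bounds [5, 500], and — since the source protocol is
silent — the universe is all genes entering the stratum's analysis
(post-filter), the standard guard against detection bias. Identifier
resolution across annotation sources keeps, per identifier, the
association referenced by the most sources; ties are dropped with a
warning so the result is a function. Ortholog-based augmentation unions a
gene's native terms with those of its (better-annotated) ortholog.

## The synthetic-data generator

`sim_config()` encodes the study conditions: 6 families with reversal
rates (18, 34, 73, 26, 100, 12) %, two arms per family, 48 libraries
(2 tissues × 2 stages), balanced control sex ratio (0.5), reversal
probability 0.44 (the mean reversal rate of the profiled families),
survival 0.8 (control) vs 0.9 (treated), 200 fish per batch (within the
19–319 sexed-fish range of the source design). Counts are negative
binomial (Var $= \mu + \phi\mu^2$, $\phi = 0.1$, a typical bulk RNA-seq
dispersion) around log-normal baselines; library sizes target 2 × 10⁶
reads — far below real sequencing depth, chosen so the full test suite
runs at desk scale while keeping per-gene counts in a realistic regime.
Exon counts are generated first and gene counts are their sums, so the
gene/exon consistency the splicing test assumes holds by construction.
Planted effects are disjoint gene classes: a ±2 log2 treatment shift (5%
of genes), an IR-proportional shift of ±0.02 log2 per IR percent (5%),
and a +3 log2 single-exon shift (5%). Each output table draws from its
own RNG stream split from the master seed, so enlarging the count matrix
never perturbs the phenotype simulation.

The generator emulates the statistical skeleton of the design, not its
biology: no GC or length bias, no batch effects beyond family, no
read-level artifacts, no correlation structure among null genes, and
effects identical across tissues and stages. Passing recovery tests
therefore demonstrates that the inference chain detects what it is built
to detect under its own model — not pipeline performance on real
sequencing data.

## Numerical choices and known limitations

* Prior count 0.5, lowess span 0.5, minimum 50 genes for the trend,
  $d_0$ cap $10^6$, BH everywhere a family-wise list is thresholded.
* Network ties are lexicographic; letter-display sets are ordered by
  first group for stable output.
* CPM-only normalization (no TMM-style composition correction) follows
  the source protocol, but has a measurable cost: planting asymmetric
  effects inflates treated library sizes, shifting null genes' apparent
  fold changes slightly; in the recovery simulations the realized
  false-discovery proportion at BH 0.05 averages just under 0.10 rather
  than the nominal 0.05. This is a property of the normalization choice,
  not of the moderation.
* The per-family batch records behind the published population
  correlation table are not redistributable here; the functions that
  recompute those correlations are implemented and tested on synthetic
  pairs, and the corresponding acceptance check activates when a
  transcription is placed at
  `inst/extdata/family_phenotypes_observed.csv`.
* Test and acceptance problem sizes — 2000 genes for calibration and DE
  recovery, 300–400 genes for splicing and correlation recovery, five
  seeds per recovery average — were chosen as the smallest scales at
  which the binomial/continuous acceptance margins are stable.

## Reproducing the analysis

The numbered scripts under `analysis/` run the chain end to end on the
simulated study design (`01_simulate.R` … `07_integration_enrichment.R`),
writing tables under `results/`. The same computations are available as a
single call:

```{r}
library(thermosex)
report <- run_pipeline(run_config(out_dir = "results/run",
                                  sim = sim_config(seed = 1)))
```
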