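---
title: "Purity-aware comparison of cell-line and tumour transcriptomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-aware comparison of cell-line and tumour transcriptomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linefidelity)
```

## The problem

Cancer cell lines are the workhorse model of tumour biology, but a bulk
tumour is not a bag of cancer cells: a substantial fraction of its RNA comes
from stromal (fibroblast, endothelial) and immune cells that are absent from
monoculture. A naive differential-expression comparison of cell lines against
tumours therefore conflates two very different phenomena: genes that change
because the cells adapt to culture, and genes that merely mark the
non-malignant compartments that culture lacks. This package implements a
comparison workflow that separates the two, and a synthetic admixture cohort
with known ground truth on which every stage of the workflow can be
validated.

## The admixture model behind the synthetic cohort

`generate_cohort()` draws, per gene, a baseline linear abundance
$2^{z_g}$ with $z_g \sim \mathcal{N}(5, 2^2)$ on the log2 scale, and
partitions the genes into disjoint mechanism blocks: stromal markers, immune
markers, culture-up, culture-down, subtype markers, and null genes. Three
component profiles are built from the baseline:

* the **malignant profile** $M_s$ (one per subtype, default luminal and
  basal): stromal/immune markers attenuated by the corresponding effect
  fold; subtype markers elevated in their own subtype;
* the **stromal profile** $S$ and **immune profile** $I$: their own markers
  elevated by the effect fold.

A tumour with malignant fraction $f_{mal}$ (drawn from a Beta distribution,
default $\mathrm{Beta}(5, 2)$, so purity varies realistically across the
cohort) has linear expression

$$x = f_{mal}\,M_s + f_{str}\,S + f_{imm}\,I,$$

with the non-malignant mass split between stroma and immune cells around a
configurable mean (default 50/50, jittered per tumour). A cell line is the
pure malignant profile of its subtype with culture-up genes multiplied and
culture-down genes divided by the culture fold change. Gaussian noise of
standard deviation `noise_sd` is added on the log2 scale (multiplicative
log-normal noise, matching the log-scale analyses downstream), and every
column is renormalised to TPM.

Two modelling choices deserve emphasis because the whole analysis depends on
them:

1. **Marker blocks are compartment-specific.** Stromal and immune markers
   are elevated in their compartment's profile *and* attenuated in the
   malignant profile. This is what real signature genes look like — a
   collagen gene is a fibroblast product, near-absent in a pure cancer-cell
   culture — and it is what makes compartment loss visible as
   high-in-tumour/low-in-cell-line genes. If the malignant profile expressed
   markers at baseline, mixture dilution would cap the observable difference
   at roughly the mean non-malignant fraction and culture effects would
   dominate every ranking, which is not how purity artifacts behave in real
   cohorts.
2. **Components are mass-balanced.** Marker baselines are drawn effect-fold
   lower than the global baseline (so the elevated, in-compartment level
   sits at a typical expression level), and each component profile is
   normalised to TPM before mixing, so a component contributes reads in
   proportion to its cell fraction. Without this, the elevated markers carry
   a large share of the stromal/immune component's transcriptome mass and
   purity variation drags *every* gene into strong anticorrelation with the
   stromal score — a compositional artifact that would make a
   purity-correlation filter remove essentially the whole transcriptome.
   With mass balancing, only a mild compositional residue remains (null
   genes sit at small negative correlations), which we consider realistic:
   TPM is a relative measure and some compositional leakage is a genuine
   property of bulk RNA-seq.

The generator's defaults are the standard study cohort used by the tests and
the acceptance script: 200 tumours, 50 cell lines, 2000 genes, 10% stromal
and 10% immune markers at 8-fold, 5% culture-up and 5% culture-down genes at
4-fold, 10% subtype markers at 4-fold, `noise_sd = 0.3`. Subtype composition
follows the asymmetry of real breast-cancer panels (about a quarter of
tumours basal/ER− versus more than half of cell lines). The purity Beta
shape parameters are stand-ins chosen to give a mean malignant fraction
around 0.7 with wide spread; no published per-cohort purity distribution is
encoded.

## Expression harmonisation

Real inputs arrive on different scales; everything is brought to
log2(TPM + 1):

* `fpkm_to_tpm()` — FPKM is already length-normalised, so TPM is the
  within-sample renormalisation $x_g / \sum_h x_h \times 10^6$;
* `scaled_estimate_to_tpm()` — RSEM scaled estimates sum to 1 per sample, so
  TPM is $x \times 10^6$ (a strictness flag downgrades the sum check to a
  warning for files with rounding drift);
* `log_transform()` — $\log_2(x + 1)$, so zeros map to zero;
* `merge_datasets()` — exact-identifier intersection of gene sets in
  lexicographic order, samples concatenated. Duplicate gene ids are rejected
  rather than resolved: no alias table is bundled and determinism matters
  more than coverage here.

## Stromal and immune scoring

`ssgsea_score()` is a single-sample, rank-based running-sum statistic. All
genes in a sample are ranked by descending abundance with average ranks for
ties; walking the ranked list, signature genes add weight proportional to
their descending-rank weight raised to `exponent` (normalised to sum to 1)
and background genes add $1/(G - m)$; the score integrates the gap between
the two cumulative distributions. Only ranks enter, so the score is
invariant under any strictly increasing transform — computing on
log2(TPM + 1) rather than TPM is cosmetic. The exponent defaults to 0.25,
the customary choice for this family of scores; it is configurable and the
tests exercise 0, 0.25 and 1. Tied genes are walked in gene-id order so the
result is independent of input permutation.

`estimate_scores()` applies the score per tumour for a stromal and an immune
signature; the composite (stromal + immune) serves as the purity proxy, with
*negated* composite standing in for purity itself (more non-malignant signal
means less purity). No calibration to an absolute purity fraction is
attempted — the fitting constants such a transform needs are cohort-specific
and not part of this package's scope. `gene_purity_correlation()` then
computes each gene's Pearson correlation with the stromal score, the immune
score and the negated composite; zero-variance genes are flagged undefined
rather than coerced to zero.

## Global structure and cell-line ranking

`select_top_variance_genes()` ranks genes by variance on the log scale
across all samples (cell lines and tumours combined — the scale is a choice;
log is used because every downstream analysis is log-based), breaking ties
lexicographically. `run_pca()` centres features without unit-variance
scaling — the usual expression-PCA convention, which keeps the dominant
purity and subtype axes interpretable — and fixes each component's sign so
its largest-magnitude loading is positive, making scores reproducible.
`correlation_cluster()` uses $1 - r$ as the sample distance with the
Ward variant that squares dissimilarities (`ward.D2`); distances lie in
$[0, 2]$ and merge heights are nondecreasing. Dendrograms export to Newick.

`rank_cell_lines()` computes, per cell line, the mean Pearson correlation
with all tumours of its comparison subtype over the selected genes, ranking
within subtype. Claudin-low lines are compared against basal tumours, since
that subtype is poorly represented among tumours. `average_cell_line()`
builds the fictional average line of a subtype — the per-gene mean over its
lines — and scores it identically; with enough lines, noise averaging makes
this synthetic profile outrank every individual line, an argument for
multi-line panel designs.

## Differential expression and the purity filter

`welch_t_per_gene()` computes, per gene, the two-sample Welch $t$ (cell line
minus tumour) with Welch–Satterthwaite degrees of freedom and two-sided
p-values, vectorised over genes. Degenerate genes (zero variance in both
groups) get $t = 0,\ p = 1$ at equal means and an infinite statistic with
$p = 0$ otherwise. `bh_adjust()` applies Benjamini–Hochberg step-up
correction. `top_fraction()` selects the `ceiling(fraction × n)` most
significant genes (ties: smaller p, then larger $|t|$, then gene id); at the
conventional 1% this yields 163 genes from a 16,282-gene table.

`purity_filter()` removes genes whose absolute stromal *or* immune
correlation exceeds `tau` (default 0.2) and reranks the survivors; the
filtered ranking is by construction a subsequence of the unfiltered one. The
filter is applied to the full table before top-fraction selection — a new
ranked list, not a pruned old one. Genes with undefined correlations are
retained but flagged: absence of evidence of stromal association is not
evidence of it. The separate reporting threshold (`report_r = 0.5`,
`highly_stromal` flag) marks genes strongly explained by compartment loss
but plays no role in filtering.

## Gene-set enrichment and purity attribution

`gage_test()` reports per set the arithmetic mean of member Welch $t$
statistics and tests it with a two-sided two-sample Welch test of member
statistics against all non-member statistics, BH-corrected across sets. Sets
with fewer than 2 or with 200 or more present members are excluded
(strictly "fewer than 200"). This is a deliberate simplification of the
full per-sample-pair formulation with Stouffer combination used by the
generally-applicable enrichment tradition: the quantity reported downstream
is exactly the mean $t$ statistic, which this construction yields directly.
One consequence is honesty about sensitivity: with thousands of genes, the
background comparison is powerful enough that even mild compositional
shifts reach small q-values, so the default reporting cutoff is strict
(q < 1e-4) and direction plus attribution, not bare significance, carry the
interpretation.

`essential_genes()` defines a set's essential genes as its individually
significant (member q < 0.05), direction-concordant members — a declared
substitute for the upstream tool's unpublished criterion, and configurable.
`attribute_purity()` averages the essential genes' stromal, immune and
purity-proxy correlations: a strongly down-in-culture set whose essential
genes correlate highly with the stromal score is a compartment-loss
artifact; an up-in-culture set with near-zero attribution reflects the
cultured cells themselves.

## Genomic frequency tests

`binomial_frequency_test()` (mutated lines out of $n$ against a tumour
baseline frequency) and `composition_fisher_test()` (2×2 exact test, e.g.
ER status by sample source) both use exact enumeration with the
minimum-likelihood two-sided rule — the convention of standard statistical
environments, stated here because the two-sided rule is not unique.
`fraction_genome_altered()` is the length-weighted fraction of segments with
$|\log_2 \text{ratio}|$ strictly above 0.2. Tumour baseline frequencies are
inputs, not derived quantities.

## The pipeline and determinism

`run_pipeline()` chains the stages behind one `pipeline_config()` whose
defaults are the workflow's standard parameters (top 5000 variance genes,
top 1% DE, filter at |r| > 0.2, report at r > 0.5, sets with fewer than 200
members, set q cutoff 1e-4, exponent 0.25). One seed governs the entire run:
the pipeline seed overwrites the cohort seed so a single integer reproduces
the bundle. Identical configuration and seed produce byte-identical output
directories, and the JSON manifest records configuration, seed and
stage-by-stage counts — the manifest alone is enough to re-run the pipeline
to identical outputs. On any stage failure the stage name is reported and
partial outputs are removed. The numbered scripts under `analysis/` run the
same computations step by step with narrative output; the genomic tests run
in file mode when mutation or segment tables are supplied (the synthetic
generator does not simulate mutations or copy number).

## What the synthetic cohort does and does not show

The generator reproduces the statistical structure the workflow assumes:
purity-graded mixtures, compartment-specific markers, subtype structure,
culture fold changes, log-normal noise, and TPM compositionality. Passing
the recovery tests therefore shows the *machinery* is sound — scores track
the simulated fractions, the filter separates compartment from culture
genes, ranking recovers subtype identity. It does not show that real
signature gene lists are good markers, that real purity follows the Beta
used here, that 8-fold is the real marker contrast, or that real culture
adaptation is a clean two-block fold change; correlated marker co-expression
within compartments, batch effects between datasets, and claudin-low
biology are all absent. Results on real cohorts depend on those properties
and should be validated against orthogonal purity estimates. Printed
correlation tables from any particular real cohort are likewise not
reproduction targets of the test suite.

## Problem sizes

The tests and the acceptance script use the 2000-gene, 250-sample default
cohort for recovery checks, a 400-gene cohort for the shared unit-test
fixture, and universes of at most 10 genes or 6 samples where results are
checked against exhaustive brute-force oracles (running-sum enumeration,
naive Ward agglomeration, binomial and hypergeometric enumeration). These
sizes were chosen so the whole suite exercises every claim in minutes while
keeping each statistical check far from its decision boundary.
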