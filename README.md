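# linefidelity

Purity-aware comparison of cancer cell-line and tumour transcriptomes.

Bulk tumours are mixtures: malignant cells plus stromal and immune
compartments that cell-line monocultures lack. Any direct differential
comparison of cell lines against tumours therefore mixes two signals —
genuine culture adaptation of the cancer cells, and the simple absence of
non-malignant cell types. `linefidelity` is for computational biologists who
want to make that separation explicit: it scores each tumour for stromal and
immune content with a single-sample rank statistic, correlates every gene
with those scores, filters purity-driven genes out of the differential
ranking, attributes gene-set perturbations to compartment loss versus
culture, and ranks cell lines by transcriptional fidelity to their subtype's
tumours. A synthetic admixture generator with full ground truth makes every
stage testable without any external download.

## The model in brief

* **Admixture cohort.** Tumour expression is
  `x = f_mal * M_s + f_str * S + f_imm * I` on the linear scale, where `M_s`
  is the malignant profile of subtype `s` and `S`, `I` are stromal/immune
  profiles elevated on their compartment-specific marker blocks (and
  attenuated in `M`). `f_mal ~ Beta(α, β)` varies purity across tumours.
  Cell lines are pure `M_s` with multiplicative culture fold changes.
  Log-normal noise, TPM renormalisation, full truth labels per gene and
  sample.
* **Purity scores.** A rank-based running-sum enrichment score per sample
  and signature (exponent 0.25, average ranks for ties); composite =
  stromal + immune, with the negated composite as the purity proxy.
* **Differential expression.** Per-gene Welch *t* (cell line − tumour) with
  Welch–Satterthwaite df, Benjamini–Hochberg q-values, top-1% selection
  (`ceiling`: 163 genes from a 16,282-gene table), and the purity filter
  removing genes with `|r| > 0.2` against either score.
* **Gene sets.** Per set, the mean of member *t* statistics, tested against
  the non-member background (two-sample Welch, BH across sets, sets with
  fewer than 200 members); essential genes = individually significant,
  direction-concordant members; purity attribution = mean essential-gene
  correlations.
* **Structure.** Top-5000-variance gene selection, centred (unscaled) PCA
  with fixed sign convention, Ward.D2 clustering on `1 − r` distances with
  Newick export, and subtype-specific cell-line ranking by mean correlation
  with matched tumours (claudin-low lines compared against basal tumours).
* **Genomics.** Exact binomial tests of mutation frequencies against tumour
  baselines, two-tailed Fisher tests of cohort composition, and fraction of
  genome altered at `|log2 ratio| > 0.2`.

## Worked example

The numbered scripts under `analysis/` run the whole study on the default
synthetic cohort (200 tumours, 50 cell lines, 2000 genes, seed 1):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_purity_scores.R
Rscript analysis/03_global_structure.R
Rscript analysis/04_differential_expression.R
Rscript analysis/05_gene_sets.R
Rscript analysis/06_genomic_tests.R
```

`02_purity_scores.R` prints:

```
tumours scored: 200
r(stromal score, true stromal fraction): 0.978
r(immune score, true immune fraction): 0.978
r(composite score, true malignant fraction): -0.980 (negative: more stroma/immune = less purity)
genes with |stromal r| > 0.2: 507 of 2000
```

i.e. the rank-based scores recover the simulated compartment fractions
almost perfectly, and about a quarter of the transcriptome correlates with
stromal content strongly enough to be filtered. `04_differential_expression.R`
then shows why the filter matters:

```
genes tested: 2000 -> top 1% = 20 genes
fraction stromal/immune-driven: 100%
purity filter (|r| > 0.2) removed 508 genes; 1492 remain
mechanisms in the filtered top list ( 15 genes ):
culture_down
          15
fraction culture-driven: 100%
```

The naive top list is entirely compartment-loss artifact; after filtering,
every surviving top gene is a genuine culture effect. `03_global_structure.R`
reports that PC1 of the tumours tracks the stromal score
(`r = 0.976`), that matched-subtype ranking separates subtypes perfectly
(`AUC = 1.000`), and that the fictional average cell line outranks the best
individual line in both subtypes (e.g. luminal `0.907` vs `0.906`).

The same computations are available behind one call:

```r
library(linefidelity)
cfg <- pipeline_config(cohort = cohort_config(), seed = 1)
res <- run_pipeline(cfg, "results/run1")   # writes tables + manifest.json
```

Two runs with the same config and seed produce byte-identical bundles.

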