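#!/usr/bin/env Rscript
# Simulate the study cohort: 200 tumours as purity-weighted mixtures of
# malignant + stromal + immune profiles, and 50 pure-malignant cell lines
# with culture-adaptation fold changes, with full ground truth.
library(linefidelity)

out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- cohort_config(seed = 1)
co <- generate_cohort(cfg)

write_expression_matrix(co$matrix, file.path(out, "expression_tpm.tsv"))
write_sample_annotations(co$matrix$samples,
                         file.path(out, "sample_annotations.tsv"))
write_truth(co$truth, file.path(out, "truth"))
sigs <- builtin_signatures(co$truth)
write_gmt(list(sigs$stromal, sigs$immune), file.path(out, "signatures.gmt"))
write_gmt(truth_gene_sets(co$truth, seed = 1), file.path(out, "gene_sets.gmt"))

fr <- co$truth$tumour_fractions
cat("cohort:", nrow(co$matrix$values), "genes x", ncol(co$matrix$values),
    "samples\n")
cat("tumour malignant fraction: mean",
    sprintf("%.2f", mean(fr$malignant)), "range",
    sprintf("[%.2f, %.2f]", min(fr$malignant), max(fr$malignant)), "\n")
print(table(mechanism = as.character(co$truth$gene_mechanism)))
cat("written to", out, "\n")
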