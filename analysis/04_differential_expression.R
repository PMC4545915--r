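#!/usr/bin/env Rscript
# Differential expression between cell lines and tumours, before and after
# the purity filter: how much of the naive top list is explained by
# stromal/immune compartment loss, and what survives once those genes are
# removed?
library(linefidelity)

cohort <- "results/cohort"
out <- "results/de"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mat <- read_expression_matrix(file.path(cohort, "expression_tpm.tsv"),
                              scale = "tpm",
                              annotations = file.path(cohort,
                                                      "sample_annotations.tsv"))
purcor <- read.delim("results/purity/gene_purity_correlation.tsv")
truth_genes <- read.delim(file.path(cohort, "truth_genes.tsv"))

lg <- log_transform(mat)
de <- welch_t_per_gene(lg)
de <- annotate_purity(de, purcor, tau = 0.2, report_r = 0.5)
write_de_table(de, file.path(out, "de_table.tsv"))

mech <- setNames(truth_genes$mechanism, truth_genes$gene_id)
top <- top_fraction(de, 0.01)
writeLines(top, file.path(out, "top_de_genes.txt"))
cat("genes tested:", nrow(de), "-> top 1% =", length(top), "genes\n")
cat("mechanisms in the unfiltered top list:\n")
print(table(mech[top]))
cat("fraction stromal/immune-driven:",
    sprintf("%.0f%%", 100 * mean(mech[top] %in% c("stromal", "immune"))),
    "\n")
cat("genes in the top list with stromal or immune r > 0.5:",
    sum(de$highly_stromal[match(top, de$gene)]), "of", length(top), "\n\n")

flt <- purity_filter(de, tau = 0.2)
writeLines(flt$removed, file.path(out, "removed_genes.txt"))
top_f <- top_fraction(flt$filtered, 0.01)
writeLines(top_f, file.path(out, "filtered_top_de_genes.txt"))
cat("purity filter (|r| > 0.2) removed", length(flt$removed), "genes;",
    nrow(flt$filtered), "remain\n")
cat("mechanisms in the filtered top list (", length(top_f), "genes ):\n")
print(table(mech[top_f]))
cat("fraction culture-driven:",
    sprintf("%.0f%%",
            100 * mean(mech[top_f] %in% c("culture_up", "culture_down"))),
    "\n")
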