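#!/usr/bin/env Rscript
# Global structure of the combined cohort: top-variance gene selection,
# PCA (does PC1 track the stromal score?), Ward correlation clustering,
# and the subtype-specific cell-line fidelity ranking with the fictional
# average cell line.
library(linefidelity)

cohort <- "results/cohort"
out <- "results/structure"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mat <- read_expression_matrix(file.path(cohort, "expression_tpm.tsv"),
                              scale = "tpm",
                              annotations = file.path(cohort,
                                                      "sample_annotations.tsv"))
sigs <- read_gmt(file.path(cohort, "signatures.gmt"))
lg <- log_transform(mat)
tum <- subset_expr(lg, source = "tumour")
scores <- estimate_scores(tum, sigs$stromal_signature, sigs$immune_signature)

k <- min(5000, nrow(lg$values))
sel <- select_top_variance_genes(lg, k)
selmat <- subset_expr(lg, genes = sel)
writeLines(sel, file.path(out, "selected_genes.txt"))

pca <- run_pca(selmat)
write.table(data.frame(sample_id = rownames(pca$sample_scores),
                       pca$sample_scores[, 1:5], check.names = FALSE),
            file.path(out, "pca_scores.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
pc1 <- correlate_pc_with_scores(pca, tum$samples$sample_id, scores)
cat(k, "genes selected; PC1 + PC2 explain",
    sprintf("%.0f%%", 100 * sum(pca$variance_explained[1:2])),
    "of the variance\n")
cat("r(PC1 tumour scores, stromal score):",
    sprintf("%.3f", pc1$r_stromal), "\n")

hc <- correlation_cluster(selmat)
write_dendrogram_newick(hc, file.path(out, "dendrogram.nwk"))

ranking <- rank_cell_lines(selmat)
write.table(ranking, file.path(out, "cell_line_ranking.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ntop-ranked cell lines per subtype:\n")
print(do.call(rbind, lapply(split(ranking, ranking$comparison_subtype),
                            head, 3)), row.names = FALSE)
cat("\nmatched-vs-mismatched subtype AUC:",
    sprintf("%.3f", subtype_separation_auc(selmat)), "\n")

for (s in unique(ranking$subtype)) {
  if (sum(ranking$subtype == s) < 2) next
  avg <- average_cell_line(selmat, s)
  best <- max(ranking$mean_correlation[ranking$subtype == s])
  cat(sprintf("average %s line: r = %.3f vs best individual %.3f\n",
              s, avg$mean_correlation, best))
}
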