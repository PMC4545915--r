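#!/usr/bin/env Rscript
# Genomic frequency tests on small synthetic example tables: exact binomial
# tests of cell-line vs tumour mutation frequencies, fraction of genome
# altered from copy-number segments, and the ER-status composition test.
# The mutation counts are illustrative stand-ins; the ER composition counts
# are reconstructed from a 50-line panel that is 60% ER-negative versus a
# 975-tumour cohort that is 23% ER-negative.
library(linefidelity)

out <- "results/genomics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
ext <- function(f) system.file("extdata", f, package = "linefidelity")

mut <- mutation_frequency_tests(read.delim(ext("example_mutations.tsv")))
write.table(mut, file.path(out, "mutation_tests.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("binomial tests of cell-line mutation frequency vs tumour baseline:\n")
print(mut, row.names = FALSE, digits = 3)
cat("genes significantly enriched in cell lines (p < 0.05):",
    paste(mut$gene[mut$p_value < 0.05 &
                     mut$cell_line_frequency > mut$tumour_frequency],
          collapse = ", "), "\n\n")

seg <- read_segment_table(ext("example_segments.tsv"))
fga <- fraction_genome_altered(seg, threshold = 0.2)
cat(sprintf("fraction of genome altered (|log2 ratio| > 0.2): %.3f over %d segments\n\n",
            fga, nrow(seg)))

# ER-negative overrepresentation among cell lines: 30/50 lines vs 224/975
# tumours
er <- matrix(c(30, 20, 224, 751), nrow = 2, byrow = TRUE,
             dimnames = list(c("cell_line", "tumour"),
                             c("er_negative", "er_positive")))
p <- composition_fisher_test(er)
write.table(data.frame(test = "er_negative_overrepresentation",
                       p_value = p),
            file.path(out, "composition_test.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("ER-negative fraction: cell lines 30/50 vs tumours 224/975\n")
cat("two-tailed Fisher exact p:", format(p, digits = 3),
    if (p < 1e-4) "(p < 0.0001)\n" else "\n")
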