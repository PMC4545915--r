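Package: linefidelity
Title: Purity-Aware Comparison of Cancer Cell-Line and Tumour Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparing bulk cancer cell-line transcriptomes with
    tumour transcriptomes while accounting for tumour purity. Implements
    expression-scale harmonisation (FPKM and RSEM scaled estimates to TPM,
    log2(TPM+1)), single-sample rank-based stromal and immune signature
    scoring, gene-to-score correlation, variance-based gene selection with
    PCA and Ward correlation clustering, subtype-specific cell-line fidelity
    ranking, per-gene Welch differential expression with a stromal/immune
    correlation filter, mean-t gene-set enrichment with purity attribution,
    and exact frequency tests for genomic summaries. Includes a synthetic
    admixture cohort generator with full ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
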