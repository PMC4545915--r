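# Shared small synthetic cohort (generated once per test run) and a tiny
# deterministic toy matrix for the cheap unit tests.

small_cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(small_cohort_cache$co)) {
    cfg <- cohort_config(n_tumours = 60, n_cell_lines = 20, n_genes = 400,
                         seed = 11)
    small_cohort_cache$co <- generate_cohort(cfg)
  }
  small_cohort_cache$co
}

# Deterministic toy expr_matrix: `g` genes x `s` samples, first half of
# samples tumours, second half cell lines, alternating subtypes.
toy_matrix <- function(g = 10, s = 6, seed = 42, scale = "log2_tpm_plus1") {
  set.seed(seed)
  v <- matrix(abs(rnorm(g * s, 5, 2)), nrow = g,
              dimnames = list(sprintf("g%02d", seq_len(g)),
                              sprintf("s%02d", seq_len(s))))
  n_tum <- ceiling(s / 2)
  ann <- data.frame(
    sample_id = colnames(v),
    source = rep(c("tumour", "cell_line"), c(n_tum, s - n_tum)),
    er_status = "unknown",
    subtype = rep_len(c("luminal", "basal"), s),
    stringsAsFactors = FALSE
  )
  if (scale == "tpm") v <- sweep(v, 2, colSums(v), "/") * 1e6
  expression_matrix(v, scale, ann)
}
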