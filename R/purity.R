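#' Gene signature
#'
#' A named, duplicate-free list of gene identifiers used for single-sample
#' scoring or set-level enrichment.
#'
#' @param name Signature name.
#' @param genes Character vector of gene ids (nonempty, no duplicates).
#' @param description Optional free-text description (stored in GMT output).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, description = "") {
  genes <- as.character(genes)
  if (!length(genes)) stop("signature '", name, "' is empty", call. = FALSE)
  if (anyDuplicated(genes)) {
    stop("signature '", name, "' contains duplicate genes", call. = FALSE)
  }
  structure(list(name = name, description = description, genes = genes),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("gene_signature '", x$name, "': ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then the gene identifiers.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of [gene_signature()]s.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", ln, call. = FALSE)
    gene_signature(f[1], f[-(1:2)], description = f[2])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

#' @rdname read_gmt
#' @param sets A list of [gene_signature()]s (a single one is accepted).
#' @export
write_gmt <- function(sets, path) {
  if (inherits(sets, "gene_signature")) sets <- list(sets)
  lines <- vapply(sets, function(s) {
    paste(c(s$name, s$description, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Single-sample rank-based enrichment score
#'
#' Ranks all genes in one sample by descending abundance (average ranks for
#' ties) and walks the ranked list accumulating two empirical distributions:
#' signature genes contribute increments proportional to their descending
#' rank weight raised to `exponent` (normalised to sum to 1), background
#' genes contribute `1/(G - m)`. The score is the sum over all positions of
#' the difference between the cumulative signature weight and the cumulative
#' background weight — the integrated gap between the two distributions. A
#' signature concentrated among highly expressed genes scores positive,
#' among lowly expressed genes negative. Because only ranks enter, the score
#' is invariant under any strictly increasing transform of the abundances.
#'
#' @param x Named numeric vector of per-gene abundances for one sample.
#' @param signature A [gene_signature()] (or plain character vector of gene
#'   ids); must be a strict, nonempty subset of `names(x)` after
#'   intersection.
#' @param exponent Nonnegative rank-weight exponent; 0 gives the unweighted
#'   Kolmogorov-Smirnov-style running sum.
#' @return A single numeric score.
#' @export
ssgsea_score <- function(x, signature, exponent = 0.25) {
  if (inherits(signature, "gene_signature")) signature <- signature$genes
  if (is.null(names(x))) stop("`x` must be a named vector", call. = FALSE)
  if (exponent < 0) stop("exponent must be nonnegative", call. = FALSE)
  g <- names(x)
  G <- length(x)
  sig <- intersect(signature, g)
  m <- length(sig)
  if (m == 0) stop("signature has no genes in the sample", call. = FALSE)
  if (m == G) {
    stop("degenerate signature: covers the whole gene universe",
         call. = FALSE)
  }
  r <- rank(-x, ties.method = "average")    # 1 = most abundant
  ord <- order(r, g)                        # walk high -> low, ties by id
  in_sig <- g[ord] %in% sig
  w <- (G - r[ord] + 1)^exponent            # descending-rank weight
  step_in <- ifelse(in_sig, w, 0)
  step_in <- step_in / sum(step_in)
  step_out <- ifelse(in_sig, 0, 1 / (G - m))
  sum(cumsum(step_in) - cumsum(step_out))
}

#' Stromal / immune purity scores for a set of samples
#'
#' Applies [ssgsea_score()] per sample for a stromal and an immune
#' signature; the composite score is their sum and serves as the
#' purity proxy (high composite = low malignant fraction). Intended for the
#' tumour subset of a log2(TPM+1) matrix; the log is cosmetic since only
#' ranks matter.
#'
#' @param mat An `expr_matrix` (typically tumours only) or plain gene x
#'   sample matrix.
#' @param stromal_sig,immune_sig [gene_signature()]s.
#' @param exponent Rank-weight exponent, default 0.25.
#' @return A `data.frame` with columns `sample_id`, `stromal_score`,
#'   `immune_score`, `composite_score` in the input sample order.
#' @export
estimate_scores <- function(mat, stromal_sig, immune_sig, exponent = 0.25) {
  v <- if (inherits(mat, "expr_matrix")) mat$values else mat
  score <- function(sig) {
    apply(v, 2, ssgsea_score, signature = sig, exponent = exponent)
  }
  s <- score(stromal_sig)
  i <- score(immune_sig)
  data.frame(sample_id = colnames(v), stromal_score = unname(s),
             immune_score = unname(i), composite_score = unname(s + i),
             stringsAsFactors = FALSE)
}

#' Correlate every gene with the purity scores
#'
#' Per-gene Pearson correlation of log-scale expression (across tumours)
#' with the stromal score, the immune score, and the purity proxy (the
#' negated composite score: higher composite means more non-malignant
#' signal, hence lower purity). Zero-variance genes get `NA` with the
#' `undefined` flag set rather than a coerced 0.
#'
#' @param mat An `expr_matrix` or plain matrix; samples must match `scores`.
#' @param scores Output of [estimate_scores()] for the same samples.
#' @return A `data.frame` with columns `gene`, `stromal_r`, `immune_r`,
#'   `purity_r`, `undefined`.
#' @export
gene_purity_correlation <- function(mat, scores) {
  v <- if (inherits(mat, "expr_matrix")) mat$values else mat
  if (!identical(colnames(v), scores$sample_id)) {
    if (!setequal(colnames(v), scores$sample_id)) {
      stop("samples in matrix and scores differ", call. = FALSE)
    }
    scores <- scores[match(colnames(v), scores$sample_id), , drop = FALSE]
  }
  if (ncol(v) < 3) {
    stop("need at least 3 samples for gene-score correlation", call. = FALSE)
  }
  tv <- t(v)
  corr_with <- function(y) {
    suppressWarnings(as.vector(stats::cor(tv, y)))
  }
  sr <- corr_with(scores$stromal_score)
  ir <- corr_with(scores$immune_score)
  pr <- corr_with(-scores$composite_score)
  data.frame(gene = rownames(v), stromal_r = sr, immune_r = ir,
             purity_r = pr, undefined = is.na(sr) & is.na(ir),
             stringsAsFactors = FALSE)
}
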