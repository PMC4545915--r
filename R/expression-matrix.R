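#' Expression matrix container
#'
#' A light container for a gene-by-sample abundance matrix together with an
#' explicit scale tag and per-sample annotations. The scale tag is what makes
#' downstream steps refuse to, say, log-transform already-logged data.
#'
#' @param values Numeric matrix, genes in rows (rownames are gene ids),
#'   samples in columns (colnames are sample ids).
#' @param scale One of `"fpkm"`, `"scaled_estimate"`, `"tpm"`,
#'   `"log2_tpm_plus1"`.
#' @param samples Data frame of sample annotations with columns
#'   `sample_id`, `source` (`"cell_line"` or `"tumour"`), `er_status`
#'   (`"positive"`, `"negative"`, `"unknown"`) and `subtype` (`"luminal"`,
#'   `"basal"`, `"claudin_low"`, `"unknown"`). If `NULL`, a skeleton with
#'   everything `"unknown"` is built from the column names.
#'
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, scale, samples = NULL) {
  scale <- match.arg(scale, expr_scales())
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` needs gene ids as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids in matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids in matrix", call. = FALSE)
  }
  if (scale != "log2_tpm_plus1" && any(values < 0)) {
    stop("negative values are not allowed on scale '", scale, "'",
         call. = FALSE)
  }
  if (is.null(samples)) {
    samples <- data.frame(
      sample_id = colnames(values),
      source = "unknown",
      er_status = "unknown",
      subtype = "unknown",
      stringsAsFactors = FALSE
    )
  }
  samples <- validate_sample_annotations(samples)
  if (!identical(sort(samples$sample_id), sort(colnames(values)))) {
    stop("sample annotations do not match matrix columns", call. = FALSE)
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (scale == "tpm") {
    cs <- colSums(values)
    bad <- abs(cs - 1e6) > 1e-3 * 1e6
    if (any(bad)) {
      stop("TPM columns must sum to 1e6; offending sample(s): ",
           paste(colnames(values)[bad][seq_len(min(3, sum(bad)))],
                 collapse = ", "), call. = FALSE)
    }
  }
  structure(list(values = values, scale = scale, samples = samples),
            class = "expr_matrix")
}

expr_scales <- function() c("fpkm", "scaled_estimate", "tpm", "log2_tpm_plus1")

validate_sample_annotations <- function(samples) {
  need <- c("sample_id", "source", "er_status", "subtype")
  if (!all(need %in% names(samples))) {
    stop("sample annotations need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in annotations", call. = FALSE)
  }
  chk <- function(x, allowed, what) {
    bad <- setdiff(unique(x), allowed)
    if (length(bad)) {
      stop("invalid ", what, ": ", paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  chk(samples$source, c("cell_line", "tumour", "unknown"), "source")
  chk(samples$er_status, c("positive", "negative", "unknown"), "er_status")
  chk(samples$subtype, c("luminal", "basal", "claudin_low", "unknown"),
      "subtype")
  samples[, need, drop = FALSE]
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples, scale =", x$scale, "\n")
  tab <- table(x$samples$source)
  cat("  sources:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by samples and/or genes
#'
#' @param mat An `expr_matrix`.
#' @param samples Character vector of sample ids, or `NULL` to keep all.
#' @param genes Character vector of gene ids, or `NULL` to keep all.
#' @param source Optionally restrict to one `source` annotation value
#'   (e.g. `"tumour"`).
#' @return An `expr_matrix`.
#' @export
subset_expr <- function(mat, samples = NULL, genes = NULL, source = NULL) {
  stopifnot(inherits(mat, "expr_matrix"))
  keep <- colnames(mat$values)
  if (!is.null(source)) {
    keep <- intersect(keep, mat$samples$sample_id[mat$samples$source %in% source])
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(mat$values))
    if (length(missing)) {
      stop("unknown sample id(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    keep <- keep[keep %in% samples]
  }
  if (!length(keep)) stop("no samples left after subsetting", call. = FALSE)
  v <- mat$values[, keep, drop = FALSE]
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing)) {
      stop("unknown gene id(s): ", paste(missing[seq_len(min(3, length(missing)))],
                                         collapse = ", "), call. = FALSE)
    }
    v <- v[genes, , drop = FALSE]
  }
  ann <- mat$samples[match(keep, mat$samples$sample_id), , drop = FALSE]
  out <- structure(list(values = v, scale = mat$scale, samples = ann),
                   class = "expr_matrix")
  rownames(out$samples) <- NULL
  out
}

#' Convert an FPKM column to TPM
#'
#' FPKM is already length-normalised, so conversion to transcripts per
#' million is a within-sample renormalisation: each value is divided by the
#' column total and multiplied by 1e6.
#'
#' @param x Nonnegative numeric vector of per-gene FPKM values with at least
#'   one positive entry.
#' @return Numeric vector summing to 1e6.
#' @export
fpkm_to_tpm <- function(x) {
  if (any(x < 0)) stop("negative FPKM value", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("degenerate sample: all-zero FPKM column", call. = FALSE)
  x / s * 1e6
}

#' Convert an RSEM scaled-estimate column to TPM
#'
#' Scaled estimates are relative abundances summing to 1 per sample; TPM is
#' simply 1e6 times that. Level-3 style files carry rounding drift, so the
#' sum check can be downgraded to a warning.
#'
#' @param x Nonnegative numeric vector summing to approximately 1.
#' @param strict If `TRUE` (default), a column sum outside `[0.99, 1.01]`
#'   is an error; otherwise a warning.
#' @return Numeric vector on the TPM scale.
#' @export
scaled_estimate_to_tpm <- function(x, strict = TRUE) {
  if (any(x < 0)) stop("negative scaled-estimate value", call. = FALSE)
  s <- sum(x)
  if (s <= 0) stop("degenerate sample: all-zero column", call. = FALSE)
  if (s < 0.99 || s > 1.01) {
    msg <- sprintf("scaled-estimate column sums to %.4f, expected ~1", s)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  x * 1e6
}

#' Bring a matrix to the TPM scale
#'
#' Applies the per-column conversion appropriate to the matrix's scale tag
#' (`fpkm` or `scaled_estimate`); a matrix already tagged `tpm` is returned
#' unchanged.
#'
#' @param mat An `expr_matrix` on the `fpkm`, `scaled_estimate` or `tpm`
#'   scale.
#' @param strict Passed to [scaled_estimate_to_tpm()].
#' @return An `expr_matrix` with scale `"tpm"`.
#' @export
to_tpm <- function(mat, strict = TRUE) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$scale == "tpm") return(mat)
  if (mat$scale == "log2_tpm_plus1") {
    stop("matrix is already log-transformed; cannot go back to TPM",
         call. = FALSE)
  }
  f <- switch(mat$scale,
              fpkm = fpkm_to_tpm,
              scaled_estimate = function(x) scaled_estimate_to_tpm(x, strict))
  v <- apply(mat$values, 2, f)
  dimnames(v) <- dimnames(mat$values)
  expression_matrix(v, "tpm", mat$samples)
}

#' Log-transform a TPM matrix
#'
#' Adds 1 to every TPM value and takes log2, so zeros map to zero and the
#' result is finite everywhere. The scale tag is updated to
#' `"log2_tpm_plus1"`.
#'
#' @param mat An `expr_matrix` on the `tpm` scale.
#' @return An `expr_matrix` on the `log2_tpm_plus1` scale.
#' @export
log_transform <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$scale != "tpm") {
    stop("log_transform expects a TPM-scale matrix, got '", mat$scale, "'",
         call. = FALSE)
  }
  v <- log2(mat$values + 1)
  expression_matrix(v, "log2_tpm_plus1", mat$samples)
}

#' Merge two expression matrices on their shared genes
#'
#' Takes the intersection of gene ids (in lexicographic order), concatenates
#' the samples, and reports the intersection size. Both matrices must carry
#' the same scale tag and must not share sample ids.
#'
#' @param a,b `expr_matrix` objects on the same scale.
#' @return An `expr_matrix` over the shared genes; the number of shared
#'   genes is attached as attribute `"n_shared_genes"` and also reported via
#'   `message()`.
#' @export
merge_datasets <- function(a, b) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  if (a$scale != b$scale) {
    stop("cannot merge matrices on different scales (", a$scale, " vs ",
         b$scale, ")", call. = FALSE)
  }
  shared <- sort(intersect(rownames(a$values), rownames(b$values)))
  if (!length(shared)) stop("no shared genes between datasets", call. = FALSE)
  dup <- intersect(colnames(a$values), colnames(b$values))
  if (length(dup)) {
    stop("duplicate sample ids across datasets: ",
         paste(dup[seq_len(min(3, length(dup)))], collapse = ", "),
         call. = FALSE)
  }
  v <- cbind(a$values[shared, , drop = FALSE], b$values[shared, , drop = FALSE])
  samples <- rbind(a$samples, b$samples)
  message("merge_datasets: ", length(shared), " shared genes, ",
          ncol(v), " samples")
  out <- expression_matrix(v, a$scale, samples)
  attr(out, "n_shared_genes") <- length(shared)
  out
}

#' Read / write expression tables
#'
#' Tables are tab-separated with gene ids in the first column and a header
#' row of sample ids. Annotations live in a separate tab-separated table
#' with columns `sample_id`, `source`, `er_status`, `subtype`.
#'
#' @param path File path.
#' @param scale Scale tag to attach on read.
#' @param annotations Optional path to the sample-annotation table.
#' @return `read_expression_matrix()` returns an `expr_matrix`;
#'   `write_expression_matrix()` returns its input invisibly.
#' @export
read_expression_matrix <- function(path, scale, annotations = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(tab[[1]])
  v <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- genes
  ann <- if (!is.null(annotations)) read_sample_annotations(annotations)
  expression_matrix(v, scale, ann)
}

#' @rdname read_expression_matrix
#' @param mat An `expr_matrix`.
#' @export
write_expression_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "expr_matrix"))
  df <- data.frame(gene_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(mat)
}

#' @rdname read_expression_matrix
#' @export
read_sample_annotations <- function(path) {
  validate_sample_annotations(
    utils::read.delim(path, stringsAsFactors = FALSE)
  )
}

#' @rdname read_expression_matrix
#' @param samples A sample-annotation data frame.
#' @export
write_sample_annotations <- function(samples, path) {
  utils::write.table(validate_sample_annotations(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(samples)
}
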