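#' Configuration for a synthetic tumour / cell-line cohort
#'
#' The generator emulates the structure the downstream analyses assume:
#' tumours are purity-weighted mixtures of a malignant profile (one per
#' subtype), a shared stromal profile and a shared immune profile; cell
#' lines are pure malignant profiles with multiplicative culture-adaptation
#' fold changes on designated gene blocks. All randomness flows from one
#' seed.
#'
#' Defaults describe the standard study cohort used throughout the package:
#' 200 tumours, 50 cell lines, 2000 genes, 10% stromal and 10% immune
#' marker genes at 8-fold elevation in their compartment, 5% up- and 5%
#' down-regulated culture genes at 4-fold, malignant fraction drawn from
#' Beta(5, 2), and log-normal noise with sd 0.3 on the log2 scale. Subtype
#' composition mirrors the asymmetry seen in real breast-cancer panels:
#' basal (ER-negative) samples make up roughly a quarter of tumours but more
#' than half of cell lines.
#'
#' @param n_tumours,n_cell_lines,n_genes Cohort dimensions (all >= 1).
#' @param subtype_labels Names of the malignant subtypes (default two).
#' @param tumour_subtype_proportions,cell_line_subtype_proportions Simplex
#'   weights over `subtype_labels`.
#' @param frac_stromal_genes,frac_immune_genes,frac_culture_up,frac_culture_down
#'   Fractions of genes assigned to each mechanism block (disjoint; together
#'   with `frac_subtype_genes` they must sum to <= 1).
#' @param frac_subtype_genes Fraction of genes that discriminate the
#'   malignant subtypes (half elevated in each); these carry the `null`
#'   mechanism label since they are not culture or purity driven.
#' @param stromal_effect,immune_effect,culture_effect,subtype_effect
#'   Multiplicative fold changes (> 1).
#' @param purity_alpha,purity_beta Shape parameters of the Beta distribution
#'   of the tumour malignant fraction. `purity_alpha = Inf` forces purity 1.
#' @param stromal_immune_split Mean fraction of the non-malignant mass that
#'   is stromal (the rest is immune); jittered slightly per tumour.
#' @param split_jitter_sd Standard deviation of that per-tumour jitter.
#' @param noise_sd Standard deviation of additive Gaussian noise on the
#'   log2 scale (log-normal multiplicative noise).
#' @param seed Integer RNG seed.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_tumours = 200,
                          n_cell_lines = 50,
                          n_genes = 2000,
                          subtype_labels = c("luminal", "basal"),
                          tumour_subtype_proportions = c(0.77, 0.23),
                          cell_line_subtype_proportions = c(0.4, 0.6),
                          frac_stromal_genes = 0.1,
                          frac_immune_genes = 0.1,
                          frac_culture_up = 0.05,
                          frac_culture_down = 0.05,
                          frac_subtype_genes = 0.1,
                          stromal_effect = 8,
                          immune_effect = 8,
                          culture_effect = 4,
                          subtype_effect = 4,
                          purity_alpha = 5,
                          purity_beta = 2,
                          stromal_immune_split = 0.5,
                          split_jitter_sd = 0.05,
                          noise_sd = 0.3,
                          seed = 1) {
  cfg <- list(
    n_tumours = n_tumours, n_cell_lines = n_cell_lines, n_genes = n_genes,
    subtype_labels = subtype_labels,
    tumour_subtype_proportions = tumour_subtype_proportions,
    cell_line_subtype_proportions = cell_line_subtype_proportions,
    frac_stromal_genes = frac_stromal_genes,
    frac_immune_genes = frac_immune_genes,
    frac_culture_up = frac_culture_up,
    frac_culture_down = frac_culture_down,
    frac_subtype_genes = frac_subtype_genes,
    stromal_effect = stromal_effect, immune_effect = immune_effect,
    culture_effect = culture_effect, subtype_effect = subtype_effect,
    purity_alpha = purity_alpha, purity_beta = purity_beta,
    stromal_immune_split = stromal_immune_split,
    split_jitter_sd = split_jitter_sd,
    noise_sd = noise_sd, seed = seed
  )
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_tumours < 1 || n_cell_lines < 1 || n_genes < 1) {
      stop("invalid config: all counts must be >= 1", call. = FALSE)
    }
    fr <- c(frac_stromal_genes, frac_immune_genes, frac_culture_up,
            frac_culture_down, frac_subtype_genes)
    if (any(fr < 0) || sum(fr) > 1) {
      stop("invalid config: mechanism fractions must be nonnegative and sum to <= 1",
           call. = FALSE)
    }
    active <- fr[fr > 0]
    if (length(active) && any(round(active * n_genes) < 1)) {
      stop("invalid config: n_genes too small to allocate one gene per block",
           call. = FALSE)
    }
    if (stromal_effect <= 1 || immune_effect <= 1 || culture_effect <= 1 ||
        subtype_effect <= 1) {
      stop("invalid config: effects must be > 1", call. = FALSE)
    }
    if (purity_alpha <= 0 || purity_beta <= 0) {
      stop("invalid config: Beta shape parameters must be positive",
           call. = FALSE)
    }
    for (p in list(tumour_subtype_proportions, cell_line_subtype_proportions)) {
      if (length(p) != length(subtype_labels) || any(p < 0) ||
          abs(sum(p) - 1) > 1e-8) {
        stop("invalid config: subtype proportions must match labels and sum to 1",
             call. = FALSE)
      }
    }
    if (stromal_immune_split < 0 || stromal_immune_split > 1) {
      stop("invalid config: stromal_immune_split must be in [0, 1]",
           call. = FALSE)
    }
    if (noise_sd < 0) stop("invalid config: noise_sd must be >= 0", call. = FALSE)
  })
  invisible(cfg)
}

#' Generate a synthetic cohort with ground truth
#'
#' Per tumour, linear expression is `f_mal * M_s + f_str * S + f_imm * I`
#' where `M_s` is the malignant profile of the tumour's subtype and `S`, `I`
#' are shared stromal/immune profiles elevated on their marker blocks;
#' marker blocks are compartment-specific, i.e. attenuated by the same fold
#' in the malignant profile, so compartment loss in culture shows up as
#' high-in-tumour/low-in-cell-line genes. Per
#' cell line, expression is `M_s` with culture-block genes multiplied or
#' divided by the culture fold change. Gaussian noise is added on the log2
#' scale, then every column is renormalised to TPM (sums to 1e6).
#'
#' @param config A [cohort_config()].
#' @return A list with elements `matrix` (an `expr_matrix`, scale `"tpm"`)
#'   and `truth` (class `synthetic_truth`: per-gene mechanism labels,
#'   per-tumour component fractions, per-sample subtypes, and the noise-free
#'   component profiles on the linear scale).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(G))

  base <- 2^stats::rnorm(G, mean = 5, sd = 2)

  n_blk <- vapply(
    c("frac_stromal_genes", "frac_immune_genes", "frac_culture_up",
      "frac_culture_down", "frac_subtype_genes"),
    function(f) round(config[[f]] * G), numeric(1)
  )
  perm <- sample.int(G)
  at <- cumsum(c(0, n_blk))
  idx <- lapply(seq_along(n_blk), function(i) {
    if (n_blk[i] == 0) integer(0) else perm[(at[i] + 1):at[i + 1]]
  })
  names(idx) <- c("stromal", "immune", "culture_up", "culture_down", "subtype")

  mechanism <- rep("null", G)
  for (m in c("stromal", "immune", "culture_up", "culture_down")) {
    mechanism[idx[[m]]] <- m
  }
  mechanism <- factor(mechanism,
                      levels = c("stromal", "immune", "culture_up",
                                 "culture_down", "null"))

  # Marker blocks are compartment-specific: elevated by the effect fold in
  # their own compartment profile and attenuated by the same fold in the
  # malignant profile, so compartment loss in culture shows up as
  # high-in-tumour/low-in-cell-line genes. Marker baselines are drawn
  # effect-fold lower than the global baseline so that the elevated
  # (in-compartment) level sits at a typical expression level: that keeps
  # every component profile at comparable transcriptome mass, and purity
  # variation from dragging every non-marker gene along compositionally.
  base[idx$stromal] <- base[idx$stromal] / config$stromal_effect
  base[idx$immune] <- base[idx$immune] / config$immune_effect

  S <- base
  S[idx$stromal] <- S[idx$stromal] * config$stromal_effect
  I <- base
  I[idx$immune] <- I[idx$immune] * config$immune_effect

  mal_base <- base
  mal_base[idx$stromal] <- mal_base[idx$stromal] / config$stromal_effect
  mal_base[idx$immune] <- mal_base[idx$immune] / config$immune_effect
  labs <- config$subtype_labels
  M <- matrix(mal_base, nrow = G, ncol = length(labs),
              dimnames = list(gene_ids, labs))
  if (length(idx$subtype)) {
    # round-robin split of the subtype block: each subtype gets its own
    # elevated marker genes
    owner <- rep_len(seq_along(labs), length(idx$subtype))
    for (s in seq_along(labs)) {
      g <- idx$subtype[owner == s]
      M[g, s] <- M[g, s] * config$subtype_effect
    }
  }

  # Components mix as relative abundance profiles: each is normalised to
  # TPM before mixing, so a component contributes mass in proportion to its
  # cell fraction.
  M <- sweep(M, 2, colSums(M), "/") * 1e6
  S <- S / sum(S) * 1e6
  I <- I / sum(I) * 1e6

  tum_sub <- sample(labs, config$n_tumours, replace = TRUE,
                    prob = config$tumour_subtype_proportions)
  cl_sub <- sample(labs, config$n_cell_lines, replace = TRUE,
                   prob = config$cell_line_subtype_proportions)

  f_mal <- if (is.finite(config$purity_alpha)) {
    stats::rbeta(config$n_tumours, config$purity_alpha, config$purity_beta)
  } else {
    rep(1, config$n_tumours)
  }
  split <- pmin(pmax(config$stromal_immune_split +
                       stats::rnorm(config$n_tumours, 0, config$split_jitter_sd),
                     0), 1)
  f_str <- (1 - f_mal) * split
  f_imm <- 1 - f_mal - f_str

  Mt <- M[, match(tum_sub, labs), drop = FALSE]
  lin_t <- sweep(Mt, 2, f_mal, "*") + outer(S, f_str) + outer(I, f_imm)

  culture <- rep(1, G)
  culture[idx$culture_up] <- config$culture_effect
  culture[idx$culture_down] <- 1 / config$culture_effect
  lin_c <- M[, match(cl_sub, labs), drop = FALSE] * culture

  lin <- cbind(lin_t, lin_c)
  n_samp <- ncol(lin)
  noise <- matrix(stats::rnorm(G * n_samp, 0, config$noise_sd), nrow = G)
  lin <- 2^(log2(lin) + noise)
  tpm <- sweep(lin, 2, colSums(lin), "/") * 1e6

  tum_ids <- sprintf("tumour_%03d", seq_len(config$n_tumours))
  cl_ids <- sprintf("cellline_%02d", seq_len(config$n_cell_lines))
  dimnames(tpm) <- list(gene_ids, c(tum_ids, cl_ids))

  er <- function(sub) ifelse(sub == "basal", "negative", "positive")
  samples <- data.frame(
    sample_id = c(tum_ids, cl_ids),
    source = rep(c("tumour", "cell_line"),
                 c(config$n_tumours, config$n_cell_lines)),
    er_status = c(er(tum_sub), er(cl_sub)),
    subtype = c(tum_sub, cl_sub),
    stringsAsFactors = FALSE
  )

  truth <- structure(list(
    gene_ids = gene_ids,
    gene_mechanism = stats::setNames(mechanism, gene_ids),
    subtype_marker = stats::setNames(seq_len(G) %in% idx$subtype, gene_ids),
    tumour_fractions = data.frame(
      sample_id = tum_ids, malignant = f_mal, stromal = f_str,
      immune = f_imm, stringsAsFactors = FALSE
    ),
    subtype_of_sample = stats::setNames(c(tum_sub, cl_sub),
                                        c(tum_ids, cl_ids)),
    component_profiles = list(malignant = M, stromal = S, immune = I),
    config = config
  ), class = "synthetic_truth")

  list(matrix = expression_matrix(tpm, "tpm", samples), truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("synthetic_truth:", length(x$gene_ids), "genes,",
      nrow(x$tumour_fractions), "tumours\n")
  print(table(x$gene_mechanism))
  invisible(x)
}

#' Built-in stromal and immune signatures from a synthetic truth
#'
#' Returns the stromal-block and immune-block gene identifiers as two
#' disjoint signatures, playing the role that published stromal/immune
#' signature lists play on real data.
#'
#' @param truth A `synthetic_truth`.
#' @return Named list with `stromal` and `immune` [gene_signature()]s.
#' @export
builtin_signatures <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mech <- truth$gene_mechanism
  str_genes <- names(mech)[mech == "stromal"]
  imm_genes <- names(mech)[mech == "immune"]
  if (!length(str_genes) || !length(imm_genes)) {
    stop("empty stromal or immune block in truth", call. = FALSE)
  }
  list(stromal = gene_signature("stromal_signature", str_genes),
       immune = gene_signature("immune_signature", imm_genes))
}

#' Mechanism-block gene sets from a synthetic truth
#'
#' Packages each mechanism block (and optionally random null sets) as gene
#' sets for enrichment testing, with the block labels as set names.
#'
#' @param truth A `synthetic_truth`.
#' @param n_null_sets Number of random same-size sets drawn from null genes.
#' @param null_set_size Size of each null set.
#' @param max_genes_per_set Cap on members per set (first genes in id
#'   order), keeping the sets below the conventional 200-member exclusion
#'   bound of the enrichment test; default 150.
#' @param seed Seed for the null-set draw.
#' @return A list of [gene_signature()] objects.
#' @export
truth_gene_sets <- function(truth, n_null_sets = 5, null_set_size = 50,
                            max_genes_per_set = 150, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  mech <- truth$gene_mechanism
  sets <- list()
  for (m in c("stromal", "immune", "culture_up", "culture_down")) {
    g <- sort(names(mech)[mech == m])
    g <- g[seq_len(min(length(g), max_genes_per_set))]
    if (length(g) >= 2) {
      sets[[paste0(m, "_program")]] <- gene_signature(paste0(m, "_program"), g)
    }
  }
  null_genes <- names(mech)[mech == "null" & !truth$subtype_marker]
  if (n_null_sets > 0 && length(null_genes) >= null_set_size) {
    rs <- local({
      set.seed(seed)
      lapply(seq_len(n_null_sets),
             function(i) sample(null_genes, null_set_size))
    })
    for (i in seq_along(rs)) {
      nm <- sprintf("null_set_%02d", i)
      sets[[nm]] <- gene_signature(nm, rs[[i]])
    }
  }
  sets
}

#' Write a synthetic truth bundle
#'
#' Two tab-separated files: a per-gene table (`<prefix>_genes.tsv` with the
#' mechanism label) and a per-sample table (`<prefix>_samples.tsv` with
#' subtype and, for tumours, the true component fractions).
#'
#' @param truth A `synthetic_truth`.
#' @param prefix File path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_truth <- function(truth, prefix) {
  stopifnot(inherits(truth, "synthetic_truth"))
  gene_path <- paste0(prefix, "_genes.tsv")
  samp_path <- paste0(prefix, "_samples.tsv")
  utils::write.table(
    data.frame(gene_id = truth$gene_ids,
               mechanism = as.character(truth$gene_mechanism),
               subtype_marker = truth$subtype_marker,
               stringsAsFactors = FALSE),
    gene_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  fr <- truth$tumour_fractions
  samp <- data.frame(
    sample_id = names(truth$subtype_of_sample),
    subtype = unname(truth$subtype_of_sample),
    stringsAsFactors = FALSE
  )
  samp <- merge(samp, fr, by = "sample_id", all.x = TRUE, sort = FALSE)
  utils::write.table(samp, samp_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gene_path, samp_path))
}
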