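test_that("variance selection orders by variance with lexicographic ties", {
  v <- rbind(gA = c(1, 1, 1),        # var 0
             gB = c(0, 2, 4),        # var 4
             gC = c(1, 2, 3))        # var 1
  colnames(v) <- paste0("s", 1:3)
  expect_identical(select_top_variance_genes(v, 2), c("gB", "gC"))
  expect_identical(select_top_variance_genes(v, 3), c("gB", "gC", "gA"))
  tie <- rbind(gZ = c(1, 2), gA = c(1, 2))
  colnames(tie) <- c("s1", "s2")
  expect_identical(select_top_variance_genes(tie, 1), "gA")
  expect_error(select_top_variance_genes(v, 4), "exceeds")
})

test_that("PCA is centred, ordered, sign-fixed and reconstructs the data", {
  # rank-1 data: all variance on PC1
  v1 <- outer(c(1, 2, 3), c(0, 1, 2, 3))
  dimnames(v1) <- list(paste0("g", 1:3), paste0("s", 1:4))
  p1 <- run_pca(v1)
  expect_equal(p1$variance_explained[1], 1, tolerance = 1e-9)

  # two perfectly correlated genes: PC1 loading (1,1)/sqrt(2)
  v2 <- rbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8) / 2)
  colnames(v2) <- paste0("s", 1:4)
  p2 <- run_pca(v2)
  expect_equal(abs(p2$loadings[, 1]), rep(1 / sqrt(2), 2), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_gt(p2$loadings[which.max(abs(p2$loadings[, 1])), 1], 0)

  co <- small_cohort()
  lg <- log_transform(co$matrix)
  sel <- select_top_variance_genes(lg, 100)
  sm <- subset_expr(lg, genes = sel)
  p <- run_pca(sm)
  expect_true(all(diff(p$variance_explained) <= 1e-12))
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # projecting centred data onto loadings reproduces the scores
  centred <- t(sm$values) - rep(rowMeans(sm$values), each = ncol(sm$values))
  expect_equal(centred %*% p$loadings, p$sample_scores, tolerance = 1e-8,
               ignore_attr = TRUE)
  # full reconstruction from all components
  expect_equal(p$sample_scores %*% t(p$loadings), centred, tolerance = 1e-8)
  expect_error(run_pca(matrix(3, 4, 4,
                              dimnames = list(paste0("g", 1:4),
                                              paste0("s", 1:4)))),
               "degenerate")
})

test_that("PC-score correlation behaves on exact and degenerate inputs", {
  co <- small_cohort()
  lg <- log_transform(co$matrix)
  tum <- subset_expr(lg, source = "tumour")
  sigs <- builtin_signatures(co$truth)
  sc <- estimate_scores(tum, sigs$stromal, sigs$immune)
  p <- run_pca(subset_expr(lg, genes = select_top_variance_genes(lg, 100)))
  # scores equal to PC1 scores correlate exactly 1
  fake <- data.frame(sample_id = tum$samples$sample_id,
                     stromal_score = p$sample_scores[tum$samples$sample_id, 1],
                     immune_score = 0)
  r <- correlate_pc_with_scores(p, tum$samples$sample_id, fake)
  expect_equal(r$r_stromal, 1)
  expect_error(correlate_pc_with_scores(p, tum$samples$sample_id[1:2], sc),
               "at least 3")
})

test_that("correlation clustering matches a naive Ward.D2 oracle", {
  # pairwise 1 - r distances live in [0, 2]; exact endpoints first
  two <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3) + 0.0)
  rownames(two) <- paste0("g", 1:3)
  hc2 <- correlation_cluster(two)
  expect_equal(hc2$height, 0)
  anti <- cbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1))
  rownames(anti) <- paste0("g", 1:3)
  expect_equal(max(1 - cor(anti)), 2)

  set.seed(9)
  for (i in 1:8) {
    n <- sample(4:6, 1)
    v <- matrix(rnorm(8 * n), 8, n,
                dimnames = list(paste0("g", 1:8), paste0("s", seq_len(n))))
    hc <- correlation_cluster(v)
    d <- as.dist(1 - cor(v))
    expect_true(all(d >= 0 & d <= 2))
    expect_equal(hc$height, oracle_ward2(d), tolerance = 1e-10)
    # Ward heights are monotone along the merge sequence
    expect_true(all(diff(hc$height) >= -1e-12))
  }

  const <- cbind(s1 = rep(1, 3), s2 = c(1, 2, 3))
  rownames(const) <- paste0("g", 1:3)
  expect_error(correlation_cluster(const), "s1")
})

test_that("dendrograms export as Newick with additive heights", {
  co <- small_cohort()
  lg <- log_transform(co$matrix)
  hc <- correlation_cluster(
    subset_expr(lg, genes = select_top_variance_genes(lg, 50))$values)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(hc, tmp)
  tree <- ape::read.tree(tmp)
  expect_setequal(tree$tip.label, colnames(lg$values))
})

test_that("cell-line ranking averages matched-subtype correlations", {
  co <- small_cohort()
  lg <- log_transform(co$matrix)
  sel <- select_top_variance_genes(lg, 100)
  sm <- subset_expr(lg, genes = sel)
  rk <- rank_cell_lines(sm)
  expect_setequal(rk$cell_line_id,
                  sm$samples$sample_id[sm$samples$source == "cell_line"])
  # ranks are a permutation of 1..n within each comparison group,
  # ordered by nonincreasing mean correlation
  for (g in split(rk, rk$comparison_subtype)) {
    expect_setequal(g$rank, seq_len(nrow(g)))
    expect_true(all(diff(g$mean_correlation[order(g$rank)]) <= 0))
  }
  # direct recomputation for one line
  one <- rk[1, ]
  tum_ids <- sm$samples$sample_id[sm$samples$source == "tumour" &
                                    sm$samples$subtype == one$comparison_subtype]
  expect_equal(one$mean_correlation,
               mean(cor(sm$values[, one$cell_line_id],
                        sm$values[, tum_ids])))

  # a line identical to the single tumour ranks 1 with correlation 1
  v <- toy_matrix(g = 8, s = 4, seed = 2)$values
  ann <- data.frame(sample_id = colnames(v),
                    source = c("tumour", "cell_line", "cell_line", "cell_line"),
                    er_status = "unknown",
                    subtype = c("basal", "basal", "basal", "basal"))
  v[, 2] <- v[, 1]
  em <- expression_matrix(v, "log2_tpm_plus1", ann)
  rk2 <- rank_cell_lines(em)
  expect_equal(rk2$mean_correlation[rk2$cell_line_id == colnames(v)[2]], 1)
  expect_equal(rk2$rank[rk2$cell_line_id == colnames(v)[2]], 1)

  # claudin-low lines are compared against basal tumours
  ann$subtype[3] <- "claudin_low"
  em2 <- expression_matrix(v, "log2_tpm_plus1", ann)
  rk3 <- rank_cell_lines(em2)
  expect_equal(rk3$comparison_subtype[rk3$cell_line_id == colnames(v)[3]],
               "basal")

  # missing tumour counterpart errors with the subtype named
  ann$subtype[2:4] <- "luminal"
  em3 <- expression_matrix(v, "log2_tpm_plus1", ann)
  expect_error(rank_cell_lines(em3), "luminal")
})

test_that("the average cell line outranks individual lines on synthetic data", {
  # enough lines per subtype for noise averaging to dominate
  co <- generate_cohort(cohort_config(n_tumours = 100, n_cell_lines = 30,
                                      n_genes = 600, seed = 11))
  lg <- log_transform(co$matrix)
  sm <- subset_expr(lg, genes = select_top_variance_genes(lg, 100))
  rk <- rank_cell_lines(sm)
  for (s in unique(rk$subtype)) {
    if (sum(rk$subtype == s) < 2) next
    avg <- average_cell_line(sm, s)
    best <- max(rk$mean_correlation[rk$subtype == s])
    expect_gte(avg$mean_correlation, best)
  }
  # identical lines: the average equals each line
  v <- toy_matrix(g = 6, s = 4, seed = 5)$values
  v[, 3] <- v[, 2]
  ann <- data.frame(sample_id = colnames(v),
                    source = c("tumour", "cell_line", "cell_line", "tumour"),
                    er_status = "unknown", subtype = "basal")
  em <- expression_matrix(v, "log2_tpm_plus1", ann)
  avg <- average_cell_line(em, "basal")
  expect_equal(unname(avg$profile), unname(v[, 2]))
  expect_error(average_cell_line(em, "luminal"), "at least 2")
})
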