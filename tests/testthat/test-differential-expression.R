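test_that("control-gene factor tracks a planted batch effect", {
  expr <- tiny_cohort(seed = 14, batch_lfc = 2, n_markers = 0)
  counts <- expr$counts
  batch <- expr$truth$batch$batch
  f <- estimate_control_gene_factor(counts, expr$truth$control_ids, k = 1)
  expect_gt(abs(cor(f[, 1], batch)), 0.9)
  expect_equal(sd(f[, 1]), 1, tolerance = 1e-8)
  # null batch: correlation indistinguishable from permuted labels
  expr0 <- tiny_cohort(seed = 15, batch_lfc = 0, n_markers = 0)
  f0 <- estimate_control_gene_factor(expr0$counts, expr0$truth$control_ids)
  obs <- abs(cor(f0[, 1], expr0$truth$batch$batch))
  set.seed(1)
  perm <- replicate(200, abs(cor(f0[, 1], sample(expr0$truth$batch$batch))))
  expect_gt(mean(perm >= obs), 0.05)
  expect_error(estimate_control_gene_factor(expr0$counts, c("nope")),
               class = "validation_error")
})

test_that("hidden factors are orthogonal to knowns and recover planted axes", {
  expr <- tiny_cohort(seed = 16, n_markers = 0)
  counts <- expr$counts
  known <- matrix(rnorm(ncol(counts$values)), ncol = 1)
  h <- estimate_hidden_factors(counts, known, n = 3)
  expect_lt(max(abs(t(h) %*% known)), 1e-6)
  expect_lt(max(abs(colSums(h))), 1e-6)   # orthogonal to intercept
  # n = 0 -> empty matrix
  h0 <- estimate_hidden_factors(counts, known, n = 0)
  expect_equal(dim(h0), c(ncol(counts$values), 0))
  # planted structured axis independent of the known factor is recovered
  set.seed(5)
  axis <- rnorm(25)
  m <- counts$values
  idx <- seq_len(nrow(m) / 2)   # structured axis on half the genes only,
  m[idx, ] <- round(m[idx, ] * 2^outer(rep(1, length(idx)), axis))
  h2 <- estimate_hidden_factors(count_matrix(m), NULL, n = 2)
  expect_gt(max(abs(cor(h2, axis))), 0.9)
  expect_error(estimate_hidden_factors(counts, known, n = 30),
               class = "validation_error")
})

test_that("BH adjustment equals the definitional step-up oracle", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (rep in 1:200) {
    n <- sample(1:6, 1)
    p <- sample(seq(0, 1, by = 0.01), n, replace = TRUE)
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # permutation equivariance
  p <- c(0.3, 0.01, 0.77, 0.05)
  perm <- c(3, 1, 4, 2)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  # missing values keep their positions and reduce m
  pm <- c(0.01, NA, 0.04)
  expect_equal(bh_adjust(pm), c(0.02, NA, 0.04))
  expect_error(bh_adjust(c(0.5, 2)), class = "validation_error")
})

test_that("NB Wald handles degenerate genes and approaches the mean ratio", {
  expr <- tiny_cohort(seed = 18, n_genes = 100, dispersion = 0.01)
  m <- expr$counts$values
  m[1, ] <- 0
  de <- nb_wald_de(count_matrix(m),
                   design_info(factor(expr$truth$labels$group,
                                      levels = c("C2", "C1"))))
  expect_equal(de$log2fc[1], 0)
  expect_true(is.na(de$p[1]))
  expect_true(all(de$padj >= de$p, na.rm = TRUE))
  # low-dispersion 2-group design: log2FC approx log2 ratio of group means
  c1 <- expr$truth$labels$group == "C1"
  sf <- size_factors(expr$counts)$size_factors
  q <- sweep(expr$counts$values, 2, sf, `/`)
  ratio <- log2(rowMeans(q[, c1]) / rowMeans(q[, !c1]))
  ok <- de$status == "ok" & de$base_mean > 50
  expect_lt(max(abs(de$log2fc[ok] - ratio[ok])), 0.05)
})

test_that("NB Wald agrees with an independent NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  expr <- tiny_cohort(seed = 19, n_genes = 120, dispersion = 0.1)
  cond <- factor(expr$truth$labels$group, levels = c("C2", "C1"))
  de <- nb_wald_de(expr$counts, design_info(cond))
  dds <- DESeq2::DESeqDataSetFromMatrix(expr$counts$values,
                                        S4Vectors::DataFrame(cond = cond),
                                        ~cond)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("cond", "C1", "C2"))
  ok <- de$status == "ok" & !is.na(res$log2FoldChange) & de$base_mean > 20
  # effect sizes agree closely even though dispersion estimators differ
  expect_gt(cor(de$log2fc[ok], res$log2FoldChange[ok]), 0.98)
  expect_lt(median(abs(de$log2fc[ok] - res$log2FoldChange[ok])), 0.1)
  # both calls rank the planted markers on top
  top <- de$gene[order(de$padj)][1:6]
  expect_setequal(top, expr$truth$marker_ids)
})

test_that("planted markers reach stringent significance with no false calls", {
  expr <- simulate_expression(cohort_config(seed = 20, n_genes = 1000,
                                            n_markers = 6, marker_lfc = 5))
  cond <- factor(expr$truth$labels$group, levels = c("C2", "C1"))
  de <- nb_wald_de(expr$counts, design_info(cond))
  hits <- de$gene[!is.na(de$padj) & de$padj < 1e-4 & abs(de$log2fc) > 4]
  expect_true(all(expr$truth$marker_ids %in% hits))
  expect_lte(length(setdiff(hits, expr$truth$marker_ids)), 1)
})

test_that("unwanted-variation covariates shrink the DE set but keep markers", {
  cfg <- cohort_config(seed = 23, n_genes = 800, n_markers = 6,
                       marker_lfc = 5, batch_lfc = 1.5,
                       batch_confounded = TRUE)
  expr <- simulate_expression(cfg)
  counts <- expr$counts
  cond <- factor(expr$truth$labels$group, levels = c("C2", "C1"))
  de_plain <- nb_wald_de(counts, design_info(cond))
  w <- estimate_control_gene_factor(counts, expr$truth$control_ids)
  known <- cbind(w, cond = as.numeric(cond) - 1)
  h <- estimate_hidden_factors(counts, known, n = 5)
  de_adj <- nb_wald_de(counts, design_info(cond, cbind(w, h)))
  n_plain <- sum(de_plain$padj < 0.01, na.rm = TRUE)
  n_adj <- sum(de_adj$padj < 0.01, na.rm = TRUE)
  expect_lt(n_adj, n_plain)
  sig_adj <- de_adj$gene[!is.na(de_adj$padj) & de_adj$padj < 0.01]
  expect_true(all(expr$truth$marker_ids %in% sig_adj))
})
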