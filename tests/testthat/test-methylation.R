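toy_probes <- function() {
  # 10 probes with disjoint failure reasons: 2 detection, 1 SNP, 2 on X/Y,
  # 3 outside promoter-island intersection, 2 clean
  anno <- tibble::tibble(
    probe = sprintf("cg%02d", 1:10),
    chrom = c("1", "2", "3", "4", "5", "X", "Y", "6", "7", "8"),
    snp_10bp = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE,
                 FALSE, FALSE),
    promoter = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, TRUE,
                 TRUE),
    island = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
               TRUE))
  beta <- matrix(0.5, 10, 4, dimnames = list(anno$probe, paste0("s", 1:4)))
  detp <- matrix(0.001, 10, 4, dimnames = dimnames(beta))
  detp[1, 2] <- 0.05
  detp[2, 4] <- 0.2
  list(beta = beta, anno = anno, detp = detp)
}

test_that("probe filtering applies each exclusion rule", {
  tp <- toy_probes()
  filt <- filter_probes(tp$beta, tp$anno, tp$detp)
  expect_equal(rownames(filt$beta), c("cg09", "cg10"))
  expect_equal(filt$removed$n, c(2, 1, 2, 3))
  # all probes passing -> identity, values untouched
  clean <- filter_probes(tp$beta[9:10, ], tp$anno[9:10, ], tp$detp[9:10, ])
  expect_identical(clean$beta, tp$beta[9:10, ])
  # all probes on X/Y -> empty output
  anno_xy <- tp$anno; anno_xy$chrom <- "X"
  expect_equal(nrow(filter_probes(tp$beta, anno_xy, tp$detp)$beta), 0)
  # mask scope keeps the probe, masks the failing entry
  masked <- filter_probes(tp$beta, tp$anno, tp$detp, scope = "mask")
  expect_true("cg01" %in% rownames(masked$beta))
  expect_true(is.na(masked$beta["cg01", "s2"]))
  expect_error(filter_probes(tp$beta, tp$anno[-1, ], tp$detp),
               class = "validation_error")
  # filtering is a subset operation: no new probes, no altered values
  expect_true(all(rownames(filt$beta) %in% rownames(tp$beta)))
  expect_identical(filt$beta, tp$beta[rownames(filt$beta), ])
})

test_that("supervised selection recovers planted probes and gates on effect size", {
  cfg <- cohort_config(seed = 51, n_c1 = 10, n_c2 = 10, n_probes = 600,
                       n_diff_probes = 40, delta_beta_true = 0.3)
  meth <- simulate_methylation(cfg)
  sel <- supervised_probe_selection(meth$beta, meth$truth$labels$group)
  recall <- mean(meth$truth$diff_probe_ids %in% sel$probe)
  expect_gte(recall, 0.95)
  expect_true(all(sel$padj < 0.01 & sel$delta_beta > 0.2))
  # significant but small effect is excluded by the delta-beta gate
  set.seed(1)
  groups <- rep(c("C1", "C2"), each = 10)
  b <- matrix(rnorm(200, 0.5, 0.005), 10, 20,
              dimnames = list(sprintf("p%02d", 1:10), NULL))
  b[1, groups == "C1"] <- b[1, groups == "C1"] + 0.1   # tiny but significant
  sel2 <- supervised_probe_selection(b, groups)
  all_tab <- attr(sel2, "all")
  expect_lt(all_tab$padj[1], 0.01)
  expect_false("p01" %in% sel2$probe)
  expect_error(supervised_probe_selection(b, c("A", rep("B", 19))),
               class = "meningiomics_error")
})

test_that("delta-beta is label-permutation invariant; selection probe-order invariant", {
  cfg <- cohort_config(seed = 52, n_c1 = 6, n_c2 = 6, n_probes = 100,
                       n_diff_probes = 10)
  meth <- simulate_methylation(cfg)
  g <- meth$truth$labels$group
  sel <- supervised_probe_selection(meth$beta, g)
  swap <- ifelse(g == "C1", "C2", "C1")
  sel_swap <- supervised_probe_selection(meth$beta, swap)
  expect_equal(attr(sel, "all")$delta_beta, attr(sel_swap, "all")$delta_beta)
  perm <- sample(nrow(meth$beta))
  sel_perm <- supervised_probe_selection(meth$beta[perm, ], g)
  expect_setequal(sel$probe, sel_perm$probe)
})

test_that("null methylation keeps the false-selection rate near zero", {
  hits <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    cfg <- cohort_config(seed = 6000 + s, n_c1 = 6, n_c2 = 6,
                         n_probes = 100, n_diff_probes = 0,
                         delta_beta_true = 0)
    meth <- simulate_methylation(cfg)
    sel <- supervised_probe_selection(meth$beta, meth$truth$labels$group)
    hits <- hits + nrow(sel)
  }
  # FDR 0.01 AND delta-beta > 0.2 under the null: selections are rare
  expect_lte(hits / n_rep, 0.05)
})

test_that("methylation clustering recovers planted groups in both modes", {
  cfg <- cohort_config(seed = 53, n_c1 = 10, n_c2 = 9, n_probes = 500,
                       n_diff_probes = 50, delta_beta_true = 0.3)
  meth <- simulate_methylation(cfg)
  filt <- filter_probes(meth$beta, meth$annotation, meth$detection_p)
  sel <- supervised_probe_selection(filt$beta, meth$truth$labels$group)
  part_s <- methylation_clustering(filt$beta, "supervised", probes = sel$probe)
  truth <- meth$truth$labels$group[match(part_s$labels$sample,
                                         meth$truth$labels$sample)]
  expect_equal(adjusted_rand(part_s$labels$cluster, truth), 1)
  expect_equal(part_s$linkage, "ward.D2")
  part_u <- methylation_clustering(filt$beta, "unsupervised")
  expect_equal(part_u$n_top_genes, 75)
  expect_equal(adjusted_rand(part_u$labels$cluster, truth), 1)
  expect_error(methylation_clustering(matrix(0.4, 20, 8,
                                             dimnames = list(sprintf("p%d", 1:20), NULL)),
                                      "unsupervised"),
               class = "degenerate_input_error")
  expect_error(methylation_clustering(meth$beta, "supervised",
                                      probes = "cg000001"),
               class = "validation_error")
})

test_that("expression and methylation partitions agree on a shared-label cohort", {
  cohort <- simulate_cohort(cohort_config(seed = 54, n_genes = 800,
                                          n_probes = 600))
  expr_part <- discover_subgroups(cohort$counts)$partition
  filt <- filter_probes(cohort$methylation$beta, cohort$methylation$annotation,
                        cohort$methylation$detection_p)
  meth_part <- methylation_clustering(filt$beta, "unsupervised")
  common <- intersect(expr_part$labels$sample, meth_part$labels$sample)
  expect_equal(adjusted_rand(
    expr_part$labels$cluster[match(common, expr_part$labels$sample)],
    meth_part$labels$cluster[match(common, meth_part$labels$sample)]), 1)
})
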