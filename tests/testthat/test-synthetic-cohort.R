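test_that("generators are deterministic under the config seed", {
  cfg <- cohort_config(seed = 11, n_genes = 200, n_probes = 200)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts$values, b$counts$values)
  expect_identical(a$survival, b$survival)
  expect_identical(a$methylation$beta, b$methylation$beta)
  expect_identical(a$segments, b$segments)
  expect_identical(a$catalogue, b$catalogue)
  c <- simulate_cohort(cohort_config(seed = 12, n_genes = 200, n_probes = 200))
  expect_false(identical(a$counts$values, c$counts$values))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_c1 = 1, n_c2 = 1), class = "config_error")
  expect_error(cohort_config(n_markers = 100, n_genes = 50),
               class = "config_error")
  expect_error(cohort_config(delta_beta_true = 0.9), class = "config_error")
  expect_error(cohort_config(surv_baseline_rate = 0), class = "config_error")
  expect_error(cohort_config(n_diff_probes = 10, n_probes = 5),
               class = "config_error")
  bad_p <- matrix(1, 2, 96)
  expect_error(cohort_config(signature_profiles = bad_p),
               class = "config_error")
})

test_that("expression generator plants markers with the largest fold changes", {
  expr <- simulate_expression(cohort_config(seed = 3, n_genes = 400,
                                            n_markers = 6, marker_lfc = 5,
                                            dispersion = 0.05))
  m <- expr$counts$values
  c1 <- expr$truth$labels$group == "C1"
  lfc <- abs(log2((rowMeans(m[, c1]) + 0.5) / (rowMeans(m[, !c1]) + 0.5)))
  top6 <- names(sort(lfc, decreasing = TRUE))[1:6]
  expect_setequal(top6, expr$truth$marker_ids)
  # markers are not control genes
  expect_length(intersect(expr$truth$marker_ids, expr$truth$control_ids), 0)
})

test_that("null expression configuration has no group signal", {
  expr <- simulate_expression(cohort_config(seed = 5, n_genes = 1000,
                                            n_markers = 0, marker_lfc = 0,
                                            batch_lfc = 0))
  c1 <- expr$truth$labels$group == "C1"
  m <- expr$counts$values
  lfc <- log2((rowMeans(m[, c1]) + 0.5) / (rowMeans(m[, !c1]) + 0.5))
  # fold changes concentrate near zero: no gene beyond sampling noise
  expect_lt(max(abs(lfc)), 1)
  expect_lt(abs(mean(lfc)), 0.05)
})

test_that("survival generator respects the exponential model and censoring", {
  cfg <- cohort_config(seed = 9, n_c1 = 200, n_c2 = 200, surv_hr = 1)
  rec <- simulate_survival(cfg)
  r1 <- sum(rec$event[rec$group == "C1"]) / sum(rec$time_days[rec$group == "C1"])
  r2 <- sum(rec$event[rec$group == "C2"]) / sum(rec$time_days[rec$group == "C2"])
  expect_lt(abs(log(r1 / r2)), 0.5)      # equal rates within MC noise
  cfg0 <- cohort_config(seed = 9, censor_time = 0)
  rec0 <- simulate_survival(cfg0)
  expect_true(all(rec0$time_days == 0))
  expect_true(all(!rec0$event))
})

test_that("methylation generator plants the largest beta differences", {
  cfg <- cohort_config(seed = 21, n_c1 = 10, n_c2 = 10, n_probes = 500,
                       n_diff_probes = 50, delta_beta_true = 0.3)
  meth <- simulate_methylation(cfg)
  c1 <- meth$truth$labels$group == "C1"
  dbeta <- abs(rowMeans(meth$beta[, c1]) - rowMeans(meth$beta[, !c1]))
  top <- names(sort(dbeta, decreasing = TRUE))[1:50]
  expect_gte(length(intersect(top, meth$truth$diff_probe_ids)), 48)
  expect_true(all(meth$beta >= 0 & meth$beta <= 1))
  # diff probes survive the standard filters by construction
  anno <- meth$annotation[match(meth$truth$diff_probe_ids,
                                meth$annotation$probe), ]
  expect_true(all(anno$promoter & anno$island & !anno$snp_10bp))
  expect_false(any(anno$chrom %in% c("X", "Y")))
})

test_that("null methylation configuration yields empty downstream selection", {
  cfg <- cohort_config(seed = 2, n_c1 = 8, n_c2 = 8, n_probes = 400,
                       n_diff_probes = 0, delta_beta_true = 0)
  meth <- simulate_methylation(cfg)
  sel <- supervised_probe_selection(meth$beta, meth$truth$labels$group)
  expect_equal(nrow(sel), 0)
})

test_that("segment generator tiles the genome and plants callable drivers", {
  cfg <- cohort_config(seed = 13)
  segs <- simulate_segments(cfg, driver_prob = 0.5)
  # tiling: per sample/chrom, segments are non-overlapping and cover the chrom
  cover <- segs$segments |>
    dplyr::group_by(sample, chrom) |>
    dplyr::summarise(bp = sum(end - start + 1), .groups = "drop") |>
    dplyr::left_join(default_genome(), by = "chrom")
  expect_true(all(cover$bp == cover$length))
  calls <- call_cnv_drivers(segs$segments, default_driver_genes())
  truth <- segs$truth$driver_events
  expect_setequal(paste(calls$sample, calls$gene, calls$type),
                  paste(truth$sample, truth$gene, truth$type))
})

test_that("malformed segments are rejected", {
  seg <- tibble::tibble(sample = "s1", chrom = "1", start = 100, end = 50,
                        total_cn = 2, ploidy = 2)
  expect_error(aggregate_profile(seg), class = "validation_error")
  seg2 <- tibble::tibble(sample = "s1", chrom = c("1", "1"),
                         start = c(1, 50), end = c(100, 150),
                         total_cn = 2, ploidy = 2)
  expect_error(aggregate_profile(seg2), class = "validation_error")
})

test_that("catalogue generator matches its signature mixture", {
  p <- default_signature_profiles()
  cfg <- cohort_config(seed = 31, n_catalogue_samples = 1)
  # single signature at exposure 1000: cosine >= 0.97 with the truth
  cats <- simulate_catalogues(cfg, exposures = matrix(c(1000, 0), 1, 2))
  prof <- cats$catalogue[1, ] / sum(cats$catalogue[1, ])
  cosine <- sum(prof * p[1, ]) / sqrt(sum(prof^2) * sum(p[1, ]^2))
  expect_gte(cosine, 0.97)
  # zero exposure: all-zero catalogue
  cats0 <- simulate_catalogues(cfg, exposures = matrix(0, 1, 2))
  expect_true(all(cats0$catalogue == 0))
  # orthogonal-support signatures: channel support matches the mixture
  ch <- trinucleotide_channels()
  pa <- ifelse(grepl("C>A", ch, fixed = TRUE), 1, 0); pa <- pa / sum(pa)
  pb <- ifelse(grepl("T>G", ch, fixed = TRUE), 1, 0); pb <- pb / sum(pb)
  cfg2 <- cohort_config(seed = 32, n_catalogue_samples = 2,
                        signature_profiles = rbind(pa, pb))
  cats2 <- simulate_catalogues(cfg2, exposures = rbind(c(5000, 0), c(0, 5000)))
  expect_true(all(cats2$catalogue[1, pa == 0] == 0))
  expect_true(all(cats2$catalogue[2, pb == 0] == 0))
  expect_error(simulate_catalogues(cfg, exposures = matrix(-1, 1, 2)),
               class = "config_error")
})

test_that("every planted entity exists in the generated matrices", {
  cohort <- simulate_cohort(cohort_config(seed = 17, n_genes = 300,
                                          n_probes = 300))
  expect_true(all(cohort$truth$marker_ids %in% rownames(cohort$counts$values)))
  expect_true(all(cohort$truth$control_ids %in% rownames(cohort$counts$values)))
  expect_true(all(cohort$truth$diff_probe_ids %in%
                    rownames(cohort$methylation$beta)))
  expect_true(all(cohort$truth$labels$sample %in%
                    colnames(cohort$counts$values)))
  expect_true(all(cohort$truth$driver_events$sample %in%
                    cohort$segments$sample))
})
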