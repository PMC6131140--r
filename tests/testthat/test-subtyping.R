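test_that("size factors obey identity, scaling law and the hand oracle", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2)
  expect_equal(size_factors(count_matrix(m))$size_factors, c(1, 1))
  m2 <- cbind(a = c(10, 20, 30), b = 2 * c(10, 20, 30))
  s <- size_factors(count_matrix(m2))$size_factors
  expect_equal(s[2] / s[1], 2)
  # 3x3 toy: explicit median-of-ratios computation
  m3 <- matrix(c(4, 10, 20,
                 8, 10, 10,
                 2, 40, 40), 3, 3)
  geo <- apply(m3, 1, function(r) exp(mean(log(r))))
  raw <- apply(m3 / geo, 2, median)
  expected <- raw / exp(mean(log(raw)))
  expect_equal(size_factors(count_matrix(m3))$size_factors, expected)
  expect_error(size_factors(count_matrix(matrix(c(0, 1, 1, 0), 2, 2))),
               class = "normalization_error")
})

test_that("vst transform hits exact values and stabilizes variance", {
  cm <- count_matrix(matrix(c(0, 7), 2, 1))
  v <- vst_transform(cm)
  expect_equal(unname(v$values[, 1]), c(0, 3))   # log2(1), log2(8)
  # monotone per gene
  cm2 <- count_matrix(matrix(c(1, 5, 9, 2, 6, 10), 3, 2))
  v2 <- vst_transform(cm2)
  expect_true(all(diff(v2$values[, 1]) > 0))
  # variance profile flatter than raw log2 counts on NB data
  expr <- tiny_cohort(seed = 8, n_markers = 0)
  vshr <- vst_transform(expr$counts, shrink = TRUE)$values
  raw <- log2(expr$counts$values + 1)
  strata <- cut(rowMeans(expr$counts$values), c(0, 50, 500, Inf))
  sd_prof <- function(x) tapply(apply(x, 1, sd), strata, mean)
  expect_lt(diff(range(sd_prof(vshr))), diff(range(sd_prof(raw))))
})

test_that("TPM normalizes per the definition", {
  expect_equal(unname(compute_tpm(count_matrix(matrix(5, 1, 1)), 100)[1, 1]),
               1e6)
  m <- matrix(3, 4, 2)
  expect_true(all(compute_tpm(count_matrix(m), rep(200, 4)) == 2.5e5))
  # 3-gene hand computation
  m3 <- matrix(c(10, 20, 30), 3, 1)
  len <- c(1000, 500, 100)
  r <- m3[, 1] / len
  expect_equal(unname(compute_tpm(count_matrix(m3), len)[, 1]),
               r / sum(r) * 1e6)
  expect_error(compute_tpm(count_matrix(m3), c(0, 1, 1)),
               class = "validation_error")
})

test_that("top_variable_genes ranks by variance with deterministic ties", {
  m <- matrix(1, 6, 4, dimnames = list(paste0("g", 1:6), NULL))
  expect_equal(top_variable_genes(m, 5), paste0("g", 1:5))
  expect_equal(length(top_variable_genes(m, 6)), 6)
  m[3, ] <- c(0, 10, 0, 10)
  expect_equal(top_variable_genes(m, 1), "g3")
  expect_error(top_variable_genes(m, 10), class = "validation_error")
})

test_that("poisson distance matches the brute-force deviance oracle", {
  # identical samples, equal size factors -> zero distance
  m <- matrix(c(5, 9, 2, 5, 9, 2), 3, 2)
  d0 <- poisson_distance(count_matrix(m))
  expect_equal(max(abs(d0$values)), 0)
  # dense random sweep over all shapes up to 5x5
  set.seed(99)
  for (rep in 1:60) {
    ng <- sample(1:5, 1); ns <- sample(2:5, 1)
    m <- matrix(rnbinom(ng * ns, mu = 20, size = 2), ng, ns)
    if (!any(rowSums(m > 0) == ns)) m[1, ] <- m[1, ] + 1
    cm <- size_factors(count_matrix(m))
    got <- poisson_distance(cm)$values
    want <- oracle_poisson_distance(m, cm$size_factors)
    expect_lt(max(abs(unname(got) - want)), 1e-7)
    expect_equal(got, t(got))
    expect_true(all(diag(got) == 0))
  }
  expect_error(poisson_distance(count_matrix(m), character()),
               class = "validation_error")
})

test_that("hierarchical partition separates point clouds and follows the hand trace", {
  # two tight clouds far apart
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(pts))
  part <- hierarchical_partition(d, k = 2)
  expect_equal(adjusted_rand(part$labels$cluster, rep(1:2, each = 3)), 1)
  # k = n -> singletons
  part_n <- hierarchical_partition(d, k = 6)
  expect_equal(sort(unique(part_n$labels$cluster)), 1:6)
  expect_error(hierarchical_partition(d, k = 7), class = "validation_error")
  # hand-traced complete-linkage agglomeration on 6 points:
  # pairs (1,2)=1, (3,4)=2, (5,6)=3 merge first; cross distances >= 10
  dm <- matrix(10, 6, 6); diag(dm) <- 0
  dm[1, 2] <- dm[2, 1] <- 1
  dm[3, 4] <- dm[4, 3] <- 2
  dm[5, 6] <- dm[6, 5] <- 3
  p3 <- hierarchical_partition(dm, k = 3)
  expect_equal(p3$labels$cluster, rep(1:3, each = 2))
  hc <- p3$hclust
  expect_equal(hc$height[1:3], c(1, 2, 3))
})

test_that("silhouette k-selection finds planted cluster numbers", {
  expr2 <- tiny_cohort(seed = 4, marker_lfc = 5)
  res2 <- discover_subgroups(expr2$counts, n_top = 100)
  expect_equal(res2$k_star, 2)
  truth <- expr2$truth$labels$group[match(res2$partition$labels$sample,
                                          expr2$truth$labels$sample)]
  expect_equal(adjusted_rand(res2$partition$labels$cluster, truth), 1)
  # three well-separated clouds in euclidean space
  set.seed(1)
  pts <- c(rnorm(8, 0, 0.05), rnorm(8, 5, 0.05), rnorm(8, 11, 0.05))
  res3 <- select_k_silhouette(as.matrix(dist(pts)), 2:5)
  expect_equal(res3$k_star, 3)
  # perfect two-cluster split with zero within-cluster spread -> silhouette 1
  dperf <- matrix(5, 4, 4); diag(dperf) <- 0
  dperf[1, 2] <- dperf[2, 1] <- 0
  dperf[3, 4] <- dperf[4, 3] <- 0
  resp <- select_k_silhouette(dperf, 2:3)
  expect_equal(resp$profile$mean_silhouette[resp$profile$k == 2], 1)
  expect_error(select_k_silhouette(matrix(0, 2, 2), 2),
               class = "validation_error")
})

test_that("silhouette k-selection is invariant to sample order", {
  expr <- tiny_cohort(seed = 6)
  d <- poisson_distance(expr$counts,
                        top_variable_genes(vst_transform(expr$counts), 100))
  res <- select_k_silhouette(d)
  set.seed(2)
  perm <- sample(ncol(d$values))
  dperm <- structure(list(values = d$values[perm, perm],
                          method = d$method), class = "distance_matrix")
  res_perm <- select_k_silhouette(dperm)
  expect_equal(res_perm$k_star, res$k_star)
  expect_equal(res_perm$profile$mean_silhouette, res$profile$mean_silhouette,
               tolerance = 1e-12)
})

test_that("PCA loadings are orthonormal, complete, and find planted factors", {
  expr <- tiny_cohort(seed = 12)
  vst <- vst_transform(expr$counts)
  pca <- pca_top_variable(vst, n_top = 200)
  g <- t(pca$loadings) %*% pca$loadings
  expect_equal(unname(g), diag(ncol(pca$loadings)), tolerance = 1e-8)
  # scores reconstruct the centered data with all components kept
  sub <- vst$values[pca$genes, ]
  centered <- t(sub - rowMeans(sub))
  expect_equal(unname(pca$scores %*% t(pca$loadings)), unname(centered),
               tolerance = 1e-8)
  expect_true(all(diff(pca$variance_explained) <= 1e-12))
  # sign convention: largest-|loading| entry positive
  for (j in seq_len(ncol(pca$loadings))) {
    col <- pca$loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
  # planted one-factor structure dominates PC1
  set.seed(3)
  f <- rnorm(20)
  load <- rnorm(100)
  x <- outer(load, f) + matrix(rnorm(2000, 0, 0.05), 100, 20)
  rownames(x) <- sprintf("g%03d", 1:100)
  p1 <- pca_top_variable(x, 100)
  expect_gt(p1$variance_explained[1], 0.9)
  expect_error(pca_top_variable(matrix(1, 5, 4,
                                       dimnames = list(paste0("g", 1:5), NULL))),
               class = "degenerate_input_error")
})
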