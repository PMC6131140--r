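#' Median-of-ratios size factors
#'
#' Per-sample depth normalization: for each sample, the median across genes
#' of the ratio count / geometric-mean(count across samples), restricted to
#' genes expressed in every sample; factors are rescaled to geometric mean 1.
#'
#' @param counts A [count_matrix()] (or coercible).
#' @return The `count_matrix` with `size_factors` filled in.
#' @export
size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  m <- counts$values
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    abort("no gene expressed in all samples; cannot normalize",
          class = c("normalization_error", "meningiomics_error"))
  }
  lg <- log(m[all_pos, , drop = FALSE])
  geo <- rowMeans(lg)
  s <- exp(apply(lg - geo, 2, median))
  s <- s / exp(mean(log(s)))
  counts$size_factors <- unname(s)
  counts
}

ensure_size_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  if (is.null(counts$size_factors)) counts <- size_factors(counts)
  counts
}

#' Variance-stabilizing log transform of normalized counts
#'
#' `log2(count / s_j + 1)`, optionally shrunk toward the per-gene mean with a
#' weight that grows with the gene's fitted dispersion (a lightweight
#' regularized-log analogue: noisy, high-dispersion genes are pulled toward
#' their mean, stabilizing variance across expression strata while staying
#' monotone in the counts per gene).
#'
#' @param counts A [count_matrix()].
#' @param shrink Apply dispersion-weighted shrinkage toward the gene mean.
#' @return A `transformed_matrix` (list: `values`, `transform_meta`).
#' @export
vst_transform <- function(counts, shrink = FALSE) {
  counts <- ensure_size_factors(counts)
  v <- log2(sweep(counts$values, 2, counts$size_factors, `/`) + 1)
  if (shrink) {
    alpha <- dispersion_mom(counts)$alpha_shrunk
    w <- alpha / (alpha + 0.5)          # in [0,1), larger for noisier genes
    v <- v * (1 - w) + rowMeans(v) * w
  }
  structure(list(values = v, gene_ids = counts$gene_ids,
                 sample_ids = counts$sample_ids,
                 transform_meta = list(pseudocount = 1, shrinkage = shrink)),
            class = "transformed_matrix")
}

#' Transcripts-per-million normalization
#'
#' `tpm_gj = (count_gj / length_g) / sum_g (count_gj / length_g) * 1e6`.
#'
#' @param counts A [count_matrix()].
#' @param gene_lengths Positive per-gene lengths in bp, in gene order.
#' @return Genes x samples matrix whose columns sum to 1e6.
#' @export
compute_tpm <- function(counts, gene_lengths) {
  counts <- as_count_matrix(counts)
  if (length(gene_lengths) != nrow(counts$values)) {
    validation_error("gene_lengths must have one entry per gene")
  }
  if (any(gene_lengths <= 0)) validation_error("zero or negative gene length")
  r <- counts$values / gene_lengths
  sweep(r, 2, colSums(r), `/`) * 1e6
}

#' Top variable genes of a transformed matrix
#'
#' The `n` genes with largest per-gene variance; ties resolved by gene-id
#' order so the selection is deterministic.
#'
#' @param x A `transformed_matrix` (or plain matrix with rownames).
#' @param n Number of genes.
#' @return Character vector of gene ids, descending variance.
#' @export
top_variable_genes <- function(x, n) {
  v <- if (inherits(x, "transformed_matrix")) x$values else as.matrix(x)
  if (n > nrow(v)) validation_error("n exceeds number of genes")
  vars <- apply(v, 1, var)
  ids <- rownames(v) %||% as.character(seq_len(nrow(v)))
  ids[order(-vars, ids)][seq_len(n)]
}

#' Poisson deviance distance between samples
#'
#' For samples a, b the squared distance is the summed Poisson deviance of
#' both samples' counts around the shared-rate maximum-likelihood mean split
#' by size factors: `mu_ga = s_a (x_ga + x_gb) / (s_a + s_b)`, with
#' `dev(x; mu) = x log(x/mu) - (x - mu)` and `0 log 0 = 0`.
#'
#' @param counts A [count_matrix()].
#' @param gene_subset Optional character vector of gene ids to restrict to.
#' @return A `distance_matrix` (list: `values` symmetric matrix, `method`).
#' @export
poisson_distance <- function(counts, gene_subset = NULL) {
  counts <- ensure_size_factors(counts)
  m <- counts$values
  if (!is.null(gene_subset)) {
    if (length(gene_subset) == 0) validation_error("empty gene subset")
    missing <- setdiff(gene_subset, rownames(m))
    if (length(missing)) validation_error("gene subset not in matrix")
    m <- m[gene_subset, , drop = FALSE]
  }
  s <- counts$size_factors
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      tot <- (m[, a] + m[, b]) / (s[a] + s[b])
      mua <- s[a] * tot
      mub <- s[b] * tot
      d2 <- sum(pois_dev(m[, a], mua) + pois_dev(m[, b], mub))
      d[a, b] <- d[b, a] <- sqrt(max(d2, 0))
    }
  }
  structure(list(values = d, method = "poisson_deviance"),
            class = "distance_matrix")
}

pois_dev <- function(x, mu) {
  t1 <- ifelse(x > 0, x * log(x / mu), 0)
  t1 - (x - mu)
}

#' Hierarchical partition of a distance matrix
#'
#' Agglomerative clustering (stats::hclust) cut at `k` clusters.
#'
#' @param dist A `distance_matrix`, `dist`, or symmetric matrix.
#' @param k Number of clusters (>= 1).
#' @param linkage One of `"complete"`, `"average"`, `"ward.D2"`.
#' @return A `subgroup_partition` (list: `labels` tibble with `sample` and
#'   `cluster`, plus `k`, `linkage`, `hclust`).
#' @export
hierarchical_partition <- function(dist, k = 2, linkage = c("complete", "average", "ward.D2")) {
  linkage <- match.arg(linkage)
  d <- as_dist_obj(dist)
  n <- attr(d, "Size")
  if (k > n) validation_error("k exceeds number of samples")
  hc <- hclust(d, method = linkage)
  cl <- cutree(hc, k = k)
  structure(list(labels = tibble::tibble(sample = names(cl) %||%
                                           as.character(seq_len(n)),
                                         cluster = unname(cl)),
                 k = k, linkage = linkage, hclust = hc,
                 n_top_genes = attr(dist, "n_top_genes")),
            class = "subgroup_partition")
}

as_dist_obj <- function(dist) {
  if (inherits(dist, "distance_matrix")) return(as.dist(dist$values))
  if (inherits(dist, "dist")) return(dist)
  as.dist(as.matrix(dist))
}

#' @export
print.subgroup_partition <- function(x, ...) {
  cat(sprintf("<subgroup_partition> k=%d (%s linkage): %s\n", x$k, x$linkage,
              paste(sprintf("%d x cluster %s", table(x$labels$cluster),
                            names(table(x$labels$cluster))), collapse = ", ")))
  invisible(x)
}

#' Tidy a subgroup partition
#' @param x A `subgroup_partition`.
#' @param ... Unused.
#' @return Tibble with `sample` and `cluster`.
#' @export
tidy.subgroup_partition <- function(x, ...) x$labels

#' Silhouette-guided choice of the number of clusters
#'
#' For each k in `k_range`, cuts the hierarchical tree and computes the mean
#' silhouette width `s(i) = (b_i - a_i) / max(a_i, b_i)`; returns the k with
#' the highest mean (ties to the smallest k).
#'
#' @param dist A `distance_matrix` (or coercible).
#' @param k_range Candidate cluster numbers, within `[2, n - 1]`.
#' @param linkage Linkage passed to [hierarchical_partition()].
#' @return List with `k_star`, `profile` (tibble `k`, `mean_silhouette`),
#'   and the winning `partition`.
#' @export
select_k_silhouette <- function(dist, k_range = 2:6,
                                linkage = "complete") {
  d <- as_dist_obj(dist)
  n <- attr(d, "Size")
  if (n < 3) validation_error("need at least 3 samples for silhouette selection")
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  assert_that(length(k_range) > 0, "k_range empty after clipping to [2, n-1]")
  dm <- as.matrix(d)
  prof <- purrr::map_dfr(k_range, function(k) {
    part <- hierarchical_partition(structure(list(values = dm),
                                             class = "distance_matrix"),
                                   k, linkage)
    sil <- cluster::silhouette(part$labels$cluster, dmatrix = dm)
    tibble::tibble(k = k, mean_silhouette = mean(sil[, "sil_width"]))
  })
  k_star <- prof$k[which.max(prof$mean_silhouette)]
  list(k_star = k_star, profile = prof,
       partition = hierarchical_partition(structure(list(values = dm),
                                                    class = "distance_matrix"),
                                          k_star, linkage))
}

#' PCA of the top variable genes
#'
#' Gene-centred (not scaled) singular value decomposition of the `n_top`
#' most variable genes. Loadings are orthonormal; the sign of each component
#' is fixed so its largest-magnitude loading is positive.
#'
#' @param x A `transformed_matrix` or plain numeric matrix (features x
#'   samples).
#' @param n_top Number of top-variance features to keep (clipped to the
#'   feature count).
#' @return A `pca_result` (list: `loadings` gene x PC, `scores` sample x PC,
#'   `variance_explained`).
#' @export
pca_top_variable <- function(x, n_top = 500) {
  v <- if (inherits(x, "transformed_matrix")) x$values else as.matrix(x)
  n_top <- min(n_top, nrow(v))
  keep <- top_variable_genes(v, n_top)
  sub <- v[keep, , drop = FALSE]
  if (all(apply(sub, 1, var) < 1e-12)) {
    abort("constant matrix: PCA is degenerate",
          class = c("degenerate_input_error", "meningiomics_error"))
  }
  if (ncol(sub) < 2) validation_error("need >= 2 samples for PCA")
  pc <- prcomp(t(sub), center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(col) {
    if (col[which.max(abs(col))] < 0) -1 else 1
  })
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  scores <- sweep(pc$x, 2, flip, `*`)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(loadings = loadings, scores = scores,
                 variance_explained = ve, genes = keep),
            class = "pca_result")
}

#' Tidy PCA loadings
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return Tibble with `gene`, `component`, `loading`.
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$loadings, stringsAsFactors = FALSE)) |>
    setNames(c("gene", "component", "loading")) |>
    tibble::as_tibble()
}

#' One-line PCA summary
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return Tibble with component count and variance explained by PC1/PC2.
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(n_components = ncol(x$loadings),
                 pve_pc1 = x$variance_explained[1],
                 pve_pc2 = if (length(x$variance_explained) > 1)
                   x$variance_explained[2] else NA_real_)
}

#' Discover expression subgroups from a count matrix
#'
#' The full subgroup-discovery recipe: variance-stabilized transform,
#' top-`n_top` variable transcripts, Poisson deviance distance, hierarchical
#' clustering, and silhouette-based selection of the cluster number.
#'
#' @param counts A [count_matrix()].
#' @param n_top Number of most-variable transcripts used for the distance
#'   (default 250).
#' @param k_range Candidate cluster counts.
#' @param linkage Linkage method.
#' @return The result of [select_k_silhouette()], with the gene subset used
#'   attached.
#' @export
discover_subgroups <- function(counts, n_top = 250, k_range = 2:6,
                               linkage = "complete") {
  counts <- ensure_size_factors(counts)
  vst <- vst_transform(counts)
  genes <- top_variable_genes(vst, min(n_top, nrow(vst$values)))
  d <- poisson_distance(counts, genes)
  res <- select_k_silhouette(d, k_range, linkage)
  res$genes <- genes
  res$partition$n_top_genes <- length(genes)
  res
}
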