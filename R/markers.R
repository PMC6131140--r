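#' Candidate marker transcripts from PC1 loadings and DE significance
#'
#' Intersects the `n_top` transcripts with the largest absolute PC1
#' coefficients with the genes passing `|log2FC| > lfc_min` and
#' `padj < padj_max` in the subgroup comparison (`de_a`) — and, when given,
#' also in the external-reference comparison (`de_b`). Defaults are the
#' stringent panel-selection thresholds (top 50 loadings, |log2FC| > 4,
#' adjusted p < 1e-4).
#'
#' @param pca A `pca_result` from [pca_top_variable()].
#' @param de_a DE result for the subgroup (C1 vs C2) comparison.
#' @param de_b Optional DE result for the external-grade comparison; when
#'   absent only `de_a` gates candidacy.
#' @param n_top,lfc_min,padj_max Selection thresholds.
#' @return A `marker_candidates` tibble (`gene`, `pc1`, `log2fc_a`,
#'   `padj_a`, and `_b` columns when `de_b` given), ordered by |PC1|
#'   descending with gene-id tie-break.
#' @export
candidate_markers <- function(pca, de_a, de_b = NULL, n_top = 50,
                              lfc_min = 4, padj_max = 1e-4) {
  assert_that(n_top > 0 && lfc_min > 0 && padj_max > 0, "thresholds must be positive")
  pc1 <- pca$loadings[, 1]
  ord <- order(-abs(pc1), names(pc1))
  top <- names(pc1)[ord][seq_len(min(n_top, length(pc1)))]
  passes <- function(de) {
    de$gene[!is.na(de$padj) & de$padj < padj_max & abs(de$log2fc) > lfc_min]
  }
  keep <- intersect(top, passes(de_a))
  if (!is.null(de_b)) keep <- intersect(keep, passes(de_b))
  keep <- keep[order(-abs(pc1[keep]), keep)]
  out <- tibble::tibble(
    gene = keep,
    pc1 = unname(pc1[keep]),
    log2fc_a = de_a$log2fc[match(keep, de_a$gene)],
    padj_a = de_a$padj[match(keep, de_a$gene)])
  if (!is.null(de_b)) {
    out$log2fc_b <- de_b$log2fc[match(keep, de_b$gene)]
    out$padj_b <- de_b$padj[match(keep, de_b$gene)]
  }
  structure(out, class = c("marker_candidates", class(out)))
}

recapitulates <- function(genes, counts, reference, linkage = "complete") {
  d <- poisson_distance(counts, genes)
  part <- hierarchical_partition(d, k = 2, linkage)
  ref <- reference$labels$cluster[match(part$labels$sample,
                                        reference$labels$sample)]
  isTRUE(all.equal(adjusted_rand(part$labels$cluster, ref), 1))
}

#' Minimal marker panel recapitulating the subgroup partition
#'
#' Greedy elimination over the PC1-ranked candidates: repeatedly drop the
#' lowest-|PC1| remaining gene, recluster the samples on the surviving genes
#' (Poisson distance + hierarchical clustering at k = 2), and keep going
#' while the clustering still reproduces the reference partition exactly
#' (adjusted Rand index 1). Returns the smallest prefix on that path. A PCA
#' separation score (mean silhouette of the reference groups on PC1-PC2
#' scores of the panel) is reported but not binding.
#'
#' With `exhaustive = TRUE` (candidate sets of <= 20 genes) all subsets are
#' searched for a certified minimum-size recapitulating panel.
#'
#' @param candidates A `marker_candidates` tibble (nonempty).
#' @param counts The cohort [count_matrix()].
#' @param reference A `subgroup_partition` with k = 2.
#' @param linkage Linkage used when reclustering.
#' @param exhaustive Certify minimality by enumerating all subsets.
#' @return A `minimal_marker_set`: list with `genes`, `size`,
#'   `recapitulation` flag, `path` tibble of the greedy trajectory, and
#'   `pca_silhouette`.
#' @export
minimize_markers <- function(candidates, counts, reference,
                             linkage = "complete", exhaustive = FALSE) {
  if (nrow(candidates) == 0) validation_error("empty candidate set")
  assert_that(inherits(reference, "subgroup_partition") && reference$k == 2,
              "reference partition must have k = 2")
  counts <- ensure_size_factors(counts)
  genes <- candidates$gene

  if (exhaustive) {
    if (length(genes) > 20) validation_error("exhaustive search limited to 20 candidates")
    best <- NULL
    for (size in seq_along(genes)) {
      subsets <- utils::combn(genes, size, simplify = FALSE)
      hits <- purrr::keep(subsets, recapitulates, counts = counts,
                          reference = reference, linkage = linkage)
      if (length(hits)) {
        best <- hits[[1]]
        break
      }
    }
    if (is.null(best)) {
      return(minimal_marker_result(character(), FALSE, NULL, counts, reference))
    }
    return(minimal_marker_result(best, TRUE, NULL, counts, reference))
  }

  path <- tibble::tibble(size = integer(), recapitulates = logical())
  if (!recapitulates(genes, counts, reference, linkage)) {
    return(minimal_marker_result(genes, FALSE, path, counts, reference))
  }
  best <- genes
  m <- length(genes)
  path <- tibble::add_row(path, size = m, recapitulates = TRUE)
  while (m > 1) {
    trial <- genes[seq_len(m - 1)]
    ok <- recapitulates(trial, counts, reference, linkage)
    path <- tibble::add_row(path, size = m - 1, recapitulates = ok)
    if (!ok) break
    best <- trial
    m <- m - 1
  }
  minimal_marker_result(best, TRUE, path, counts, reference)
}

minimal_marker_result <- function(genes, recap, path, counts, reference) {
  sil <- NA_real_
  if (recap && length(genes) >= 2) {
    vst <- vst_transform(counts)
    sub <- vst$values[genes, , drop = FALSE]
    if (any(apply(sub, 1, var) > 1e-12)) {
      pc <- pca_top_variable(sub, n_top = length(genes))
      sc <- pc$scores[, seq_len(min(2, ncol(pc$scores))), drop = FALSE]
      ref <- reference$labels$cluster[match(rownames(sc),
                                            reference$labels$sample)]
      sil <- mean(cluster::silhouette(ref, dist(sc))[, "sil_width"])
    }
  }
  structure(list(genes = genes, size = length(genes),
                 recapitulation = recap, path = path,
                 pca_silhouette = sil),
            class = "minimal_marker_set")
}

#' @export
print.minimal_marker_set <- function(x, ...) {
  cat(sprintf("<minimal_marker_set> %d genes, recapitulation=%s\n  %s\n",
              x$size, x$recapitulation, paste(x$genes, collapse = ", ")))
  invisible(x)
}

#' Tidy a minimal marker set
#' @param x A `minimal_marker_set`.
#' @param ... Unused.
#' @return Tibble with one row per panel gene.
#' @export
tidy.minimal_marker_set <- function(x, ...) {
  tibble::tibble(gene = x$genes, rank = seq_along(x$genes),
                 recapitulation = x$recapitulation)
}
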