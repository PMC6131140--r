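#' EPIC-style methylation probe filtering
#'
#' Drops probes with a detection p-value above `detect_p_max` in any sample
#' (or masks per-sample with `scope = "mask"`), probes with a common SNP
#' within 10 bp of the interrogated CpG, probes on the X/Y chromosomes, and
#' probes not located in both a promoter region (TSS/5'UTR/1st exon) and a
#' CpG island. Probe order is preserved and no value is altered.
#'
#' @param beta Probes x samples matrix of beta values in `[0, 1]`.
#' @param annotation Tibble with `probe`, `chrom`, `snp_10bp`, `promoter`,
#'   `island` covering every probe.
#' @param detection_p Probes x samples matrix of detection p-values.
#' @param detect_p_max Detection threshold (default 0.01).
#' @param scope `"any"` drops a probe failing detection in any sample;
#'   `"mask"` sets failing entries to `NA` and keeps the probe.
#' @return List with `beta` (filtered matrix), `annotation` (matching rows),
#'   and a `removed` tibble of per-rule counts.
#' @export
filter_probes <- function(beta, annotation, detection_p = NULL,
                          detect_p_max = 0.01, scope = c("any", "mask")) {
  scope <- match.arg(scope)
  beta <- as.matrix(beta)
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    validation_error("beta values outside [0, 1]")
  }
  probes <- rownames(beta) %||% as.character(seq_len(nrow(beta)))
  missing <- setdiff(probes, annotation$probe)
  if (length(missing)) validation_error("annotation missing for some probes")
  anno <- annotation[match(probes, annotation$probe), ]
  fail_detect <- if (is.null(detection_p)) {
    rep(FALSE, nrow(beta))
  } else {
    rowSums(as.matrix(detection_p) > detect_p_max) > 0
  }
  drop_snp <- anno$snp_10bp
  drop_xy <- anno$chrom %in% c("X", "Y")
  drop_region <- !(anno$promoter & anno$island)
  if (scope == "mask" && !is.null(detection_p)) {
    beta[as.matrix(detection_p) > detect_p_max] <- NA
    keep <- !(drop_snp | drop_xy | drop_region)
  } else {
    keep <- !(fail_detect | drop_snp | drop_xy | drop_region)
  }
  list(beta = beta[keep, , drop = FALSE],
       annotation = anno[keep, ],
       removed = tibble::tibble(
         rule = c("detection", "snp_10bp", "chrXY", "not_promoter_island"),
         n = c(sum(fail_detect), sum(drop_snp), sum(drop_xy),
               sum(drop_region))))
}

# Vectorized one-way ANOVA F across probes (rows) given group labels.
probe_anova <- function(beta, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(groups)
  idx <- split(seq_len(n), groups)
  gm <- sapply(idx, function(i) rowMeans(beta[, i, drop = FALSE]))
  gn <- lengths(idx)
  grand <- rowMeans(beta)
  ss_between <- rowSums(sweep(sweep(gm, 1, grand, `-`)^2, 2, gn, `*`))
  ss_total <- rowSums((beta - grand)^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df1 <- k - 1
  df2 <- n - k
  f <- (ss_between / df1) / (ss_within / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  delta <- apply(gm, 1, function(m) max(dist(m)))
  list(f = f, p = p, delta_beta = delta, group_means = gm)
}

#' Supervised differential-methylation probe selection
#'
#' Per-probe one-way ANOVA across the groups, Benjamini-Hochberg adjustment
#' over tested probes, and an effect-size gate on the maximum pairwise
#' group-mean beta difference.
#'
#' @param beta Probes x samples beta matrix.
#' @param groups Group label per sample (>= 2 groups, each >= 2 samples).
#' @param padj_max FDR threshold (default 0.01).
#' @param delta_beta_min Minimum group-mean beta difference (default 0.2).
#' @return A `supervised_selection` tibble of the selected probes (`probe`,
#'   `f`, `p`, `padj`, `delta_beta`); the full tested table is in
#'   `attr(, "all")`.
#' @export
supervised_probe_selection <- function(beta, groups, padj_max = 0.01,
                                       delta_beta_min = 0.2) {
  beta <- as.matrix(beta)
  groups <- as.factor(groups)
  assert_that(length(groups) == ncol(beta), "groups/sample mismatch")
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    abort("need >= 2 groups with >= 2 samples each",
          class = c("config_error", "meningiomics_error"))
  }
  a <- probe_anova(beta, groups)
  all_tab <- tibble::tibble(
    probe = rownames(beta) %||% as.character(seq_len(nrow(beta))),
    f = a$f, p = a$p, padj = bh_adjust(a$p), delta_beta = a$delta_beta)
  sel <- all_tab[!is.na(all_tab$padj) & all_tab$padj < padj_max &
                   all_tab$delta_beta > delta_beta_min, ]
  structure(sel, class = c("supervised_selection", class(sel)), all = all_tab)
}

#' Cluster samples on methylation beta values
#'
#' Manhattan (L1) distance between samples on a chosen probe subset, cut at
#' `k` clusters. Supervised mode takes an explicit probe set (typically from
#' [supervised_probe_selection()]) and uses Ward linkage; unsupervised mode
#' takes the `n_top` highest-variance probes (default 75) with configurable
#' linkage.
#'
#' @param beta Probes x samples beta matrix.
#' @param mode `"supervised"` or `"unsupervised"`.
#' @param probes Probe ids for supervised mode.
#' @param n_top Probe count for unsupervised mode (default 75).
#' @param k Number of clusters.
#' @param linkage Linkage for unsupervised mode (supervised is Ward).
#' @return A `subgroup_partition`.
#' @export
methylation_clustering <- function(beta, mode = c("supervised", "unsupervised"),
                                   probes = NULL, n_top = 75, k = 2,
                                   linkage = "ward.D2") {
  mode <- match.arg(mode)
  beta <- as.matrix(beta)
  if (mode == "supervised") {
    assert_that(!is.null(probes), "supervised mode needs a probe set")
    probes <- intersect(probes, rownames(beta))
    if (length(probes) < 2) validation_error("fewer than 2 probes after selection")
    sub <- beta[probes, , drop = FALSE]
    linkage <- "ward.D2"
  } else {
    n_top <- min(n_top, nrow(beta))
    sub <- beta[top_variable_genes(beta, n_top), , drop = FALSE]
  }
  if (all(apply(sub, 1, var) < 1e-15)) {
    abort("constant beta matrix: clustering is degenerate",
          class = c("degenerate_input_error", "meningiomics_error"))
  }
  d <- dist(t(sub), method = "manhattan")
  part <- hierarchical_partition(d, k = k,
                                 linkage = if (linkage == "ward.D2") "ward.D2" else linkage)
  part$n_top_genes <- nrow(sub)
  part
}
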