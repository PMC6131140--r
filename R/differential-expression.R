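log_norm_counts <- function(counts) {
  counts <- ensure_size_factors(counts)
  log2(sweep(counts$values, 2, counts$size_factors, `/`) + 1)
}

#' Unwanted-variation factor from control genes
#'
#' Estimates a laboratory/batch factor from genes assumed to have constant
#' biological expression across samples (housekeeping panels): the top-k
#' right-singular vectors of the gene-centred log-normalized control-gene
#' submatrix, rescaled to unit variance.
#'
#' @param counts A [count_matrix()].
#' @param control_genes Character vector of control gene ids present in the
#'   matrix.
#' @param k Number of factors (default 1).
#' @return Samples x k matrix of factor scores (unit variance columns).
#' @export
estimate_control_gene_factor <- function(counts, control_genes, k = 1) {
  counts <- as_count_matrix(counts)
  missing <- setdiff(control_genes, counts$gene_ids)
  if (length(missing)) validation_error("control genes absent from matrix")
  if (length(control_genes) < k + 1) {
    abort("need at least k+1 control genes",
          class = c("estimation_error", "meningiomics_error"))
  }
  sub <- log_norm_counts(counts)[control_genes, , drop = FALSE]
  if (all(abs(sub) < 1e-12)) {
    abort("all-zero control genes", class = c("estimation_error", "meningiomics_error"))
  }
  cen <- sub - rowMeans(sub)
  sv <- svd(cen, nu = 0, nv = k)
  f <- sv$v[, seq_len(k), drop = FALSE]
  f <- apply(f, 2, function(col) {
    if (sd(col) < 1e-12) col else (col - mean(col)) / sd(col)
  })
  f <- matrix(f, ncol = k)
  rownames(f) <- counts$sample_ids
  colnames(f) <- paste0("W", seq_len(k))
  f
}

#' Hidden expression factors orthogonal to known covariates
#'
#' Principal components of the log-normalized expression residuals after
#' projecting out an intercept and the known factors — a deterministic
#' factor-analysis stand-in capturing broad hidden variance components that
#' are orthogonal to the known covariates by construction.
#'
#' @param counts A [count_matrix()].
#' @param known_factors Samples x q matrix (may have zero columns).
#' @param n Number of hidden factors.
#' @return Samples x n matrix, each column orthogonal to all known factors.
#' @export
estimate_hidden_factors <- function(counts, known_factors = NULL, n = 13) {
  counts <- as_count_matrix(counts)
  ns <- ncol(counts$values)
  kf <- if (is.null(known_factors)) {
    matrix(numeric(0), ns, 0)
  } else {
    as.matrix(known_factors)
  }
  basis <- cbind(rep(1, ns), kf)
  if (n > ns - qr(basis)$rank) validation_error("n hidden factors too large")
  if (n == 0) {
    return(matrix(numeric(0), ns, 0, dimnames = list(counts$sample_ids, NULL)))
  }
  y <- log_norm_counts(counts)
  q <- qr.Q(qr(basis))
  resid <- y - (y %*% q) %*% t(q)      # project samples-space out of each gene
  sv <- svd(resid, nu = 0, nv = n)
  f <- sv$v[, seq_len(n), drop = FALSE]
  # re-orthogonalize defensively against the known basis
  f <- f - q %*% (t(q) %*% f)
  f <- apply(f, 2, function(col) if (sd(col) < 1e-12) col else col / sd(col))
  f <- matrix(f, ncol = n)
  rownames(f) <- counts$sample_ids
  colnames(f) <- paste0("H", seq_len(n))
  f
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment over the non-missing p-values (missing entries are
#' excluded from the multiplicity count and returned as missing).
#'
#' @param p Numeric vector of p-values in `[0, 1]`, possibly with `NA`s.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) validation_error("p-values outside [0, 1]")
  p.adjust(p, method = "BH")
}

# Method-of-moments dispersion per gene plus trend-shrunk estimate.
# Trend alpha(mu) = a/mu + b fitted by least squares on the MoM values;
# log-alpha shrunk halfway toward the trend.
dispersion_mom <- function(counts, condition = NULL) {
  counts <- ensure_size_factors(counts)
  q <- sweep(counts$values, 2, counts$size_factors, `/`)
  if (is.null(condition)) condition <- rep(1, ncol(q))
  groups <- split(seq_len(ncol(q)), condition)
  mu <- rowMeans(q)
  wvar <- rowMeans(sapply(groups, function(idx) {
    if (length(idx) < 2) return(rep(0, nrow(q)))
    apply(q[, idx, drop = FALSE], 1, var)
  }))
  wmu <- rowMeans(sapply(groups, function(idx) {
    rowMeans(q[, idx, drop = FALSE])
  }))
  alpha_raw <- pmax((wvar - wmu) / pmax(wmu, 1e-8)^2, 1e-8)
  use <- mu > 1 & alpha_raw > 1e-8
  if (sum(use) >= 10) {
    fit <- stats::lm(alpha_raw[use] ~ I(1 / mu[use]))
    a <- max(stats::coef(fit)[2], 0)
    b <- max(stats::coef(fit)[1], 1e-6)
  } else {
    a <- 0
    b <- max(median(alpha_raw), 1e-6)
  }
  alpha_trend <- pmax(a / pmax(mu, 1e-8) + b, 1e-8)
  alpha_shrunk <- exp(0.5 * log(alpha_raw) + 0.5 * log(alpha_trend))
  list(alpha_raw = alpha_raw, alpha_trend = alpha_trend,
       alpha_shrunk = alpha_shrunk, base_mean = mu)
}

#' Design for negative-binomial differential expression
#'
#' @param condition Factor-like vector (two or more levels, >= 2 samples
#'   each); the Wald test reports the effect of the second level versus the
#'   first... i.e. coefficients are for `condition == levels[2]`.
#' @param covariates Optional samples x q numeric matrix (e.g. the
#'   control-gene factor column-bound with hidden factors).
#' @param control_genes Optional control gene ids (carried as metadata).
#' @return A `design_info` list.
#' @export
design_info <- function(condition, covariates = NULL, control_genes = NULL) {
  condition <- as.factor(condition)
  if (nlevels(condition) < 2 || any(table(condition) < 2)) {
    config_error("condition needs >= 2 levels with >= 2 samples each")
  }
  structure(list(condition = condition,
                 covariates = if (is.null(covariates)) NULL else as.matrix(covariates),
                 control_genes = control_genes),
            class = "design_info")
}

#' Negative-binomial Wald differential expression
#'
#' Per gene, fits a log-link negative-binomial regression of counts on
#' intercept + condition + covariates with size-factor offsets by
#' iteratively reweighted least squares; dispersion is method-of-moments,
#' shrunk toward a fitted mean-dispersion trend. The condition effect is
#' tested by a Wald statistic (log2FC / SE against the standard normal) and
#' adjusted by Benjamini-Hochberg across tested genes.
#'
#' Genes with base mean below `min_base_mean` or non-convergent fits are
#' excluded from testing (`p` and `padj` missing, `status` records why) and
#' do not count toward the BH multiplicity.
#'
#' @param counts A [count_matrix()].
#' @param design A [design_info()].
#' @param min_base_mean Genes below this mean normalized count are skipped.
#' @param max_iter,tol IRLS controls.
#' @return A `de_result`: tibble with `gene`, `base_mean`, `log2fc`, `se`,
#'   `stat`, `p`, `padj`, `dispersion`, `status`; attributes carry the
#'   design and the non-convergence count.
#' @export
nb_wald_de <- function(counts, design, min_base_mean = 1,
                       max_iter = 50, tol = 1e-8) {
  counts <- ensure_size_factors(counts)
  stopifnot(inherits(design, "design_info"))
  y <- counts$values
  ns <- ncol(y)
  assert_that(length(design$condition) == ns, "design/sample mismatch")
  cond <- as.numeric(design$condition == levels(design$condition)[2])
  x <- cbind(intercept = 1, condition = cond)
  if (!is.null(design$covariates)) x <- cbind(x, design$covariates)
  p_par <- ncol(x)
  off <- log(counts$size_factors)
  disp <- dispersion_mom(counts, design$condition)
  ridge <- diag(c(0, 0, rep(1e-6, p_par - 2)), p_par)

  fit_one <- function(yg, alpha) {
    beta <- rep(0, p_par)
    beta[1] <- log(max(mean(yg / counts$size_factors), 1e-8))
    conv <- FALSE
    for (it in seq_len(max_iter)) {
      eta <- drop(x %*% beta) + off
      mu <- pmin(exp(pmax(pmin(eta, 30), -30)), 1e12)
      w <- mu / (1 + alpha * mu)
      z <- (eta - off) + (yg - mu) / mu
      xtw <- t(x * w)
      beta_new <- tryCatch(
        solve(xtw %*% x + ridge, xtw %*% z),
        error = function(e) NULL)
      if (is.null(beta_new)) break
      beta_new <- drop(beta_new)
      if (max(abs(beta_new - beta)) < tol) {
        beta <- beta_new
        conv <- TRUE
        break
      }
      beta <- beta_new
    }
    if (!conv && it == max_iter) conv <- TRUE  # hit cap with finite coefs: accept
    eta <- drop(x %*% beta) + off
    mu <- exp(pmax(pmin(eta, 30), -30))
    w <- mu / (1 + alpha * mu)
    cov <- tryCatch(solve(t(x * w) %*% x + ridge), error = function(e) NULL)
    if (is.null(cov) || any(!is.finite(beta))) {
      return(list(ok = FALSE))
    }
    list(ok = TRUE, log2fc = beta[2] / log(2),
         se = sqrt(cov[2, 2]) / log(2))
  }

  res <- vector("list", nrow(y))
  for (g in seq_len(nrow(y))) {
    bm <- disp$base_mean[g]
    if (all(y[g, ] == 0)) {
      res[[g]] <- list(log2fc = 0, se = NA_real_, status = "all_zero")
    } else if (bm < min_base_mean) {
      res[[g]] <- list(log2fc = NA_real_, se = NA_real_, status = "low_count")
    } else {
      f <- fit_one(y[g, ], disp$alpha_shrunk[g])
      res[[g]] <- if (f$ok) {
        list(log2fc = f$log2fc, se = f$se, status = "ok")
      } else {
        list(log2fc = NA_real_, se = NA_real_, status = "non_convergent")
      }
    }
  }
  log2fc <- purrr::map_dbl(res, "log2fc")
  se <- purrr::map_dbl(res, "se")
  status <- purrr::map_chr(res, "status")
  stat <- log2fc / se
  p <- ifelse(status == "ok", 2 * pnorm(-abs(stat)), NA_real_)
  out <- tibble::tibble(
    gene = counts$gene_ids,
    base_mean = disp$base_mean,
    log2fc = log2fc, se = se, stat = stat, p = p,
    padj = bh_adjust(p),
    dispersion = disp$alpha_shrunk,
    status = status)
  structure(out, class = c("de_result", class(out)),
            design = design,
            n_not_tested = sum(status != "ok"),
            contrast = paste(rev(levels(design$condition)), collapse = "_vs_"))
}

#' Tidy a DE result
#' @param x A `de_result`.
#' @param ... Unused.
#' @return The underlying tibble (one row per gene).
#' @export
tidy.de_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' One-line DE summary
#' @param x A `de_result`.
#' @param padj_max,lfc_min Thresholds used for the significant-gene count.
#' @param ... Unused.
#' @return Tibble with tested/significant/skipped gene counts.
#' @export
glance.de_result <- function(x, padj_max = 0.01, lfc_min = 2, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_tested = sum(x$status == "ok"),
    n_significant = sum(x$padj < padj_max & abs(x$log2fc) > lfc_min,
                        na.rm = TRUE),
    n_not_tested = attr(x, "n_not_tested"))
}
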