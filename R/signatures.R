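kl_div <- function(v, wh) {
  # generalized KL with 0 log 0 = 0
  sum(ifelse(v > 0, v * log(v / wh), 0) - v + wh)
}

nmf_kl_once <- function(v, k, max_iter = 1000, tol = 1e-6) {
  # v: channels x samples; multiplicative updates for generalized KL
  m <- nrow(v); n <- ncol(v)
  w <- matrix(runif(m * k, 0.1, 1), m, k)
  h <- matrix(runif(k * n, 0.1, 1), k, n)
  eps <- 1e-12
  obj_prev <- Inf
  for (it in seq_len(max_iter)) {
    wh <- w %*% h + eps
    w <- w * ((v / wh) %*% t(h)) / pmax(matrix(rowSums(h), m, k, byrow = TRUE), eps)
    wh <- w %*% h + eps
    h <- h * (t(w) %*% (v / wh)) / pmax(matrix(colSums(w), k, n), eps)
    if (it %% 10 == 0) {
      obj <- kl_div(v, w %*% h + eps)
      if (abs(obj_prev - obj) < tol * (abs(obj_prev) + eps)) break
      obj_prev <- obj
    }
  }
  scale <- colSums(w)
  w <- sweep(w, 2, pmax(scale, eps), `/`)
  h <- sweep(h, 1, scale, `*`)
  list(w = w, h = h, objective = kl_div(v, w %*% h + eps))
}

cosine_sim <- function(a, b) {
  num <- sum(a * b)
  den <- sqrt(sum(a^2)) * sqrt(sum(b^2))
  if (den == 0) 0 else num / den
}

all_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in all_perms(k - 1)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

# Optimal matching of columns of w2 onto columns of w1 by total cosine
# similarity; exact enumeration (k is small).
match_signatures <- function(w1, w2) {
  k <- ncol(w1)
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    sim[i, j] <- cosine_sim(w1[, i], w2[, j])
  }
  best <- NULL; best_val <- -Inf
  for (p in all_perms(k)) {
    val <- sum(sim[cbind(seq_len(k), p)])
    if (val > best_val) {
      best_val <- val
      best <- p
    }
  }
  list(perm = best, cosines = sim[cbind(seq_len(k), best)])
}

#' Extract mutational signatures by KL non-negative matrix factorization
#'
#' Decomposes a samples x 96 trinucleotide catalogue into `k` signature
#' probability vectors and per-sample exposures, minimizing the generalized
#' Kullback-Leibler divergence with multiplicative updates. The best of
#' `n_restarts` random initializations (by objective) is returned;
#' per-signature stability is the mean cosine similarity of the matched
#' signature across all restarts.
#'
#' @param catalogue Samples x 96 non-negative count matrix in canonical
#'   channel order ([trinucleotide_channels()]).
#' @param k Number of signatures (`k <= min(n_samples, 96)`).
#' @param n_restarts Random restarts (default 50).
#' @param seed Seed controlling the restarts.
#' @param max_iter Update iterations per restart.
#' @return A `signature_set`: list with `signatures` (k x 96, rows sum to
#'   1), `exposures` (samples x k), `stability` (length k), `objective`
#'   (best KL), `k`.
#' @export
extract_signatures <- function(catalogue, k, n_restarts = 50, seed = 1,
                               max_iter = 1000) {
  catalogue <- as.matrix(catalogue)
  if (any(catalogue < 0)) validation_error("negative catalogue counts")
  if (sum(catalogue) == 0) validation_error("empty catalogue")
  if (k > min(nrow(catalogue), 96)) validation_error("k exceeds sample count")
  v <- t(catalogue)                     # channels x samples
  runs <- with_seed(derive_seed(seed, "nmf"), {
    lapply(seq_len(n_restarts), function(i) nmf_kl_once(v, k, max_iter))
  })
  objs <- vapply(runs, `[[`, numeric(1), "objective")
  best <- runs[[which.min(objs)]]
  stab <- matrix(NA_real_, n_restarts, k)
  for (i in seq_len(n_restarts)) {
    stab[i, ] <- match_signatures(best$w, runs[[i]]$w)$cosines
  }
  signatures <- t(best$w)
  rownames(signatures) <- paste0("S", seq_len(k))
  colnames(signatures) <- colnames(catalogue) %||% trinucleotide_channels()
  exposures <- t(best$h)
  rownames(exposures) <- rownames(catalogue)
  colnames(exposures) <- rownames(signatures)
  structure(list(signatures = signatures, exposures = exposures,
                 stability = colMeans(stab), objective = min(objs), k = k),
            class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> k=%d, KL objective %.2f, stability %s\n",
              x$k, x$objective,
              paste(sprintf("%.3f", x$stability), collapse = "/")))
  invisible(x)
}

#' Tidy a signature set
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return Long tibble: `signature`, `channel`, `probability`.
#' @export
tidy.signature_set <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$signatures,
                                        stringsAsFactors = FALSE)) |>
    setNames(c("signature", "channel", "probability")) |>
    tibble::as_tibble()
}

#' One-line signature-set summary
#' @param x A `signature_set`.
#' @param ... Unused.
#' @return Tibble with k, objective, and minimum stability.
#' @export
glance.signature_set <- function(x, ...) {
  tibble::tibble(k = x$k, kl_objective = x$objective,
                 min_stability = min(x$stability))
}

#' Attribute catalogue counts to reference signatures
#'
#' Per-sample non-negative least squares fit of the 96-channel counts onto
#' fixed reference signature profiles.
#'
#' @param catalogue Samples x 96 count matrix.
#' @param reference_signatures k x 96 matrix of probability rows.
#' @return Samples x k non-negative exposure matrix.
#' @export
attribute_exposures <- function(catalogue, reference_signatures) {
  catalogue <- as.matrix(catalogue)
  p <- as.matrix(reference_signatures)
  assert_that(ncol(catalogue) == ncol(p), "channel dimensions disagree")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-6)) {
    validation_error("reference signatures must be probability vectors")
  }
  a <- t(p)                              # 96 x k
  e <- t(apply(catalogue, 1, function(y) pracma::lsqnonneg(a, y)$x))
  e <- matrix(e, nrow = nrow(catalogue))
  rownames(e) <- rownames(catalogue)
  colnames(e) <- rownames(p) %||% paste0("S", seq_len(nrow(p)))
  e
}

#' Choose the number of signatures
#'
#' Runs [extract_signatures()] for each k and scores the
#' stability-reconstruction trade-off: the selected k is the largest k whose
#' minimum signature stability stays above `stability_min`, among those
#' improving reconstruction over k - 1 by at least `improve_min` (relative
#' KL decrease).
#'
#' @param catalogue Samples x 96 count matrix.
#' @param k_range Candidate signature numbers.
#' @param n_restarts,seed Passed to [extract_signatures()].
#' @param stability_min,improve_min Selection thresholds.
#' @return List with `k_star` and a `profile` tibble (k, objective,
#'   min_stability).
#' @export
select_n_signatures <- function(catalogue, k_range = 1:4, n_restarts = 20,
                                seed = 1, stability_min = 0.85,
                                improve_min = 0.2) {
  fits <- lapply(k_range, function(k) {
    extract_signatures(catalogue, k, n_restarts, seed = seed + k)
  })
  prof <- tibble::tibble(
    k = k_range,
    objective = vapply(fits, `[[`, numeric(1), "objective"),
    min_stability = vapply(fits, function(f) min(f$stability), numeric(1)))
  k_star <- k_range[1]
  for (i in seq_along(k_range)[-1]) {
    rel_gain <- (prof$objective[i - 1] - prof$objective[i]) /
      max(prof$objective[i - 1], 1e-9)
    if (prof$min_stability[i] >= stability_min && rel_gain >= improve_min) {
      k_star <- k_range[i]
    } else {
      break
    }
  }
  list(k_star = k_star, profile = prof, fits = fits)
}
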