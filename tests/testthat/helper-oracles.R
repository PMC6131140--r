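# Independent oracles used by the tests. These are deliberately naive,
# loop-based implementations kept separate from the package internals.

# Poisson deviance distance, element-by-element loops
oracle_poisson_distance <- function(m, s) {
  n <- ncol(m)
  d <- matrix(0, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    if (a == b) next
    acc <- 0
    for (g in seq_len(nrow(m))) {
      mu_a <- s[a] * (m[g, a] + m[g, b]) / (s[a] + s[b])
      mu_b <- s[b] * (m[g, a] + m[g, b]) / (s[a] + s[b])
      dev <- function(x, mu) {
        (if (x > 0) x * log(x / mu) else 0) - (x - mu)
      }
      acc <- acc + dev(m[g, a], mu_a) + dev(m[g, b], mu_b)
    }
    d[a, b] <- sqrt(max(acc, 0))
  }
  d
}

# Benjamini-Hochberg by the definitional max-min step-up formula
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(sapply(i:n, function(j) ranked[j] * n / j), 1)
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Upper-tail hypergeometric by explicit enumeration of all draws of B
oracle_hypergeom <- function(size_a, size_b, overlap, universe) {
  genes <- seq_len(universe)
  a_set <- genes[seq_len(size_a)]
  draws <- utils::combn(universe, size_b, simplify = FALSE)
  mean(vapply(draws, function(b) length(intersect(a_set, b)) >= overlap,
              logical(1)))
}

# Log-rank chi-square via explicit 2x2 tables at event times
oracle_logrank_chi2 <- function(time, event, g1) {
  o1 <- e1 <- v <- 0
  for (t in sort(unique(time[event]))) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & g1)
    d <- sum(time == t & event)
    d1 <- sum(time == t & event & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (v <= 0) 0 else (o1 - e1)^2 / v
}

# small NB cohort used by several tests
tiny_cohort <- function(seed = 42, n_genes = 300, ...) {
  simulate_expression(cohort_config(seed = seed, n_genes = n_genes, ...))
}
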