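#' Upper-tail hypergeometric overlap test
#'
#' Probability of observing at least `overlap` shared genes between a set of
#' size `size_a` and a set of size `size_b` drawn from a universe of
#' `universe` genes: `P(X >= overlap)` with
#' `X ~ Hypergeometric(universe, size_a, size_b)`.
#'
#' @param size_a,size_b Set sizes.
#' @param overlap Observed intersection size.
#' @param universe Universe size.
#' @return A single p-value.
#' @export
hypergeometric_overlap <- function(size_a, size_b, overlap, universe) {
  ok <- overlap >= 0 && size_a >= 0 && size_b >= 0 &&
    overlap <= min(size_a, size_b) && max(size_a, size_b) <= universe
  if (!ok) validation_error("inconsistent set/universe sizes")
  phyper(overlap - 1, size_a, universe - size_a, size_b, lower.tail = FALSE)
}

#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (set name, description, members per line).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t")
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, character(1), 1))
}

#' Functional class scoring of gene sets with hallmark aggregation
#'
#' Scores each gene set by the mean absolute per-gene statistic of its
#' members and obtains a permutation p-value from `n_perm` same-size random
#' gene draws (smoothed as `(r + 1) / (n_perm + 1)`); p-values are BH
#' adjusted across sets. Sets with less than `min_coverage` of their members
#' covered by the statistics are skipped. When a hallmark map is supplied,
#' per-hallmark p-values combine member-set p-values by Fisher's method.
#'
#' @param gene_stats Named numeric vector of per-gene statistics (e.g. Wald
#'   statistics from [nb_wald_de()]).
#' @param collection Named list of gene-id vectors, or a list with `sets`
#'   and `hallmark_map` (named character vector set -> hallmark).
#' @param n_perm Number of permutations (> 0).
#' @param seed Seed for the permutation draws.
#' @param min_coverage Minimum fraction of set members with statistics.
#' @return An `enrichment_result`: tibble (`set`, `size`, `score`, `p`,
#'   `padj`, `hallmark`) with a `hallmarks` tibble attribute when a map was
#'   given.
#' @export
functional_class_scoring <- function(gene_stats, collection, n_perm = 10000,
                                     seed = 1, min_coverage = 0.8) {
  if (n_perm <= 0) config_error("permutations required (n_perm > 0)")
  sets <- if (is.list(collection) && !is.null(collection$sets)) {
    collection$sets
  } else {
    collection
  }
  hallmark_map <- if (is.list(collection) && !is.null(collection$hallmark_map)) {
    collection$hallmark_map
  }
  if (length(sets) == 0) validation_error("empty gene-set collection")
  stats_abs <- abs(gene_stats[!is.na(gene_stats)])
  universe <- names(stats_abs)
  rows <- with_seed(derive_seed(seed, "fcs"), {
    purrr::imap(sets, function(members, name) {
      members <- unique(members)
      present <- intersect(members, universe)
      if (length(present) < min_coverage * length(members) ||
          length(present) == 0) {
        return(NULL)
      }
      obs <- mean(stats_abs[present])
      sz <- length(present)
      perm <- replicate(n_perm, mean(stats_abs[sample.int(length(stats_abs), sz)]))
      tibble::tibble(set = name, size = sz, score = obs,
                     p = (sum(perm >= obs) + 1) / (n_perm + 1))
    })
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) validation_error("no set met the coverage requirement")
  out$padj <- bh_adjust(out$p)
  out$hallmark <- if (is.null(hallmark_map)) NA_character_ else
    unname(hallmark_map[out$set])
  hall <- NULL
  if (!is.null(hallmark_map)) {
    hall <- out |>
      dplyr::filter(!is.na(.data$hallmark)) |>
      dplyr::group_by(hallmark = .data$hallmark) |>
      dplyr::summarise(
        n_sets = dplyr::n(),
        p = {
          x2 <- -2 * sum(log(pmax(.data$p, 1e-300)))
          pchisq(x2, df = 2 * dplyr::n(), lower.tail = FALSE)
        },
        .groups = "drop")
    hall$padj <- bh_adjust(hall$p)
  }
  out <- dplyr::arrange(out, .data$p)
  structure(out, class = c("enrichment_result", class(out)),
            hallmarks = hall)
}

#' Per-hallmark aggregated enrichment
#' @param x An `enrichment_result`.
#' @return Tibble of hallmark-level Fisher-combined p-values (or `NULL`).
#' @export
hallmark_summary <- function(x) attr(x, "hallmarks")
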