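#' Expression count matrix container
#'
#' A light wrapper around a genes-by-samples integer matrix carrying gene and
#' sample identifiers plus (optionally) median-of-ratios size factors. All
#' expression stages of the pipeline consume this container.
#'
#' @param values Non-negative numeric matrix, genes in rows, samples in
#'   columns. Dimnames are used as identifiers when `gene_ids`/`sample_ids`
#'   are not given.
#' @param gene_ids,sample_ids Optional character identifiers; must be unique.
#' @param size_factors Optional positive per-sample scalars.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(values, gene_ids = NULL, sample_ids = NULL,
                         size_factors = NULL) {
  values <- as.matrix(values)
  if (any(values < 0)) validation_error("count matrix has negative entries")
  gene_ids <- gene_ids %||% rownames(values) %||% sprintf("g%04d", seq_len(nrow(values)))
  sample_ids <- sample_ids %||% colnames(values) %||% sprintf("s%03d", seq_len(ncol(values)))
  assert_that(length(gene_ids) == nrow(values), "gene_ids length mismatch")
  assert_that(length(sample_ids) == ncol(values), "sample_ids length mismatch")
  assert_that(!anyDuplicated(gene_ids) && !anyDuplicated(sample_ids),
              "gene and sample ids must be unique")
  if (!is.null(size_factors)) {
    assert_that(length(size_factors) == ncol(values) && all(size_factors > 0),
                "size_factors must be positive, one per sample")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
                 size_factors = size_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d samples; size factors %s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$size_factors)) "unset" else "set"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$values)

#' Coerce a long tibble to a count matrix
#'
#' Accepts tidy long data (`gene`, `sample`, `count` columns) and pivots it
#' into the matrix container used by the expression stages.
#'
#' @param data A data frame with columns `gene`, `sample`, `count`.
#' @return A `count_matrix`.
#' @export
as_count_matrix <- function(data) {
  if (inherits(data, "count_matrix")) return(data)
  if (is.matrix(data)) return(count_matrix(data))
  assert_that(all(c("gene", "sample", "count") %in% names(data)),
              "need columns gene, sample, count")
  wide <- tidyr::pivot_wider(data, id_cols = "gene", names_from = "sample",
                             values_from = "count", values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$gene
  count_matrix(m)
}

#' Tidy a count matrix into long format
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `sample`, `count`.
#' @export
tidy.count_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$values, stringsAsFactors = FALSE),
                    .name_repair = "minimal") |>
    setNames(c("gene", "sample", "count")) |>
    tibble::as_tibble()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
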