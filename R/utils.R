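#' @importFrom rlang abort warn %||% .data
#' @importFrom stats median var sd quantile rnorm runif rexp rpois rnbinom
#'   rbinom pnorm pchisq phyper p.adjust prcomp hclust cutree dist as.dist
#'   setNames complete.cases qnorm
#' @importFrom utils head modifyList
NULL

# Per-stage seeds derived from one root seed so pipeline stages are
# individually reproducible. Kept below 2^31 - 1.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729 + 17) %% 2147483647L)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_that <- function(ok, msg, class = "meningiomics_error") {
  if (!isTRUE(ok)) abort(msg, class = class)
  invisible(TRUE)
}

config_error <- function(msg) abort(msg, class = c("config_error", "meningiomics_error"))
validation_error <- function(msg) abort(msg, class = c("validation_error", "meningiomics_error"))

#' Adjusted Rand index between two partitions
#'
#' Convenience wrapper used throughout the pipeline as the "recapitulation"
#' criterion: ARI equal to 1 means the two labelings agree exactly up to a
#' permutation of cluster names.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
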