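#' Write a simulated cohort to plain-text files
#'
#' Emits the standard tabular formats: counts TSV (genes x samples),
#' survival CSV, beta + probe annotation TSVs, SEG-like segment TSV,
#' catalogue TSV (96 canonical channels x samples), and a ground-truth JSON.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param outdir Directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_cohort <- function(cohort, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(outdir, "counts.tsv"),
             survival = file.path(outdir, "survival.csv"),
             beta = file.path(outdir, "beta.tsv"),
             annotation = file.path(outdir, "probe_annotation.tsv"),
             segments = file.path(outdir, "segments.tsv"),
             catalogue = file.path(outdir, "catalogue.tsv"),
             truth = file.path(outdir, "ground_truth.json"))
  write_matrix_tsv(cohort$counts$values, paths["counts"], "gene")
  utils::write.csv(cohort$survival, paths["survival"], row.names = FALSE)
  write_matrix_tsv(cohort$methylation$beta, paths["beta"], "probe")
  utils::write.table(cohort$methylation$annotation, paths["annotation"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$segments, paths["segments"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(t(cohort$catalogue), paths["catalogue"], "channel")
  truth <- cohort$truth
  truth$true_exposures <- as.data.frame(truth$true_exposures)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a counts TSV into a count matrix
#' @param path TSV with a `gene` id column then one column per sample.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(path) count_matrix(read_matrix_tsv(path))

#' Read a survival CSV
#' @param path CSV with `sample`, `time_days`, `event`, `group`.
#' @return Tibble of survival records.
#' @export
read_survival_csv <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path))
  df$event <- as.logical(df$event)
  validate_survival(df)
}

#' Read a beta-value TSV
#' @param path TSV with a `probe` id column then one column per sample.
#' @return Probes x samples matrix.
#' @export
read_beta_tsv <- function(path) read_matrix_tsv(path)

#' Read a probe-annotation TSV
#' @param path TSV with `probe`, `chrom`, `pos`, `snp_10bp`, `promoter`, `island`.
#' @return Tibble.
#' @export
read_annotation_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path,
                                      colClasses = c(chrom = "character")))
}

#' Read a SEG-like segment TSV
#' @param path TSV with `sample`, `chrom`, `start`, `end`, `total_cn`, `ploidy`.
#' @return Validated segment tibble.
#' @export
read_segments_tsv <- function(path) {
  seg <- tibble::as_tibble(utils::read.delim(path,
                                             colClasses = c(chrom = "character")))
  validate_segments(seg)
}

#' Read a 96-channel catalogue TSV
#' @param path TSV with a `channel` column (canonical order) then samples.
#' @return Samples x 96 count matrix.
#' @export
read_catalogue_tsv <- function(path) t(read_matrix_tsv(path))
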