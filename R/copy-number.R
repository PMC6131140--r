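#' Ploidy-adjusted aggregate copy-number profile
#'
#' Divides the genome into fixed-width bins (default 10 kb) and, per sample
#' per bin, records the relative copy-number change of the segment covering
#' the bin midpoint: `total_cn - ploidy` on the additive scale (zero means
#' no change) or `log2(total_cn / ploidy)` on the ratio scale. Bins not
#' covered by any segment in a sample contribute 0. Across samples the
#' median and first/third quartiles are reported per bin.
#'
#' @param segments Tibble (`sample`, `chrom`, `start`, `end`, `total_cn`,
#'   `ploidy`), 1-based inclusive, non-overlapping per sample/chromosome.
#' @param bin Bin width in bp (default 10000).
#' @param scale `"difference"` (`cn - ploidy`) or `"log2ratio"`.
#' @param genome Optional tibble (`chrom`, `length`); defaults to the
#'   maximum segment end per chromosome.
#' @return An `aggregate_profile` tibble: `chrom`, `start`, `end`, `median`,
#'   `q1`, `q3`.
#' @export
aggregate_profile <- function(segments, bin = 10000,
                              scale = c("difference", "log2ratio"),
                              genome = NULL) {
  scale <- match.arg(scale)
  validate_segments(segments)
  if (is.null(genome)) {
    genome <- segments |>
      dplyr::group_by(chrom = .data$chrom) |>
      dplyr::summarise(length = max(.data$end), .groups = "drop")
  }
  samples <- unique(segments$sample)
  out <- purrr::map_dfr(seq_len(nrow(genome)), function(ci) {
    chrom <- genome$chrom[ci]
    starts <- seq(1, genome$length[ci], by = bin)
    mids <- starts + floor(bin / 2)
    rel <- matrix(0, length(starts), length(samples))
    for (si in seq_along(samples)) {
      seg <- segments[segments$sample == samples[si] &
                        segments$chrom == chrom, ]
      if (nrow(seg) == 0) next
      seg <- seg[order(seg$start), ]
      idx <- findInterval(mids, seg$start)
      covered <- idx >= 1 & mids <= seg$end[pmax(idx, 1)]
      vals <- rep(0, length(mids))
      if (scale == "difference") {
        vals[covered] <- seg$total_cn[idx[covered]] - seg$ploidy[idx[covered]]
      } else {
        vals[covered] <- log2(pmax(seg$total_cn[idx[covered]], 0.5) /
                                seg$ploidy[idx[covered]])
      }
      rel[, si] <- vals
    }
    qs <- t(apply(rel, 1, quantile, probs = c(0.25, 0.5, 0.75), names = FALSE))
    tibble::tibble(chrom = chrom, start = starts,
                   end = pmin(starts + bin - 1, genome$length[ci]),
                   q1 = qs[, 1], median = qs[, 2], q3 = qs[, 3])
  })
  structure(out, class = c("aggregate_profile", class(out)),
            bin = bin, scale = scale, n_samples = length(samples))
}

#' Rule-based copy-number driver calling
#'
#' Flags focal (< 1 Mb) events over known cancer genes: homozygous deletions
#' (`total_cn == 0`) over tumor suppressors, and oncogene amplifications
#' exceeding 5 copies on diploid backgrounds (ploidy <= 3) or 9 copies on
#' tetraploid backgrounds (ploidy > 3). Gene-segment overlap is >= 1 bp;
#' focality is judged on segment length.
#'
#' @param segments Segment tibble as in [aggregate_profile()] (one or many
#'   samples).
#' @param genes Tibble (`gene`, `chrom`, `start`, `end`, `role`) with `role`
#'   in `{"TSG", "oncogene"}`.
#' @param focal_max Maximum driver segment length in bp (default 1e6).
#' @return Tibble of calls: `sample`, `gene`, `type`, `total_cn`, `ploidy`,
#'   `seg_start`, `seg_end`, `focal`.
#' @export
call_cnv_drivers <- function(segments, genes, focal_max = 1e6) {
  validate_segments(segments)
  if (!all(genes$role %in% c("TSG", "oncogene"))) {
    validation_error("unknown gene role (must be TSG or oncogene)")
  }
  calls <- list()
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    hit <- segments[segments$chrom == g$chrom &
                      segments$start <= g$end & segments$end >= g$start, ]
    if (nrow(hit) == 0) next
    hit$seg_len <- hit$end - hit$start + 1
    focal <- hit$seg_len < focal_max
    if (g$role == "TSG") {
      sel <- hit$total_cn == 0 & focal
      type <- "homozygous_deletion"
    } else {
      thr <- ifelse(hit$ploidy > 3, 9, 5)
      sel <- hit$total_cn > thr & focal
      type <- "amplification"
    }
    if (any(sel)) {
      h <- hit[sel, ]
      calls[[length(calls) + 1]] <- tibble::tibble(
        sample = h$sample, gene = g$gene, type = type,
        total_cn = h$total_cn, ploidy = h$ploidy,
        seg_start = h$start, seg_end = h$end, focal = TRUE)
    }
  }
  if (length(calls) == 0) {
    return(tibble::tibble(sample = character(), gene = character(),
                          type = character(), total_cn = numeric(),
                          ploidy = numeric(), seg_start = numeric(),
                          seg_end = numeric(), focal = logical()))
  }
  dplyr::distinct(dplyr::bind_rows(calls))
}

#' Flag truncating events in tumor suppressors
#'
#' Emits variants whose consequence is disruptive — nonsense, frameshift,
#' essential splice site, or a rearrangement breakpoint — in an established
#' tumor suppressor as truncating driver calls. Unrecognized consequence
#' terms are skipped with a warning.
#'
#' @param variants Tibble with `sample`, `gene`, `consequence` columns
#'   (MAF-like).
#' @param tsg_list Character vector of tumor-suppressor gene symbols.
#' @return Tibble of calls: `sample`, `gene`, `type = "truncating"`,
#'   `consequence`.
#' @export
flag_truncating_events <- function(variants, tsg_list) {
  assert_that(all(c("sample", "gene", "consequence") %in% names(variants)),
              "variant table needs sample, gene, consequence columns")
  truncating <- c("nonsense", "frameshift", "essential_splice",
                  "rearrangement_breakpoint")
  benign <- c("missense", "synonymous", "intronic", "utr", "inframe_indel",
              "splice_region", "upstream", "downstream")
  unknown <- setdiff(unique(variants$consequence), c(truncating, benign))
  if (length(unknown)) {
    warn(paste("skipping unrecognized consequence terms:",
               paste(unknown, collapse = ", ")))
  }
  hit <- variants[variants$consequence %in% truncating &
                    variants$gene %in% tsg_list, ]
  tibble::tibble(sample = hit$sample, gene = hit$gene, type = "truncating",
                 consequence = hit$consequence)
}
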