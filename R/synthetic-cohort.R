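#' Configuration for a synthetic multi-omic meningioma cohort
#'
#' Builds and validates the parameter set for the cohort generator. Defaults
#' mirror the structure of an anaplastic-meningioma study cohort: two latent
#' expression subgroups (12 + 13 samples) separated by a handful of
#' large-effect marker transcripts, a laboratory batch factor with stably
#' expressed control genes, strongly subgroup-linked survival (true hazard
#' ratio 17 for the poor-prognosis group), planted differentially methylated
#' promoter/island probes, focal copy-number drivers on diploid or
#' tetraploid backgrounds, and trinucleotide mutation catalogues mixed from
#' known signature profiles.
#'
#' @param n_c1,n_c2 Samples in subgroup C1 (poor prognosis) and C2.
#' @param n_genes Total genes simulated.
#' @param n_markers Planted subgroup marker genes (up-regulated in C1).
#' @param marker_lfc log2 fold change of markers in C1.
#' @param dispersion Negative-binomial dispersion alpha (Var = mu + alpha mu^2);
#'   scalar or per-gene vector.
#' @param n_batches Number of laboratory batches (random assignment unless
#'   `batch_confounded`).
#' @param batch_lfc log2 fold change applied to all non-control genes in the
#'   second batch (0 disables the batch effect).
#' @param batch_confounded If `TRUE`, batch is aligned with subgroup to
#'   stress-test the unwanted-variation correction.
#' @param n_control_genes Stably expressed control genes (no subgroup or
#'   batch multiplier), analogous to housekeeping panels such as
#'   RPL37A/EIF2B1/PGK1 used in transcript assays.
#' @param surv_baseline_rate Baseline exponential event rate (events/day) in C2.
#' @param surv_hr True hazard ratio for C1 versus C2.
#' @param censor_time Administrative censoring time in days.
#' @param n_probes,n_diff_probes,delta_beta_true,m_sd Methylation array
#'   parameters: probe count, planted differential probes, true group beta
#'   difference, and Gaussian noise SD on the logit (M-value) scale.
#' @param genome Tibble of chromosome lengths (`chrom`, `length`) for the
#'   copy-number generator.
#' @param driver_genes Tibble (`gene`, `chrom`, `start`, `end`, `role`) of
#'   cancer genes; `role` is `"TSG"` or `"oncogene"`.
#' @param n_segment_samples Samples in the copy-number branch.
#' @param tetraploid_fraction Fraction of tetraploid genomes.
#' @param signature_profiles k x 96 matrix of signature probability vectors
#'   (rows sum to 1); default two well-separated profiles.
#' @param exposure_mean Mean total mutations per sample in the catalogue
#'   generator.
#' @param n_catalogue_samples Samples in the mutational-catalogue branch.
#' @param seed Root seed; every generator derives its own stream from it.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_c1 = 12, n_c2 = 13,
                          n_genes = 2000, n_markers = 6, marker_lfc = 5,
                          dispersion = 0.1,
                          n_batches = 2, batch_lfc = 0, batch_confounded = FALSE,
                          n_control_genes = 7,
                          surv_baseline_rate = 4e-4, surv_hr = 17,
                          censor_time = 1825,
                          n_probes = 2000, n_diff_probes = 50,
                          delta_beta_true = 0.3, m_sd = 0.5,
                          genome = default_genome(),
                          driver_genes = default_driver_genes(),
                          n_segment_samples = n_c1 + n_c2,
                          tetraploid_fraction = 0.2,
                          signature_profiles = default_signature_profiles(),
                          exposure_mean = 1000,
                          n_catalogue_samples = n_c1 + n_c2,
                          seed = 1L) {
  cfg <- list(n_c1 = n_c1, n_c2 = n_c2, n_genes = n_genes,
              n_markers = n_markers, marker_lfc = marker_lfc,
              dispersion = dispersion, n_batches = n_batches,
              batch_lfc = batch_lfc, batch_confounded = batch_confounded,
              n_control_genes = n_control_genes,
              surv_baseline_rate = surv_baseline_rate, surv_hr = surv_hr,
              censor_time = censor_time, n_probes = n_probes,
              n_diff_probes = n_diff_probes,
              delta_beta_true = delta_beta_true, m_sd = m_sd,
              genome = tibble::as_tibble(genome),
              driver_genes = tibble::as_tibble(driver_genes),
              n_segment_samples = n_segment_samples,
              tetraploid_fraction = tetraploid_fraction,
              signature_profiles = signature_profiles,
              exposure_mean = exposure_mean,
              n_catalogue_samples = n_catalogue_samples,
              seed = as.integer(seed))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  counts <- c(cfg$n_c1, cfg$n_c2, cfg$n_genes, cfg$n_markers, cfg$n_probes,
              cfg$n_diff_probes, cfg$n_control_genes)
  if (any(counts < 0)) config_error("all counts must be >= 0")
  if (cfg$n_c1 + cfg$n_c2 < 4) config_error("need at least 4 samples")
  if (cfg$n_markers + cfg$n_control_genes > cfg$n_genes) {
    config_error("n_markers + n_control_genes exceeds n_genes")
  }
  if (cfg$n_diff_probes > cfg$n_probes) config_error("n_diff_probes > n_probes")
  if (any(cfg$dispersion < 0)) config_error("dispersion must be >= 0")
  if (cfg$surv_baseline_rate <= 0 || cfg$surv_hr <= 0) {
    config_error("survival rates must be positive")
  }
  if (cfg$delta_beta_true < 0 || cfg$delta_beta_true >= 1) {
    config_error("delta_beta_true must lie in [0, 1)")
  }
  base_beta <- 0.3
  if (cfg$delta_beta_true > 0 && base_beta + cfg$delta_beta_true >= 1) {
    config_error("delta_beta_true pushes group means outside (0, 1)")
  }
  p <- cfg$signature_profiles
  if (!is.matrix(p) || ncol(p) != 96 || any(p < 0) ||
      any(abs(rowSums(p) - 1) > 1e-9)) {
    config_error("signature_profiles must be a k x 96 matrix of probability rows")
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(paste0("<cohort_config> %d+%d samples, %d genes (%d markers @ lfc %.1f),\n",
                     "  %d probes (%d diff @ delta-beta %.2f), true HR %.1f, seed %d\n"),
              x$n_c1, x$n_c2, x$n_genes, x$n_markers, x$marker_lfc,
              x$n_probes, x$n_diff_probes, x$delta_beta_true, x$surv_hr, x$seed))
  invisible(x)
}

#' Default synthetic genome (three chromosomes)
#' @return Tibble with `chrom` and `length` (bp).
#' @export
default_genome <- function() {
  tibble::tibble(chrom = c("1", "2", "3"),
                 length = c(100e6, 80e6, 60e6))
}

#' Default synthetic cancer-gene table
#'
#' Coordinates are synthetic; gene symbols are meningioma-relevant so that
#' driver calls read naturally (NF2/CDKN2A/ARID1A tumor suppressors, an
#' EGFR-like oncogene).
#' @return Tibble (`gene`, `chrom`, `start`, `end`, `role`).
#' @export
default_driver_genes <- function() {
  tibble::tibble(
    gene  = c("NF2", "CDKN2A", "ARID1A", "EGFR", "MYCL"),
    chrom = c("2", "1", "1", "3", "3"),
    start = c(30e6, 21.9e6, 27e6, 15e6, 40e6),
    end   = c(30.1e6, 21.93e6, 27.09e6, 15.19e6, 40.01e6),
    role  = c("TSG", "TSG", "TSG", "oncogene", "oncogene"))
}

#' Canonical 96-channel trinucleotide ordering
#'
#' Six pyrimidine substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) by 16
#' flanking contexts, flanks ordered A, C, G, T; e.g. `"A[C>A]A"`.
#' @return Character vector of length 96.
#' @export
trinucleotide_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  flank <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(flank, flank, function(l, r) paste0(l, "[", s, "]", r))))
  }))
}

#' Default pair of well-separated signature profiles
#'
#' Signature A loads on C>T channels (an ageing-like, deamination-dominated
#' spectrum); signature B on T>C channels. Built deterministically.
#' @return 2 x 96 matrix with rows summing to 1, rownames `SigA`/`SigB`.
#' @export
default_signature_profiles <- function() {
  ch <- trinucleotide_channels()
  a <- rep(0.05, 96); a[grepl("C>T", ch, fixed = TRUE)] <- 4
  a[grepl("\\[C>T\\]G", ch)] <- 12
  b <- rep(0.05, 96); b[grepl("T>C", ch, fixed = TRUE)] <- 5
  p <- rbind(SigA = a / sum(a), SigB = b / sum(b))
  colnames(p) <- ch
  p
}

cohort_labels <- function(cfg) {
  tibble::tibble(
    sample = sprintf("s%03d", seq_len(cfg$n_c1 + cfg$n_c2)),
    group = rep(c("C1", "C2"), c(cfg$n_c1, cfg$n_c2)))
}

#' Simulate a subgroup-structured expression count matrix
#'
#' Counts are negative-binomial with mean
#' `s_j * q_g * 2^(marker_lfc * [marker & C1]) * 2^(batch_lfc * [batch 2 & susceptible])`
#' and `Var = mu + alpha mu^2`. Batch susceptibility is gene-specific
#' (roughly half the genes); control genes always carry the batch effect but
#' never the subgroup effect, so an unwanted-variation factor estimated from
#' them is identifiable. Deterministic under the config seed.
#'
#' @param config A [cohort_config()].
#' @return List with `counts` (a [count_matrix()]) and `truth` (labels
#'   tibble, `marker_ids`, `control_ids`, `batch` tibble).
#' @export
simulate_expression <- function(config) {
  cfg <- validate_cohort_config(config)
  n <- cfg$n_c1 + cfg$n_c2
  labels <- cohort_labels(cfg)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  marker_ids <- if (cfg$n_markers > 0) gene_ids[seq_len(cfg$n_markers)] else character()
  control_ids <- if (cfg$n_control_genes > 0) {
    gene_ids[seq(cfg$n_genes - cfg$n_control_genes + 1, cfg$n_genes)]
  } else character()

  with_seed(derive_seed(cfg$seed, "expression"), {
    # baseline expression strengths spanning ~3 orders of magnitude
    q <- 2^runif(cfg$n_genes, 3, 11)
    s <- exp(rnorm(n, 0, 0.15))
    s <- s / exp(mean(log(s)))
    if (cfg$batch_confounded) {
      batch <- ifelse(labels$group == "C1", 1L, 2L)
    } else {
      batch <- sample(rep_len(seq_len(cfg$n_batches), n))
    }
    is_marker <- gene_ids %in% marker_ids
    is_control <- gene_ids %in% control_ids
    # batch susceptibility is gene-specific (a uniform multiplier would be
    # indistinguishable from depth); control genes always reflect the batch
    # but never the subgroup, mirroring the unwanted-variation assumption
    susceptible <- runif(cfg$n_genes) < 0.5 | is_control
    grp_mult <- outer(ifelse(is_marker, 2^cfg$marker_lfc, 1),
                      as.numeric(labels$group == "C1"), `^`)
    grp_mult[is_control, ] <- 1
    bat_mult <- outer(ifelse(susceptible, 2^cfg$batch_lfc, 1),
                      as.numeric(batch == 2L), `^`)
    mu <- (q %o% s) * grp_mult * bat_mult
    alpha <- rep_len(cfg$dispersion, cfg$n_genes)
    counts <- matrix(0, cfg$n_genes, n)
    for (g in seq_len(cfg$n_genes)) {
      counts[g, ] <- if (alpha[g] > 0) {
        rnbinom(n, size = 1 / alpha[g], mu = mu[g, ])
      } else {
        rpois(n, mu[g, ])
      }
    }
    dimnames(counts) <- list(gene_ids, labels$sample)
    list(counts = count_matrix(counts),
         truth = list(labels = labels, marker_ids = marker_ids,
                      control_ids = control_ids,
                      batch_susceptible_ids = gene_ids[susceptible],
                      batch = tibble::tibble(sample = labels$sample,
                                             batch = batch)))
  })
}

#' Simulate subgroup-linked exponential survival with censoring
#'
#' Event times are exponential with rate
#' `surv_baseline_rate * surv_hr^[C1]`, administratively censored at
#' `censor_time`, so proportional hazards holds by construction and the true
#' hazard ratio is identifiable.
#'
#' @param config A [cohort_config()].
#' @param labels Tibble with `sample` and `group` covering all samples
#'   (defaults to the cohort's own labels).
#' @return Tibble (`sample`, `time_days`, `event`, `group`).
#' @export
simulate_survival <- function(config, labels = NULL) {
  cfg <- validate_cohort_config(config)
  labels <- labels %||% cohort_labels(cfg)
  assert_that(all(c("sample", "group") %in% names(labels)),
              "labels needs sample and group columns")
  with_seed(derive_seed(cfg$seed, "survival"), {
    rate <- cfg$surv_baseline_rate * cfg$surv_hr^(labels$group == "C1")
    t_event <- rexp(nrow(labels), rate)
    tibble::tibble(sample = labels$sample,
                   time_days = pmin(t_event, cfg$censor_time),
                   event = t_event < cfg$censor_time,
                   group = labels$group)
  })
}

#' Simulate a methylation beta matrix with planted differential probes
#'
#' Betas arise from Gaussian noise on the logit (M-value) scale around
#' group-specific means; the first `n_diff_probes` probes have a true
#' group-mean beta difference of `delta_beta_true` and are guaranteed to be
#' autosomal promoter-island probes with clean detection so they survive the
#' standard filters. Remaining probes receive random annotation: a sprinkle
#' of X/Y placements, SNP-within-10bp flags, detection failures, and
#' promoter/island flags.
#'
#' @param config A [cohort_config()].
#' @param labels Optional labels tibble as in [simulate_survival()].
#' @return List with `beta` (probes x samples matrix), `detection_p`
#'   (same shape), `annotation` tibble, and `truth` (diff probe ids, labels).
#' @export
simulate_methylation <- function(config, labels = NULL) {
  cfg <- validate_cohort_config(config)
  labels <- labels %||% cohort_labels(cfg)
  n <- nrow(labels)
  probe_ids <- sprintf("cg%06d", seq_len(cfg$n_probes))
  diff_ids <- if (cfg$n_diff_probes > 0) probe_ids[seq_len(cfg$n_diff_probes)] else character()
  with_seed(derive_seed(cfg$seed, "methylation"), {
    base_beta <- runif(cfg$n_probes, 0.15, 0.8)
    base_beta[seq_along(diff_ids)] <- 0.3
    delta <- numeric(cfg$n_probes)
    delta[seq_along(diff_ids)] <- cfg$delta_beta_true
    mean_beta <- outer(base_beta, rep(1, n)) +
      outer(delta, as.numeric(labels$group == "C1"))
    m <- log2(mean_beta / (1 - mean_beta)) +
      matrix(rnorm(cfg$n_probes * n, 0, cfg$m_sd), cfg$n_probes, n)
    beta <- 2^m / (1 + 2^m)
    dimnames(beta) <- list(probe_ids, labels$sample)
    detection_p <- matrix(runif(cfg$n_probes * n, 0, 0.005), cfg$n_probes, n,
                          dimnames = dimnames(beta))
    n_bg <- max(1, round(0.01 * cfg$n_probes))
    bg_rows <- sample(setdiff(seq_len(cfg$n_probes), seq_along(diff_ids)), n_bg)
    detection_p[cbind(bg_rows, sample(n, n_bg, replace = TRUE))] <-
      runif(n_bg, 0.02, 0.5)
    chrom <- sample(c(as.character(1:22), "X", "Y"), cfg$n_probes,
                    replace = TRUE, prob = c(rep(0.9 / 22, 22), 0.07, 0.03))
    chrom[seq_along(diff_ids)] <- sample(as.character(1:22),
                                         length(diff_ids), replace = TRUE)
    snp <- runif(cfg$n_probes) < 0.05
    promoter <- runif(cfg$n_probes) < 0.6
    island <- runif(cfg$n_probes) < 0.6
    snp[seq_along(diff_ids)] <- FALSE
    promoter[seq_along(diff_ids)] <- TRUE
    island[seq_along(diff_ids)] <- TRUE
    annotation <- tibble::tibble(
      probe = probe_ids, chrom = chrom,
      pos = sample.int(5e7, cfg$n_probes, replace = TRUE),
      snp_10bp = snp, promoter = promoter, island = island)
    list(beta = beta, detection_p = detection_p, annotation = annotation,
         truth = list(diff_probe_ids = diff_ids, labels = labels))
  })
}

#' Simulate per-sample copy-number segment profiles with planted drivers
#'
#' Each sample receives a diploid or tetraploid background tiled across the
#' genome, a few broad (arm-scale) gains/losses, and planted focal (<1 Mb)
#' events at cancer genes: 0-copy homozygous deletions over tumor
#' suppressors and high-level amplifications over oncogenes that respect the
#' driver-calling thresholds (total copies > 5 on diploid, > 9 on tetraploid
#' backgrounds).
#'
#' @param config A [cohort_config()].
#' @param driver_prob Probability that a given sample carries a planted
#'   focal driver at a given cancer gene.
#' @return List with `segments` (tibble: `sample`, `chrom`, `start`, `end`,
#'   `total_cn`, `ploidy`; 1-based inclusive) and `truth$driver_events`
#'   (tibble: `sample`, `gene`, `type`).
#' @export
simulate_segments <- function(config, driver_prob = 0.3) {
  cfg <- validate_cohort_config(config)
  samples <- sprintf("s%03d", seq_len(cfg$n_segment_samples))
  genome <- cfg$genome
  genes <- cfg$driver_genes
  with_seed(derive_seed(cfg$seed, "segments"), {
    out <- vector("list", length(samples))
    events <- list()
    for (i in seq_along(samples)) {
      ploidy <- if (runif(1) < cfg$tetraploid_fraction) 4 else 2
      segs <- tibble::tibble(chrom = genome$chrom, start = 1,
                             end = genome$length, total_cn = ploidy)
      # broad arm-scale changes (never copy-neutral==driver rules untouched)
      for (ci in seq_len(nrow(genome))) {
        if (runif(1) < 0.3) {
          half <- floor(genome$length[ci] / 2)
          change <- sample(c(-1, 1), 1)
          segs <- segment_carve(segs, genome$chrom[ci], 1, half,
                                max(0, ploidy + change))
        }
      }
      for (gi in seq_len(nrow(genes))) {
        if (runif(1) < driver_prob) {
          g <- genes[gi, ]
          pad <- runif(2, 1e4, 2e5)
          start <- max(1, floor(g$start - pad[1]))
          end <- floor(g$end + pad[2])
          if (end - start + 1 >= 1e6) end <- start + 9e5
          if (g$role == "TSG") {
            cn <- 0
            type <- "homozygous_deletion"
          } else {
            cn <- if (ploidy > 3) 10 + rpois(1, 2) else 6 + rpois(1, 1)
            type <- "amplification"
          }
          segs <- segment_carve(segs, g$chrom, start, end, cn)
          events[[length(events) + 1]] <-
            tibble::tibble(sample = samples[i], gene = g$gene, type = type)
        }
      }
      segs$sample <- samples[i]
      segs$ploidy <- ploidy
      out[[i]] <- segs
    }
    segments <- dplyr::bind_rows(out) |>
      dplyr::select("sample", "chrom", "start", "end", "total_cn", "ploidy")
    validate_segments(segments)
    list(segments = segments,
         truth = list(driver_events = if (length(events)) {
           dplyr::bind_rows(events)
         } else {
           tibble::tibble(sample = character(), gene = character(),
                          type = character())
         }))
  })
}

# replace [start, end] on one chromosome with total_cn, splitting the tiles
segment_carve <- function(segs, chrom, start, end, total_cn) {
  if (end < start) validation_error("segment end < start")
  hit <- segs$chrom == chrom & segs$start <= end & segs$end >= start
  keep <- segs[!hit, ]
  pieces <- list()
  for (j in which(hit)) {
    s <- segs[j, ]
    if (s$start < start) {
      left <- s
      left$end <- start - 1
      pieces[[length(pieces) + 1]] <- left
    }
    if (s$end > end) {
      right <- s
      right$start <- end + 1
      pieces[[length(pieces) + 1]] <- right
    }
  }
  new <- tibble::tibble(chrom = chrom, start = start, end = end,
                        total_cn = total_cn)
  dplyr::arrange(dplyr::bind_rows(keep, dplyr::bind_rows(pieces), new),
                 .data$chrom, .data$start)
}

validate_segments <- function(segments) {
  if (any(segments$end < segments$start)) {
    validation_error("segment end < start")
  }
  if (any(segments$total_cn < 0)) validation_error("negative total_cn")
  bad <- segments |>
    dplyr::group_by(.data$sample, .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::summarise(overlap = any(.data$start[-1] <= .data$end[-dplyr::n()]),
                     .groups = "drop")
  if (any(bad$overlap, na.rm = TRUE)) {
    validation_error("overlapping segments within a sample")
  }
  invisible(segments)
}

#' Simulate 96-channel mutation catalogues from signature mixtures
#'
#' Channel counts are Poisson with mean `exposures %*% profiles`; channels
#' follow the canonical trinucleotide ordering ([trinucleotide_channels()]).
#'
#' @param config A [cohort_config()].
#' @param exposures Optional samples x k non-negative weight matrix; by
#'   default gamma-distributed weights scaled to `exposure_mean` mutations
#'   per sample on average.
#' @return List with `catalogue` (samples x 96 count matrix) and
#'   `truth$exposures`.
#' @export
simulate_catalogues <- function(config, exposures = NULL) {
  cfg <- validate_cohort_config(config)
  p <- cfg$signature_profiles
  k <- nrow(p)
  n <- cfg$n_catalogue_samples
  with_seed(derive_seed(cfg$seed, "catalogues"), {
    if (is.null(exposures)) {
      exposures <- matrix(stats::rgamma(n * k, shape = 2, rate = 2), n, k)
      exposures <- exposures / rowSums(exposures) * cfg$exposure_mean
    }
    if (any(exposures < 0)) config_error("negative exposures")
    assert_that(ncol(exposures) == k, "exposures not conformable with profiles")
    mu <- exposures %*% p
    catalogue <- matrix(rpois(length(mu), mu), nrow(mu), ncol(mu))
    dimnames(catalogue) <- list(sprintf("s%03d", seq_len(n)),
                                trinucleotide_channels())
    rownames(exposures) <- rownames(catalogue)
    colnames(exposures) <- rownames(p)
    list(catalogue = catalogue, truth = list(exposures = exposures))
  })
}

#' Simulate the full multi-omic cohort
#'
#' Runs every generator under per-stage seeds derived from the config's root
#' seed and returns all matrices together with the combined ground truth.
#'
#' @param config A [cohort_config()].
#' @return List with `counts`, `survival`, `methylation`, `segments`,
#'   `catalogue` components and a merged `truth` list.
#' @export
simulate_cohort <- function(config) {
  expr <- simulate_expression(config)
  surv <- simulate_survival(config, expr$truth$labels)
  meth <- simulate_methylation(config, expr$truth$labels)
  segs <- simulate_segments(config)
  cats <- simulate_catalogues(config)
  list(counts = expr$counts,
       survival = surv,
       methylation = meth[c("beta", "detection_p", "annotation")],
       segments = segs$segments,
       catalogue = cats$catalogue,
       truth = list(labels = expr$truth$labels,
                    marker_ids = expr$truth$marker_ids,
                    control_ids = expr$truth$control_ids,
                    batch = expr$truth$batch,
                    true_hr = config$surv_hr,
                    diff_probe_ids = meth$truth$diff_probe_ids,
                    driver_events = segs$truth$driver_events,
                    true_exposures = cats$truth$exposures))
}
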