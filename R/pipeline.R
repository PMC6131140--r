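pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = NULL,
    simulate = NULL,
    inputs = NULL,
    stages = list(subtype = TRUE, de = TRUE, markers = TRUE, survival = TRUE,
                  methylation = TRUE, cnv = TRUE, signatures = TRUE,
                  enrichment = FALSE),
    thresholds = list(n_top_cluster = 250, n_top_pca = 500, n_top_loadings = 50,
                      lfc_min = 4, padj_max = 1e-4, delta_beta_min = 0.2,
                      fdr = 0.01, n_hidden = 13, n_signatures = 2,
                      nmf_restarts = 20))
}

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    abort(sprintf("unknown config key(s) in %s: %s", where,
                  paste(bad, collapse = ", ")),
          class = c("schema_error", "meningiomics_error"))
  }
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), validates the schema — unknown keys
#' are rejected by name — and fills omitted parameters with the standard
#' defaults (250 clustering transcripts, top-500 PCA, top-50 loadings,
#' |log2FC| > 4, adjusted p < 1e-4, delta-beta > 0.2, FDR 0.01).
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated `pipeline_config` list.
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  def <- pipeline_defaults()
  check_keys(raw, names(def), "top level")
  check_keys(raw$stages %||% list(), names(def$stages), "stages")
  check_keys(raw$thresholds %||% list(), names(def$thresholds), "thresholds")
  if (!is.null(raw$simulate)) {
    check_keys(raw$simulate, setdiff(names(formals(cohort_config)), "seed"),
               "simulate")
  }
  if (!is.null(raw$inputs)) {
    check_keys(raw$inputs, c("counts", "survival", "beta", "annotation",
                             "segments", "catalogue", "gene_sets"), "inputs")
    for (f in unlist(raw$inputs)) {
      if (!file.exists(f)) config_error(sprintf("input file not found: %s", f))
    }
  }
  if (is.null(raw$simulate) && is.null(raw$inputs)) {
    config_error("config needs either a simulate block or an inputs block")
  }
  cfg <- def
  cfg$seed <- as.integer(raw$seed %||% def$seed)
  cfg$outdir <- raw$outdir
  cfg$simulate <- raw$simulate
  cfg$inputs <- raw$inputs
  cfg$stages <- modifyList(def$stages, raw$stages %||% list())
  cfg$thresholds <- modifyList(def$thresholds, raw$thresholds %||% list())
  stochastic <- any(unlist(cfg$stages)) || !is.null(cfg$simulate)
  if (stochastic && is.null(cfg$seed)) config_error("seed required")
  structure(cfg, class = "pipeline_config")
}

check_stage_plan <- function(stages) {
  need <- function(stage, deps) {
    missing <- deps[!unlist(stages[deps])]
    if (isTRUE(stages[[stage]]) && length(missing)) {
      abort(sprintf("stage '%s' requires stage(s): %s", stage,
                    paste(missing, collapse = ", ")),
            class = c("planning_error", "meningiomics_error"))
    }
  }
  need("de", "subtype")
  need("markers", c("subtype", "de"))
  need("survival", "subtype")
  need("enrichment", "de")
  invisible(TRUE)
}

# Map discovered clusters onto C1/C2: the cluster with the higher mean
# variance-stabilized expression over the strongest |PC1| transcripts is C1
# (the marker-overexpressing, poor-prognosis group by construction).
orient_partition <- function(partition, vst, pca) {
  pc1 <- pca$loadings[, 1]
  top <- names(sort(-abs(pc1)))[seq_len(min(50, length(pc1)))]
  mean_by_cluster <- tapply(
    colMeans(vst$values[top, partition$labels$sample, drop = FALSE]),
    partition$labels$cluster, mean)
  c1 <- as.integer(names(which.max(mean_by_cluster)))
  partition$labels$group <- ifelse(partition$labels$cluster == c1, "C1", "C2")
  partition
}

#' Run the integrated multi-omic pipeline
#'
#' Executes the enabled stages in dependency order on a simulated cohort or
#' on files named in the config: expression subgrouping, differential
#' expression with unwanted-variation factors, marker-panel minimization,
#' survival comparison, methylation filtering/selection/clustering,
#' copy-number profiling and driver calling, and mutational-signature
#' extraction. Failure in one omics branch is caught and logged without
#' aborting independent branches. Intermediates are written to the config's
#' `outdir` when set.
#'
#' @param config A `pipeline_config` from [load_config()] (or a path/list).
#' @return A `pipeline_report` list with per-stage key outputs, parameters,
#'   and errors (if any).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- load_config(config)
  check_stage_plan(config$stages)
  th <- config$thresholds
  report <- list(seed = config$seed, parameters = th,
                 stages_enabled = config$stages, errors = list())
  outdir <- config$outdir
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  data <- if (!is.null(config$simulate)) {
    cc <- do.call(cohort_config, c(config$simulate, list(seed = config$seed)))
    cohort <- simulate_cohort(cc)
    if (!is.null(outdir)) write_cohort(cohort, file.path(outdir, "simulated"))
    report$simulated <- TRUE
    cohort
  } else {
    ip <- config$inputs
    list(counts = if (!is.null(ip$counts)) read_counts_tsv(ip$counts),
         survival = if (!is.null(ip$survival)) read_survival_csv(ip$survival),
         methylation = if (!is.null(ip$beta)) {
           list(beta = read_beta_tsv(ip$beta),
                detection_p = NULL,
                annotation = if (!is.null(ip$annotation))
                  read_annotation_tsv(ip$annotation))
         },
         segments = if (!is.null(ip$segments)) read_segments_tsv(ip$segments),
         catalogue = if (!is.null(ip$catalogue)) read_catalogue_tsv(ip$catalogue),
         truth = NULL)
  }

  try_stage <- function(name, code) {
    if (isTRUE(getOption("meningiomics.stop_on_error"))) return(force(code))
    tryCatch(code, error = function(e) {
      report$errors[[name]] <<- conditionMessage(e)
      NULL
    })
  }

  partition <- NULL
  vst <- NULL
  pca <- NULL
  if (isTRUE(config$stages$subtype)) {
    sub <- try_stage("subtype", {
      counts <- size_factors(data$counts)
      vst <- vst_transform(counts)
      disc <- discover_subgroups(counts, n_top = min(th$n_top_cluster,
                                                     nrow(counts$values)))
      pca <- pca_top_variable(vst, n_top = min(th$n_top_pca,
                                               nrow(vst$values)))
      part <- orient_partition(disc$partition, vst, pca)
      list(k_star = disc$k_star, silhouette = disc$profile, partition = part)
    })
    if (!is.null(sub)) {
      partition <- sub$partition
      report$subtype <- list(
        k_star = sub$k_star,
        mean_silhouette = sub$silhouette$mean_silhouette[
          sub$silhouette$k == sub$k_star],
        groups = table(partition$labels$group),
        labels = partition$labels)
      if (!is.null(data$truth)) {
        report$subtype$ari_vs_truth <- adjusted_rand(
          partition$labels$group,
          data$truth$labels$group[match(partition$labels$sample,
                                        data$truth$labels$sample)])
      }
    }
  }

  de <- NULL
  if (isTRUE(config$stages$de) && !is.null(partition)) {
    de <- try_stage("de", {
      counts <- size_factors(data$counts)
      controls <- data$truth$control_ids %||% character()
      cond <- factor(partition$labels$group, levels = c("C2", "C1"))
      covars <- NULL
      if (length(controls) >= 2) {
        w <- estimate_control_gene_factor(counts, controls, k = 1)
        # hidden factors are estimated orthogonal to both the batch factor
        # and the condition, so they cannot absorb the subgroup contrast
        known <- cbind(w, cond = as.numeric(cond) - 1)
        n_hidden <- min(th$n_hidden,
                        ncol(counts$values) - qr(cbind(1, known))$rank - 2)
        h <- if (n_hidden > 0) estimate_hidden_factors(counts, known, n_hidden)
        covars <- cbind(w, h)
      }
      nb_wald_de(counts, design_info(cond, covars, controls))
    })
    if (!is.null(de)) {
      report$de <- glance(de, padj_max = 0.01, lfc_min = 2)
      if (!is.null(outdir)) {
        utils::write.table(tidy(de), file.path(outdir, "de_c1_vs_c2.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  if (isTRUE(config$stages$markers) && !is.null(de) && !is.null(pca)) {
    mk <- try_stage("markers", {
      cand <- candidate_markers(pca, de, n_top = th$n_top_loadings,
                                lfc_min = th$lfc_min, padj_max = th$padj_max)
      if (nrow(cand) == 0) {
        list(candidates = cand, minimal = NULL)
      } else {
        list(candidates = cand,
             minimal = minimize_markers(cand, data$counts, partition))
      }
    })
    if (!is.null(mk)) {
      report$markers <- list(
        n_candidates = nrow(mk$candidates),
        panel = if (!is.null(mk$minimal)) mk$minimal$genes else character(),
        panel_size = if (!is.null(mk$minimal)) mk$minimal$size else 0L,
        recapitulation = if (!is.null(mk$minimal)) mk$minimal$recapitulation
        else FALSE,
        pca_silhouette = if (!is.null(mk$minimal)) mk$minimal$pca_silhouette
        else NA_real_)
    }
  }

  if (isTRUE(config$stages$survival) && !is.null(partition) &&
      !is.null(data$survival)) {
    sv <- try_stage("survival", {
      rec <- data$survival
      rec$group <- partition$labels$group[match(rec$sample,
                                                partition$labels$sample)]
      rec <- rec[!is.na(rec$group), ]
      compare_survival(rec)
    })
    if (!is.null(sv)) {
      report$survival <- c(tidy(sv$hazard_ratio),
                           list(logrank_chi2 = sv$logrank$chi2,
                                logrank_p = sv$logrank$p))
    }
  }

  if (isTRUE(config$stages$methylation) && !is.null(data$methylation)) {
    me <- try_stage("methylation", {
      m <- data$methylation
      filt <- filter_probes(m$beta, m$annotation, m$detection_p)
      groups <- if (!is.null(partition)) {
        partition$labels$group[match(colnames(filt$beta),
                                     partition$labels$sample)]
      } else if (!is.null(data$truth)) {
        data$truth$labels$group[match(colnames(filt$beta),
                                      data$truth$labels$sample)]
      } else {
        abort("no grouping available for supervised methylation analysis")
      }
      sel <- supervised_probe_selection(filt$beta, groups,
                                        padj_max = th$fdr,
                                        delta_beta_min = th$delta_beta_min)
      unsup <- methylation_clustering(filt$beta, "unsupervised")
      list(filtered = filt, selection = sel, unsupervised = unsup)
    })
    if (!is.null(me)) {
      report$methylation <- list(
        n_probes_retained = nrow(me$filtered$beta),
        n_selected = nrow(me$selection),
        unsupervised_k = me$unsupervised$k,
        unsupervised_labels = me$unsupervised$labels)
    }
  }

  if (isTRUE(config$stages$cnv) && !is.null(data$segments)) {
    cn <- try_stage("cnv", {
      genes <- if (!is.null(config$simulate)) {
        do.call(cohort_config,
                c(config$simulate, list(seed = config$seed)))$driver_genes
      } else {
        default_driver_genes()
      }
      list(profile = aggregate_profile(data$segments),
           drivers = call_cnv_drivers(data$segments, genes))
    })
    if (!is.null(cn)) {
      report$cnv <- list(n_bins = nrow(cn$profile),
                         n_driver_calls = nrow(cn$drivers),
                         drivers = cn$drivers)
      if (!is.null(outdir)) {
        utils::write.table(cn$drivers, file.path(outdir, "driver_calls.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
  }

  if (isTRUE(config$stages$signatures) && !is.null(data$catalogue)) {
    sg <- try_stage("signatures", {
      extract_signatures(data$catalogue, k = th$n_signatures,
                         n_restarts = th$nmf_restarts,
                         seed = derive_seed(config$seed, "signatures"))
    })
    if (!is.null(sg)) report$signatures <- glance(sg)
  }

  if (isTRUE(config$stages$enrichment) && !is.null(de)) {
    en <- try_stage("enrichment", {
      sets <- if (!is.null(config$inputs$gene_sets)) {
        read_gmt(config$inputs$gene_sets)
      } else {
        synthetic_gene_sets(de, seed = derive_seed(config$seed, "genesets"))
      }
      stats <- setNames(de$stat, de$gene)
      functional_class_scoring(stats, sets, n_perm = 1000,
                               seed = derive_seed(config$seed, "enrich"))
    })
    if (!is.null(en)) {
      report$enrichment <- utils::head(tibble::as_tibble(en), 10)
    }
  }

  report <- structure(report, class = "pipeline_report")
  if (!is.null(outdir)) {
    jsonlite::write_json(report_to_json(report),
                         file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

# Synthetic demonstration collection: random sets from the tested genes plus
# one set seeded with the strongest DE genes.
synthetic_gene_sets <- function(de, n_sets = 20, seed = 1) {
  universe <- de$gene[de$status == "ok"]
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      sample(universe, sample(10:40, 1))
    })
    names(sets) <- sprintf("synthetic_set_%02d", seq_len(n_sets))
    top <- de$gene[order(de$padj)][seq_len(min(15, length(universe)))]
    sets$synthetic_top_de <- top
    sets
  })
}

report_to_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "tbl_df") || is.data.frame(x)) return(as.data.frame(x))
    if (is.list(x)) return(lapply(x, strip))
    if (is.table(x)) return(as.list(x))
    x
  }
  strip(unclass(report))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$subtype)) {
    cat(sprintf("  subtype: k*=%d, ARI vs truth=%s\n", x$subtype$k_star,
                format(x$subtype$ari_vs_truth %||% NA)))
  }
  if (!is.null(x$de)) {
    cat(sprintf("  de: %d/%d significant at padj<0.01 & |lfc|>2\n",
                x$de$n_significant, x$de$n_tested))
  }
  if (!is.null(x$markers)) {
    cat(sprintf("  markers: panel of %d (%s)\n", x$markers$panel_size,
                paste(x$markers$panel, collapse = ", ")))
  }
  if (!is.null(x$survival)) {
    cat(sprintf("  survival: HR %.2f (%.2f-%.2f), log-rank p=%.3g\n",
                x$survival$estimate, x$survival$conf.low,
                x$survival$conf.high, x$survival$logrank_p))
  }
  if (!is.null(x$methylation)) {
    cat(sprintf("  methylation: %d retained, %d selected\n",
                x$methylation$n_probes_retained, x$methylation$n_selected))
  }
  if (!is.null(x$cnv)) {
    cat(sprintf("  cnv: %d driver calls over %d bins\n",
                x$cnv$n_driver_calls, x$cnv$n_bins))
  }
  if (!is.null(x$signatures)) {
    cat(sprintf("  signatures: k=%d, min stability %.3f\n",
                x$signatures$k, x$signatures$min_stability))
  }
  if (length(x$errors)) {
    cat(sprintf("  errors: %s\n", paste(names(x$errors), collapse = ", ")))
  }
  invisible(x)
}
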