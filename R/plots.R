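#' @importFrom ggplot2 ggplot aes geom_step geom_point geom_line geom_ribbon
#'   geom_col geom_hline labs facet_grid facet_wrap theme_minimal
NULL

#' Kaplan-Meier plot
#'
#' Step curves per group with censoring ticks.
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.km_curve <- function(object, ...) {
  steps <- object |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ tibble::add_row(.x, time = 0, survival = 1,
                                          .before = 1)) |>
    dplyr::ungroup()
  cens <- object[object$n_censor > 0, ]
  ggplot(steps, aes(x = .data$time, y = .data$survival,
                    colour = .data$group)) +
    geom_step() +
    geom_point(data = cens, shape = 3, show.legend = FALSE) +
    labs(x = "Days from first surgery", y = "Overall survival",
         colour = "Subgroup") +
    theme_minimal()
}

#' Aggregate copy-number profile plot
#'
#' Median relative copy-number change per 10-kb bin with the interquartile
#' band, faceted by chromosome; zero marks a copy-neutral genome.
#'
#' @param object An `aggregate_profile` from [aggregate_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.aggregate_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$start / 1e6)) +
    geom_ribbon(aes(ymin = .data$q1, ymax = .data$q3), fill = "grey80") +
    geom_line(aes(y = pmax(.data$median, 0)), colour = "red") +
    geom_line(aes(y = pmin(.data$median, 0)), colour = "blue") +
    geom_hline(yintercept = 0, linetype = "dotted") +
    facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
               space = "free_x") +
    labs(x = "Position (Mb)", y = "Median relative copy-number change") +
    theme_minimal()
}

#' Volcano plot of a DE result
#'
#' @param object A `de_result` from [nb_wald_de()].
#' @param padj_max,lfc_min Highlighting thresholds (default 0.01 and 2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.de_result <- function(object, padj_max = 0.01, lfc_min = 2, ...) {
  df <- tidy(object)
  df <- df[!is.na(df$padj), ]
  df$significant <- df$padj < padj_max & abs(df$log2fc) > lfc_min
  ggplot(df, aes(x = .data$log2fc, y = -log10(pmax(.data$padj, 1e-300)),
                 colour = .data$significant)) +
    geom_point(size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "red")) +
    labs(x = "log2 fold change", y = "-log10 adjusted p",
         colour = sprintf("padj<%.2g & |lfc|>%g", padj_max, lfc_min)) +
    theme_minimal()
}

#' Signature profile plot
#'
#' 96-channel probability bars per extracted signature.
#'
#' @param object A `signature_set` from [extract_signatures()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signature_set <- function(object, ...) {
  df <- tidy(object)
  df$channel <- factor(df$channel, levels = trinucleotide_channels())
  df$class <- sub(".*\\[(.*)\\].*", "\\1", as.character(df$channel))
  ggplot(df, aes(x = .data$channel, y = .data$probability,
                 fill = .data$class)) +
    geom_col() +
    facet_wrap(~ .data$signature, ncol = 1) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    labs(x = "Trinucleotide channel", y = "Probability", fill = "Substitution")
}

#' Silhouette-vs-k profile plot
#'
#' @param x Result of [select_k_silhouette()] or [discover_subgroups()].
#' @return A ggplot.
#' @export
plot_silhouette_profile <- function(x) {
  ggplot(x$profile, aes(x = .data$k, y = .data$mean_silhouette)) +
    geom_line() + geom_point() +
    geom_point(data = x$profile[x$profile$k == x$k_star, ],
               colour = "red", size = 3) +
    labs(x = "Number of clusters", y = "Mean silhouette width") +
    theme_minimal()
}
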