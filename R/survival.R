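validate_survival <- function(records) {
  assert_that(all(c("time_days", "event", "group") %in% names(records)),
              "records need time_days, event, group columns")
  if (any(records$time_days < 0)) validation_error("negative survival time")
  if (any(is.na(records$group))) validation_error("missing group label")
  invisible(records)
}

#' Kaplan-Meier product-limit estimate
#'
#' @param records Tibble with `time_days`, `event` (logical), `group`.
#' @param group Optional single group to restrict to.
#' @return A `km_curve` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival` — one row per distinct time, survival stepping
#'   down only at event times.
#' @export
km_estimate <- function(records, group = NULL) {
  validate_survival(records)
  if (!is.null(group)) records <- records[records$group %in% group, ]
  assert_that(nrow(records) > 0, "no records in requested group")
  out <- records |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(df, key) {
      tt <- sort(unique(df$time_days))
      n_risk <- vapply(tt, function(t) sum(df$time_days >= t), numeric(1))
      n_event <- vapply(tt, function(t) sum(df$time_days == t & df$event),
                        numeric(1))
      n_censor <- vapply(tt, function(t) sum(df$time_days == t & !df$event),
                         numeric(1))
      tibble::tibble(time = tt, n_risk = n_risk, n_event = n_event,
                     n_censor = n_censor,
                     survival = cumprod(1 - n_event / n_risk))
    }) |>
    dplyr::ungroup()
  structure(out, class = c("km_curve", class(out)))
}

# Log-rank O/E/V table at distinct event times; group1 = first level
logrank_table <- function(records) {
  validate_survival(records)
  groups <- sort(unique(records$group))
  if (length(groups) != 2) validation_error("need exactly two groups")
  ev_times <- sort(unique(records$time_days[records$event]))
  if (length(ev_times) == 0) validation_error("no events observed")
  g1 <- records$group == groups[1]
  o1 <- e1 <- v <- 0
  for (t in ev_times) {
    at_risk <- records$time_days >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(records$time_days == t & records$event)
    d1 <- sum(records$time_days == t & records$event & g1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(o1 = o1, e1 = e1, v = v, groups = groups)
}

#' Log-rank (Mantel-Cox) test between two groups
#'
#' At each distinct event time the expected events per group follow the
#' hypergeometric distribution on the risk sets; ties use the standard
#' multiplicity-corrected variance. Censoring at an event time keeps the
#' censored subject in the risk set (left-continuous convention).
#'
#' @param records Tibble with `time_days`, `event`, `group` (two groups).
#' @return List with `chi2` and `p` (chi-squared, 1 df).
#' @export
logrank_test <- function(records) {
  tab <- logrank_table(records)
  if (tab$v <= 0) {
    return(list(chi2 = 0, p = 1))
  }
  chi2 <- (tab$o1 - tab$e1)^2 / tab$v
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Mantel-Haenszel hazard ratio with 95% confidence interval
#'
#' The O-E/V estimator from the log-rank table:
#' `HR = exp((O1 - E1) / V)` with `CI95 = exp((O1 - E1)/V +- 1.96/sqrt(V))`,
#' reported for the first group (alphabetically; C1 in pipeline context)
#' versus the second.
#'
#' @param records Tibble with `time_days`, `event`, `group`.
#' @return A `hazard_ratio` list: `hr`, `ci_low`, `ci_high`, `chi2`, `p`,
#'   `o1`, `e1`, `v`, `groups`.
#' @export
mh_hazard_ratio <- function(records) {
  tab <- logrank_table(records)
  if (tab$v <= 0) {
    abort("zero log-rank variance: hazard ratio undefined",
          class = c("undefined_hr_error", "meningiomics_error"))
  }
  lhr <- (tab$o1 - tab$e1) / tab$v
  half <- 1.96 / sqrt(tab$v)
  chi2 <- (tab$o1 - tab$e1)^2 / tab$v
  structure(list(hr = exp(lhr), ci_low = exp(lhr - half),
                 ci_high = exp(lhr + half), chi2 = chi2,
                 p = pchisq(chi2, 1, lower.tail = FALSE),
                 o1 = tab$o1, e1 = tab$e1, v = tab$v, groups = tab$groups),
            class = "hazard_ratio")
}

#' @export
print.hazard_ratio <- function(x, ...) {
  cat(sprintf("<hazard_ratio> %s vs %s: HR %.2f (95%% CI %.2f-%.2f), p = %.3g\n",
              x$groups[1], x$groups[2], x$hr, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Tidy a hazard-ratio estimate
#' @param x A `hazard_ratio`.
#' @param ... Unused.
#' @return One-row tibble with estimate, CI, test statistic and p.
#' @export
tidy.hazard_ratio <- function(x, ...) {
  tibble::tibble(estimate = x$hr, conf.low = x$ci_low, conf.high = x$ci_high,
                 statistic = x$chi2, p.value = x$p,
                 observed = x$o1, expected = x$e1, variance = x$v)
}

#' Compare survival between two subgroups
#'
#' Kaplan-Meier curves, log-rank test and Mantel-Haenszel hazard ratio in
#' one call.
#'
#' @param records Tibble with `time_days`, `event`, `group`.
#' @return List with `km` (a `km_curve`), `logrank`, and `hazard_ratio`.
#' @export
compare_survival <- function(records) {
  list(km = km_estimate(records),
       logrank = logrank_test(records),
       hazard_ratio = mh_hazard_ratio(records))
}
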