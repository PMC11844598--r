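# ggplot2 views of the main result types.

#' Plot an occurrence-decay curve
#'
#' Top: number of probes meeting the reporting threshold (log scale).
#' Bottom: percent of those probes overlapping CoRSIVs vs the control
#' mean.
#'
#' @param decay Tibble from [decay_curve()].
#' @return A ggplot object (percent-overlap panel with the probe counts
#'   mapped to point size).
#' @export
plot_decay <- function(decay) {
  long <- decay |>
    tidyr::pivot_longer(c("pct_corsiv_overlap", "pct_control_overlap"),
                        names_to = "set", values_to = "pct") |>
    dplyr::mutate(set = dplyr::recode(.data$set,
                                      pct_corsiv_overlap = "CoRSIV",
                                      pct_control_overlap = "control (mean)"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$pct,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$probes_at_least_t)) +
    ggplot2::scale_size_continuous(trans = "log10") +
    ggplot2::labs(x = "minimum papers reporting a probe",
                  y = "% of probes overlapping", colour = NULL,
                  size = "probes at threshold") +
    ggplot2::theme_minimal()
}

#' Plot the permutation null against the observed enrichment ratio
#'
#' @param x A `corsiv_enrichment` from [test_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot corsiv_enrichment
#' @export
autoplot.corsiv_enrichment <- function(x, ...) {
  nulls <- tibble(ratio = x$null_ratios[is.finite(x$null_ratios)])
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$ratio)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70") +
    ggplot2::geom_vline(xintercept = x$ratio, colour = "red") +
    ggplot2::labs(
      title = sprintf("%s: ratio = %.2f, permutation p = %.3g",
                      x$term %||% "enrichment", x$ratio, x$p_perm),
      x = "null enrichment ratio", y = "permutations") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot binned stability medians against paper counts
#'
#' @param trend Result of [binned_trend()].
#' @param metric Label for the y axis.
#' @return A ggplot object.
#' @export
plot_binned_trend <- function(trend, metric = "median metric") {
  ggplot2::ggplot(trend$bins,
                  ggplot2::aes(x = .data$n_papers_reporting,
                               y = .data$median_metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n)) +
    ggplot2::labs(x = "papers reporting the probe", y = metric,
                  size = "probes in bin",
                  subtitle = if (!is.na(trend$p_trend))
                    sprintf("trend p = %.3g (Jonckheere-Terpstra)", trend$p_trend)
                  else "fewer than 2 qualifying bins") +
    ggplot2::theme_minimal()
}
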