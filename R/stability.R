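# Test-retest stability: intraclass correlation (ICC) and interindividual
# range (IIR, 2nd-98th percentile) of methylation betas.

panel_betas <- function(panel) {
  if (inherits(panel, "methylation_panel")) panel$betas else panel
}

icc_from_matrix <- function(v1, v2, variant = c("oneway", "consistency")) {
  # v1, v2: probes x subjects matrices of the two visits
  variant <- match.arg(variant)
  ns <- ncol(v1)
  m_s <- (v1 + v2) / 2                       # subject means
  grand <- rowMeans(m_s)
  ssb <- 2 * rowSums((m_s - grand)^2)
  msb <- ssb / (ns - 1)
  ssw <- rowSums((v1 - m_s)^2 + (v2 - m_s)^2)
  if (variant == "oneway") {
    msw <- ssw / ns                          # n(v-1) df, v = 2
    (msb - msw) / (msb + msw)
  } else {
    # two-way consistency ICC(3,1): remove the visit (occasion) effect
    visit_mean1 <- rowMeans(v1); visit_mean2 <- rowMeans(v2)
    ssv <- ns * ((visit_mean1 - grand)^2 + (visit_mean2 - grand)^2)
    mse <- (ssw - ssv) / (ns - 1)
    (msb - mse) / (msb + mse)
  }
}

panel_matrices <- function(panel, probes = NULL) {
  b <- panel_betas(panel)
  if (!is.null(probes)) b <- b[b$probe_id %in% probes, , drop = FALSE]
  w <- b |>
    tidyr::pivot_wider(names_from = "visit", values_from = "beta",
                       names_prefix = "v") |>
    arrange(.data$probe_id, .data$subject_id)
  if (anyNA(w$v1) || anyNA(w$v2)) {
    abort("every (probe, subject) pair must have both visits")
  }
  ids <- unique(w$probe_id)
  ns <- nrow(w) / length(ids)
  list(probe_id = ids,
       v1 = matrix(w$v1, nrow = length(ids), byrow = TRUE),
       v2 = matrix(w$v2, nrow = length(ids), byrow = TRUE),
       n_subjects = ns)
}

#' Intraclass correlation of a probe's test-retest betas
#'
#' One-way random-effects ICC(1,1):
#' `(MSB - MSW) / (MSB + (v - 1) MSW)` with `v = 2` visits. Negative
#' values are reported as computed, not clamped. The `"consistency"`
#' variant is the two-way consistency ICC(3,1), which removes a visit
#' (occasion) effect before comparing subjects.
#'
#' @param panel A `methylation_panel` or a long beta tibble (probe_id,
#'   subject_id, visit, beta) with exactly two visits per subject.
#' @param probe Single probe ID.
#' @param variant `"oneway"` (default) or `"consistency"`.
#' @return ICC in `(-Inf, 1]`.
#' @export
compute_icc <- function(panel, probe, variant = c("oneway", "consistency")) {
  variant <- match.arg(variant)
  pm <- panel_matrices(panel, probes = probe)
  if (pm$n_subjects < 2) abort("need at least 2 subjects")
  if (stats::var(c(pm$v1[1, ], pm$v2[1, ])) == 0) {
    abort(sprintf("probe %s is constant: total variance is zero", probe))
  }
  as.numeric(icc_from_matrix(pm$v1, pm$v2, variant))
}

#' Interindividual range (2nd-98th percentile) of a probe
#'
#' Per-subject values are the mean of the two visits; the IIR is the 98th
#' minus the 2nd percentile across subjects, with the linear-interpolation
#' percentile definition (`quantile` type 7).
#'
#' @inheritParams compute_icc
#' @return IIR in beta units (>= 0).
#' @export
compute_iir <- function(panel, probe) {
  pm <- panel_matrices(panel, probes = probe)
  if (pm$n_subjects < 2) abort("need at least 2 subjects")
  subj_means <- (pm$v1[1, ] + pm$v2[1, ]) / 2
  q <- stats::quantile(subj_means, c(0.02, 0.98), type = 7, names = FALSE)
  q[2] - q[1]
}

#' Per-probe stability records for a whole panel
#'
#' Vectorised ICC and IIR for every probe in the panel. Probes with zero
#' total variance get `NA` ICC (with a message) rather than an error.
#'
#' @param panel A `methylation_panel` or long beta tibble.
#' @param is_corsiv Optional logical vector or tibble (probe_id,
#'   is_corsiv); defaults to the panel's ground-truth flags when present.
#' @param variant ICC variant, see [compute_icc()].
#' @return Tibble (probe_id, icc, iir, is_corsiv).
#' @export
stability_records <- function(panel, is_corsiv = NULL,
                              variant = c("oneway", "consistency")) {
  variant <- match.arg(variant)
  pm <- panel_matrices(panel)
  if (pm$n_subjects < 3) abort("need at least 3 subjects")
  icc <- as.numeric(icc_from_matrix(pm$v1, pm$v2, variant))
  const <- apply(cbind(pm$v1, pm$v2), 1, function(r) stats::var(r) == 0)
  if (any(const)) {
    inform(sprintf("%d constant probe(s): ICC set to NA", sum(const)))
    icc[const] <- NA_real_
  }
  subj_means <- (pm$v1 + pm$v2) / 2
  qs <- apply(subj_means, 1, stats::quantile, probs = c(0.02, 0.98),
              type = 7, names = FALSE)
  iir <- qs[2, ] - qs[1, ]
  rec <- tibble(probe_id = pm$probe_id, icc = icc, iir = iir)
  flags <-
    if (!is.null(is_corsiv)) {
      if (is.data.frame(is_corsiv)) is_corsiv else
        tibble(probe_id = pm$probe_id, is_corsiv = is_corsiv)
    } else if (inherits(panel, "methylation_panel")) {
      panel$truth |> select("probe_id", "is_corsiv")
    } else {
      tibble(probe_id = pm$probe_id, is_corsiv = NA)
    }
  rec |> dplyr::left_join(flags, by = "probe_id")
}

#' Group medians of stability metrics
#'
#' @param records Tibble from [stability_records()] (or any tibble with
#'   numeric metric columns).
#' @param group Column name to group by (default `is_corsiv`).
#' @param metrics Metric columns to summarise.
#' @return Tibble with one row per group and `median_<metric>` columns.
#' @export
group_medians <- function(records, group = "is_corsiv",
                          metrics = c("icc", "iir")) {
  metrics <- intersect(metrics, names(records))
  records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(metrics),
                    ~ stats::median(.x, na.rm = TRUE),
                    .names = "median_{.col}"),
      n = dplyr::n(), .groups = "drop")
}

#' Jonckheere-Terpstra test for an ordered trend across groups
#'
#' Tests whether `values` trend monotonically across the ordered levels
#' of `groups`, using the tie-corrected normal approximation to the
#' Jonckheere-Terpstra statistic (pairs in higher-ordered groups
#' exceeding those in lower-ordered groups, ties counted half).
#'
#' @param values Numeric vector.
#' @param groups Ordered grouping (numeric, ordered factor, or anything
#'   `sort`able); at least two distinct levels.
#' @return List with `statistic` (J), `mean`, `sd`, `z`, and the
#'   two-sided `p.value`.
#' @export
jonckheere_test <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  g <- as.integer(factor(groups, levels = sort(unique(groups))))
  levs <- sort(unique(g))
  if (length(levs) < 2) abort("need at least 2 ordered groups")
  J <- 0
  for (a in seq_along(levs)) {
    for (b in seq_along(levs)) {
      if (a >= b) next
      xa <- values[g == levs[a]]; xb <- values[g == levs[b]]
      # ranks trick: count pairs xb > xa, ties half
      J <- J + sum(vapply(xb, function(y) sum(y > xa) + 0.5 * sum(y == xa),
                          numeric(1)))
    }
  }
  n_i <- as.vector(table(g))
  N <- sum(n_i)
  t_u <- as.vector(table(values))
  mu <- (N^2 - sum(n_i^2)) / 4
  v1 <- N * (N - 1) * (2 * N + 5) -
    sum(n_i * (n_i - 1) * (2 * n_i + 5)) -
    sum(t_u * (t_u - 1) * (2 * t_u + 5))
  v2 <- sum(n_i * (n_i - 1) * (n_i - 2)) * sum(t_u * (t_u - 1) * (t_u - 2))
  v3 <- sum(n_i * (n_i - 1)) * sum(t_u * (t_u - 1))
  sig2 <- v1 / 72 + v2 / (36 * N * (N - 1) * (N - 2)) + v3 / (8 * N * (N - 1))
  if (sig2 <= 0) return(list(statistic = J, mean = mu, sd = 0, z = 0, p.value = 1))
  z <- (J - mu) / sqrt(sig2)
  list(statistic = J, mean = mu, sd = sqrt(sig2), z = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}

#' Binned trend of a stability metric against per-probe paper counts
#'
#' Joins stability (or concordance) records to a category incidence,
#' forms one bin per exact paper-count value with at least
#' `min_bin_size` probes, reports per-bin medians, and assesses the
#' ordered trend with the Jonckheere-Terpstra test (two-sided).
#'
#' @param records Tibble with `probe_id` and the metric column.
#' @param inc A `category_incidence`.
#' @param metric Column name: `"icc"`, `"iir"` or `"becon_score"`.
#' @param min_bin_size Minimum probes per bin (default 15).
#' @return List with `bins` (tibble: n_papers_reporting, n,
#'   median_metric) and `p_trend` (NA with fewer than 2 qualifying bins).
#' @export
binned_trend <- function(records, inc, metric = c("iir", "icc", "becon_score"),
                         min_bin_size = 15) {
  metric <- match.arg(metric)
  joined <- records |>
    dplyr::inner_join(inc, by = "probe_id") |>
    dplyr::filter(!is.na(.data[[metric]]))
  bins <- joined |>
    dplyr::group_by(.data$n_papers_reporting) |>
    dplyr::summarise(n = dplyr::n(),
                     median_metric = stats::median(.data[[metric]]),
                     .groups = "drop") |>
    dplyr::filter(.data$n >= min_bin_size) |>
    arrange(.data$n_papers_reporting)
  if (nrow(bins) < 2) {
    return(list(bins = bins, p_trend = NA_real_, test = NULL))
  }
  sub <- joined |> dplyr::filter(.data$n_papers_reporting %in% bins$n_papers_reporting)
  jt <- jonckheere_test(sub[[metric]], sub$n_papers_reporting)
  list(bins = bins, p_trend = jt$p.value, test = jt)
}

#' Group medians of blood-brain concordance scores
#'
#' @param concordance Tibble (probe_id, becon_score).
#' @param groups Tibble (probe_id, is_corsiv) or named list of probe ID
#'   vectors.
#' @return Tibble with one row per group: `median_becon_score`, `n`.
#' @export
concordance_compare <- function(concordance, groups) {
  if (is.data.frame(groups)) {
    joined <- concordance |> dplyr::inner_join(groups, by = "probe_id")
    grp_col <- setdiff(names(groups), "probe_id")[1]
  } else {
    joined <- purrr::imap_dfr(groups, function(ids, nm) {
      concordance |> dplyr::filter(.data$probe_id %in% ids) |>
        dplyr::mutate(group = nm)
    })
    grp_col <- "group"
  }
  if (nrow(joined) == 0) abort("no probes left after joining groups to the concordance table")
  joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp_col))) |>
    dplyr::summarise(median_becon_score = stats::median(.data$becon_score),
                     n = dplyr::n(), .groups = "drop")
}
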