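# The occurrence spectrum tabulates, for each number of papers i >= 1:
#   p_i  total probes reported in exactly i papers,
#   n_i  CoRSIV probes reported in exactly i papers,
#   m_i  control probes reported in exactly i papers, pooled over sets.

#' Build an occurrence spectrum from an incidence table
#'
#' @param inc A `category_incidence` tibble (probe_id,
#'   n_papers_reporting) from [build_incidence()] or [sim_incidence()].
#' @param corsiv_probes Character vector of CoRSIV probe IDs.
#' @param control_sets List of character vectors, one per control set;
#'   `m_i` is pooled by summing the per-set exact-count histograms.
#' @return An `occurrence_spectrum` tibble (i, p_i, n_i, m_i) with
#'   attributes `n_control_sets`, `term`, `n_papers`.
#' @export
build_spectrum <- function(inc, corsiv_probes, control_sets) {
  counts <- inc$n_papers_reporting
  if (length(counts) == 0) {
    sp <- tibble(i = integer(0), p_i = integer(0), n_i = integer(0), m_i = integer(0))
  } else {
    imax <- max(counts)
    hist_of <- function(sel) tabulate(counts[sel], nbins = imax)
    p <- tabulate(counts, nbins = imax)
    n <- hist_of(inc$probe_id %in% corsiv_probes)
    m <- Reduce(`+`, lapply(control_sets, function(s) hist_of(inc$probe_id %in% s)),
                accumulate = FALSE, init = integer(imax))
    sp <- tibble(i = seq_len(imax), p_i = p, n_i = n, m_i = m)
  }
  structure(sp,
            n_control_sets = length(control_sets),
            term = attr(inc, "term"),
            n_papers = attr(inc, "n_papers"),
            class = c("occurrence_spectrum", class(tibble())))
}

#' Truncation level k of an occurrence spectrum
#'
#' `k` is the highest number of papers `i` such that at least `min_probes`
#' probes are reported in exactly `i` papers. With
#' `contiguous = TRUE` the largest `k` such that *every* `i <= k` has
#' `p_i >= min_probes` is returned instead (sensitivity variant).
#'
#' @param spectrum An `occurrence_spectrum`.
#' @param min_probes Minimum probes at a level (default 10).
#' @param contiguous Require all lower levels to qualify too?
#' @return Integer `k`.
#' @export
select_k <- function(spectrum, min_probes = 10, contiguous = FALSE) {
  ok <- which(spectrum$p_i >= min_probes)
  if (length(ok) == 0) {
    abort(sprintf("no occurrence level has at least %d probes; term unanalyzable",
                  min_probes))
  }
  if (contiguous) {
    k <- 0L
    for (i in seq_len(max(ok))) {
      if (i %in% ok) k <- i else break
    }
    spectrum$i[k]
  } else {
    spectrum$i[max(ok)]
  }
}

#' Publication-weighted enrichment ratio
#'
#' The ratio of the weighted sum of CoRSIV-probe occurrences to the
#' set-averaged weighted sum of control-probe occurrences,
#' \deqn{\frac{\sum_{i=1}^{k} i\, n_i / p_i}{\sum_{i=1}^{k} i\, (m_i/S) / p_i},}
#' with `S` the number of control sets. Levels with `p_i = 0` are
#' skipped. The `"occurrence"` weighting drops the `1/p_i`
#' normalisation (sensitivity variant):
#' \eqn{\sum i\, n_i / \sum i\, m_i / S}.
#'
#' @param spectrum An `occurrence_spectrum`.
#' @param k Truncation level; defaults to [select_k()].
#' @param weights `"paper"` (default, with the `1/p_i` normalisation) or
#'   `"occurrence"`.
#' @return The ratio (>= 0); `Inf` with a warning when the control sum is
#'   zero but the CoRSIV sum is not; error when both are zero.
#' @export
enrichment_ratio <- function(spectrum, k = select_k(spectrum),
                             weights = c("paper", "occurrence")) {
  weights <- match.arg(weights)
  S <- attr(spectrum, "n_control_sets")
  sp <- spectrum[spectrum$i <= k & spectrum$p_i > 0, , drop = FALSE]
  w <- switch(weights, paper = sp$i / sp$p_i, occurrence = sp$i)
  num <- sum(w * sp$n_i)
  den <- sum(w * sp$m_i / S)
  if (den == 0) {
    if (num == 0) abort("both CoRSIV and control weighted sums are zero")
    warn("control weighted sum is zero; enrichment ratio reported as Inf")
    return(Inf)
  }
  num / den
}

#' Permutation test of the enrichment ratio
#'
#' Null draws reassign the CoRSIV label to `|corsiv_probes|` probes
#' sampled without replacement from the union of CoRSIV and pooled
#' control probes; the remainder forms pseudo-control sets of the
#' original total size. `k` is held at its observed value (it is a
#' property of `p_i`, which label permutation does not change; a
#' re-derivation variant is available via `refit_k`). The p-value uses
#' the add-one estimator `(1 + #\{null >= observed\}) / (1 + n_iter)`,
#' so `p` is never zero.
#'
#' @inheritParams build_spectrum
#' @param n_iter Number of permutations (warning below 100).
#' @param seed Seed for the permutation stream.
#' @param weights Passed to [enrichment_ratio()].
#' @param refit_k Recompute `k` per permutation? With this scheme `p_i`
#'   is invariant, so the default `FALSE` is exact.
#' @return A `corsiv_enrichment` object: list with `term`, `ratio`, `k`,
#'   `p_perm`, `n_iter`, `seed`, `spectrum`, `null_ratios`,
#'   `contributing_corsiv_probes`, `contributing_papers`.
#' @export
test_enrichment <- function(inc, corsiv_probes, control_sets,
                            n_iter = 1000, seed = 1,
                            weights = c("paper", "occurrence"),
                            refit_k = FALSE) {
  weights <- match.arg(weights)
  if (n_iter < 100) warn("fewer than 100 permutation iterations; p-value resolution is poor")
  spectrum <- build_spectrum(inc, corsiv_probes, control_sets)
  k <- select_k(spectrum)
  observed <- enrichment_ratio(spectrum, k = k, weights = weights)
  S <- length(control_sets)

  pooled_controls <- unique(unlist(control_sets, use.names = FALSE))
  union_ids <- c(corsiv_probes, setdiff(pooled_controls, corsiv_probes))
  n_c <- length(corsiv_probes)
  if (length(union_ids) < n_c) {
    abort("union of CoRSIV and control probes is smaller than the CoRSIV set")
  }
  counts <- inc$n_papers_reporting[match(union_ids, inc$probe_id)]
  counts[is.na(counts)] <- 0L

  # per-probe weight of a count c: i/p_i (or i) for 1 <= c <= k, else 0
  sp <- spectrum
  wlev <- numeric(max(sp$i, 1L))
  idx <- sp$i <= k & sp$p_i > 0
  wlev[sp$i[idx]] <- if (weights == "paper") sp$i[idx] / sp$p_i[idx] else sp$i[idx]
  wvec <- ifelse(counts >= 1, wlev[pmax(counts, 1L)], 0)
  total <- sum(wvec)

  null_ratios <- withr::with_seed(seed, {
    vapply(seq_len(n_iter), function(it) {
      s <- sum(wvec[sample.int(length(union_ids), n_c)])
      den <- (total - s) / S
      if (den == 0) if (s == 0) 1 else Inf else s / den
    }, numeric(1))
  })
  p_perm <- (1 + sum(null_ratios >= observed)) / (1 + n_iter)

  contributing <- inc$probe_id %in% corsiv_probes &
    inc$n_papers_reporting >= 1 & inc$n_papers_reporting <= k
  structure(list(
    term = attr(inc, "term"), ratio = observed, k = k,
    p_perm = p_perm, n_iter = as.integer(n_iter), seed = as.integer(seed),
    weights = weights, spectrum = spectrum, null_ratios = null_ratios,
    contributing_corsiv_probes = sum(contributing),
    contributing_papers = attr(inc, "n_papers")
  ), class = "corsiv_enrichment")
}

#' @export
print.corsiv_enrichment <- function(x, ...) {
  cat(sprintf("<corsiv_enrichment> term=%s ratio=%.3g k=%d p_perm=%.3g (%d permutations)\n",
              x$term %||% "?", x$ratio, x$k, x$p_perm, x$n_iter))
  invisible(x)
}

#' @rdname test_enrichment
#' @param x A `corsiv_enrichment` object.
#' @param ... Unused.
#' @method tidy corsiv_enrichment
#' @export
tidy.corsiv_enrichment <- function(x, ...) {
  tibble(term = x$term %||% NA_character_, ratio = x$ratio, k = x$k,
         p_perm = x$p_perm, n_iter = x$n_iter,
         contributing_corsiv_probes = x$contributing_corsiv_probes,
         contributing_papers = x$contributing_papers)
}

#' @rdname test_enrichment
#' @method glance corsiv_enrichment
#' @export
glance.corsiv_enrichment <- function(x, ...) {
  tibble(ratio = x$ratio, p_perm = x$p_perm, k = x$k, n_iter = x$n_iter,
         null_median = stats::median(x$null_ratios[is.finite(x$null_ratios)]))
}

#' Occurrence-decay and CoRSIV-overlap curve
#'
#' For each reporting threshold `t`, the number of probes reported in at
#' least `t` papers, the percentage of those that are CoRSIV probes, and
#' the mean percentage that fall in a control set (averaged over sets).
#'
#' @inheritParams build_spectrum
#' @param t_max Largest threshold to tabulate.
#' @return Tibble (threshold, probes_at_least_t, pct_corsiv_overlap,
#'   pct_control_overlap).
#' @export
decay_curve <- function(inc, corsiv_probes, control_sets, t_max = NULL) {
  if (nrow(inc) == 0) {
    return(tibble(threshold = integer(0), probes_at_least_t = integer(0),
                  pct_corsiv_overlap = numeric(0), pct_control_overlap = numeric(0)))
  }
  t_max <- t_max %||% max(inc$n_papers_reporting)
  if (t_max < 1) abort("`t_max` must be >= 1")
  purrr::map_dfr(seq_len(t_max), function(t) {
    ids <- inc$probe_id[inc$n_papers_reporting >= t]
    n <- length(ids)
    tibble(
      threshold = t,
      probes_at_least_t = n,
      pct_corsiv_overlap = if (n > 0) 100 * sum(ids %in% corsiv_probes) / n else NA_real_,
      pct_control_overlap = if (n > 0)
        mean(vapply(control_sets, function(s) 100 * sum(ids %in% s) / n, numeric(1)))
      else NA_real_
    )
  })
}

#' Coverage-scaled power projection
#'
#' Scales an enrichment ratio by the reciprocal of the platform coverage
#' fraction of the region catalog, projecting the fold gain in power of
#' profiling all regions rather than only the platform-covered ones.
#'
#' @param ratio Enrichment ratio.
#' @param coverage_fraction Fraction of regions covered, in (0, 1].
#' @return `ratio / coverage_fraction`.
#' @export
#' @examples
#' power_projection(53.5, 0.155) # ~345
power_projection <- function(ratio, coverage_fraction) {
  if (any(coverage_fraction <= 0 | coverage_fraction > 1)) {
    abort("`coverage_fraction` must lie in (0, 1]")
  }
  ratio / coverage_fraction
}
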