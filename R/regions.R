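# Genomic regions are tibbles (region_id, chrom, start, end, kind) with
# 0-based half-open coordinates; a probe is a single CpG point (pos).

regions_gr <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    region_id = regions$region_id
  )
}

probes_gr <- function(probes) {
  GenomicRanges::GRanges(
    seqnames = probes$chrom,
    ranges = IRanges::IRanges(start = probes$pos + 1L, width = 1L),
    probe_id = probes$probe_id
  )
}

validate_regions <- function(regions) {
  if (nrow(regions) == 0) return(invisible(regions))
  if (any(regions$start >= regions$end)) {
    bad <- regions$region_id[regions$start >= regions$end]
    abort(sprintf("regions with start >= end: %s", paste(head(bad, 5), collapse = ", ")))
  }
  invisible(regions)
}

#' Assign probes to regions by genomic overlap
#'
#' A probe at point `pos` overlaps region `[start, end)` iff
#' `start <= pos < end` on the same chromosome. Regions of the same kind
#' must be disjoint (CoRSIVs are by construction); a probe falling in two
#' same-kind regions raises an error listing the offenders.
#'
#' @param regions Region tibble (region_id, chrom, start, end, kind).
#' @param probes Probe tibble (probe_id, chrom, pos).
#' @return Tibble (region_id, probe_id, chrom, pos), one row per
#'   overlapping pair.
#' @export
overlap_probes <- function(regions, probes) {
  validate_regions(regions)
  if (nrow(regions) == 0 || nrow(probes) == 0) {
    return(tibble(region_id = character(0), probe_id = character(0),
                  chrom = character(0), pos = integer(0)))
  }
  kinds <- regions$kind %||% rep("region", nrow(regions))
  for (k in unique(kinds)) {
    sub <- regions[kinds == k, , drop = FALSE]
    gr <- regions_gr(sub)
    self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
    if (length(self) > 0) {
      pairs <- sprintf("%s/%s",
                       sub$region_id[S4Vectors::queryHits(self)],
                       sub$region_id[S4Vectors::subjectHits(self)])
      abort(sprintf("overlapping %s regions: %s", k,
                    paste(head(pairs, 5), collapse = ", ")))
    }
  }
  hits <- GenomicRanges::findOverlaps(probes_gr(probes), regions_gr(regions))
  tibble(
    region_id = regions$region_id[S4Vectors::subjectHits(hits)],
    probe_id = probes$probe_id[S4Vectors::queryHits(hits)],
    chrom = probes$chrom[S4Vectors::queryHits(hits)],
    pos = probes$pos[S4Vectors::queryHits(hits)]
  ) |> arrange(.data$region_id, .data$pos)
}

#' Coverage summary from region/probe counts
#'
#' The arithmetic core of [coverage_stats()], usable directly with
#' published counts: fraction covered, percent covered at one decimal,
#' and mean probes per covered region.
#'
#' @param n_regions Total regions (> 0).
#' @param n_covered Regions covered by at least one probe.
#' @param n_overlapping_probes Distinct probes falling in any region.
#' @return One-row tibble with the counts, `fraction_covered`,
#'   `pct_covered`, and `mean_probes_per_covered_region`.
#' @export
#' @examples
#' coverage_summary(10388, 1607, 3517)
coverage_summary <- function(n_regions, n_covered, n_overlapping_probes) {
  if (n_regions <= 0) abort("`n_regions` must be positive")
  tibble(
    n_regions = n_regions,
    n_covered = n_covered,
    fraction_covered = n_covered / n_regions,
    pct_covered = 100 * n_covered / n_regions,
    n_overlapping_probes = n_overlapping_probes,
    mean_probes_per_covered_region =
      if (n_covered > 0) n_overlapping_probes / n_covered else NA_real_
  )
}

#' Probe coverage of a region set
#'
#' @inheritParams overlap_probes
#' @return One-row tibble, as [coverage_summary()].
#' @export
coverage_stats <- function(regions, probes) {
  if (nrow(regions) == 0) abort("`regions` is empty")
  ov <- overlap_probes(regions, probes)
  coverage_summary(nrow(regions),
                   dplyr::n_distinct(ov$region_id),
                   dplyr::n_distinct(ov$probe_id))
}

#' Genic-context labels for regions
#'
#' A region inherits the majority context of its member probes; ties are
#' broken by promoter proximity (TSS200 > TSS1500 > 5UTR > Body > 3UTR >
#' Intergenic). Probe-free regions get `NA`.
#'
#' @inheritParams overlap_probes
#' @return Tibble (region_id, context).
#' @export
region_context <- function(regions, probes) {
  ov <- overlap_probes(regions, probes) |>
    dplyr::left_join(probes |> select("probe_id", "context"), by = "probe_id")
  maj <- ov |>
    dplyr::count(.data$region_id, .data$context) |>
    dplyr::mutate(rank = match(.data$context, context_levels())) |>
    dplyr::group_by(.data$region_id) |>
    arrange(dplyr::desc(.data$n), .data$rank, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    select("region_id", "context")
  regions |> select("region_id") |>
    dplyr::left_join(maj, by = "region_id")
}

#' Distribution over genic-context categories
#'
#' Accepts either a probe tibble (with a `context` column), a character
#' vector of context labels, or a region tibble (`start`/`end` present),
#' in which case regions first inherit contexts via [region_context()].
#'
#' @param x Probe tibble, label vector, or region tibble.
#' @param probes Probe tibble; required when `x` is a region tibble.
#' @return Tibble (context, n) covering all six categories (zero counts
#'   included); `n` sums to the size of the input set.
#' @export
context_distribution <- function(x, probes = NULL) {
  labels <-
    if (is.character(x)) x
    else if (all(c("start", "end") %in% names(x))) {
      if (is.null(probes)) abort("`probes` needed to derive region contexts")
      region_context(x, probes)$context
    } else x$context
  tibble(context = factor(labels, levels = context_levels())) |>
    dplyr::count(.data$context, .drop = FALSE) |>
    dplyr::mutate(context = as.character(.data$context))
}

#' Chi-square comparison of one context category between two sets
#'
#' Builds the 2x2 table (in-category vs not) x (observed vs reference)
#' and applies Pearson's chi-square without Yates continuity correction.
#'
#' @param observed,reference Context label vectors, or tibbles with a
#'   `context` column. Both must be nonempty.
#' @param category Context label to test (e.g. `"TSS200"`).
#' @return List with `chi2`, `p`, and the 2x2 `table`.
#' @export
context_chi_square <- function(observed, reference, category) {
  lab <- function(x) if (is.character(x)) x else x$context
  o <- lab(observed); r <- lab(reference)
  if (length(o) == 0 || length(r) == 0) abort("both sets must be nonempty")
  tab <- rbind(
    observed = c(sum(o == category), sum(o != category)),
    reference = c(sum(r == category), sum(r != category))
  )
  colnames(tab) <- c(category, paste0("not_", category))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("a margin of the 2x2 table is zero; consider an exact test (fisher.test)")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value), table = tab)
}
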