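#' Configuration for matched control-region construction
#'
#' @param n_sets Number of control sets (one control region per covered
#'   CoRSIV per set); the analysis design uses 10.
#' @param length_tolerance Preferred relative length difference between a
#'   control region and its CoRSIV; candidates within the tolerance are
#'   preferred, the nearest length is used otherwise.
#' @param exclusion_buffer Minimum distance (bp) any candidate region must
#'   keep from every CoRSIV.
#' @param seed Seed driving the per-set CoRSIV processing order.
#' @param allow_cross_chromosome_fallback If `TRUE`, a CoRSIV whose
#'   same-chromosome candidate pool is exhausted may take a control from
#'   another chromosome (logged); otherwise exhaustion is an error.
#' @return A list of class `match_config`.
#' @export
match_config <- function(n_sets = 10, length_tolerance = 0.5,
                         exclusion_buffer = 1000, seed = 1,
                         allow_cross_chromosome_fallback = FALSE) {
  if (n_sets < 1) abort("`n_sets` must be >= 1")
  if (length_tolerance < 0) abort("`length_tolerance` must be >= 0")
  structure(list(n_sets = as.integer(n_sets),
                 length_tolerance = length_tolerance,
                 exclusion_buffer = as.integer(exclusion_buffer),
                 seed = as.integer(seed),
                 allow_cross_chromosome_fallback = allow_cross_chromosome_fallback),
            class = "match_config")
}

#' Candidate control regions
#'
#' For every window of `q` consecutive non-CoRSIV probes (for each `q` in
#' the range of CoRSIV probe counts) whose span keeps at least
#' `exclusion_buffer` bp away from every CoRSIV, emits a candidate region
#' spanning the first to the last probe of the window (half-open, so a
#' single-probe window has length 1).
#'
#' @param probes Probe tibble (probe_id, chrom, pos).
#' @param corsivs CoRSIV region tibble.
#' @param cfg A [match_config()].
#' @param q_values Integer vector of window sizes; defaults to the sorted
#'   unique probe counts of the covered CoRSIVs.
#' @return Tibble (region_id, chrom, start, end, q, length), canonically
#'   ordered by (chrom, start, q).
#' @export
build_candidates <- function(probes, corsivs, cfg = match_config(),
                             q_values = NULL) {
  validate_regions(corsivs)
  ov <- overlap_probes(corsivs, probes)
  if (is.null(q_values)) {
    q_values <- sort(unique(as.integer(table(ov$region_id))))
  }
  if (length(q_values) == 0) {
    return(tibble(region_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  q = integer(0), length = integer(0)))
  }
  bg <- probes |>
    dplyr::filter(!(.data$probe_id %in% ov$probe_id)) |>
    arrange(.data$chrom, .data$pos)
  buf <- cfg$exclusion_buffer

  out <- vector("list", 0L)
  for (chr in unique(bg$chrom)) {
    pos <- bg$pos[bg$chrom == chr]
    n <- length(pos)
    cc <- corsivs[corsivs$chrom == chr, , drop = FALSE]
    for (q in q_values) {
      if (n < q) next
      s <- pos[seq_len(n - q + 1L)]
      e <- pos[q:n] + 1L
      keep <- rep(TRUE, length(s))
      if (nrow(cc) > 0) {
        # candidate must not intersect any buffer-expanded CoRSIV interval
        cand <- IRanges::IRanges(start = s + 1L, end = e)
        excl <- IRanges::IRanges(start = pmax(0L, cc$start - buf) + 1L,
                                 end = cc$end + buf)
        keep <- IRanges::countOverlaps(cand, excl) == 0
      }
      if (!any(keep)) next
      out[[length(out) + 1L]] <- tibble(
        chrom = chr, start = s[keep], end = e[keep], q = as.integer(q)
      )
    }
  }
  cand <- dplyr::bind_rows(out)
  if (nrow(cand) == 0) {
    return(tibble(region_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0),
                  q = integer(0), length = integer(0)))
  }
  cand |>
    dplyr::mutate(length = .data$end - .data$start,
                  region_id = sprintf("ctrl_%s_%09d_q%d",
                                      .data$chrom, .data$start, .data$q)) |>
    select("region_id", "chrom", "start", "end", "q", "length") |>
    arrange(.data$chrom, .data$start, .data$q)
}

#' Match control regions to covered CoRSIVs
#'
#' Builds `n_sets` control sets. Within each set, CoRSIVs are processed in
#' a seeded random order; each takes, without replacement across all sets,
#' a same-chromosome candidate with exactly its probe count `q`,
#' preferring candidates within the length tolerance and minimising the
#' absolute length difference, with ties broken by genomic distance to
#' the CoRSIV and then lexicographic region id. Selected regions never
#' overlap one another (candidates intersecting a selected region are
#' retired from the pool), so on every successful run
#' `n_control_regions = n_sets * n_covered_corsivs` and
#' `n_control_probes = n_sets * n_corsiv_probes`.
#'
#' @param corsivs CoRSIV region tibble.
#' @param probes Probe tibble.
#' @param cfg A [match_config()].
#' @param candidates Optional candidate pool from [build_candidates()];
#'   built on the fly otherwise.
#' @return A `control_sets` tibble: one row per (set_index, corsiv_id)
#'   with the chosen control region, its `q`, and the length difference.
#' @export
match_controls <- function(corsivs, probes, cfg = match_config(),
                           candidates = NULL) {
  ov <- overlap_probes(corsivs, probes)
  cov <- ov |>
    dplyr::count(.data$region_id, name = "q") |>
    dplyr::inner_join(corsivs, by = "region_id") |>
    dplyr::mutate(length = .data$end - .data$start) |>
    arrange(.data$region_id)
  if (nrow(cov) == 0) abort("no CoRSIV is covered by any probe")
  if (is.null(candidates)) {
    candidates <- build_candidates(probes, corsivs, cfg,
                                   q_values = sort(unique(cov$q)))
  }
  if (nrow(candidates) == 0) abort("candidate pool is empty")

  # canonical candidate order makes selection independent of input order
  candidates <- candidates |> arrange(.data$chrom, .data$start, .data$q)
  n_cand <- nrow(candidates)
  used <- rep(FALSE, n_cand)
  idx_by_cq <- split(seq_len(n_cand), paste(candidates$chrom, candidates$q))
  idx_by_chrom <- split(seq_len(n_cand), candidates$chrom)
  cand_start <- candidates$start
  cand_end <- candidates$end
  cand_len <- candidates$length
  cand_id <- candidates$region_id
  # candidates are start-sorted within a chromosome, so everything that can
  # overlap a selected interval lies in a bounded start window
  max_len_by_chrom <- vapply(idx_by_chrom, function(ix) max(cand_len[ix]), numeric(1))

  pick <- function(pool, corsiv_len, corsiv_start, corsiv_end, tol) {
    if (length(pool) == 0) return(NA_integer_)
    dlen <- abs(cand_len[pool] - corsiv_len)
    within <- dlen <= tol * corsiv_len
    if (any(within)) { pool <- pool[within]; dlen <- dlen[within] }
    best <- pool[dlen == min(dlen)]
    if (length(best) > 1) {
      gap <- pmax(0L, corsiv_start - cand_end[best], cand_start[best] - corsiv_end)
      best <- best[gap == min(gap)]
      if (length(best) > 1) best <- best[cand_id[best] == min(cand_id[best])]
    }
    best[1L]
  }

  rows <- vector("list", cfg$n_sets * nrow(cov))
  ri <- 0L
  fallback_used <- 0L
  withr::with_seed(cfg$seed, {
    for (set in seq_len(cfg$n_sets)) {
      ord <- sample.int(nrow(cov))
      for (j in ord) {
        key <- paste(cov$chrom[j], cov$q[j])
        pool <- idx_by_cq[[key]] %||% integer(0)
        if (length(pool) > 0) {
          pool <- pool[!used[pool]]          # compact: retired candidates leave the pool
          idx_by_cq[[key]] <- pool
        }
        sel <- pick(pool, cov$length[j], cov$start[j], cov$end[j],
                    cfg$length_tolerance)
        if (is.na(sel) && cfg$allow_cross_chromosome_fallback) {
          all_q <- which(candidates$q == cov$q[j] & !used)
          sel <- pick(all_q, cov$length[j], cov$start[j], cov$end[j],
                      cfg$length_tolerance)
          if (!is.na(sel)) fallback_used <- fallback_used + 1L
        }
        if (is.na(sel)) {
          abort(sprintf(
            "control candidate pool exhausted for CoRSIV %s (chrom %s, q = %d)",
            cov$region_id[j], cov$chrom[j], cov$q[j]))
        }
        # retire the chosen candidate and everything overlapping it
        chr <- candidates$chrom[sel]
        chr_idx <- idx_by_chrom[[chr]]
        bounds <- findInterval(c(cand_start[sel] - max_len_by_chrom[[chr]] - 1L,
                                 cand_end[sel] - 1L), cand_start[chr_idx])
        if (bounds[2] >= 1L) {
          win <- chr_idx[max(1L, bounds[1]):bounds[2]]
          used[win[cand_end[win] > cand_start[sel]]] <- TRUE
        }
        ri <- ri + 1L
        rows[[ri]] <- tibble(
          set_index = set, corsiv_id = cov$region_id[j],
          region_id = cand_id[sel], chrom = candidates$chrom[sel],
          start = cand_start[sel], end = cand_end[sel],
          q = cov$q[j], corsiv_length = cov$length[j],
          length = cand_len[sel],
          delta_length = cand_len[sel] - cov$length[j]
        )
      }
    }
  })
  if (fallback_used > 0) {
    inform(sprintf("cross-chromosome fallback used for %d assignment(s)", fallback_used))
  }
  res <- dplyr::bind_rows(rows) |> arrange(.data$set_index, .data$corsiv_id)
  class(res) <- c("control_sets", class(res))
  res
}

#' Probe membership of matched control sets
#'
#' @param matches A `control_sets` tibble from [match_controls()].
#' @param probes Probe tibble.
#' @return Named list (one element per set index) of character vectors of
#'   control probe IDs.
#' @export
control_probe_sets <- function(matches, probes) {
  sets <- sort(unique(matches$set_index))
  setNames(lapply(sets, function(s) {
    reg <- matches |>
      dplyr::filter(.data$set_index == s) |>
      dplyr::mutate(kind = "control") |>
      select("region_id", "chrom", "start", "end", "kind")
    sort(unique(overlap_probes(reg, probes)$probe_id))
  }), paste0("set", sets))
}
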