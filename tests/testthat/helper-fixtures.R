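# Small fixture builders shared across test files.

tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(list(
    seed = seed, n_chromosomes = 2, probes_per_chromosome = 500,
    n_corsivs = 40, n_categories = 2, papers_per_category = 20,
    background_report_prob = 0.005, relative_risk = c(8, 1),
    n_individuals = 10
  ), list(...))
  do.call(synth_config, args)
}

# probe map with fully controlled coordinates
manual_probes <- function(pos, chrom = "chr1", context = "Body",
                          corsiv_id = NA_character_) {
  tibble::tibble(
    probe_id = sprintf("cg%08d", seq_along(pos)),
    chrom = chrom, pos = as.integer(pos),
    context = rep_len(context, length(pos)),
    corsiv_id = rep_len(corsiv_id, length(pos))
  )
}

manual_regions <- function(start, end, chrom = "chr1", kind = "corsiv",
                           prefix = "r") {
  tibble::tibble(
    region_id = sprintf("%s%03d", prefix, seq_along(start)),
    chrom = chrom, start = as.integer(start), end = as.integer(end),
    kind = kind
  )
}

# a long-format panel from a subjects x 2 matrix of betas for one probe
manual_panel <- function(v1, v2, probe_id = "cg00000001") {
  n <- length(v1)
  tibble::tibble(
    probe_id = probe_id,
    subject_id = rep(sprintf("S%03d", seq_len(n)), 2),
    visit = rep(1:2, each = n),
    beta = c(v1, v2)
  )
}

make_incidence <- function(probe_id, counts, term = "t", n_papers = max(counts)) {
  as_incidence(tibble::tibble(probe_id = probe_id, n_papers_reporting = counts),
               term = term, n_papers = n_papers)
}

# spectrum assembled by hand (for ratio arithmetic tests)
manual_spectrum <- function(i, p_i, n_i, m_i, n_sets = 10) {
  structure(tibble::tibble(i = i, p_i = p_i, n_i = n_i, m_i = m_i),
            n_control_sets = n_sets, term = "manual", n_papers = max(i),
            class = c("occurrence_spectrum", class(tibble::tibble())))
}
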