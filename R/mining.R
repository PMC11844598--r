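#' Extract Illumina probe IDs from document text
#'
#' Matches probe IDs at token boundaries: an ID must not be preceded or
#' followed by an alphanumeric character, so `"xcg12345678"`,
#' `"cg123456789"` and `"CG12345678x"` are all rejected while
#' `"(cg00000029)."` matches. The default pattern set recognises only
#' `cg` + exactly 8 digits, case-sensitively; `"cg+ch"` adds
#' non-CpG `ch.<chrom>.<number>[FR]` IDs and `"cg+ch+rs"` adds SNP
#' `rs<number>` IDs. Duplicates are collapsed.
#'
#' @param text Character vector (lines or whole documents).
#' @param pattern_set One of `"cg"`, `"cg+ch"`, `"cg+ch+rs"`.
#' @return Sorted character vector of unique probe IDs (possibly empty).
#' @export
#' @examples
#' extract_probe_ids("methylation at cg00000029 and again cg00000029.")
extract_probe_ids <- function(text, pattern_set = c("cg", "cg+ch", "cg+ch+rs")) {
  pattern_set <- match.arg(pattern_set)
  pats <- c(cg = "(?<![A-Za-z0-9])cg[0-9]{8}(?![A-Za-z0-9])")
  if (pattern_set %in% c("cg+ch", "cg+ch+rs")) {
    pats <- c(pats, ch = "(?<![A-Za-z0-9])ch\\.[0-9XY]+\\.[0-9]+[FR]?(?![A-Za-z0-9.])")
  }
  if (pattern_set == "cg+ch+rs") {
    pats <- c(pats, rs = "(?<![A-Za-z0-9])rs[0-9]+(?![A-Za-z0-9])")
  }
  txt <- paste(text, collapse = "\n")
  hits <- unlist(lapply(pats, function(p) {
    stringr::str_extract_all(txt, stringr::regex(p))[[1]]
  }), use.names = FALSE)
  sort(unique(hits))
}

#' Read a corpus manifest
#'
#' The manifest is a TSV with one row per paper: `paper_id`, `mesh_terms`
#' (semicolon-joined term strings, at least one per paper) and `path`
#' (document file, relative to the manifest's directory). An optional
#' `probe_whitelist` column (semicolon-joined probe IDs) restricts the
#' probes counted for that paper, emulating manual curation of
#' statistically significant probes.
#'
#' @param path Manifest TSV path.
#' @return Tibble with the manifest columns.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("paper_id", "mesh_terms", "path")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols) > 0) {
    abort(sprintf("manifest %s lacks required column(s): %s",
                  path, paste(missing_cols, collapse = ", ")))
  }
  if (any(is.na(m$mesh_terms) | m$mesh_terms == "")) {
    abort("every manifest row must carry at least one MeSH term")
  }
  m
}

#' Mine probe IDs from a manifest-driven document corpus
#'
#' Reads every document named in the manifest, extracts probe IDs with
#' [extract_probe_ids()], and assembles a `paper_corpus` with one row per
#' (paper, probe) pair. Within-paper repeats are collapsed: a probe counts
#' at most once per paper. If the manifest has a `probe_whitelist` column,
#' extracted IDs are intersected with it per paper.
#'
#' @param manifest Manifest tibble from [read_manifest()], or a path.
#' @param root Directory that document paths are relative to (defaults to
#'   the manifest's directory when `manifest` is a path, else `"."`).
#' @param pattern_set Passed to [extract_probe_ids()].
#' @param mesh Optional MeSH edge-list tibble to attach to the corpus.
#' @return A `paper_corpus` (see [gen_corpus()]).
#' @export
mine_corpus <- function(manifest, root = NULL, pattern_set = "cg", mesh = NULL) {
  if (is.character(manifest) && length(manifest) == 1) {
    root <- root %||% dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  root <- root %||% "."
  occ <- purrr::map2(manifest$paper_id, manifest$path, function(id, p) {
    fp <- file.path(root, p)
    if (!file.exists(fp)) abort(sprintf("document not found: %s", fp))
    ids <- extract_probe_ids(readr::read_file(fp), pattern_set = pattern_set)
    if (length(ids) == 0) return(NULL)
    tibble(paper_id = id, probe_id = ids)
  }) |> dplyr::bind_rows()
  if (nrow(occ) == 0) occ <- tibble(paper_id = character(0), probe_id = character(0))
  if ("probe_whitelist" %in% names(manifest)) {
    wl <- manifest |>
      select("paper_id", "probe_whitelist") |>
      dplyr::filter(!is.na(.data$probe_whitelist)) |>
      dplyr::mutate(probe_id = strsplit(.data$probe_whitelist, ";")) |>
      tidyr::unnest("probe_id") |>
      select("paper_id", "probe_id")
    restricted <- unique(wl$paper_id)
    occ <- dplyr::bind_rows(
      occ |> dplyr::filter(!(.data$paper_id %in% restricted)),
      occ |> dplyr::inner_join(wl, by = c("paper_id", "probe_id"))
    )
  }
  papers <- manifest |>
    dplyr::mutate(category = NA_character_) |>
    select("paper_id", "category", "mesh_terms")
  structure(list(papers = papers,
                 occurrences = occ |> dplyr::distinct() |>
                   arrange(.data$paper_id, .data$probe_id),
                 mesh = mesh, truth = NULL),
            class = "paper_corpus")
}

#' Read a MeSH hierarchy edge list
#'
#' @param path TSV with columns `parent` and `child` (term strings).
#' @return Tibble edge list.
#' @export
read_mesh <- function(path) {
  m <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("parent", "child") %in% names(m))) {
    abort(sprintf("MeSH table %s must have columns parent, child", path))
  }
  m
}

#' All descendants of a MeSH term (including the term itself)
#'
#' @param mesh Edge-list tibble (`parent`, `child`).
#' @param term Query term; must appear in the table.
#' @return Character vector of terms.
#' @export
mesh_descendants <- function(mesh, term) {
  if (!(term %in% mesh$parent) && !(term %in% mesh$child)) {
    abort(sprintf("term '%s' not present in the MeSH table", term))
  }
  seen <- term
  frontier <- term
  while (length(frontier) > 0) {
    kids <- mesh$child[mesh$parent %in% frontier]
    frontier <- setdiff(kids, seen)
    seen <- c(seen, frontier)
  }
  seen
}

new_incidence <- function(df, term, n_papers) {
  structure(df, term = term, n_papers = as.integer(n_papers),
            class = c("category_incidence", class(tibble())))
}

#' Construct a category incidence table from columns
#'
#' Useful for assembling an incidence by hand or re-reading one written
#' by the pipeline.
#'
#' @param df Data frame with `probe_id` and `n_papers_reporting` columns.
#' @param term Term label.
#' @param n_papers Number of papers in the term's paper set.
#' @return A `category_incidence` tibble.
#' @export
as_incidence <- function(df, term, n_papers) {
  if (!all(c("probe_id", "n_papers_reporting") %in% names(df))) {
    abort("`df` needs columns probe_id and n_papers_reporting")
  }
  if (any(df$n_papers_reporting < 1) || any(df$n_papers_reporting > n_papers)) {
    abort("counts must lie in [1, n_papers]")
  }
  new_incidence(as_tibble(df[c("probe_id", "n_papers_reporting")]),
                term = term, n_papers = n_papers)
}

#' Per-category probe incidence
#'
#' Selects the papers annotated to `term` or any of its MeSH descendants
#' (each paper counted once, even if annotated to several matching terms)
#' and counts, for every probe, the number of distinct papers in that set
#' reporting it.
#'
#' @param corpus A `paper_corpus`.
#' @param term MeSH term string.
#' @param mesh Edge-list tibble; defaults to `corpus$mesh`. With `NULL`
#'   mesh, papers are matched on the literal term only.
#' @return A `category_incidence` tibble (probe_id, n_papers_reporting),
#'   with attributes `term` and `n_papers` (size of the paper set).
#' @export
build_incidence <- function(corpus, term, mesh = corpus$mesh) {
  terms <- if (is.null(mesh)) term else mesh_descendants(mesh, term)
  ann <- strsplit(corpus$papers$mesh_terms, ";")
  in_set <- vapply(ann, function(a) any(a %in% terms), logical(1))
  ids <- corpus$papers$paper_id[in_set]
  counts <- corpus$occurrences |>
    dplyr::filter(.data$paper_id %in% ids) |>
    dplyr::distinct(.data$paper_id, .data$probe_id) |>
    dplyr::count(.data$probe_id, name = "n_papers_reporting") |>
    arrange(.data$probe_id)
  new_incidence(counts, term = term, n_papers = length(ids))
}

#' Incidence tables for several terms at once
#'
#' @inheritParams build_incidence
#' @param terms Character vector of terms.
#' @return Named list of `category_incidence` tibbles.
#' @export
build_incidence_all <- function(corpus, terms, mesh = corpus$mesh) {
  setNames(lapply(terms, function(t) build_incidence(corpus, t, mesh)), terms)
}

#' Probes reported in at least `t` papers
#'
#' @param inc A `category_incidence`.
#' @param t Reporting threshold (>= 1).
#' @return Character vector of probe IDs.
#' @export
filter_min_papers <- function(inc, t) {
  if (t < 1) abort("threshold `t` must be >= 1")
  inc$probe_id[inc$n_papers_reporting >= t]
}

#' Probes reported in one term and in no other
#'
#' Probes with count >= `t` under `term` and count zero in every other
#' incidence table supplied.
#'
#' @param incidences Named list of `category_incidence` tibbles.
#' @param term Name of the focal term within `incidences`.
#' @param t Reporting threshold in the focal term.
#' @return Character vector of probe IDs.
#' @export
unique_to_term <- function(incidences, term, t = 1) {
  if (!(term %in% names(incidences))) {
    abort(sprintf("term '%s' not among the supplied incidence tables", term))
  }
  hits <- filter_min_papers(incidences[[term]], t)
  others <- unlist(lapply(incidences[setdiff(names(incidences), term)],
                          function(i) i$probe_id), use.names = FALSE)
  sort(setdiff(hits, others))
}
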