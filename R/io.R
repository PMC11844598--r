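# Interchange formats: TSV (tab-separated, header row, UTF-8) with "#"
# provenance comment lines; BED (0-based half-open) for regions; GMT for
# gene sets; JSON for run summaries.

provenance_header <- function(seed = NULL, extra = NULL) {
  c(sprintf("# corsivlit %s", as.character(utils::packageVersion("corsivlit"))),
    if (!is.null(seed)) sprintf("# seed: %s", seed),
    sprintf("# created: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    extra)
}

#' Write a TSV with a provenance header
#'
#' @param x Data frame.
#' @param path Output path.
#' @param seed Optional seed to record.
#' @param extra Optional extra `"# ..."` header lines.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(x, path, seed = NULL, extra = NULL) {
  writeLines(provenance_header(seed, extra), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a provenance-headed TSV
#'
#' @param path Input path.
#' @return Tibble (comment lines skipped).
#' @export
read_tsv_prov <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Read and write BED region files
#'
#' BED3+ with a name column, 0-based half-open, handled through
#' `rtracklayer`. Files are validated line-by-line first so malformed
#' rows (e.g. `start >= end`) are reported with their line number.
#'
#' @param path File path.
#' @param kind Region kind to stamp on the result (`corsiv`, `control`,
#'   `candidate`).
#' @return `read_bed`: region tibble (region_id, chrom, start, end, kind).
#' @export
read_bed <- function(path, kind = "corsiv") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 3) abort(sprintf("%s line %d: fewer than 3 BED fields", path, i))
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e)) abort(sprintf("%s line %d: non-numeric coordinates", path, i))
    if (s >= e) abort(sprintf("%s line %d: start >= end (%s >= %s)", path, i, f[2], f[3]))
  }
  if (!any(keep)) {
    return(tibble(region_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), kind = character(0)))
  }
  gr <- rtracklayer::import(path, format = "bed")
  nm <- if (!is.null(gr$name) && !all(is.na(gr$name))) gr$name
        else sprintf("%s_%06d", kind, seq_along(gr))
  tibble(region_id = nm,
         chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         kind = kind)
}

#' @rdname read_bed
#' @param regions Region tibble (region_id, chrom, start, end).
#' @export
write_bed <- function(regions, path) {
  validate_regions(regions)
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    name = regions$region_id)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect (set name, description, members...), read with
#' `fgsea`; duplicate members within a set are collapsed. Empty files
#' yield an empty collection.
#'
#' @param path GMT path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (file.size(path) == 0) return(setNames(list(), character(0)))
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' @rdname read_gmt
#' @param gene_sets Named list of character vectors.
#' @param descriptions Optional character vector of set descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  if (length(gene_sets) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  descriptions <- descriptions %||% rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descriptions[i], unique(gene_sets[[i]])),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read and write the probe map TSV
#'
#' Columns: probe_id, chrom, pos, context, corsiv_id (NA for non-CoRSIV
#' probes).
#'
#' @param path File path.
#' @return `read_probe_map`: probe tibble.
#' @export
read_probe_map <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    probe_id = readr::col_character(),
                    chrom = readr::col_character(),
                    pos = readr::col_integer(),
                    context = readr::col_character(),
                    corsiv_id = readr::col_character()))
}

#' @rdname read_probe_map
#' @param probes Probe tibble.
#' @param seed Optional seed to record in the header.
#' @export
write_probe_map <- function(probes, path, seed = NULL) {
  write_tsv_prov(probes, path, seed = seed)
}

#' Read a long-format methylation panel TSV
#'
#' Columns: probe_id, subject_id, visit, beta.
#'
#' @param path File path.
#' @return Long beta tibble usable by the stability functions.
#' @export
read_panel <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    probe_id = readr::col_character(),
                    subject_id = readr::col_character(),
                    visit = readr::col_integer(),
                    beta = readr::col_double()))
}

#' Materialise a synthetic corpus as documents plus manifest
#'
#' Each paper becomes a UTF-8 `.txt` document embedding its reported
#' probe IDs amid filler tokens, including near-miss tokens
#' (`cg1234567`, `CG12345678x`, `xcg00000001`, `cg123456789`) that a
#' correct extractor must reject. A manifest TSV (paper_id, mesh_terms,
#' path) and a MeSH edge-list TSV are written alongside.
#'
#' @param corpus A `paper_corpus` from [gen_corpus()].
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest header.
#' @return Paths list (`manifest`, `mesh`, `docs_dir`), invisibly.
#' @export
write_corpus <- function(corpus, dir, seed = NULL) {
  docs_dir <- file.path(dir, "docs")
  dir.create(docs_dir, recursive = TRUE, showWarnings = FALSE)
  filler <- c("DNA methylation was profiled on the Illumina array.",
              "Differential methylation was observed at",
              "adjusting for cell composition and batch;",
              "near-miss tokens: cg1234567 CG12345678x xcg00000001 cg123456789.")
  occ <- split(corpus$occurrences$probe_id, corpus$occurrences$paper_id)
  paths <- character(nrow(corpus$papers))
  for (i in seq_len(nrow(corpus$papers))) {
    id <- corpus$papers$paper_id[i]
    ids <- occ[[id]] %||% character(0)
    body <- c(filler[1], filler[4],
              if (length(ids) > 0) paste(filler[2], paste(ids, collapse = ", "), filler[3]),
              "End of report.")
    rel <- file.path("docs", paste0(id, ".txt"))
    writeLines(body, file.path(dir, rel))
    paths[i] <- rel
  }
  manifest <- corpus$papers |>
    dplyr::mutate(path = paths) |>
    select("paper_id", "mesh_terms", "path")
  manifest_path <- file.path(dir, "manifest.tsv")
  write_tsv_prov(manifest, manifest_path, seed = seed)
  mesh_path <- file.path(dir, "mesh.tsv")
  if (!is.null(corpus$mesh)) write_tsv_prov(corpus$mesh, mesh_path, seed = seed)
  invisible(list(manifest = manifest_path, mesh = mesh_path, docs_dir = docs_dir))
}

#' Write every synthetic input for an end-to-end run
#'
#' Generates the probe map, CoRSIV BED, document corpus with manifest and
#' MeSH table, test-retest panel, concordance scores and gene sets from a
#' single [synth_config()], and writes them under `dir` together with a
#' ground-truth JSON (planted relative risks, true ICCs, planted gene
#' set).
#'
#' @param config A [synth_config()].
#' @param dir Output directory.
#' @param panel_probes Optional probe subset for the methylation panel
#'   (default: all probes).
#' @return Named list of file paths.
#' @export
simulate_study <- function(config, dir, panel_probes = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pm <- gen_probe_map(config)
  corpus <- gen_corpus(config, pm)
  panel <- gen_methylation_panel(config, pm, probes = panel_probes)
  conc <- gen_concordance(config, pm)
  genes <- gen_gene_sets(config, pm)
  s <- config$seed

  paths <- list(
    probe_map = file.path(dir, "probe_map.tsv"),
    corsiv_bed = file.path(dir, "corsivs.bed"),
    panel = file.path(dir, "panel.tsv"),
    concordance = file.path(dir, "concordance.tsv"),
    probe_genes = file.path(dir, "probe_genes.tsv"),
    gmt = file.path(dir, "gene_sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_probe_map(pm$probes, paths$probe_map, seed = s)
  write_bed(pm$corsivs, paths$corsiv_bed)
  cp <- write_corpus(corpus, dir, seed = s)
  paths$manifest <- cp$manifest
  paths$mesh <- cp$mesh
  write_tsv_prov(panel$betas, paths$panel, seed = s)
  write_tsv_prov(conc, paths$concordance, seed = s)
  write_tsv_prov(genes$probe_genes, paths$probe_genes, seed = s)
  write_gmt(genes$gene_sets, paths$gmt)
  jsonlite::write_json(list(
    seed = s,
    relative_risk = setNames(as.list(corpus$truth$relative_risk),
                             corpus$truth$category),
    planted_gene_set = genes$planted,
    true_icc = setNames(as.list(panel$truth$true_icc), panel$truth$probe_id)
  ), paths$truth, auto_unbox = TRUE, digits = NA)
  paths
}
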