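#' Assemble or read an end-to-end run configuration
#'
#' @param paths Named list of input paths: `manifest`, `mesh`,
#'   `probe_map`, `corsiv_bed`; optional `panel`, `concordance`,
#'   `probe_genes`, `gmt`.
#' @param terms Character vector of MeSH terms to analyse.
#' @param out_dir Output directory.
#' @param seed Seed recorded in every output header and driving control
#'   matching and permutations.
#' @param n_sets Control sets to build.
#' @param n_iter Permutation iterations per term.
#' @param min_papers Reporting threshold used for reported probe lists.
#' @param min_bin_size Minimum probes per bin in stability trends.
#' @param pattern_set Probe-ID pattern set for mining.
#' @param run_stability,run_ora Toggle the optional stages.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(paths, terms, out_dir, seed = 1, n_sets = 10,
                       n_iter = 1000, min_papers = 2, min_bin_size = 15,
                       pattern_set = "cg", run_stability = TRUE,
                       run_ora = TRUE) {
  need <- c("manifest", "mesh", "probe_map", "corsiv_bed")
  missing_p <- setdiff(need, names(paths))
  if (length(missing_p) > 0) {
    abort(sprintf("run_config lacks required path(s): %s",
                  paste(missing_p, collapse = ", ")))
  }
  for (nm in names(paths)) {
    if (!is.null(paths[[nm]]) && !file.exists(paths[[nm]])) {
      abort(sprintf("input path '%s' does not exist: %s", nm, paths[[nm]]))
    }
  }
  structure(list(paths = paths, terms = terms, out_dir = out_dir,
                 seed = as.integer(seed), n_sets = as.integer(n_sets),
                 n_iter = as.integer(n_iter), min_papers = min_papers,
                 min_bin_size = min_bin_size, pattern_set = pattern_set,
                 run_stability = run_stability, run_ora = run_ora),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file supplies the fields of [run_config()]; relative input paths
#' are resolved against the config file's directory.
#'
#' @param path Config file (`.yaml`/`.yml` or `.json`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  root <- dirname(path)
  cfg$paths <- lapply(cfg$paths, function(p) {
    if (is.character(p) && !file.exists(p) && file.exists(file.path(root, p)))
      file.path(root, p) else p
  })
  do.call(run_config, cfg)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full literature-enrichment pipeline
#'
#' Executes mine -> overlap -> match -> spectra -> enrichment, plus the
#' optional stability and over-representation stages, for every
#' configured term. Writes per-term incidence and decay TSVs, control
#' BED files with a match-audit TSV, stability records, ORA tables, and
#' a machine-readable `summary.json` (per-term ratio, k, permutation p,
#' projected power) — all headed with provenance (seed, package
#' version). A stage failure aborts with the stage name.
#'
#' @param config A `run_config` (or path to one).
#' @return The summary list, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  s <- config$seed

  probes <- pipeline_stage("read probe map", read_probe_map(config$paths$probe_map))
  corsivs <- pipeline_stage("read CoRSIV BED", read_bed(config$paths$corsiv_bed, kind = "corsiv"))
  mesh <- pipeline_stage("read MeSH table", read_mesh(config$paths$mesh))
  corpus <- pipeline_stage("mine corpus",
    mine_corpus(config$paths$manifest, pattern_set = config$pattern_set, mesh = mesh))

  cov <- pipeline_stage("coverage", coverage_stats(corsivs, probes))
  corsiv_probe_ids <- overlap_probes(corsivs, probes)$probe_id

  matches <- pipeline_stage("match controls",
    match_controls(corsivs, probes,
                   cfg = match_config(n_sets = config$n_sets, seed = s)))
  ctrl_sets <- control_probe_sets(matches, probes)
  write_tsv_prov(matches, file.path(out, "control_audit.tsv"), seed = s)
  for (set in unique(matches$set_index)) {
    reg <- matches |> dplyr::filter(.data$set_index == set)
    write_bed(reg |> select("region_id", "chrom", "start", "end"),
              file.path(out, sprintf("controls_set%02d.bed", set)))
  }

  term_summaries <- list()
  for (term in config$terms) {
    inc <- pipeline_stage(sprintf("incidence [%s]", term),
                          build_incidence(corpus, term, mesh))
    write_tsv_prov(
      inc |> dplyr::mutate(term = term) |>
        select("term", "probe_id", "n_papers_reporting"),
      file.path(out, sprintf("incidence_%s.tsv", term)), seed = s)
    dc <- decay_curve(inc, corsiv_probe_ids, ctrl_sets)
    decay_path <- file.path(out, sprintf("decay_%s.tsv", term))
    write_tsv_prov(dc, decay_path, seed = s)
    enr <- pipeline_stage(sprintf("enrichment [%s]", term),
      test_enrichment(inc, corsiv_probe_ids, ctrl_sets,
                      n_iter = config$n_iter, seed = s))
    term_summaries[[term]] <- list(
      term = term, n_papers = attr(inc, "n_papers"),
      ratio = enr$ratio, k = enr$k, p_perm = enr$p_perm,
      n_iter = enr$n_iter,
      projected_power_fold = power_projection(enr$ratio, cov$fraction_covered),
      decay_table = basename(decay_path))
  }

  stability <- NULL
  if (isTRUE(config$run_stability) && !is.null(config$paths$panel)) {
    stability <- pipeline_stage("stability", {
      panel <- read_panel(config$paths$panel)
      flags <- probes |>
        dplyr::mutate(is_corsiv = !is.na(.data$corsiv_id)) |>
        select("probe_id", "is_corsiv")
      rec <- stability_records(panel, is_corsiv = flags)
      write_tsv_prov(rec, file.path(out, "stability_records.tsv"), seed = s)
      gm <- group_medians(rec)
      write_tsv_prov(gm, file.path(out, "stability_group_medians.tsv"), seed = s)
      lapply(split(gm, gm$is_corsiv), as.list)
    })
  }

  ora_top <- NULL
  if (isTRUE(config$run_ora) && !is.null(config$paths$gmt) &&
      !is.null(config$paths$probe_genes)) {
    ora_top <- pipeline_stage("ora", {
      ann <- read_tsv_prov(config$paths$probe_genes)
      sets <- read_gmt(config$paths$gmt)
      universe <- sort(unique(ann$gene))
      res <- list()
      for (term in config$terms) {
        inc <- build_incidence(corpus, term, mesh)
        qp <- filter_min_papers(inc, config$min_papers)
        qg <- probe_to_genes(qp, ann)
        if (length(qg) == 0 || length(sets) == 0) next
        tab <- ora(qg, sets, universe)
        write_tsv_prov(tab, file.path(out, sprintf("ora_%s.tsv", term)), seed = s)
        res[[term]] <- list(top_set = tab$set_name[1], top_p_adj = tab$p_adj[1])
      }
      res
    })
  }

  summary <- list(
    package = "corsivlit",
    version = as.character(utils::packageVersion("corsivlit")),
    seed = s,
    n_papers = nrow(corpus$papers),
    coverage = as.list(cov),
    n_control_regions = nrow(matches),
    n_control_probes = sum(lengths(ctrl_sets)),
    terms = term_summaries,
    stability = stability,
    ora = ora_top
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_lines <- c(provenance_header(seed = s),
                 sprintf("# R %s", getRversion()),
                 sprintf("terms analysed: %s", paste(config$terms, collapse = ", ")),
                 sprintf("papers: %d, probes: %d, CoRSIVs: %d",
                         nrow(corpus$papers), nrow(probes), nrow(corsivs)))
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(summary)
}
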