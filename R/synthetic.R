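#' Configuration for the synthetic study generator
#'
#' Bundles every parameter the synthetic-data generators need. The defaults
#' describe a desk-scale literature corpus: a 5,000-probe array spread over
#' four chromosomes, 200 CoRSIVs averaging 2.2 probes each, three disease
#' categories of 50 papers, and a test-retest methylation panel of 92
#' individuals profiled twice. Variance components default to values that
#' reproduce the qualitative CoRSIV vs non-CoRSIV contrast seen on real
#' arrays: CoRSIV probes with high between-subject spread and high
#' test-retest stability, non-CoRSIV probes with little of either.
#'
#' @param seed Integer seed; mandatory. All generators derive their random
#'   streams from it, so identical `seed` + config gives identical output.
#' @param n_chromosomes,probes_per_chromosome Array layout.
#' @param n_corsivs Number of CoRSIV regions (all probe-covered).
#' @param probes_per_corsiv Function `n -> integer vector >= 1` drawing the
#'   number of probes per CoRSIV. Default `1 + Poisson(1.2)`, mean 2.2.
#' @param corsiv_length Function `n -> bp lengths` for CoRSIV regions.
#' @param n_categories,papers_per_category Corpus size. Categories get
#'   disease-like names (cancer, neurological, metabolic, ...).
#' @param background_report_prob Per-paper probability `pi` that a given
#'   non-CoRSIV probe is reported.
#' @param relative_risk Planted relative risk `r >= 0`: CoRSIV probes are
#'   reported with probability `min(1, r * pi)`. Scalar or one value per
#'   category. `r = 1` makes CoRSIV and non-CoRSIV probes exchangeable.
#' @param icc_params Named list with elements `corsiv` and `other`, each a
#'   list with between-subject SD `tau` and within-subject SD `sigma` on
#'   the methylation beta scale.
#' @param n_individuals,n_visits Test-retest panel dimensions; `n_visits`
#'   is fixed at 2.
#' @return A list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(seed = 1, n_corsivs = 20, probes_per_chromosome = 100)
synth_config <- function(seed,
                         n_chromosomes = 4,
                         probes_per_chromosome = 1250,
                         n_corsivs = 200,
                         probes_per_corsiv = function(n) 1L + stats::rpois(n, 1.2),
                         corsiv_length = function(n) round(stats::runif(n, 200, 3000)),
                         n_categories = 3,
                         papers_per_category = 50,
                         background_report_prob = 0.002,
                         relative_risk = c(11, 26, 24),
                         icc_params = list(
                           corsiv = list(tau = 0.052, sigma = 0.024),
                           other  = list(tau = 0.008, sigma = 0.018)
                         ),
                         n_individuals = 92,
                         n_visits = 2) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is mandatory and must be a single integer.")
  }
  if (n_visits != 2) abort("`n_visits` is fixed at 2 in the test-retest design.")
  pi0 <- background_report_prob
  if (pi0 < 0 || pi0 > 1) abort("`background_report_prob` must lie in [0, 1].")
  if (any(relative_risk < 0)) abort("`relative_risk` must be >= 0.")
  if (length(relative_risk) == 1) {
    relative_risk <- rep(relative_risk, n_categories)
  }
  if (length(relative_risk) != n_categories) {
    abort("`relative_risk` must be scalar or one value per category.")
  }
  for (g in c("corsiv", "other")) {
    p <- icc_params[[g]]
    if (is.null(p) || p$tau < 0 || p$sigma < 0) {
      abort(sprintf("`icc_params$%s` must supply non-negative `tau` and `sigma`.", g))
    }
  }
  structure(list(
    seed = as.integer(seed),
    n_chromosomes = as.integer(n_chromosomes),
    probes_per_chromosome = as.integer(probes_per_chromosome),
    n_corsivs = as.integer(n_corsivs),
    probes_per_corsiv = probes_per_corsiv,
    corsiv_length = corsiv_length,
    n_categories = as.integer(n_categories),
    papers_per_category = as.integer(papers_per_category),
    background_report_prob = pi0,
    relative_risk = relative_risk,
    icc_params = icc_params,
    n_individuals = as.integer(n_individuals),
    n_visits = 2L
  ), class = "synth_config")
}

default_category_names <- function(n) {
  pool <- c("cancer", "neurological", "metabolic", "cardiovascular",
            "endocrine", "immune", "respiratory", "digestive",
            "urogenital", "hematological", "obesity")
  if (n <= length(pool)) pool[seq_len(n)] else sprintf("category%02d", seq_len(n))
}

#' Generate a synthetic probe map with CoRSIV regions
#'
#' Lays out probes with strictly increasing coordinates per chromosome.
#' CoRSIVs are disjoint intervals separated from background probes by
#' several kilobases, each containing the number of probes drawn from
#' `config$probes_per_corsiv`. Probe IDs follow the Illumina shape
#' (`cg` + 8 digits), assigned sequentially in genome order. Each probe
#' carries a genic-context label from the fixed vocabulary (TSS200,
#' TSS1500, 5UTR, Body, 3UTR, Intergenic); CoRSIV probes are biased toward
#' TSS-proximal contexts, mirroring the promoter-proximal skew of
#' literature-reported CoRSIVs.
#'
#' @param config A [synth_config()].
#' @return A list with elements `probes` (tibble: probe_id, chrom, pos,
#'   context, corsiv_id) and `corsivs` (tibble: region_id, chrom, start,
#'   end, kind; 0-based half-open coordinates).
#' @export
gen_probe_map <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, gen_probe_map_impl(config))
}

gen_probe_map_impl <- function(config) {
  n_chr <- config$n_chromosomes
  ppc <- config$probes_per_chromosome
  n_cor <- config$n_corsivs
  chroms <- sprintf("chr%d", seq_len(n_chr))

  if (n_cor > 0) {
    q <- as.integer(config$probes_per_corsiv(n_cor))
    if (any(q < 1)) abort("probes_per_corsiv drew a value < 1; the distribution must be over >= 1.")
    len <- pmax(as.integer(config$corsiv_length(n_cor)), 2L * q)
    cor_chr <- sort(rep_len(seq_len(n_chr), n_cor))
  } else {
    q <- integer(0); len <- integer(0); cor_chr <- integer(0)
  }

  probe_rows <- vector("list", n_chr)
  corsiv_rows <- vector("list", n_chr)
  for (ci in seq_len(n_chr)) {
    idx <- which(cor_chr == ci)
    need <- sum(q[idx])
    n_bg <- ppc - need
    if (n_bg < 0) {
      abort(sprintf(
        "impossible layout on %s: CoRSIVs require %d probes but only %d are available per chromosome",
        chroms[ci], need, ppc))
    }
    k <- length(idx)
    # how many background probes fall in each of the k+1 inter-CoRSIV segments
    seg <- if (k > 0) as.vector(stats::rmultinom(1, n_bg, rep(1, k + 1))) else n_bg
    cursor <- 1000L
    pos <- integer(0)
    in_cor <- character(0)
    cstart <- integer(0); cend <- integer(0)
    for (s in seq_along(seg)) {
      nb <- seg[s]
      if (nb > 0) {
        gaps <- round(stats::runif(nb, 500, 5000))
        p <- cursor + cumsum(gaps)
        pos <- c(pos, p)
        in_cor <- c(in_cor, rep(NA_character_, nb))
        cursor <- p[nb]
      }
      if (s <= k) {
        j <- idx[s]
        cursor <- cursor + round(stats::runif(1, 3000, 10000))
        start <- cursor
        offs <- if (len[j] > q[j]) sort(sample.int(len[j], q[j]) - 1L) else seq_len(q[j]) - 1L
        pos <- c(pos, start + offs)
        in_cor <- c(in_cor, rep(sprintf("corsiv_%04d", j), q[j]))
        cstart <- c(cstart, start); cend <- c(cend, start + len[j])
        cursor <- start + len[j] + round(stats::runif(1, 3000, 10000))
      }
    }
    probe_rows[[ci]] <- tibble(chrom = chroms[ci], pos = as.integer(pos),
                               corsiv_id = in_cor)
    if (k > 0) {
      corsiv_rows[[ci]] <- tibble(region_id = sprintf("corsiv_%04d", idx),
                                  chrom = chroms[ci],
                                  start = as.integer(cstart),
                                  end = as.integer(cend),
                                  kind = "corsiv")
    }
  }
  probes <- dplyr::bind_rows(probe_rows)
  corsivs <- dplyr::bind_rows(corsiv_rows)
  if (nrow(corsivs) == 0) {
    corsivs <- tibble(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), kind = character(0))
  }
  probes <- probes |> arrange(.data$chrom, .data$pos)
  n <- nrow(probes)
  probes$probe_id <- sprintf("cg%08d", seq_len(n))
  lv <- context_levels()
  bg_probs <- c(0.08, 0.08, 0.08, 0.42, 0.06, 0.28)
  cor_probs <- c(0.20, 0.12, 0.10, 0.38, 0.05, 0.15)
  is_cor <- !is.na(probes$corsiv_id)
  ctx <- character(n)
  if (any(!is_cor)) ctx[!is_cor] <- sample(lv, sum(!is_cor), TRUE, prob = bg_probs)
  if (any(is_cor)) ctx[is_cor] <- sample(lv, sum(is_cor), TRUE, prob = cor_probs)
  probes$context <- ctx
  probes <- probes |> select("probe_id", "chrom", "pos", "context", "corsiv_id")
  list(probes = probes, corsivs = arrange(corsivs, .data$chrom, .data$start))
}

#' Generate a disease-labelled synthetic paper corpus
#'
#' For each category and paper, every probe is reported independently with
#' per-paper probability `pi` (non-CoRSIV) or `min(1, r * pi)` (CoRSIV),
#' where `r` is the category's planted relative risk. Papers are annotated
#' to leaf MeSH terms beneath their category so that hierarchy-aware
#' incidence building is exercised.
#'
#' @param config A [synth_config()].
#' @param probe_map Output of [gen_probe_map()].
#' @return A `paper_corpus`: list with tibbles `papers` (paper_id,
#'   category, mesh_terms), `occurrences` (paper_id, probe_id), `mesh`
#'   (parent, child edge list) and `truth` (category, relative_risk).
#' @export
gen_corpus <- function(config, probe_map) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(probe_map$probes) == 0) abort("probe map is empty")
  withr::with_seed(config$seed + 1L, gen_corpus_impl(config, probe_map))
}

gen_corpus_impl <- function(config, probe_map) {
  cats <- default_category_names(config$n_categories)
  pi0 <- config$background_report_prob
  rr <- config$relative_risk
  probes <- probe_map$probes
  n_probes <- nrow(probes)
  is_cor <- !is.na(probes$corsiv_id)
  P <- config$papers_per_category

  mesh <- dplyr::bind_rows(
    tibble(parent = "diseases", child = cats),
    tibble(parent = rep(cats, each = 2),
           child = paste0(rep(cats, each = 2), c("_subA", "_subB")))
  )

  papers_l <- vector("list", length(cats))
  occ_l <- vector("list", length(cats))
  next_id <- 1L
  for (ci in seq_along(cats)) {
    r <- rr[ci]
    p_probe <- ifelse(is_cor, r * pi0, pi0)
    if (any(p_probe > 1)) {
      warn(sprintf("relative risk %.3g times pi exceeds 1 for category '%s'; clamped",
                   r, cats[ci]))
      p_probe <- pmin(1, p_probe)
    }
    ids <- sprintf("PMID%06d", next_id:(next_id + P - 1L))
    next_id <- next_id + P
    terms <- sample(c(paste0(cats[ci], "_subA"), paste0(cats[ci], "_subB"), cats[ci]),
                    P, replace = TRUE)
    papers_l[[ci]] <- tibble(paper_id = ids, category = cats[ci], mesh_terms = terms)
    hit <- which(matrix(stats::runif(n_probes * P), n_probes, P) < p_probe, arr.ind = TRUE)
    occ_l[[ci]] <- tibble(paper_id = ids[hit[, 2]],
                          probe_id = probes$probe_id[hit[, 1]])
  }
  structure(list(
    papers = dplyr::bind_rows(papers_l),
    occurrences = dplyr::bind_rows(occ_l) |> arrange(.data$paper_id, .data$probe_id),
    mesh = mesh,
    truth = tibble(category = cats, relative_risk = rr)
  ), class = "paper_corpus")
}

#' @export
print.paper_corpus <- function(x, ...) {
  cat(sprintf("<paper_corpus> %d papers, %d categories, %d probe instances\n",
              nrow(x$papers), length(unique(x$papers$category)), nrow(x$occurrences)))
  invisible(x)
}

#' Draw a per-category incidence table directly from the reporting model
#'
#' Equivalent in distribution to generating per-paper Bernoulli reports
#' with [gen_corpus()] and tallying them: because reports are independent
#' across papers, the number of papers reporting a probe is
#' `Binomial(n_papers, prob)`. This is the fast path for calibration
#' studies that need hundreds of replicate corpora; the document-level
#' path exists to exercise the mining stage.
#'
#' @param config A [synth_config()].
#' @param probe_map Output of [gen_probe_map()].
#' @param category Index of the category whose relative risk to use.
#' @param seed Seed for this draw (defaults to `config$seed + 1`).
#' @return A `category_incidence` tibble (probe_id, n_papers_reporting)
#'   with attributes `term` and `n_papers`.
#' @export
sim_incidence <- function(config, probe_map, category = 1L, seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  seed <- seed %||% (config$seed + 1L)
  cats <- default_category_names(config$n_categories)
  r <- config$relative_risk[category]
  pi0 <- config$background_report_prob
  probes <- probe_map$probes
  p <- pmin(1, ifelse(is.na(probes$corsiv_id), pi0, r * pi0))
  counts <- withr::with_seed(seed, stats::rbinom(nrow(probes), config$papers_per_category, p))
  keep <- counts > 0
  new_incidence(
    tibble(probe_id = probes$probe_id[keep], n_papers_reporting = counts[keep]),
    term = cats[category], n_papers = config$papers_per_category
  )
}

#' Generate a test-retest methylation panel
#'
#' Betas follow `clamp01(mu_j + b_js + e_jsv)` with subject effect
#' `b ~ N(0, tau_j^2)` and visit noise `e ~ N(0, sigma_j^2)`; `tau` and
#' `sigma` come from `config$icc_params` by CoRSIV membership. The true
#' intraclass correlation `tau^2 / (tau^2 + sigma^2)` is recorded per
#' probe as ground truth.
#'
#' @param config A [synth_config()] (needs `n_individuals >= 3`).
#' @param probe_map Output of [gen_probe_map()].
#' @param probes Optional character vector restricting to a probe subset.
#' @return A `methylation_panel`: list with `betas` (long tibble:
#'   probe_id, subject_id, visit, beta) and `truth` (probe_id, is_corsiv,
#'   tau, sigma, true_icc).
#' @export
gen_methylation_panel <- function(config, probe_map, probes = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_individuals < 3) abort("need `n_individuals` >= 3 for a test-retest panel")
  withr::with_seed(config$seed + 2L, gen_panel_impl(config, probe_map, probes))
}

gen_panel_impl <- function(config, probe_map, probes) {
  pm <- probe_map$probes
  if (!is.null(probes)) pm <- pm[pm$probe_id %in% probes, , drop = FALSE]
  np <- nrow(pm)
  ns <- config$n_individuals
  is_cor <- !is.na(pm$corsiv_id)
  tau <- ifelse(is_cor, config$icc_params$corsiv$tau, config$icc_params$other$tau)
  sigma <- ifelse(is_cor, config$icc_params$corsiv$sigma, config$icc_params$other$sigma)
  mu <- stats::runif(np, 0.2, 0.8)
  subj <- matrix(stats::rnorm(np * ns, 0, tau), np, ns)   # tau recycles by row
  base <- mu + subj
  v1 <- clamp01(base + matrix(stats::rnorm(np * ns, 0, sigma), np, ns))
  v2 <- clamp01(base + matrix(stats::rnorm(np * ns, 0, sigma), np, ns))
  subj_ids <- sprintf("S%04d", seq_len(ns))
  betas <- tibble(
    probe_id = rep(pm$probe_id, times = 2L * ns),
    subject_id = rep(rep(subj_ids, each = np), times = 2L),
    visit = rep(c(1L, 2L), each = np * ns),
    beta = c(as.vector(v1), as.vector(v2))
  )
  tt <- tau^2 + sigma^2
  truth <- tibble(probe_id = pm$probe_id, is_corsiv = is_cor,
                  tau = tau, sigma = sigma,
                  true_icc = ifelse(tt > 0, tau^2 / tt, NA_real_))
  structure(list(betas = betas, truth = truth,
                 n_individuals = ns, n_visits = 2L),
            class = "methylation_panel")
}

#' @export
print.methylation_panel <- function(x, ...) {
  cat(sprintf("<methylation_panel> %d probes x %d subjects x 2 visits\n",
              nrow(x$truth), x$n_individuals))
  invisible(x)
}

#' Generate a probe-to-gene map and gene-set collection
#'
#' Probes are assigned to genes in blocks of consecutive probes (one gene
#' per ~4 probes in genome order). Random gene sets are drawn from the
#' gene universe, plus one planted set built mostly from CoRSIV-probe
#' genes so that over-representation recovery can be tested against known
#' ground truth.
#'
#' @param config A [synth_config()].
#' @param probe_map Output of [gen_probe_map()].
#' @param n_sets Number of random gene sets in addition to the planted one.
#' @param planted_frac Fraction of the planted set drawn from CoRSIV genes.
#' @return List with `probe_genes` (tibble probe_id, gene), `gene_sets`
#'   (named list of character vectors), and `planted` (name of the
#'   CoRSIV-enriched set).
#' @export
gen_gene_sets <- function(config, probe_map, n_sets = 20, planted_frac = 0.8) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(probe_map$probes) == 0) abort("probe map is empty")
  withr::with_seed(config$seed + 3L, {
    pm <- probe_map$probes
    gene_idx <- ceiling(seq_len(nrow(pm)) / 4)
    probe_genes <- tibble(probe_id = pm$probe_id,
                          gene = sprintf("GENE%05d", gene_idx))
    universe <- unique(probe_genes$gene)
    corsiv_genes <- unique(probe_genes$gene[!is.na(pm$corsiv_id)])
    sets <- list()
    if (n_sets > 0) {
      for (i in seq_len(n_sets)) {
        sz <- sample(20:60, 1)
        sets[[sprintf("SET_%03d", i)]] <- sort(sample(universe, min(sz, length(universe))))
      }
    }
    if (length(corsiv_genes) > 0) {
      sz <- min(50L, length(corsiv_genes))
      n_cor <- round(planted_frac * sz)
      planted <- c(sample(corsiv_genes, n_cor),
                   sample(setdiff(universe, corsiv_genes), sz - n_cor))
      sets[["PLANTED_CORSIV_SET"]] <- sort(unique(planted))
      planted_name <- "PLANTED_CORSIV_SET"
    } else {
      planted_name <- NA_character_
    }
    list(probe_genes = probe_genes, gene_sets = sets, planted = planted_name)
  })
}

#' Generate synthetic blood-brain concordance scores
#'
#' One summary correlation per probe, emulating a per-probe blood-brain
#' concordance table: CoRSIV probes centred high, non-CoRSIV probes near
#' zero, both truncated to `[-1, 1]`.
#'
#' @inheritParams gen_gene_sets
#' @param means,sds Length-2 numeric: (corsiv, other) centre and spread.
#' @return Tibble (probe_id, becon_score).
#' @export
gen_concordance <- function(config, probe_map, means = c(0.40, 0.03),
                            sds = c(0.20, 0.15)) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed + 4L, {
    pm <- probe_map$probes
    is_cor <- !is.na(pm$corsiv_id)
    mu <- ifelse(is_cor, means[1], means[2])
    sd <- ifelse(is_cor, sds[1], sds[2])
    tibble(probe_id = pm$probe_id,
           becon_score = pmin(1, pmax(-1, stats::rnorm(nrow(pm), mu, sd))))
  })
}
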