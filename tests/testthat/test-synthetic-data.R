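test_that("generators are deterministic given seed and config", {
  cfg <- tiny_config(seed = 7)
  pm1 <- gen_probe_map(cfg); pm2 <- gen_probe_map(cfg)
  expect_identical(pm1, pm2)
  expect_identical(gen_corpus(cfg, pm1), gen_corpus(cfg, pm1))
  expect_identical(gen_methylation_panel(cfg, pm1, probes = pm1$probes$probe_id[1:20]),
                   gen_methylation_panel(cfg, pm1, probes = pm1$probes$probe_id[1:20]))
  expect_identical(gen_concordance(cfg, pm1), gen_concordance(cfg, pm1))
})

test_that("probe map layout honours forced counts, empty case, and errors on impossible layouts", {
  cfg <- synth_config(seed = 3, n_chromosomes = 1, probes_per_chromosome = 100,
                      n_corsivs = 5, probes_per_corsiv = function(n) rep(2L, n))
  pm <- gen_probe_map(cfg)
  expect_equal(nrow(pm$probes), 100)
  expect_equal(sum(!is.na(pm$probes$corsiv_id)), 10)
  expect_equal(nrow(pm$corsivs), 5)
  # strictly increasing coordinates per chromosome
  expect_true(all(diff(pm$probes$pos) > 0))
  expect_true(all(pm$probes$context %in%
                    c("TSS200", "TSS1500", "5UTR", "Body", "3UTR", "Intergenic")))
  # every CoRSIV overlaps its drawn number of probes
  ov <- overlap_probes(pm$corsivs, pm$probes)
  expect_true(all(table(ov$region_id) == 2))

  pm0 <- gen_probe_map(synth_config(seed = 3, n_chromosomes = 1,
                                    probes_per_chromosome = 50, n_corsivs = 0))
  expect_equal(sum(!is.na(pm0$probes$corsiv_id)), 0)
  expect_equal(nrow(pm0$corsivs), 0)

  expect_error(
    gen_probe_map(synth_config(seed = 3, n_chromosomes = 1,
                               probes_per_chromosome = 5, n_corsivs = 10,
                               probes_per_corsiv = function(n) rep(3L, n))),
    "impossible layout")
})

test_that("probes-per-CoRSIV distribution has the configured mean", {
  cfg <- synth_config(seed = 11, n_chromosomes = 4, probes_per_chromosome = 1000,
                      n_corsivs = 1000)
  pm <- gen_probe_map(cfg)
  q <- as.integer(table(pm$probes$corsiv_id))
  # default distribution is 1 + Poisson(1.2): mean 2.2, variance 1.2
  se <- sqrt(1.2 / 1000)
  expect_lt(abs(mean(q) - 2.2), 3 * se)
  expect_gte(min(q), 1)
})

test_that("corpus reporting probabilities follow the planted model", {
  cfg0 <- tiny_config(seed = 5, background_report_prob = 0)
  pm <- gen_probe_map(cfg0)
  expect_equal(nrow(gen_corpus(cfg0, pm)$occurrences), 0)

  # r = 1: CoRSIV share of reported instances matches the map's CoRSIV share
  cfg1 <- synth_config(seed = 5, n_chromosomes = 2, probes_per_chromosome = 1000,
                       n_corsivs = 80, n_categories = 1, papers_per_category = 200,
                       background_report_prob = 0.005, relative_risk = 1)
  pm1 <- gen_probe_map(cfg1)
  corpus1 <- gen_corpus(cfg1, pm1)
  frac_map <- mean(!is.na(pm1$probes$corsiv_id))
  is_cor <- corpus1$occurrences$probe_id %in%
    pm1$probes$probe_id[!is.na(pm1$probes$corsiv_id)]
  n_inst <- nrow(corpus1$occurrences)
  expect_lt(abs(mean(is_cor) - frac_map), 3 * sqrt(frac_map * (1 - frac_map) / n_inst))

  # r = 20, small pi: per-paper reporting rate ratio ~ 20
  cfg20 <- synth_config(seed = 6, n_chromosomes = 2, probes_per_chromosome = 5000,
                        n_corsivs = 500, n_categories = 1, papers_per_category = 200,
                        background_report_prob = 0.001, relative_risk = 20)
  pm20 <- gen_probe_map(cfg20)
  corpus20 <- gen_corpus(cfg20, pm20)
  cor_ids <- pm20$probes$probe_id[!is.na(pm20$probes$corsiv_id)]
  P <- 200
  n_cor <- length(cor_ids); n_bg <- nrow(pm20$probes) - n_cor
  hits_cor <- sum(corpus20$occurrences$probe_id %in% cor_ids)
  hits_bg <- nrow(corpus20$occurrences) - hits_cor
  p_cor <- hits_cor / (n_cor * P); p_bg <- hits_bg / (n_bg * P)
  se_ratio <- (p_cor / p_bg) * sqrt(1 / hits_cor + 1 / hits_bg)
  expect_lt(abs(p_cor / p_bg - 20), 3 * se_ratio)

  # r * pi > 1 clamps with a warning
  cfg_cl <- tiny_config(seed = 5, background_report_prob = 0.5,
                        relative_risk = c(3, 1))
  expect_warning(gen_corpus(cfg_cl, pm), "clamped")
})

test_that("sim_incidence matches the document-level corpus tally in distribution", {
  # same per-probe reporting law: compare the count histograms over many draws
  cfg <- synth_config(seed = 9, n_chromosomes = 1, probes_per_chromosome = 400,
                      n_corsivs = 20, n_categories = 1, papers_per_category = 30,
                      background_report_prob = 0.01, relative_risk = 4)
  pm <- gen_probe_map(cfg)
  corpus <- gen_corpus(cfg, pm)
  inc_doc <- build_incidence(corpus, "cancer")
  inc_sim <- sim_incidence(cfg, pm, 1, seed = 9)
  # both must respect the incidence invariants
  for (inc in list(inc_doc, inc_sim)) {
    expect_true(all(inc$n_papers_reporting >= 1))
    expect_true(all(inc$n_papers_reporting <= attr(inc, "n_papers")))
  }
  # total instances agree within sampling error of the shared Binomial law
  exp_inst <- 30 * (0.01 * sum(is.na(pm$probes$corsiv_id)) +
                    0.04 * sum(!is.na(pm$probes$corsiv_id)))
  for (tot in c(sum(inc_doc$n_papers_reporting), sum(inc_sim$n_papers_reporting))) {
    expect_lt(abs(tot - exp_inst), 4 * sqrt(exp_inst))
  }
})

test_that("methylation panel variance components behave as configured", {
  # sigma = 0: both visits identical
  cfg <- tiny_config(seed = 2, icc_params = list(
    corsiv = list(tau = 0.05, sigma = 0), other = list(tau = 0.05, sigma = 0)))
  pm <- gen_probe_map(cfg)
  panel <- gen_methylation_panel(cfg, pm, probes = pm$probes$probe_id[1:30])
  wide <- tidyr::pivot_wider(panel$betas, names_from = visit, values_from = beta)
  expect_equal(wide$`1`, wide$`2`)

  # tau = sigma: true ICC recorded as exactly 0.5
  cfg5 <- tiny_config(seed = 2, icc_params = list(
    corsiv = list(tau = 0.03, sigma = 0.03), other = list(tau = 0.02, sigma = 0.02)))
  panel5 <- gen_methylation_panel(cfg5, pm, probes = pm$probes$probe_id[1:10])
  expect_equal(unique(panel5$truth$true_icc), 0.5)

  # tau = 0: estimated ICC centred at zero at n = 500 subjects
  cfg0 <- tiny_config(seed = 2, n_individuals = 500, icc_params = list(
    corsiv = list(tau = 0, sigma = 0.03), other = list(tau = 0, sigma = 0.03)))
  panel0 <- gen_methylation_panel(cfg0, pm, probes = pm$probes$probe_id[1:100])
  rec <- stability_records(panel0)
  expect_lt(abs(mean(rec$icc)), 0.02)

  expect_error(tiny_config(icc_params = list(
    corsiv = list(tau = -1, sigma = 0.1), other = list(tau = 0.1, sigma = 0.1))),
    "non-negative")
  expect_error(gen_methylation_panel(tiny_config(n_individuals = 2), pm),
               "n_individuals")
})

test_that("gene annotation maps every probe to one gene and plants a recoverable set", {
  cfg <- tiny_config(seed = 13)
  pm <- gen_probe_map(cfg)
  gs <- gen_gene_sets(cfg, pm)
  expect_equal(nrow(gs$probe_genes), nrow(pm$probes))
  expect_equal(anyDuplicated(gs$probe_genes$probe_id), 0)
  expect_true(gs$planted %in% names(gs$gene_sets))

  universe <- unique(gs$probe_genes$gene)
  corsiv_genes <- probe_to_genes(pm$probes$probe_id[!is.na(pm$probes$corsiv_id)],
                                 gs$probe_genes)
  res <- ora(corsiv_genes, gs$gene_sets, universe)
  expect_equal(res$set_name[1], gs$planted)

  # degenerate ORA case: query = universe and one all-gene set gives p = 1
  res1 <- ora(universe, list(all = universe), universe)
  expect_equal(res1$p, 1)
})
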