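# Independent brute-force recomputation of the weighted ratio, written
# against the formula definition rather than the package implementation.
brute_force_ratio <- function(i, p_i, n_i, m_i, k, n_sets) {
  num <- 0; den <- 0
  for (j in seq_along(i)) {
    if (i[j] > k || p_i[j] == 0) next
    num <- num + i[j] * n_i[j] / p_i[j]
    den <- den + i[j] * (m_i[j] / n_sets) / p_i[j]
  }
  num / den
}

test_that("occurrence spectra tabulate exact counts", {
  inc <- make_incidence(c("cgA", "cgB", "cgC"), c(1L, 1L, 2L), n_papers = 5)
  sp <- build_spectrum(inc, corsiv_probes = "cgC", control_sets = list(c("cgA")))
  expect_equal(sp$p_i, c(2L, 1L))
  expect_equal(sp$n_i, c(0L, 1L))
  expect_equal(sp$m_i, c(1L, 0L))
  expect_true(all(sp$n_i <= sp$p_i))
  expect_equal(sum(sp$p_i), nrow(inc))

  empty <- build_spectrum(make_incidence(character(0), integer(0), n_papers = 5),
                          "cgC", list("cgA"))
  expect_equal(nrow(empty), 0)

  # randomized case vs brute-force histogram
  set.seed(71)
  ids <- sprintf("cg%08d", 1:200)
  counts <- sample(1:6, 200, replace = TRUE)
  cor <- sample(ids, 30)
  sets <- split(sample(setdiff(ids, cor), 100), rep(1:2, each = 50))
  inc2 <- make_incidence(ids, counts, n_papers = 10)
  sp2 <- build_spectrum(inc2, cor, sets)
  for (i in 1:6) {
    expect_equal(sp2$p_i[i], sum(counts == i))
    expect_equal(sp2$n_i[i], sum(counts == i & ids %in% cor))
    expect_equal(sp2$m_i[i], sum(counts == i & ids %in% unlist(sets)))
  }
})

test_that("k is the highest occurrence level with at least 10 probes", {
  sp <- manual_spectrum(1:3, c(50L, 12L, 9L), c(0L, 0L, 0L), c(0L, 0L, 0L))
  expect_equal(select_k(sp), 2L)
  expect_equal(select_k(manual_spectrum(1L, 10L, 0L, 0L)), 1L)
  sp4 <- manual_spectrum(1:4, c(500L, 40L, 9L, 11L), rep(0L, 4), rep(0L, 4))
  expect_equal(select_k(sp4), 4L)                      # literal maximum
  expect_equal(select_k(sp4, contiguous = TRUE), 2L)   # contiguity variant
  expect_error(select_k(manual_spectrum(1:2, c(3L, 4L), c(0L, 0L), c(0L, 0L))),
               "unanalyzable")
})

test_that("the weighted enrichment ratio matches hand computation and its contracts", {
  # symmetric construction: n_i = m_i / n_sets for all i -> ratio 1
  sym <- manual_spectrum(1:3, c(100L, 40L, 15L), c(5L, 4L, 2L), c(50L, 40L, 20L))
  expect_equal(enrichment_ratio(sym), 1)

  # worked example: numerator 0.45, denominator 0.12, ratio 3.75
  sp <- manual_spectrum(1:2, c(100L, 20L), c(5L, 4L), c(20L, 10L))
  expect_equal(enrichment_ratio(sp, k = 2), 3.75)
  expect_equal(enrichment_ratio(sp, k = 2),
               brute_force_ratio(1:2, c(100, 20), c(5, 4), c(20, 10), 2, 10))

  # all-zero controls -> Inf with warning; both zero -> error
  inf_sp <- manual_spectrum(1:2, c(100L, 20L), c(5L, 4L), c(0L, 0L))
  expect_warning(r <- enrichment_ratio(inf_sp, k = 2), "Inf")
  expect_equal(r, Inf)
  expect_error(
    suppressWarnings(enrichment_ratio(
      manual_spectrum(1:2, c(100L, 20L), c(0L, 0L), c(0L, 0L)), k = 2)),
    "zero")

  # scale invariance: m_i -> c * m_i with n_sets -> c * n_sets is a no-op
  sp_scaled <- manual_spectrum(1:2, c(100L, 20L), c(5L, 4L), c(60L, 30L), n_sets = 30)
  expect_equal(enrichment_ratio(sp_scaled, k = 2), enrichment_ratio(sp, k = 2))

  # occurrence weighting drops the 1/p_i normalisation
  expect_equal(enrichment_ratio(sp, k = 2, weights = "occurrence"),
               (1 * 5 + 2 * 4) / (1 * 2 + 2 * 1))
})

test_that("ratio equals the brute-force recomputation on random spectra", {
  set.seed(77)
  for (rep in 1:200) {
    imax <- sample(2:8, 1)
    p <- as.integer(sample(0:300, imax, replace = TRUE))
    p[1] <- p[1] + 10L   # guarantee a selectable k
    n <- vapply(p, function(x) as.integer(sample(0:x, 1)), integer(1))
    m <- vapply(p, function(x) as.integer(sample(0:(10 * x), 1)), integer(1))
    sp <- manual_spectrum(seq_len(imax), p, n, m)
    k <- select_k(sp)
    oracle <- brute_force_ratio(seq_len(imax), p, n, m, k, 10)
    if (!is.finite(oracle) || is.nan(oracle)) next
    expect_equal(enrichment_ratio(sp, k = k), oracle, tolerance = 1e-12)
  }
})

test_that("permutation p-values respect the add-one estimator bounds", {
  set.seed(81)
  ids <- sprintf("cg%08d", 1:400)
  cor <- ids[1:40]
  sets <- split(ids[41:400], rep(1:9, each = 40))
  # plant a very strong signal: CoRSIV probes all reported many times
  counts <- c(rep(5L, 40), rep(1L, 100), rep(2L, 15))
  inc <- make_incidence(c(cor, ids[41:140], ids[141:155]), counts, n_papers = 6)
  e <- test_enrichment(inc, cor, sets, n_iter = 200, seed = 4)
  expect_gt(e$ratio, 1)
  expect_gte(e$p_perm, 1 / 201)
  expect_lte(e$p_perm, 1)
  expect_equal(e$p_perm, (1 + sum(e$null_ratios >= e$ratio)) / (1 + e$n_iter))
  # p is 1/(1+n) exactly when the observed ratio beats every null draw
  if (all(e$null_ratios < e$ratio)) expect_equal(e$p_perm, 1 / 201)

  # an observed ratio below every null draw has p = 1: flip the labels so the
  # "CoRSIV" group is the weakly reported one
  weak <- ids[141:180]
  sets_strong <- split(c(cor, ids[181:220], ids[221:260], ids[261:300]),
                       rep(1:4, each = 40))
  inc2 <- make_incidence(c(cor, weak), c(rep(5L, 40), rep(1L, 40)), n_papers = 6)
  e2 <- test_enrichment(inc2, weak, sets_strong, n_iter = 200, seed = 4)
  expect_lt(e2$ratio, 1)
  expect_gt(e2$p_perm, 0.5)

  expect_warning(test_enrichment(inc, cor, sets, n_iter = 50, seed = 4),
                 "fewer than 100")
})

test_that("decay curves recount thresholds exactly and are non-increasing", {
  set.seed(85)
  ids <- sprintf("cg%08d", 1:150)
  counts <- sample(1:5, 150, replace = TRUE)
  cor <- sample(ids, 25)
  sets <- split(sample(setdiff(ids, cor), 50), rep(1:2, each = 25))
  inc <- make_incidence(ids, counts, n_papers = 8)
  dc <- decay_curve(inc, cor, sets, t_max = 5)
  expect_equal(dc$probes_at_least_t[1], 150)
  expect_true(all(diff(dc$probes_at_least_t) <= 0))
  for (t in 1:5) {
    at <- ids[counts >= t]
    expect_equal(dc$probes_at_least_t[t], length(at))
    expect_equal(dc$pct_corsiv_overlap[t], 100 * sum(at %in% cor) / length(at))
    expect_equal(dc$pct_control_overlap[t],
                 mean(c(100 * sum(at %in% sets[[1]]) / length(at),
                        100 * sum(at %in% sets[[2]]) / length(at))))
  }
  empty <- decay_curve(make_incidence(character(0), integer(0), n_papers = 5),
                       cor, sets)
  expect_equal(nrow(empty), 0)
})

test_that("power projection scales ratios by inverse coverage", {
  expect_equal(round(power_projection(53.5, 0.155)), 345)
  expect_equal(round(power_projection(25.7, 0.155)), 166)
  expect_equal(power_projection(7.3, 1), 7.3)
  expect_error(power_projection(5, 0), "coverage_fraction")
})
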