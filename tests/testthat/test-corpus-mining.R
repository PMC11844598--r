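test_that("probe-ID extraction respects token boundaries, case, and deduplication", {
  expect_equal(extract_probe_ids("methylation at cg00000029 and again cg00000029."),
               "cg00000029")
  expect_equal(extract_probe_ids("cg1234567 cg123456789 xcg12345678"), character(0))
  expect_equal(extract_probe_ids("CG12345678 CG12345678x"), character(0))
  expect_equal(extract_probe_ids(""), character(0))
  expect_equal(extract_probe_ids("(cg00000029), cg11111111;"),
               c("cg00000029", "cg11111111"))

  # brute-force oracle: tokenize on non-alphanumerics and keep ^cg\d{8}$
  txt <- paste("cg00000029 cg1234567, (cg00011122). xcg12345678 CG12345678x",
               "cg123456789 rs1234 ch.1.123F cg99999999;cg99999999")
  tokens <- unlist(strsplit(txt, "[^A-Za-z0-9.]+"))
  oracle <- sort(unique(grep("^cg[0-9]{8}$", tokens, value = TRUE)))
  expect_equal(extract_probe_ids(txt), oracle)

  # extended pattern sets
  expect_equal(extract_probe_ids("rs1234 ch.1.123F cg00000001", "cg+ch+rs"),
               c("cg00000001", "ch.1.123F", "rs1234"))
  expect_equal(extract_probe_ids("rs1234 ch.1.123F", "cg+ch"), "ch.1.123F")
})

test_that("mined corpus recovers the generator's ground-truth occurrences", {
  cfg <- tiny_config(seed = 21)
  pm <- gen_probe_map(cfg)
  corpus <- gen_corpus(cfg, pm)
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir, seed = 21)
  mined <- mine_corpus(file.path(dir, "manifest.tsv"))
  expect_equal(mined$occurrences, corpus$occurrences)
  expect_equal(sort(mined$papers$paper_id), sort(corpus$papers$paper_id))
})

test_that("incidence counts distinct papers per probe under the MeSH hierarchy", {
  corpus <- structure(list(
    papers = tibble::tibble(
      paper_id = c("P1", "P2", "P3"),
      category = "x",
      mesh_terms = c("cancer_subA", "cancer_subA;cancer_subB", "other")),
    occurrences = tibble::tibble(
      paper_id = c("P1", "P1", "P2", "P3"),
      probe_id = c("cg00000001", "cg00000002", "cg00000001", "cg00000001")),
    mesh = tibble::tibble(parent = c("diseases", "diseases", "cancer", "cancer"),
                          child = c("cancer", "other", "cancer_subA", "cancer_subB"))
  ), class = "paper_corpus")

  inc <- build_incidence(corpus, "cancer")
  # P2 annotated to two descendants counts once; P3 is outside the subtree
  expect_equal(inc$n_papers_reporting[inc$probe_id == "cg00000001"], 2L)
  expect_equal(inc$n_papers_reporting[inc$probe_id == "cg00000002"], 1L)
  expect_equal(attr(inc, "n_papers"), 2L)
  expect_error(build_incidence(corpus, "nonexistent"), "nonexistent")

  # synthetic corpus: counts equal a brute-force tally of the generator draws
  cfg <- tiny_config(seed = 31)
  pm <- gen_probe_map(cfg)
  cp <- gen_corpus(cfg, pm)
  term <- cp$truth$category[1]
  inc2 <- build_incidence(cp, term)
  in_term <- cp$papers$paper_id[cp$papers$category == term]
  brute <- table(cp$occurrences$probe_id[cp$occurrences$paper_id %in% in_term])
  expect_equal(setNames(inc2$n_papers_reporting, inc2$probe_id),
               setNames(as.integer(brute), names(brute)))
})

test_that("incidence is invariant to document order and within-paper repeats", {
  cfg <- tiny_config(seed = 33)
  pm <- gen_probe_map(cfg)
  cp <- gen_corpus(cfg, pm)
  term <- cp$truth$category[1]
  ref <- build_incidence(cp, term)
  shuf <- cp
  perm <- withr::with_seed(1, sample(nrow(shuf$occurrences)))
  shuf$occurrences <- shuf$occurrences[perm, ]
  # duplicate some occurrence rows: a probe still counts once per paper
  shuf$occurrences <- rbind(shuf$occurrences, shuf$occurrences[1:25, ])
  expect_equal(build_incidence(shuf, term), ref)
})

test_that("reporting-threshold filters match brute force and are monotone in t", {
  ids <- sprintf("cg%08d", 1:50)
  counts <- withr::with_seed(4, sample(1:8, 50, replace = TRUE))
  inc <- make_incidence(ids, counts, n_papers = 10)
  expect_setequal(filter_min_papers(inc, 1), ids)
  expect_length(filter_min_papers(inc, max(counts) + 1), 0)
  sizes <- vapply(1:9, function(t) length(filter_min_papers(inc, t)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  for (t in c(2, 5)) {
    expect_setequal(filter_min_papers(inc, t), ids[counts >= t])
  }
  expect_error(filter_min_papers(inc, 0), ">= 1")
})

test_that("unique_to_term removes probes seen in any other category", {
  incs <- list(
    a = make_incidence(c("cg00000001", "cg00000002", "cg00000003"), c(3L, 2L, 1L), "a", 5),
    b = make_incidence(c("cg00000002", "cg00000004"), c(1L, 2L), "b", 5)
  )
  expect_equal(unique_to_term(incs, "a", t = 1), c("cg00000001", "cg00000003"))
  expect_equal(unique_to_term(incs, "a", t = 2), "cg00000001")
  expect_equal(unique_to_term(incs, "b", t = 3), character(0))
  expect_error(unique_to_term(incs, "c"), "'c'")

  # brute force on random incidences
  all_ids <- sprintf("cg%08d", 1:30)
  rnd <- withr::with_seed(8, lapply(1:3, function(i) {
    ids <- sample(all_ids, 20)
    make_incidence(ids, sample(1:4, 20, replace = TRUE), paste0("t", i), 6)
  }))
  names(rnd) <- paste0("t", 1:3)
  got <- unique_to_term(rnd, "t2", t = 2)
  brute <- setdiff(rnd$t2$probe_id[rnd$t2$n_papers_reporting >= 2],
                   c(rnd$t1$probe_id, rnd$t3$probe_id))
  expect_setequal(got, brute)
})

test_that("manifest whitelist column restricts mined probes per paper", {
  dir <- withr::local_tempdir()
  writeLines("text cg00000001 cg00000002 cg00000003", file.path(dir, "d1.txt"))
  writeLines("text cg00000001 cg00000004", file.path(dir, "d2.txt"))
  manifest <- tibble::tibble(
    paper_id = c("P1", "P2"), mesh_terms = c("x", "x"),
    path = c("d1.txt", "d2.txt"),
    probe_whitelist = c("cg00000001;cg00000003", NA))
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  mined <- mine_corpus(file.path(dir, "manifest.tsv"))
  expect_equal(mined$occurrences$probe_id[mined$occurrences$paper_id == "P1"],
               c("cg00000001", "cg00000003"))
  expect_equal(mined$occurrences$probe_id[mined$occurrences$paper_id == "P2"],
               c("cg00000001", "cg00000004"))
})
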