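test_that("toy ontologies have the group/subtype structure and counts", {
  spec <- fixture_spec(seed = 31, n_disease_groups = 3,
                       subtypes_per_group = c(3, 3), n_cases = 1)
  g <- make_toy_ontology(spec)
  ids <- names(g$terms)
  disease <- ids[startsWith(ids, "MONDO:")]
  # 1 root + 3 groups + 9 subtypes
  expect_length(disease, 1 + 3 + 9)
  subs <- phenodxbench:::subtype_table(g)
  expect_identical(nrow(subs), 9L)
  expect_true(all(startsWith(subs$omim_id, "OMIM:")))
  expect_false(anyDuplicated(subs$omim_id) > 0)
  # phenotype pool present
  expect_length(phenodxbench:::phenotype_pool(g), spec$n_phenotype_terms)
  # every subtype sits one hop under its group
  for (i in seq_len(nrow(subs))) {
    expect_true(subs$mondo_id[i] %in% descendants(g, subs$group_id[i], 1))
  }
})

test_that("the worked-example triple is always group #0", {
  g <- make_toy_ontology(fixture_spec(seed = 32, n_disease_groups = 2,
                                      n_cases = 1))
  expect_true("MONDO:0013612" %in% equivalents(g, "OMIM:614185"))
  expect_true("MONDO:0013612" %in% descendants(g, "MONDO:0000127", 1))
  expect_identical(g$terms[["MONDO:0000127"]]$label, "geleophysic dysplasia")
})

test_that("generator outputs are pure functions of the spec seed", {
  spec <- fixture_spec(seed = 33, n_disease_groups = 4, n_cases = 12,
                       garbage_item_rate = 0.1, synonym_perturbation_rate = 0.3)
  g1 <- make_toy_ontology(spec)
  g2 <- make_toy_ontology(spec)
  expect_identical(g1$json, g2$json)
  c1 <- make_cohort(spec, g1)
  c2 <- make_cohort(spec, g2)
  expect_identical(c1, c2)
  m1 <- make_mock_responses(spec, c1, g1)
  m2 <- make_mock_responses(spec, c2, g2)
  expect_identical(m1, m2)
  # a different seed changes the bundle
  g3 <- make_toy_ontology(fixture_spec(seed = 34, n_disease_groups = 4,
                                       n_cases = 12))
  expect_false(identical(g1$json, g3$json))
})

test_that("cohorts match the configured feature statistics", {
  spec <- fixture_spec(seed = 35, n_cases = 100, n_disease_groups = 5)
  g <- make_toy_ontology(spec)
  cohort <- make_cohort(spec, g)
  n_feat <- vapply(cohort$cases, function(x) length(x$features), 0L)
  expect_lt(abs(mean(n_feat) - 16), 1)
  expect_identical(cohort$manifest$case_id, sprintf("case-%04d", 1:100))
  # gold diagnoses come from the ontology's OMIM-linked subtypes
  expect_true(all(cohort$manifest$gold_id %in%
                    phenodxbench:::subtype_table(g)$omim_id))

  none_excluded <- make_cohort(
    fixture_spec(seed = 36, n_cases = 30, n_disease_groups = 5,
                 excluded_fraction = 0), g)
  excl <- unlist(lapply(none_excluded$cases, function(x)
    vapply(x$features, `[[`, NA, "excluded")))
  expect_false(any(excl))
})

test_that("degenerate rank injection places every correct answer at rank 1", {
  spec <- fixture_spec(seed = 37, n_cases = 25, n_disease_groups = 5,
                       rank_injection = c(rank1 = 1, rank2_3 = 0,
                                          rank4_10 = 0, notfound = 0))
  g <- make_toy_ontology(spec)
  cohort <- make_cohort(spec, g)
  mock <- make_mock_responses(spec, cohort, g)
  expect_true(all(mock$truth$injected_rank == 1L))
  # and the correct label is literally the first item of each response
  for (i in seq_len(nrow(mock$truth))) {
    cid <- mock$truth$case_id[i]
    items <- parse_candidate_list(mock$responses[[cid]], cid)$items
    gold_label <- cohort$manifest$gold_label[cohort$manifest$case_id == cid]
    expect_identical(items[1], gold_label)
  }
})

test_that("parent-label rendering forces roll-up matches and respects the bound", {
  spec <- fixture_spec(seed = 38, n_cases = 40, n_disease_groups = 5,
                       rank_injection = c(rank1 = 0.5, rank2_3 = 0.5,
                                          rank4_10 = 0, notfound = 0))
  g <- make_toy_ontology(spec)
  cohort <- make_cohort(spec, g)
  mock <- make_mock_responses(spec, cohort, g, rendering = "parent")
  expect_true(all(mock$truth$mode == "parent"))
  gold <- stats::setNames(cohort$manifest$gold_id, cohort$manifest$case_id)
  for (cid in names(mock$responses)) {
    raw <- parse_candidate_list(mock$responses[[cid]], cid)
    d <- ground_differential(g, raw, threshold = 0.85)
    r1 <- rank_of_correct(g, d, gold[[cid]], max_descent = 1)
    truth_rank <- mock$truth$injected_rank[mock$truth$case_id == cid]
    expect_identical(r1$rank, as.integer(truth_rank))
    expect_identical(r1$match_type, "rollup")
    # equivalence-only scoring must find nothing
    r0 <- rank_of_correct(g, d, gold[[cid]], max_descent = 0)
    expect_identical(r0$rank, 0L)
  }
})

test_that("injected bucket frequencies follow the configured distribution", {
  probs <- c(rank1 = 0.3, rank2_3 = 0.15, rank4_10 = 0.15, notfound = 0.4)
  spec <- fixture_spec(seed = 39, n_cases = 600, n_disease_groups = 6,
                       rank_injection = probs)
  g <- make_toy_ontology(spec)
  cohort <- make_cohort(spec, g)
  mock <- make_mock_responses(spec, cohort, g)
  r <- mock$truth$injected_rank
  emp <- c(rank1 = mean(r == 1), rank2_3 = mean(r %in% 2:3),
           rank4_10 = mean(r %in% 4:10), notfound = mean(r == 0))
  for (b in names(probs)) {
    sd3 <- 3 * sqrt(probs[[b]] * (1 - probs[[b]]) / spec$n_cases)
    expect_lt(abs(emp[[b]] - probs[[b]]), sd3)
  }
})

test_that("fixture specs validate their rates and dimensions", {
  expect_error(fixture_spec(excluded_fraction = 1.2), "rates")
  expect_error(fixture_spec(rank_injection = c(rank1 = 0.5, rank2_3 = 0.2,
                                               rank4_10 = 0.2, notfound = 0.2)),
               "sum to 1")
  expect_error(fixture_spec(rank_injection = c(a = 1)), "buckets")
  expect_error(fixture_spec(n_disease_groups = 0), "dimensions")
  expect_error(fixture_spec(subtypes_per_group = c(4, 2)), "dimensions")
})
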