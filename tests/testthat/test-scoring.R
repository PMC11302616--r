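test_that("the three-way correctness rule fires in order", {
  g <- worked_example_graph()
  expect_identical(is_correct(g, "OMIM:614185", "OMIM:614185")$match_type,
                   "exact")
  expect_identical(is_correct(g, "MONDO:0013612", "OMIM:614185")$match_type,
                   "equivalent")
  expect_identical(is_correct(g, "MONDO:0000127", "OMIM:614185",
                              max_descent = 1)$match_type, "rollup")
  # sibling subtype never rolls up to its sibling
  expect_identical(is_correct(g, "MONDO:0011883", "OMIM:614185")$match_type,
                   "none")
  # ungrounded candidates are never correct
  expect_identical(is_correct(g, NA_character_, "OMIM:614185")$match_type,
                   "none")
  # equivalence-only mode disables roll-up
  expect_identical(is_correct(g, "MONDO:0000127", "OMIM:614185",
                              max_descent = 0)$match_type, "none")
  expect_identical(is_correct(g, "MONDO:0013612", "OMIM:614185",
                              max_descent = 0)$match_type, "equivalent")
  # a gold id nothing in the graph resolves is a configuration error
  expect_error(is_correct(g, "MONDO:0000127", "OMIM:999999"),
               "not resolvable")
})

test_that("deep roll-up honours the descent bound", {
  path <- write_obo_json(
    list(obo_node("MONDO:0000001", "root"),
         obo_node("MONDO:0000002", "group"),
         obo_node("MONDO:0000003", "subgroup"),
         obo_node("MONDO:0000004", "subtype", xrefs = "OMIM:000001")),
    list(obo_edge("MONDO:0000002", "MONDO:0000001"),
         obo_edge("MONDO:0000003", "MONDO:0000002"),
         obo_edge("MONDO:0000004", "MONDO:0000003")))
  g <- load_ontology(path)
  expect_identical(is_correct(g, "MONDO:0000002", "OMIM:000001",
                              max_descent = 1)$match_type, "none")
  expect_identical(is_correct(g, "MONDO:0000002", "OMIM:000001",
                              max_descent = 2)$match_type, "rollup")
  expect_identical(is_correct(g, "MONDO:0000002", "OMIM:000001",
                              max_descent = Inf)$match_type, "rollup")
})

test_that("correctness is non-decreasing in max_descent", {
  for (seed in c(21, 22)) {
    fix <- random_dag_fixture(n = 35, seed = seed)
    g <- fix$graph
    pairs <- expand.grid(p = fix$ids, gold = sample(fix$ids, 6),
                         stringsAsFactors = FALSE)
    prev <- NULL
    for (md in c(1, 2, 5, Inf)) {
      cur <- mapply(function(p, gold) is_correct(g, p, gold, md)$correct,
                    pairs$p, pairs$gold)
      if (!is.null(prev)) expect_true(all(cur >= prev))
      prev <- cur
    }
  }
})

test_that("is_correct agrees with the brute-force oracle on random DAGs", {
  # small sweep here; the full 200-graph sweep runs in the acceptance suite
  for (seed in 1:20) {
    fix <- random_dag_fixture(n = sample(8:25, 1), seed = 300 + seed)
    classes <- oracle_equiv_classes(fix$ids, fix$xref_pairs)
    golds <- sample(fix$ids, min(5, length(fix$ids)))
    preds <- c(fix$ids, fix$xref_pairs$b)
    for (md in c(1, 2, Inf)) {
      for (gold in golds) {
        for (p in preds) {
          expect_identical(
            is_correct(fix$graph, p, gold, md)$match_type,
            oracle_is_correct(fix, p, gold, md, classes),
            label = sprintf("seed %d pred %s gold %s md %s",
                            seed, p, gold, md))
        }
      }
    }
  }
})

grounded_diff <- function(terms, case_id = "c", source = "llm") {
  n <- length(terms)
  structure(list(
    case_id = case_id, source = source,
    candidates = data.frame(
      position = seq_len(n),
      raw_text = ifelse(is.na(terms), "gibberish", terms),
      term = terms,
      method = ifelse(is.na(terms), "none", "exact"),
      similarity = ifelse(is.na(terms), NA_real_, 1),
      stringsAsFactors = FALSE)),
    class = "differential_diagnosis")
}

test_that("rank_of_correct returns the first correct position", {
  g <- worked_example_graph()
  r <- rank_of_correct(
    g, grounded_diff(c("MONDO:0007947", "MONDO:0011883", "MONDO:0000127")),
    "OMIM:614185")
  expect_identical(r$rank, 3L)
  expect_identical(r$match_type, "rollup")
  expect_identical(r$matched_term, "MONDO:0000127")

  first <- rank_of_correct(g, grounded_diff("MONDO:0013612"), "OMIM:614185")
  expect_identical(first$rank, 1L)
  expect_identical(first$match_type, "equivalent")

  empty <- rank_of_correct(g, grounded_diff(character(0)), "OMIM:614185")
  expect_identical(empty$rank, 0L)
  expect_identical(empty$match_type, "none")

  # ungrounded items consume positions unless dropped
  mixed <- grounded_diff(c(NA, "MONDO:0013612"))
  expect_identical(rank_of_correct(g, mixed, "OMIM:614185")$rank, 2L)
  expect_identical(rank_of_correct(g, mixed, "OMIM:614185",
                                   drop_ungrounded = TRUE)$rank, 1L)
})

test_that("ranked identifier tables score without text grounding", {
  g <- worked_example_graph()
  t1 <- parse_ranked_table("rank\tdisease_id\n1\tOMIM:614185", "c")
  expect_identical(score_exomiser(g, t1, "OMIM:614185")$match_type, "exact")
  expect_identical(score_exomiser(g, t1, "OMIM:614185")$rank, 1L)

  t2 <- parse_ranked_table(
    "rank\tdisease_id\n1\tOMIM:154700\n2\tOMIM:614185", "c")
  expect_identical(score_exomiser(g, t2, "OMIM:614185")$rank, 2L)

  t3 <- parse_ranked_table(paste(
    "rank\tdisease_id",
    "1\tOMIM:154700", "2\tOMIM:231050", "3\tOMIM:617809", "4\tMONDO:0013612",
    sep = "\n"), "c")
  r3 <- score_exomiser(g, t3, "OMIM:614185")
  expect_identical(r3$rank, 4L)
  expect_identical(r3$match_type, "equivalent")
})

test_that("Top-k aggregation computes monotone proportions", {
  res <- do.call(rbind, lapply(c(1, 2, 5, 0), function(r) {
    phenodxbench:::new_case_result(paste0("c", r), "llm", "OMIM:1", r,
                                   NA_character_, if (r) "exact" else "none")
  }))
  rep <- aggregate_topk(res, ks = c(1, 3, 10))
  expect_equal(unname(rep$top_k), c(0.25, 0.5, 0.75))
  expect_true(!is.unsorted(rep$top_k))

  all1 <- res; all1$rank <- 1L
  expect_equal(unname(aggregate_topk(all1, c(1, 3, 10))$top_k), c(1, 1, 1))
  none <- res; none$rank <- 0L
  expect_equal(unname(aggregate_topk(none, c(1, 3, 10))$top_k), c(0, 0, 0))

  expect_error(aggregate_topk(res[0, ]), "no case results")
  mixed <- res; mixed$source[1] <- "other"
  expect_error(aggregate_topk(mixed), "mix sources")
})
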