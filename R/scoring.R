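# Three-way correctness rule over the disease ontology, rank-of-first-correct
# per case, and Top-k aggregation.

#' Judge a predicted diagnosis against the gold diagnosis
#'
#' A candidate is correct when (evaluated in order, first clause wins):
#' \enumerate{
#'   \item \strong{exact} — the predicted identifier equals the gold
#'     identifier;
#'   \item \strong{equivalent} — the two identifiers share an equivalence
#'     class through the ontology's OMIM/Orphanet cross-references (e.g. a
#'     Mondo subtype term vs. the OMIM id it cross-references);
#'   \item \strong{rollup} — the gold diagnosis (or an equivalent of it) is a
#'     close descendant of the predicted term (or an equivalent of it), i.e.
#'     within `max_descent` `is_a` hops below it. This credits general
#'     disease-group answers such as "geleophysic dysplasia" when the gold
#'     diagnosis is the subtype "geleophysic dysplasia 2".
#' }
#'
#' "Close" defaults to one hop (`max_descent = 1`, direct subtypes); `Inf`
#' accepts any descendant; `max_descent = 0` disables the roll-up clause
#' entirely (equivalence-only scoring).
#'
#' @param graph An `ontology_graph`.
#' @param predicted Predicted term CURIE, or `NA` (ungrounded — never
#'   correct).
#' @param gold Gold-standard diagnosis CURIE; it (or an equivalent) must be
#'   present in the graph.
#' @param max_descent Non-negative integer or `Inf`.
#' @return A `match_verdict`: list with `correct` (logical) and `match_type`
#'   (`"exact"`, `"equivalent"`, `"rollup"` or `"none"`).
#' @export
is_correct <- function(graph, predicted, gold, max_descent = 1) {
  gold <- canonical_curie(gold)
  eq_gold <- equivalents(graph, gold)
  if (!any(eq_gold %in% names(graph$terms)) &&
      !gold %in% names(graph$terms)) {
    stop("gold diagnosis not resolvable in ontology: ", gold)
  }
  verdict <- function(type) {
    structure(list(correct = type != "none", match_type = type),
              class = "match_verdict")
  }
  if (is.na(predicted)) return(verdict("none"))
  predicted <- canonical_curie(predicted)
  if (identical(predicted, gold)) return(verdict("exact"))
  eq_pred <- equivalents(graph, predicted)
  if (length(intersect(eq_pred, eq_gold))) return(verdict("equivalent"))
  if (max_descent >= 1) {
    for (p in intersect(eq_pred, names(graph$terms))) {
      if (any(eq_gold %in% descendants(graph, p, max_descent))) {
        return(verdict("rollup"))
      }
    }
  }
  verdict("none")
}

new_case_result <- function(case_id, source, gold_id, rank, matched_term,
                            match_type) {
  data.frame(case_id = case_id, source = source, gold_id = gold_id,
             rank = as.integer(rank), match_type = match_type,
             matched_term = matched_term, stringsAsFactors = FALSE)
}

#' Rank of the first correct candidate in a grounded differential
#'
#' Scans the candidates in response order and records the 1-based position of
#' the first one judged correct by [is_correct()]. Ungrounded candidates are
#' automatically incorrect but still occupy a position (conservative: a
#' grounding failure can never improve a tool's measured rank); with
#' `drop_ungrounded = TRUE` they are removed and positions renumbered before
#' scoring. Rank 0 encodes "correct diagnosis not in the list".
#'
#' @param graph An `ontology_graph`.
#' @param diff A `differential_diagnosis` from [ground_differential()].
#' @param gold Gold diagnosis CURIE.
#' @param max_descent See [is_correct()].
#' @param drop_ungrounded Remove method = "none" candidates before ranking.
#' @return One-row data frame (`case_id`, `source`, `gold_id`, `rank`,
#'   `match_type`, `matched_term`).
#' @export
rank_of_correct <- function(graph, diff, gold, max_descent = 1,
                            drop_ungrounded = FALSE) {
  stopifnot(inherits(diff, "differential_diagnosis"))
  gold <- canonical_curie(gold)
  cand <- diff$candidates
  if (drop_ungrounded) cand <- cand[cand$method != "none", , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    v <- is_correct(graph, cand$term[i], gold, max_descent)
    if (v$correct) {
      return(new_case_result(diff$case_id, diff$source, gold, i,
                             cand$term[i], v$match_type))
    }
  }
  new_case_result(diff$case_id, diff$source, gold, 0L, NA_character_, "none")
}

#' Score a ranked identifier table against the gold diagnosis
#'
#' The identifier-native route for tools that already emit OMIM/Orphanet/
#' Mondo ids: no text grounding is involved, correctness is decided purely by
#' [is_correct()] (identity, equivalence mapping, roll-up) at each rank.
#'
#' @param graph An `ontology_graph`.
#' @param ranked A `ranked_id_list` from [parse_ranked_table()].
#' @param gold Gold diagnosis CURIE.
#' @param max_descent See [is_correct()].
#' @param source Tool name for the result row.
#' @return One-row data frame as in [rank_of_correct()].
#' @export
score_exomiser <- function(graph, ranked, gold, max_descent = 1,
                           source = "exomiser") {
  stopifnot(inherits(ranked, "ranked_id_list"))
  gold <- canonical_curie(gold)
  e <- ranked$entries
  for (i in seq_len(nrow(e))) {
    v <- is_correct(graph, e$disease_id[i], gold, max_descent)
    if (v$correct) {
      return(new_case_result(ranked$case_id, source, gold, e$rank[i],
                             e$disease_id[i], v$match_type))
    }
  }
  new_case_result(ranked$case_id, source, gold, 0L, NA_character_, "none")
}

#' Aggregate per-case ranks into Top-k accuracy
#'
#' `top_k[k]` is the fraction of cases whose first correct candidate has
#' rank between 1 and `k`; rank 0 (not found) never counts. Proportions are
#' necessarily non-decreasing in `k`, which is asserted.
#'
#' @param results Data frame of case results (rows from [rank_of_correct()]
#'   or [score_exomiser()]), all from the same source.
#' @param ks Positive integers, ascending (default `c(1, 3, 10)`).
#' @param mean_grounding_rate Optional mean grounding rate to carry in the
#'   report.
#' @param parameters Optional named list of run parameters (threshold,
#'   max_descent, ontology checksum) recorded for reproducibility.
#' @return A `benchmark_report`: list with `source`, `n_cases`, `top_k`
#'   (named numeric), `mean_grounding_rate` and `parameters`.
#' @export
aggregate_topk <- function(results, ks = c(1, 3, 10),
                           mean_grounding_rate = NA_real_,
                           parameters = list()) {
  if (!is.data.frame(results) || !nrow(results)) {
    stop("no case results to aggregate")
  }
  src <- unique(results$source)
  if (length(src) != 1) {
    stop("results mix sources: ", paste(src, collapse = ", "))
  }
  stopifnot(all(ks >= 1), !is.unsorted(ks, strictly = TRUE))
  n <- nrow(results)
  top_k <- vapply(ks, function(k) sum(results$rank >= 1 & results$rank <= k) / n, 0)
  names(top_k) <- paste0("top", ks)
  stopifnot(!is.unsorted(top_k))
  structure(list(source = src, n_cases = n, top_k = top_k,
                 mean_grounding_rate = mean_grounding_rate,
                 parameters = parameters),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report> ", x$source, " on ", x$n_cases, " cases\n", sep = "")
  for (nm in names(x$top_k)) {
    cat(sprintf("  %-6s %6.3f\n", nm, x$top_k[[nm]]))
  }
  if (!is.na(x$mean_grounding_rate)) {
    cat(sprintf("  grounding rate %.3f\n", x$mean_grounding_rate))
  }
  invisible(x)
}
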