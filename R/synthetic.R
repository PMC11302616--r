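# Seeded generators for toy ontologies, case cohorts and mock tool
# responses, so the whole pipeline can be exercised end to end with known
# ground truth and no external downloads.

#' Specification for the synthetic fixture generators
#'
#' Holds every dial of the fixture generators; all outputs are pure
#' functions of this object, and in particular of its `seed`.
#'
#' @param seed Integer seed driving all sampling.
#' @param n_disease_groups Number of disease groups (each a general term
#'   with subtype children). The geleophysic dysplasia worked-example group
#'   is always group #0 and counts towards this total.
#' @param subtypes_per_group Integer range `c(min, max)` of subtypes per
#'   group (the worked-example group always has its three canonical
#'   subtypes).
#' @param n_cases Cohort size.
#' @param hpo_terms_per_case Mean of the per-case Poisson feature count
#'   (default 16, matching typical deeply-phenotyped case-report corpora).
#' @param excluded_fraction Probability a sampled feature is recorded as
#'   excluded rather than observed.
#' @param rank_injection Named probabilities over the buckets `rank1`,
#'   `rank2_3`, `rank4_10`, `notfound` that the correct diagnosis is placed
#'   at rank 1, ranks 2–3, ranks 4–10, or omitted from a mock response.
#'   Must sum to 1.
#' @param garbage_item_rate Probability a filler item is replaced by an
#'   ungroundable garbage string.
#' @param synonym_perturbation_rate Probability the correct diagnosis is
#'   rendered as one of its exact synonyms instead of its primary label.
#' @param rollup_fraction Probability the correct diagnosis is rendered as
#'   its parent group's label, so only the roll-up scoring clause can
#'   credit it.
#' @param n_phenotype_terms Size of the phenotype-term pool cases draw
#'   features from.
#' @param list_length Number of items in each mock response.
#' @param feature_onset_rate Probability an individual feature carries its
#'   own onset age.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L,
                         n_disease_groups = 10L,
                         subtypes_per_group = c(2L, 4L),
                         n_cases = 100L,
                         hpo_terms_per_case = 16,
                         excluded_fraction = 0.15,
                         rank_injection = c(rank1 = 0.30, rank2_3 = 0.15,
                                            rank4_10 = 0.15, notfound = 0.40),
                         garbage_item_rate = 0,
                         synonym_perturbation_rate = 0,
                         rollup_fraction = 0,
                         n_phenotype_terms = 80L,
                         list_length = 10L,
                         feature_onset_rate = 0.25) {
  spec <- list(seed = as.integer(seed),
               n_disease_groups = as.integer(n_disease_groups),
               subtypes_per_group = as.integer(subtypes_per_group),
               n_cases = as.integer(n_cases),
               hpo_terms_per_case = hpo_terms_per_case,
               excluded_fraction = excluded_fraction,
               rank_injection = rank_injection,
               garbage_item_rate = garbage_item_rate,
               synonym_perturbation_rate = synonym_perturbation_rate,
               rollup_fraction = rollup_fraction,
               n_phenotype_terms = as.integer(n_phenotype_terms),
               list_length = as.integer(list_length),
               feature_onset_rate = feature_onset_rate)
  rates <- c(spec$excluded_fraction, spec$garbage_item_rate,
             spec$synonym_perturbation_rate, spec$rollup_fraction,
             spec$feature_onset_rate, spec$rank_injection)
  if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
  if (!setequal(names(spec$rank_injection),
                c("rank1", "rank2_3", "rank4_10", "notfound"))) {
    stop("rank_injection needs buckets rank1, rank2_3, rank4_10, notfound")
  }
  if (abs(sum(spec$rank_injection) - 1) > 1e-9) {
    stop("rank_injection probabilities must sum to 1")
  }
  if (spec$synonym_perturbation_rate + spec$rollup_fraction > 1) {
    stop("synonym_perturbation_rate + rollup_fraction must be <= 1")
  }
  if (spec$n_disease_groups < 1 || spec$n_cases < 1 ||
      length(spec$subtypes_per_group) != 2 ||
      any(spec$subtypes_per_group < 1) ||
      spec$subtypes_per_group[1] > spec$subtypes_per_group[2] ||
      spec$hpo_terms_per_case <= 0 || spec$list_length < 1) {
    stop("invalid fixture_spec dimensions")
  }
  structure(spec, class = "fixture_spec")
}

# unique fixed-length pseudo-words; equal length means no word can be a
# substring of another, which keeps label-occurrence counting in prompts
# unambiguous
make_word_pool <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  words <- character(0)
  while (length(words) < n) {
    batch <- vapply(seq_len(n), function(i) {
      paste0(sample(cons, 3, TRUE), sample(vow, 3, TRUE), collapse = "")
    }, "")
    words <- unique(c(words, batch))
  }
  words[seq_len(n)]
}

# the worked-example disease group: geleophysic dysplasia and its three
# genetic subtypes with their OMIM cross-references
EXAMPLE_GROUP <- list(
  group = list(id = "MONDO:0000127", label = "geleophysic dysplasia",
               synonyms = "geleophysic dwarfism"),
  subtypes = list(
    list(id = "MONDO:0011883", label = "geleophysic dysplasia 1",
         omim = "OMIM:231050", synonyms = "geleophysic dwarfism 1"),
    list(id = "MONDO:0013612", label = "geleophysic dysplasia 2",
         omim = "OMIM:614185", synonyms = "geleophysic dwarfism 2"),
    list(id = "MONDO:0014276", label = "geleophysic dysplasia 3",
         omim = "OMIM:617809", synonyms = "geleophysic dwarfism 3")))

#' Generate a toy disease ontology
#'
#' Builds an ontology with the group/subtype structure disease ontologies
#' use for genetically heterogeneous diseases: one disease root,
#' `n_disease_groups` general group terms, and per group a set of subtype
#' terms each carrying a unique OMIM cross-reference. The geleophysic
#' dysplasia group (MONDO:0000127 with subtypes 1–3, subtype 2 cross-
#' referenced to OMIM:614185) is always included as group #0 so worked
#' examples are reproducible. A pool of phenotype (HP) terms under a
#' phenotype root supplies case features. Every term has a label and one or
#' two exact synonyms, all globally unique. The graph is serialized to OBO
#' Graph JSON and re-loaded through [load_ontology()], so generated
#' fixtures always satisfy the loader's invariants; the JSON text is
#' attached as `$json`.
#'
#' @param spec A [fixture_spec()].
#' @param out_file Optional path to write the OBO Graph JSON to.
#' @return An `ontology_graph` with a `json` element.
#' @export
make_toy_ontology <- function(spec, out_file = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, {
    n_groups <- spec$n_disease_groups
    n_extra <- n_groups - 1L
    counts <- seq(spec$subtypes_per_group[1], spec$subtypes_per_group[2])
    sub_counts <- if (n_extra > 0) {
      counts[sample.int(length(counts), n_extra, replace = TRUE)]
    } else integer()
    # words: one per extra group + one per subtype synonym + group synonyms
    # + phenotype terms, with headroom
    need <- n_extra * 2L + sum(sub_counts) * 2L + spec$n_phenotype_terms * 2L + 8L
    pool <- make_word_pool(need)
    wi <- 0L
    next_word <- function() {
      wi <<- wi + 1L
      stopifnot(wi <= length(pool))
      pool[wi]
    }

    nodes <- list(list(id = "MONDO:0000001", lbl = "disease",
                       meta = list(synonyms = list(
                         list(val = "disorder", pred = "hasExactSynonym")))))
    edges <- list()
    add_edge <- function(sub, obj) {
      edges[[length(edges) + 1L]] <<- list(sub = sub, pred = "is_a", obj = obj)
    }
    add_node <- function(id, lbl, synonyms = character(), xrefs = character()) {
      meta <- list()
      if (length(synonyms)) {
        meta$synonyms <- lapply(synonyms, function(s)
          list(val = s, pred = "hasExactSynonym"))
      }
      if (length(xrefs)) meta$xrefs <- lapply(xrefs, function(x) list(val = x))
      node <- list(id = id, lbl = lbl)
      if (length(meta)) node$meta <- meta
      nodes[[length(nodes) + 1L]] <<- node
    }

    # group #0: the canonical worked example
    g0 <- EXAMPLE_GROUP
    add_node(g0$group$id, g0$group$label, g0$group$synonyms)
    add_edge(g0$group$id, "MONDO:0000001")
    for (st in g0$subtypes) {
      add_node(st$id, st$label, st$synonyms, st$omim)
      add_edge(st$id, g0$group$id)
    }

    mondo_seq <- 9000000L
    omim_seq <- 700000L
    for (g in seq_len(n_extra)) {
      gw <- next_word()
      mondo_seq <- mondo_seq + 1L
      gid <- sprintf("MONDO:%07d", mondo_seq)
      add_node(gid, paste(gw, "syndrome"), paste(next_word(), "disease"))
      add_edge(gid, "MONDO:0000001")
      for (k in seq_len(sub_counts[g])) {
        mondo_seq <- mondo_seq + 1L
        omim_seq <- omim_seq + 1L
        sid <- sprintf("MONDO:%07d", mondo_seq)
        syns <- paste(next_word(), "disease")
        if (stats::runif(1) < 0.5) syns <- c(syns, paste(gw, "anomaly type", k))
        add_node(sid, paste(gw, "syndrome type", k), syns,
                 sprintf("OMIM:%06d", omim_seq))
        add_edge(sid, gid)
      }
    }

    add_node("HP:0000118", "Phenotypic abnormality")
    for (p in seq_len(spec$n_phenotype_terms)) {
      pid <- sprintf("HP:%07d", 9000000L + p)
      add_node(pid, paste("abnormality of the", next_word()),
               paste(next_word(), "anomaly"))
      add_edge(pid, "HP:0000118")
    }

    doc <- list(graphs = list(list(nodes = nodes, edges = edges)))
    json <- as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE))
  })
  tmp <- out_file %||% tempfile(fileext = ".json")
  writeLines(json, tmp, useBytes = TRUE)
  graph <- load_ontology(tmp)
  if (is.null(out_file)) unlink(tmp)
  graph$json <- json
  graph
}

# disease subtypes (terms carrying an OMIM xref) with their parent group
subtype_table <- function(graph) {
  rows <- lapply(graph$terms, function(t) {
    om <- t$xrefs[curie_prefix(t$xrefs) == "OMIM"]
    if (!length(om) || curie_prefix(t$id) != "MONDO") return(NULL)
    par <- get0(t$id, graph$parents, ifnotfound = character())
    par <- setdiff(par, "MONDO:0000001")
    data.frame(mondo_id = t$id, omim_id = om[[1]], label = t$label,
               group_id = if (length(par)) par[[1]] else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    return(data.frame(mondo_id = character(), omim_id = character(),
                      label = character(), group_id = character()))
  }
  out[order(out$mondo_id), , drop = FALSE]
}

phenotype_pool <- function(graph) {
  ids <- names(graph$terms)
  sort(ids[curie_prefix(ids) == "HP" & ids != "HP:0000118"])
}

sample_iso_age <- function(n) {
  y <- sample(0:15, n, replace = TRUE)
  m <- sample(0:11, n, replace = TRUE)
  ifelse(y == 0 & m == 0, "P0D",
         ifelse(m == 0, sprintf("P%dY", y), sprintf("P%dY%dM", y, m)))
}

#' Generate a synthetic case cohort
#'
#' Draws `n_cases` cases against a toy ontology: each case gets a gold
#' subtype diagnosis (recorded as its OMIM id, as case-report corpora do),
#' a Poisson-distributed number of phenotypic features sampled from the
#' ontology's phenotype pool (mean `hpo_terms_per_case`), a fraction of
#' them flagged excluded, and onset / last-encounter ages. Optionally
#' writes one phenopacket JSON per case.
#'
#' @param spec A [fixture_spec()].
#' @param ontology Graph from [make_toy_ontology()].
#' @param out_dir Optional directory to write phenopacket JSON files into.
#' @return List with `cases` (list of `case_record`) and `manifest`
#'   (data frame `case_id`, `gold_id`, `gold_label`).
#' @export
make_cohort <- function(spec, ontology, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  subs <- subtype_table(ontology)
  pool <- phenotype_pool(ontology)
  if (!nrow(subs)) stop("ontology has no OMIM-linked subtype terms")
  cases <- withr::with_seed(spec$seed + 1L, lapply(seq_len(spec$n_cases), function(i) {
    gold <- subs[sample.int(nrow(subs), 1L), ]
    n_feat <- min(max(1L, stats::rpois(1, spec$hpo_terms_per_case)), length(pool))
    ids <- sample(pool, n_feat)
    excluded <- stats::runif(n_feat) < spec$excluded_fraction
    if (all(excluded)) excluded[1] <- FALSE
    has_onset <- stats::runif(n_feat) < spec$feature_onset_rate
    onsets <- ifelse(has_onset, sample_iso_age(n_feat), NA_character_)
    feats <- lapply(seq_len(n_feat), function(j) {
      new_phenotypic_feature(ids[j], ontology$terms[[ids[j]]]$label,
                             excluded[j], onsets[j])
    })
    onset_age <- if (stats::runif(1) < 0.8) sample_iso_age(1) else NA_character_
    last_enc <- sprintf("P%dY", sample(1:40, 1))
    new_case_record(
      case_id = sprintf("case-%04d", i),
      sex = sample(c("FEMALE", "MALE", "OTHER", "UNKNOWN"), 1,
                   prob = c(0.48, 0.48, 0.02, 0.02)),
      features = feats,
      gold_diagnosis_id = gold$omim_id,
      gold_diagnosis_label = gold$label,
      age_of_onset = onset_age,
      age_at_last_encounter = last_enc)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (case in cases) {
      writeLines(serialize_phenopacket(case),
                 file.path(out_dir, paste0(case$case_id, ".json")),
                 useBytes = TRUE)
    }
  }
  manifest <- data.frame(
    case_id = vapply(cases, `[[`, "", "case_id"),
    gold_id = vapply(cases, `[[`, "", "gold_diagnosis_id"),
    gold_label = vapply(cases, `[[`, "", "gold_diagnosis_label"),
    stringsAsFactors = FALSE)
  list(cases = cases, manifest = manifest)
}

garbage_string <- function() {
  tok <- function() paste(sample(c("j", "q", "w", "x", "y", "h", "c"),
                                 sample(5:8, 1), TRUE), collapse = "")
  paste(vapply(seq_len(sample(2:3, 1)), function(i) tok(), ""), collapse = " ")
}

#' Generate mock free-text responses with injected correct ranks
#'
#' For each case a target rank bucket is drawn from the spec's
#' `rank_injection` distribution and a numbered differential-diagnosis list
#' is written in which the correct disease appears exactly at the drawn rank
#' (or not at all for the `notfound` bucket). The correct disease is
#' rendered as its primary label, an exact synonym, or its parent group's
#' label (forcing a roll-up match), controlled by
#' `synonym_perturbation_rate` / `rollup_fraction` or forced via
#' `rendering`. Remaining positions are filled with diseases from other
#' groups, each replaced by an ungroundable garbage string with probability
#' `garbage_item_rate`. The returned truth table records what was injected,
#' which is what end-to-end recovery tests and benchmarks compare against.
#'
#' @param spec A [fixture_spec()].
#' @param cohort Result of [make_cohort()].
#' @param ontology Graph from [make_toy_ontology()].
#' @param out_dir Optional directory for one `<case_id>.txt` per case.
#' @param rendering `"auto"` (use spec rates) or force `"label"`,
#'   `"synonym"` or `"parent"` for every case.
#' @return List with `responses` (named character vector of response texts)
#'   and `truth` (data frame `case_id`, `injected_rank`, `mode`,
#'   `gold_id`).
#' @export
make_mock_responses <- function(spec, cohort, ontology, out_dir = NULL,
                                rendering = c("auto", "label", "synonym",
                                              "parent")) {
  stopifnot(inherits(spec, "fixture_spec"))
  rendering <- match.arg(rendering)
  subs <- subtype_table(ontology)
  gold_lookup <- stats::setNames(seq_len(nrow(subs)), subs$omim_id)
  out <- withr::with_seed(spec$seed + 2L, {
    buckets <- names(spec$rank_injection)
    rows <- list()
    texts <- character()
    for (case in cohort$cases) {
      gold <- subs[gold_lookup[[case$gold_diagnosis_id]], ]
      bucket <- sample(buckets, 1, prob = spec$rank_injection)
      rank <- switch(bucket,
                     rank1 = 1L,
                     rank2_3 = sample(2:3, 1),
                     rank4_10 = sample(4:10, 1),
                     notfound = 0L)
      if (rank > spec$list_length) {
        stop("injected rank ", rank, " exceeds list_length ", spec$list_length)
      }
      mode <- if (rendering != "auto") rendering else {
        u <- stats::runif(1)
        if (u < spec$rollup_fraction) "parent"
        else if (u < spec$rollup_fraction + spec$synonym_perturbation_rate) "synonym"
        else "label"
      }
      correct_text <- switch(mode,
        label = gold$label,
        synonym = {
          syn <- ontology$terms[[gold$mondo_id]]$synonyms
          ex <- syn$text[syn$scope == "exact"]
          if (!length(ex)) gold$label else sample(ex, 1)
        },
        parent = ontology$terms[[gold$group_id]]$label)
      wrong <- subs$label[subs$group_id != gold$group_id]
      n_fill <- spec$list_length - (rank > 0)
      fillers <- if (length(wrong) >= n_fill) sample(wrong, n_fill)
                 else sample(wrong, n_fill, replace = TRUE)
      fillers <- vapply(fillers, function(f) {
        if (stats::runif(1) < spec$garbage_item_rate) garbage_string() else f
      }, "", USE.NAMES = FALSE)
      items <- if (rank > 0) append(fillers, correct_text, after = rank - 1L)
               else fillers
      text <- paste0(
        "Thank you for the detailed vignette. Based on the phenotype, my ",
        "ranked differential diagnosis is:\n\n",
        paste(sprintf("%d. %s", seq_along(items), items), collapse = "\n"),
        "\n\nI would prioritize confirmatory testing accordingly.\n")
      texts[[case$case_id]] <- text
      rows[[length(rows) + 1L]] <- data.frame(
        case_id = case$case_id, injected_rank = rank, mode = mode,
        gold_id = case$gold_diagnosis_id, stringsAsFactors = FALSE)
    }
    list(responses = texts, truth = do.call(rbind, rows))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cid in names(out$responses)) {
      writeLines(out$responses[[cid]], file.path(out_dir, paste0(cid, ".txt")),
                 useBytes = TRUE)
    }
  }
  out
}
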