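# Shared fixtures: a minimal disease-group graph (the geleophysic dysplasia
# worked example), a random-DAG generator, and an independent brute-force
# scoring oracle that never touches the package's traversal code.

write_obo_json <- function(nodes, edges, path = tempfile(fileext = ".json")) {
  doc <- list(graphs = list(list(nodes = nodes, edges = edges)))
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           pretty = TRUE)), path)
  path
}

obo_node <- function(id, lbl = NULL, synonyms = NULL, xrefs = NULL,
                     deprecated = FALSE) {
  node <- list(id = id)
  if (!is.null(lbl)) node$lbl <- lbl
  meta <- list()
  if (!is.null(synonyms)) {
    meta$synonyms <- lapply(synonyms, function(s)
      list(val = s, pred = "hasExactSynonym"))
  }
  if (!is.null(xrefs)) meta$xrefs <- lapply(xrefs, function(x) list(val = x))
  if (deprecated) meta$deprecated <- TRUE
  if (length(meta)) node$meta <- meta
  node
}

obo_edge <- function(sub, obj, pred = "is_a") list(sub = sub, pred = pred, obj = obj)

# disease root -> geleophysic dysplasia group -> subtypes 1..3, subtype k
# cross-referenced to its OMIM id; plus an unrelated disease and an HP term
worked_example_graph <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    nodes <- list(
      obo_node("MONDO:0000001", "disease"),
      obo_node("MONDO:0000127", "geleophysic dysplasia",
               synonyms = "geleophysic dwarfism"),
      obo_node("MONDO:0011883", "geleophysic dysplasia 1",
               xrefs = "OMIM:231050"),
      obo_node("MONDO:0013612", "geleophysic dysplasia 2",
               xrefs = "OMIM:614185"),
      obo_node("MONDO:0014276", "geleophysic dysplasia 3",
               xrefs = "OMIM:617809"),
      obo_node("MONDO:0007947", "Marfan syndrome", xrefs = "OMIM:154700"),
      obo_node("HP:0001166", "Arachnodactyly"))
    edges <- list(
      obo_edge("MONDO:0000127", "MONDO:0000001"),
      obo_edge("MONDO:0011883", "MONDO:0000127"),
      obo_edge("MONDO:0013612", "MONDO:0000127"),
      obo_edge("MONDO:0014276", "MONDO:0000127"),
      obo_edge("MONDO:0007947", "MONDO:0000001"))
    cache <<- load_ontology(write_obo_json(nodes, edges))
    cache
  }
})

# random DAG over n terms: term i > 1 gets 1-2 parents among earlier terms;
# xref_rate of terms carry an OMIM xref drawn from a small pool so some
# equivalence classes span several terms. Returns the graph plus the raw
# edge list and xref pairs the oracle works from.
random_dag_fixture <- function(n, seed, xref_rate = 0.3, omim_pool = NULL) {
  withr::local_seed(seed)
  ids <- sprintf("MONDO:%07d", seq_len(n))
  if (is.null(omim_pool)) {
    omim_pool <- sprintf("OMIM:%06d", sample(1e5, max(2L, round(n * xref_rate / 1.5))))
  }
  nodes <- list()
  edges <- list()
  edge_df <- data.frame(child = character(), parent = character())
  xref_pairs <- data.frame(a = character(), b = character())
  for (i in seq_len(n)) {
    xr <- NULL
    if (i > 1 && stats::runif(1) < xref_rate) {
      xr <- sample(omim_pool, 1)
      xref_pairs <- rbind(xref_pairs, data.frame(a = ids[i], b = xr))
    }
    nodes[[i]] <- obo_node(ids[i], paste("term", i), xrefs = xr)
    if (i > 1) {
      for (p in sample(seq_len(i - 1), min(i - 1, sample(1:2, 1)))) {
        edges[[length(edges) + 1L]] <- obo_edge(ids[i], ids[p])
        edge_df <- rbind(edge_df, data.frame(child = ids[i], parent = ids[p]))
      }
    }
  }
  list(graph = load_ontology(write_obo_json(nodes, edges)),
       ids = ids, edge_df = unique(edge_df), xref_pairs = xref_pairs)
}

# -- independent oracle -------------------------------------------------------

# equivalence closure by repeated expansion over the raw xref pairs
oracle_equiv_classes <- function(ids, xref_pairs) {
  all_ids <- unique(c(ids, xref_pairs$a, xref_pairs$b))
  cls <- as.list(all_ids)
  names(cls) <- all_ids
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(xref_pairs))) {
      a <- xref_pairs$a[k]; b <- xref_pairs$b[k]
      merged <- sort(unique(c(cls[[a]], cls[[b]])))
      for (m in merged) {
        if (!identical(cls[[m]], merged)) {
          cls[[m]] <- merged
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  cls
}

# all ids reachable by downward paths of length 1..md, by explicit path
# enumeration over the raw edge list
oracle_descendants <- function(edge_df, id, md) {
  out <- character()
  frontier <- id
  steps <- 0
  while (length(frontier) && steps < md) {
    steps <- steps + 1
    frontier <- unique(edge_df$child[edge_df$parent %in% frontier])
    out <- unique(c(out, frontier))
  }
  setdiff(out, id)
}

oracle_is_correct <- function(fix, predicted, gold, md, classes = NULL) {
  if (is.null(classes)) classes <- oracle_equiv_classes(fix$ids, fix$xref_pairs)
  eq <- function(x) if (x %in% names(classes)) classes[[x]] else x
  if (identical(predicted, gold)) return("exact")
  if (length(intersect(eq(predicted), eq(gold)))) return("equivalent")
  if (md >= 1) {
    for (p in intersect(eq(predicted), fix$ids)) {
      if (any(eq(gold) %in% oracle_descendants(fix$edge_df, p, md))) {
        return("rollup")
      }
    }
  }
  "none"
}

# brute-force transitive closure (ancestors) by path-following over edges
oracle_ancestors <- function(edge_df, id) {
  out <- character()
  frontier <- id
  while (length(frontier)) {
    frontier <- unique(edge_df$parent[edge_df$child %in% frontier])
    frontier <- setdiff(frontier, out)
    out <- c(out, frontier)
  }
  sort(setdiff(out, id))
}

# a small phenopacket JSON text used across case-io tests
example_phenopacket_json <- function(n_features = 16, sex = "FEMALE",
                                     gold = "OMIM:614185",
                                     gold_label = "geleophysic dysplasia 2") {
  feats <- lapply(seq_len(n_features), function(i) {
    f <- list(type = list(id = sprintf("HP:%07d", i),
                          label = paste("feature", i)))
    if (i %% 5 == 0) f$excluded <- TRUE
    if (i %% 4 == 0) f$onset <- list(age = list(iso8601duration = "P2Y"))
    f
  })
  pp <- list(
    id = "case-demo",
    subject = list(sex = sex,
                   timeAtLastEncounter = list(age = list(iso8601duration = "P10Y"))),
    phenotypicFeatures = feats,
    diseases = list(list(term = list(id = gold, label = gold_label),
                         onset = list(age = list(iso8601duration = "P1Y6M")))))
  as.character(jsonlite::toJSON(pp, auto_unbox = TRUE))
}
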