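# -- CURIE handling -----------------------------------------------------------

CURIE_PATTERN <- "^[A-Za-z][A-Za-z0-9]*:[A-Za-z0-9.]+$"

#' Canonicalize a compact identifier (CURIE)
#'
#' Identifiers are of the form `PREFIX:LOCAL` (e.g. `MONDO:0000127`,
#' `OMIM:614185`). Prefix comparison is case-insensitive; the canonical form
#' stores the prefix in upper case, and the `Orphanet` prefix is normalized to
#' `ORPHA` so both dialects of Orphanet identifiers compare equal.
#'
#' @param x Character vector of CURIEs or OBO-style IRIs
#'   (`http://purl.obolibrary.org/obo/MONDO_0000127`).
#' @return Character vector of canonical CURIEs.
#' @export
#' @examples
#' canonical_curie(c("omim:614185", "Orphanet:263", "MONDO:0000127"))
canonical_curie <- function(x) {
  x <- as.character(x)
  iri <- grepl("^https?://", x)
  if (any(iri)) {
    local <- sub("^https?://purl\\.obolibrary\\.org/obo/", "", x[iri])
    x[iri] <- sub("_", ":", local)
  }
  bad <- !is.na(x) & !grepl(CURIE_PATTERN, x)
  if (any(bad)) {
    stop("malformed identifier (expected PREFIX:LOCAL): ",
         paste(unique(x[bad]), collapse = ", "))
  }
  pre <- toupper(sub(":.*$", "", x))
  pre[pre == "ORPHANET"] <- "ORPHA"
  ifelse(is.na(x), NA_character_, paste0(pre, ":", sub("^[^:]*:", "", x)))
}

curie_prefix <- function(x) toupper(sub(":.*$", "", x))

# -- Label normalization ------------------------------------------------------

#' Normalize a disease or phenotype label for matching
#'
#' Lower-cases, folds Unicode to ASCII (NFKD decomposition, combining marks
#' removed), replaces punctuation (including en/em dashes and slashes) with
#' single spaces, collapses runs of whitespace and strips leading/trailing
#' space. Used both when building the ontology label index and when looking
#' up query strings, so matching is insensitive to case, accents and
#' punctuation style.
#'
#' @param raw Character vector.
#' @return Character vector of normalized strings (`""` stays `""`).
#' @export
#' @examples
#' normalize_label("Geleophysic Dysplasia,")
#' normalize_label("Loeys–Dietz syndrome")
normalize_label <- function(raw) {
  x <- as.character(raw)
  x <- stringi::stri_trans_general(x, "NFKD; [:Nonspacing Mark:] Remove; Latin-ASCII")
  x <- tolower(x)
  x <- gsub("[.,;:'\"()–—’/-]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# -- Graph construction -------------------------------------------------------

# terms: named list of lists(id, label, synonyms = data.frame(text, scope),
#        xrefs = character, obsolete = logical)
# edges: data.frame(sub, obj) meaning sub is_a obj
build_ontology_graph <- function(terms, edges) {
  ids <- vapply(terms, `[[`, "", "id")
  names(terms) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate term ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  for (t in terms) {
    if (!isTRUE(t$obsolete) && (is.na(t$label) || !nzchar(t$label))) {
      stop("non-obsolete term with empty label: ", t$id)
    }
    syn <- t$synonyms
    if (nrow(syn)) {
      if (any(!nzchar(syn$text))) stop("empty synonym text on ", t$id)
      if (anyDuplicated(syn[c("text", "scope")])) {
        stop("duplicate (text, scope) synonym on ", t$id)
      }
    }
  }
  missing_ep <- setdiff(unique(c(edges$sub, edges$obj)), ids)
  if (length(missing_ep)) {
    stop("edge endpoint not declared as a node: ",
         paste(missing_ep, collapse = ", "))
  }
  edges <- unique(edges[c("sub", "obj")])

  parents <- new.env(parent = emptyenv(), size = length(ids))
  children <- new.env(parent = emptyenv(), size = length(ids))
  for (i in seq_len(nrow(edges))) {
    s <- edges$sub[i]; o <- edges$obj[i]
    assign(s, c(get0(s, parents, ifnotfound = character()), o), envir = parents)
    assign(o, c(get0(o, children, ifnotfound = character()), s), envir = children)
  }
  assert_acyclic(ids, parents)

  # equivalence classes: union-find over term ids and OMIM/ORPHA xrefs
  uf <- new.env(parent = emptyenv())
  uf_find <- function(x) {
    r <- get0(x, uf, ifnotfound = x)
    if (identical(r, x)) return(x)
    root <- uf_find(r)
    assign(x, root, envir = uf)
    root
  }
  uf_union <- function(a, b) {
    ra <- uf_find(a); rb <- uf_find(b)
    if (!identical(ra, rb)) assign(rb, ra, envir = uf)
  }
  members <- character()
  for (t in terms) {
    eq_x <- t$xrefs[curie_prefix(t$xrefs) %in% c("OMIM", "ORPHA")]
    for (x in eq_x) uf_union(t$id, x)
    members <- c(members, t$id, eq_x)
  }
  members <- unique(members)
  roots <- vapply(members, uf_find, "")
  equiv <- new.env(parent = emptyenv())
  for (cls in split(members, roots)) {
    if (length(cls) > 1) {
      cls <- sort(cls)
      for (m in cls) assign(m, cls, envir = equiv)
    }
  }

  # label index over non-obsolete primary labels and exact synonyms
  rows <- lapply(terms, function(t) {
    if (isTRUE(t$obsolete)) return(NULL)
    texts <- t$label
    primary <- TRUE
    ex <- t$synonyms$text[t$synonyms$scope == "exact"]
    if (length(ex)) {
      texts <- c(texts, ex)
      primary <- c(primary, rep(FALSE, length(ex)))
    }
    data.frame(text = normalize_label(texts), id = t$id, primary = primary,
               stringsAsFactors = FALSE)
  })
  match_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(match_table)) {
    match_table <- data.frame(text = character(), id = character(),
                              primary = logical())
  }
  match_table <- match_table[nzchar(match_table$text), , drop = FALSE]
  match_table <- unique(match_table)
  label_index <- new.env(parent = emptyenv(), size = max(1L, nrow(match_table)))
  sp <- split(match_table$id, match_table$text)
  for (k in names(sp)) assign(k, unique(sp[[k]]), envir = label_index)

  structure(
    list(terms = terms, parents = parents, children = children,
         label_index = label_index, equiv = equiv, match_table = match_table,
         edges = edges),
    class = "ontology_graph"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_acyclic <- function(ids, parents) {
  # Kahn's algorithm on the child -> parent relation
  indeg <- integer(length(ids)); names(indeg) <- ids
  for (id in ids) {
    for (p in get0(id, parents, ifnotfound = character())) {
      indeg[[p]] <- indeg[[p]] + 1L
    }
  }
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    for (p in get0(v, parents, ifnotfound = character())) {
      indeg[[p]] <- indeg[[p]] - 1L
      if (indeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(ids)) {
    leftover <- names(indeg)[indeg > 0L]
    cyc <- find_one_cycle(leftover, parents)
    stop("is_a hierarchy contains a cycle: ", paste(cyc, collapse = " -> "))
  }
  invisible(TRUE)
}

find_one_cycle <- function(nodes, parents) {
  onpath <- character()
  visit <- function(v) {
    if (v %in% onpath) {
      return(c(onpath[seq(match(v, onpath), length(onpath))], v))
    }
    onpath <<- c(onpath, v)
    for (p in intersect(get0(v, parents, ifnotfound = character()), nodes)) {
      r <- visit(p)
      if (!is.null(r)) return(r)
    }
    onpath <<- onpath[-length(onpath)]
    NULL
  }
  for (n in nodes) {
    r <- visit(n)
    if (!is.null(r)) return(r)
  }
  nodes[1]
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", length(x$terms), " terms, ",
      nrow(x$edges), " is_a edges, ",
      length(ls(x$equiv)), " ids in non-trivial equivalence classes\n", sep = "")
  invisible(x)
}

# -- Loading OBO Graph JSON ---------------------------------------------------

#' Load a disease ontology from OBO Graph JSON
#'
#' Reads the strict subset of the OBO Graph JSON format that disease
#' ontologies such as Mondo are distributed in: `nodes[]` with `id`, `lbl`,
#' `meta.synonyms[].{val,pred}`, `meta.deprecated`, `meta.xrefs[].val`, and
#' `edges[]` with `sub`/`pred`/`obj`. Both `is_a` and `subClassOf` edge
#' predicates are accepted; all other predicates are ignored. OBO PURL IRIs
#' are converted to CURIEs. Cross-references to OMIM and Orphanet identifiers
#' become equivalence mappings, closed under transitivity (union-find), so an
#' equivalence class behaves as a single disease across nomenclatures.
#' Obsolete terms are loaded (their ids stay resolvable) but are excluded
#' from label matching.
#'
#' @param path Path to an OBO Graph JSON file.
#' @return An `ontology_graph` object.
#' @export
load_ontology <- function(path) {
  if (!file.exists(path)) stop("ontology file not found: ", path)
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("malformed OBO Graph JSON in ", path, ": ",
                             conditionMessage(e))
  )
  g <- if (!is.null(doc$graphs)) doc$graphs[[1]] else doc
  if (is.null(g$nodes)) stop("malformed OBO Graph JSON: no nodes[] in ", path)

  terms <- lapply(g$nodes, function(n) {
    if (is.null(n$id)) stop("malformed OBO Graph JSON: node without id")
    id <- tryCatch(canonical_curie(n$id),
                   error = function(e) stop("node '", n$id, "': ",
                                            conditionMessage(e)))
    syn <- data.frame(text = character(), scope = character(),
                      stringsAsFactors = FALSE)
    if (!is.null(n$meta$synonyms)) {
      texts <- vapply(n$meta$synonyms, function(s) s$val %||% "", "")
      preds <- vapply(n$meta$synonyms, function(s) s$pred %||% "", "")
      scope <- ifelse(grepl("exact", preds, ignore.case = TRUE), "exact", "related")
      syn <- unique(data.frame(text = texts, scope = scope,
                               stringsAsFactors = FALSE))
      syn <- syn[nzchar(syn$text), , drop = FALSE]
    }
    xr <- character()
    if (!is.null(n$meta$xrefs)) {
      raw <- vapply(n$meta$xrefs, function(x) x$val %||% "", "")
      raw <- raw[grepl(CURIE_PATTERN, raw)]
      if (length(raw)) xr <- canonical_curie(raw)
    }
    list(id = id,
         label = n$lbl %||% NA_character_,
         synonyms = syn,
         xrefs = xr,
         obsolete = isTRUE(n$meta$deprecated))
  })

  edges <- data.frame(sub = character(), obj = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(g$edges)) {
    keep <- vapply(g$edges, function(e) {
      p <- e$pred %||% ""
      grepl("(^|[#/])(is_a|subClassOf)$", p)
    }, NA)
    es <- g$edges[keep]
    if (length(es)) {
      edges <- data.frame(
        sub = canonical_curie(vapply(es, function(e) e$sub, "")),
        obj = canonical_curie(vapply(es, function(e) e$obj, "")),
        stringsAsFactors = FALSE)
    }
  }
  build_ontology_graph(terms, edges)
}

# -- Queries ------------------------------------------------------------------

assert_known_term <- function(graph, id) {
  if (!id %in% names(graph$terms)) stop("unknown term: ", id)
}

traverse <- function(env, id, max_depth = Inf) {
  out <- character()
  frontier <- id
  depth <- 0
  while (length(frontier) && depth < max_depth) {
    depth <- depth + 1
    nxt <- unique(unlist(lapply(frontier, function(v)
      get0(v, env, ifnotfound = character())), use.names = FALSE))
    nxt <- setdiff(nxt, out)
    out <- c(out, nxt)
    frontier <- nxt
  }
  sort(setdiff(out, id))
}

#' Ancestors of a term over is_a
#'
#' Transitive closure of the `is_a` relation above `id`, excluding `id`
#' itself. Used by the roll-up scoring clause: a general disease-group term
#' counts as correct when the gold diagnosis sits below it.
#'
#' @param graph An `ontology_graph`.
#' @param id A term CURIE present in the graph.
#' @return Sorted character vector of ancestor CURIEs.
#' @export
ancestors <- function(graph, id) {
  id <- canonical_curie(id)
  assert_known_term(graph, id)
  traverse(graph$parents, id)
}

#' Descendants of a term over is_a
#'
#' All terms reachable downward from `id` within `max_depth` `is_a` hops,
#' excluding `id`. `max_depth = 1` gives the direct subtypes of a disease
#' group; `Inf` gives the full subtree.
#'
#' @inheritParams ancestors
#' @param max_depth Positive integer or `Inf`.
#' @return Sorted character vector of descendant CURIEs.
#' @export
descendants <- function(graph, id, max_depth = Inf) {
  id <- canonical_curie(id)
  assert_known_term(graph, id)
  if (!is.infinite(max_depth) && (max_depth < 1 || max_depth != round(max_depth))) {
    stop("max_depth must be a positive integer or Inf")
  }
  traverse(graph$children, id, max_depth)
}

#' Equivalence class of an identifier
#'
#' Returns the set of identifiers mapped as equivalent to `id` through the
#' ontology's OMIM/Orphanet cross-references (reflexive and symmetric; closed
#' under transitivity at load time). Unknown identifiers are allowed and map
#' to themselves, so gold diagnoses coded in a nomenclature absent from the
#' graph still form a singleton class.
#'
#' @inheritParams ancestors
#' @param id Any CURIE (need not be in the graph).
#' @return Sorted character vector including `id` itself.
#' @export
equivalents <- function(graph, id) {
  id <- canonical_curie(id)
  get0(id, graph$equiv, ifnotfound = id)
}
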