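# Reading the phenopacket subset the benchmark needs, plus the normalized
# ranked-table adapter for phenotype-prioritization tools such as Exomiser.

SEX_LEVELS <- c("FEMALE", "MALE", "OTHER", "UNKNOWN")

new_phenotypic_feature <- function(term_id, label, excluded = FALSE,
                                   onset = NA_character_) {
  term_id <- canonical_curie(term_id)
  if (curie_prefix(term_id) != "HP") {
    stop("phenotypic feature must be an HP term, got ", term_id)
  }
  if (is.na(label) || !nzchar(label)) stop("feature ", term_id, " has empty label")
  list(term_id = term_id, label = label, excluded = isTRUE(excluded),
       onset = onset)
}

new_case_record <- function(case_id, sex, features, gold_diagnosis_id,
                            gold_diagnosis_label,
                            age_of_onset = NA_character_,
                            age_at_last_encounter = NA_character_) {
  if (!nzchar(case_id)) stop("empty case_id")
  sex <- match.arg(sex, SEX_LEVELS)
  if (!length(features)) stop("case ", case_id, ": no features")
  excl <- vapply(features, `[[`, NA, "excluded")
  ids <- vapply(features, `[[`, "", "term_id")
  if (!any(!excl)) stop("case ", case_id, ": at least one observed feature required")
  if (length(both <- intersect(ids[excl], ids[!excl]))) {
    stop("case ", case_id, ": feature both observed and excluded: ",
         paste(both, collapse = ", "))
  }
  gold_diagnosis_id <- canonical_curie(gold_diagnosis_id)
  if (!curie_prefix(gold_diagnosis_id) %in% c("OMIM", "ORPHA")) {
    stop("case ", case_id, ": gold diagnosis must be OMIM or ORPHA, got ",
         gold_diagnosis_id)
  }
  structure(
    list(case_id = case_id, sex = sex, age_of_onset = age_of_onset,
         age_at_last_encounter = age_at_last_encounter, features = features,
         gold_diagnosis_id = gold_diagnosis_id,
         gold_diagnosis_label = gold_diagnosis_label),
    class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  nob <- sum(!vapply(x$features, `[[`, NA, "excluded"))
  cat("<case_record> ", x$case_id, ": ", x$sex, ", ", nob, " observed + ",
      length(x$features) - nob, " excluded features, gold ",
      x$gold_diagnosis_id, "\n", sep = "")
  invisible(x)
}

extract_onset <- function(onset) {
  # phenopacket onset blocks: {age: {iso8601duration}} or {ontologyClass: {id}}
  if (is.null(onset)) return(NA_character_)
  if (!is.null(onset$age$iso8601duration)) return(onset$age$iso8601duration)
  if (!is.null(onset$ontologyClass$id)) return(canonical_curie(onset$ontologyClass$id))
  NA_character_
}

#' Parse a GA4GH phenopacket (v2) into a case record
#'
#' Extracts the subset of the Phenopacket Schema v2 that phenotype-only
#' benchmarking needs: subject sex, age at last encounter, observed and
#' excluded phenotypic features with their onsets, and the gold diagnosis
#' (the first entry of `diseases[]`, which in single-diagnosis case-report
#' corpora is the published diagnosis). Variant/interpretation blocks are
#' ignored. Onset precedence for the case-level age of onset: disease-level
#' onset, then subject-level; per-feature onsets are kept on each feature.
#'
#' @param document JSON text, or a path to a phenopacket JSON file.
#' @return A `case_record` object.
#' @export
parse_phenopacket <- function(document) {
  src <- if (length(document) == 1 && !grepl("[{\n]", document) &&
             file.exists(document)) document else paste(document, collapse = "\n")
  pp <- jsonlite::fromJSON(src, simplifyVector = FALSE)
  case_id <- pp$id %||% stop("phenopacket has no id")
  sex <- toupper(pp$subject$sex %||% "UNKNOWN")
  if (!sex %in% SEX_LEVELS) sex <- "UNKNOWN"
  if (is.null(pp$phenotypicFeatures) || !length(pp$phenotypicFeatures)) {
    stop("case ", case_id, ": no features")
  }
  features <- lapply(pp$phenotypicFeatures, function(f) {
    new_phenotypic_feature(f$type$id, f$type$label %||% NA_character_,
                           excluded = isTRUE(f$excluded),
                           onset = extract_onset(f$onset))
  })
  if (is.null(pp$diseases) || !length(pp$diseases)) {
    stop("case ", case_id, ": missing gold diagnosis")
  }
  if (length(pp$diseases) > 1) {
    stop("case ", case_id, ": multiple disease entries; expected a single gold diagnosis")
  }
  d <- pp$diseases[[1]]
  # disease-level onset wins over subject-level
  onset <- extract_onset(d$onset)
  if (is.na(onset) && !is.null(pp$subject$timeAtOnset)) {
    onset <- extract_onset(pp$subject$timeAtOnset)
  }
  last_enc <- pp$subject$timeAtLastEncounter$age$iso8601duration %||% NA_character_
  new_case_record(
    case_id = case_id, sex = sex, features = features,
    gold_diagnosis_id = d$term$id,
    gold_diagnosis_label = d$term$label %||% NA_character_,
    age_of_onset = onset, age_at_last_encounter = last_enc)
}

#' Serialize a case record back to the phenopacket subset
#'
#' Inverse of [parse_phenopacket()] over the supported field subset;
#' `parse_phenopacket(serialize_phenopacket(x))` reproduces `x` field for
#' field.
#'
#' @param case A `case_record`.
#' @param pretty Pretty-print the JSON.
#' @return JSON text (character scalar).
#' @export
serialize_phenopacket <- function(case, pretty = TRUE) {
  onset_block <- function(x) {
    if (is.na(x)) return(NULL)
    if (grepl("^P", x)) list(age = list(iso8601duration = x))
    else list(ontologyClass = list(id = x))
  }
  pp <- list(id = case$case_id)
  subj <- list(sex = case$sex)
  if (!is.na(case$age_at_last_encounter)) {
    subj$timeAtLastEncounter <- list(age = list(
      iso8601duration = case$age_at_last_encounter))
  }
  pp$subject <- subj
  pp$phenotypicFeatures <- lapply(case$features, function(f) {
    out <- list(type = list(id = f$term_id, label = f$label))
    if (f$excluded) out$excluded <- TRUE
    ob <- onset_block(f$onset)
    if (!is.null(ob)) out$onset <- ob
    out
  })
  dis <- list(term = list(id = case$gold_diagnosis_id,
                          label = case$gold_diagnosis_label))
  ob <- onset_block(case$age_of_onset)
  if (!is.null(ob)) dis$onset <- ob
  pp$diseases <- list(dis)
  pp$metaData <- list(phenopacketSchemaVersion = "2.0")
  as.character(jsonlite::toJSON(pp, auto_unbox = TRUE, pretty = pretty,
                                null = "null"))
}

#' Load a cohort of phenopackets from a directory
#'
#' Reads every `*.json` file in lexicographic filename order so cohort order
#' is deterministic across platforms. Duplicate case ids across files are an
#' error. By default any invalid file aborts the load; with
#' `skip_invalid = TRUE` failures are reported as warnings and the valid
#' records returned.
#'
#' @param directory Path containing phenopacket JSON files.
#' @param skip_invalid Keep going past files that fail to parse.
#' @return List of `case_record` objects.
#' @export
load_cohort <- function(directory, skip_invalid = FALSE) {
  files <- sort(list.files(directory, pattern = "\\.json$", full.names = TRUE))
  if (!length(files)) stop("empty cohort: no *.json files in ", directory)
  records <- list()
  failures <- character()
  for (f in files) {
    rec <- tryCatch(parse_phenopacket(f), error = function(e) {
      failures <<- c(failures, paste0(basename(f), ": ", conditionMessage(e)))
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  if (length(failures)) {
    if (skip_invalid) {
      warning("skipped invalid phenopackets:\n  ",
              paste(failures, collapse = "\n  "))
    } else {
      stop("invalid phenopackets:\n  ", paste(failures, collapse = "\n  "))
    }
  }
  ids <- vapply(records, `[[`, "", "case_id")
  if (anyDuplicated(ids)) {
    stop("duplicate case_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  records
}

#' Parse a ranked disease table into a ranked id list
#'
#' Adapter for tools that emit ranked disease identifiers (e.g. Exomiser in
#' phenotype-only mode, whose output comprises ranked lists of OMIM or
#' Orphanet ids). Expects a TSV with header columns `rank` and `disease_id`
#' (extra columns, including an optional `score`, are carried or ignored).
#' Rows are sorted by rank, consecutive repeats of the same disease id are
#' deduplicated keeping the best rank, and entries are renumbered 1..n so
#' ranks are strictly increasing with no gaps.
#'
#' @param tsv TSV text or a path to a TSV file. Lines starting `#` are
#'   skipped.
#' @param case_id Case the table belongs to.
#' @return A `ranked_id_list`: list with `case_id` and an `entries`
#'   data frame (`rank`, `disease_id`, `score`).
#' @export
parse_ranked_table <- function(tsv, case_id) {
  src <- if (length(tsv) == 1 && !grepl("[\t\n]", tsv) && file.exists(tsv)) {
    readLines(tsv)
  } else {
    unlist(strsplit(paste(tsv, collapse = "\n"), "\n"))
  }
  src <- src[!grepl("^#", src)]
  df <- utils::read.delim(text = paste(src, collapse = "\n"),
                          stringsAsFactors = FALSE)
  if (!all(c("rank", "disease_id") %in% names(df))) {
    stop("ranked table needs 'rank' and 'disease_id' columns")
  }
  if (!nrow(df)) {
    return(structure(list(case_id = case_id,
                          entries = data.frame(rank = integer(),
                                               disease_id = character(),
                                               score = numeric())),
                     class = "ranked_id_list"))
  }
  if (anyDuplicated(df$rank)) {
    stop("duplicate rank value(s): ",
         paste(unique(df$rank[duplicated(df$rank)]), collapse = ", "))
  }
  df$disease_id <- vapply(seq_len(nrow(df)), function(i) {
    id <- tryCatch(canonical_curie(df$disease_id[i]), error = function(e)
      stop("row ", i, ": ", conditionMessage(e)))
    if (!curie_prefix(id) %in% c("OMIM", "ORPHA", "MONDO")) {
      stop("row ", i, ": disease_id must be OMIM/ORPHA/MONDO, got ", id)
    }
    id
  }, "")
  df <- df[order(df$rank), , drop = FALSE]
  keep <- c(TRUE, df$disease_id[-1] != df$disease_id[-nrow(df)])
  df <- df[keep, , drop = FALSE]
  entries <- data.frame(
    rank = seq_len(nrow(df)),
    disease_id = df$disease_id,
    score = if ("score" %in% names(df)) as.numeric(df$score) else NA_real_,
    stringsAsFactors = FALSE)
  structure(list(case_id = case_id, entries = entries),
            class = "ranked_id_list")
}
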