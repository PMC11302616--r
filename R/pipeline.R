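# Stage-per-command orchestration: simulate -> prompt -> ground -> score.
# Each stage reads files from the previous one so real inputs (a full
# disease ontology, real phenopackets, real tool responses) can be swapped
# in at any point.

pkg_version <- function() {
  as.character(utils::packageVersion("phenodxbench"))
}

config_hash <- function(config) {
  # hash the scientific parameters only, not file locations
  keep <- c("seed", "template_id", "fuzzy_threshold", "max_descent", "ks",
            "drop_ungrounded", "source", "fixture")
  dump <- paste(utils::capture.output(utils::str(config[intersect(keep, names(config))])),
                collapse = "\n")
  # md5 over the serialized effective config
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(dump, tmp)
  unname(tools::md5sum(tmp))
}

file_checksum <- function(path) {
  if (is.null(path) || !file.exists(path)) return(NA_character_)
  unname(tools::md5sum(path))
}

meta_header <- function(config, extra = list()) {
  kv <- c(list(tool = paste0("phenodxbench ", pkg_version()),
               config_hash = config_hash(config),
               seed = config$seed %||% NA),
          extra)
  vapply(names(kv), function(k) paste0("# ", k, ": ", kv[[k]]), "")
}

write_tsv_with_meta <- function(df, path, config, extra = list()) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_header(config, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_skip_meta <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  utils::read.delim(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                    stringsAsFactors = FALSE)
}

#' Assemble a run configuration
#'
#' Reads an optional YAML config file and applies overrides on top of the
#' defaults (overrides win over the file, the file wins over defaults).
#' Fields: `ontology_path`, `cohort_dir`, `responses_dir`,
#' `ranked_tables_dir`, `template_id` (default `"v1"`), `fuzzy_threshold`
#' (default 0.85), `max_descent` (default 1), `ks` (default 1, 3, 10),
#' `drop_ungrounded` (default `FALSE`), `seed`, `source`, `out_dir`.
#'
#' @param path Optional YAML file.
#' @param overrides Named list overriding file values.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  config <- list(template_id = "v1", fuzzy_threshold = 0.85, max_descent = 1,
                 ks = c(1, 3, 10), drop_ungrounded = FALSE, seed = 1L,
                 source = "llm", out_dir = "phenodxbench-out")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    config <- utils::modifyList(config, yaml::read_yaml(path))
  }
  config <- utils::modifyList(config, overrides)
  config$ks <- sort(unique(as.integer(config$ks)))
  if (any(config$ks < 1)) stop("ks must be positive")
  if (identical(config$max_descent, "unlimited")) config$max_descent <- Inf
  structure(config, class = "run_config")
}

#' Simulate a fixture bundle
#'
#' Generates the toy ontology, a phenopacket cohort, mock responses and the
#' truth table into `out_dir` (`ontology.json`, `cohort/`, `responses/`,
#' `truth.tsv`, `cohort_manifest.tsv`).
#'
#' @param config A `run_config`; `config$fixture` may hold a named list of
#'   [fixture_spec()] arguments (seed defaults to `config$seed`).
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config) {
  args <- config$fixture %||% list()
  if (is.null(args$seed)) args$seed <- config$seed
  if (!is.null(args$rank_injection)) {
    args$rank_injection <- unlist(args$rank_injection)
  }
  spec <- do.call(fixture_spec, args)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  graph <- make_toy_ontology(spec, out_file = file.path(out, "ontology.json"))
  cohort <- make_cohort(spec, graph, out_dir = file.path(out, "cohort"))
  mock <- make_mock_responses(spec, cohort, graph,
                              out_dir = file.path(out, "responses"))
  write_tsv_with_meta(cohort$manifest, file.path(out, "cohort_manifest.tsv"),
                      config)
  write_tsv_with_meta(mock$truth, file.path(out, "truth.tsv"), config,
                      list(ontology_checksum =
                             file_checksum(file.path(out, "ontology.json"))))
  invisible(out)
}

#' Render prompts for a cohort directory
#'
#' @param config A `run_config` with `cohort_dir` and `out_dir`.
#' @return The prompt manifest, invisibly.
#' @export
run_prompt <- function(config) {
  if (is.null(config$cohort_dir)) stop("config needs cohort_dir")
  cohort <- load_cohort(config$cohort_dir)
  template <- load_prompt_template(config$template_id %||% "v1")
  invisible(write_prompts(cohort, template,
                          file.path(config$out_dir, "prompts"),
                          force = isTRUE(config$force)))
}

#' Ground a directory of response files
#'
#' Reads one `<case_id>.txt` per case from `config$responses_dir`, parses
#' the candidate list, grounds each item and writes
#' `grounded.tsv` (`case_id, source, position, raw_text, mondo_id, method,
#' similarity`) with run metadata (threshold, matcher, ontology checksum)
#' in `#` header lines.
#'
#' @param config A `run_config` with `ontology_path`, `responses_dir`,
#'   `out_dir`.
#' @return List of `differential_diagnosis` objects, invisibly.
#' @export
run_ground <- function(config) {
  for (f in c("ontology_path", "responses_dir")) {
    if (is.null(config[[f]])) stop("config needs ", f)
  }
  graph <- load_ontology(config$ontology_path)
  files <- sort(list.files(config$responses_dir, pattern = "\\.txt$",
                           full.names = TRUE))
  if (!length(files)) stop("no response files in ", config$responses_dir)
  diffs <- lapply(files, function(f) {
    cid <- tools::file_path_sans_ext(basename(f))
    raw <- parse_candidate_list(readLines(f, encoding = "UTF-8"), cid)
    ground_differential(graph, raw, threshold = config$fuzzy_threshold,
                        source = config$source)
  })
  rows <- lapply(diffs, function(d) {
    if (!nrow(d$candidates)) return(NULL)
    data.frame(case_id = d$case_id, source = d$source,
               position = d$candidates$position,
               raw_text = d$candidates$raw_text,
               mondo_id = d$candidates$term,
               method = d$candidates$method,
               similarity = d$candidates$similarity,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_with_meta(
    tab, file.path(config$out_dir, "grounded.tsv"), config,
    list(threshold = config$fuzzy_threshold,
         matcher = "exact+token_set",
         ontology_checksum = file_checksum(config$ontology_path)))
  invisible(diffs)
}

#' Score grounded differentials (or ranked tables) and summarize Top-k
#'
#' Consumes `grounded.tsv` from [run_ground()] (or, with
#' `config$ranked_tables_dir`, one `<case_id>.tsv` ranked identifier table
#' per case) plus the cohort manifest's gold diagnoses, writes per-case
#' results (`case_results.tsv`) and the Top-k summary (`summary.tsv`), and
#' returns the `benchmark_report`.
#'
#' @param config A `run_config` with `ontology_path`, `out_dir`, a
#'   `manifest_path` (cohort manifest TSV with `case_id`, `gold_id`), and
#'   either a `grounded.tsv` already in `out_dir` or `ranked_tables_dir`.
#' @return A `benchmark_report`.
#' @export
run_score <- function(config) {
  for (f in c("ontology_path", "manifest_path")) {
    if (is.null(config[[f]])) stop("config needs ", f)
  }
  graph <- load_ontology(config$ontology_path)
  manifest <- read_tsv_skip_meta(config$manifest_path)
  gold <- stats::setNames(manifest$gold_id, manifest$case_id)
  md <- config$max_descent

  if (!is.null(config$ranked_tables_dir)) {
    files <- sort(list.files(config$ranked_tables_dir, pattern = "\\.tsv$",
                             full.names = TRUE))
    if (!length(files)) stop("no ranked tables in ", config$ranked_tables_dir)
    results <- do.call(rbind, lapply(files, function(f) {
      cid <- tools::file_path_sans_ext(basename(f))
      if (!cid %in% names(gold)) stop("no gold diagnosis for case ", cid)
      score_exomiser(graph, parse_ranked_table(f, cid), gold[[cid]],
                     max_descent = md, source = config$source)
    }))
    mean_gr <- NA_real_
  } else {
    gpath <- file.path(config$out_dir, "grounded.tsv")
    if (!file.exists(gpath)) stop("no grounded.tsv in ", config$out_dir,
                                  " and no ranked_tables_dir configured")
    tab <- read_tsv_skip_meta(gpath)
    per_case <- split(tab, tab$case_id)
    rates <- numeric()
    results <- do.call(rbind, lapply(names(per_case), function(cid) {
      if (!cid %in% names(gold)) stop("no gold diagnosis for case ", cid)
      g <- per_case[[cid]]
      g <- g[order(g$position), , drop = FALSE]
      diff <- structure(
        list(case_id = cid, source = config$source,
             candidates = data.frame(position = g$position,
                                     raw_text = g$raw_text,
                                     term = as.character(g$mondo_id),
                                     method = g$method,
                                     similarity = g$similarity,
                                     stringsAsFactors = FALSE)),
        class = "differential_diagnosis")
      rates <<- c(rates, mean(g$method != "none"))
      rank_of_correct(graph, diff, gold[[cid]], max_descent = md,
                      drop_ungrounded = isTRUE(config$drop_ungrounded))
    }))
    # cases whose responses yielded no candidates still count, at rank 0
    missing <- setdiff(names(gold), results$case_id)
    if (length(missing)) {
      results <- rbind(results, do.call(rbind, lapply(missing, function(cid) {
        new_case_result(cid, config$source, gold[[cid]], 0L, NA_character_,
                        "none")
      })))
    }
    mean_gr <- if (length(rates)) mean(rates) else NA_real_
  }

  report <- aggregate_topk(results, ks = config$ks,
                           mean_grounding_rate = mean_gr,
                           parameters = list(
                             threshold = config$fuzzy_threshold,
                             max_descent = md,
                             ontology_checksum =
                               file_checksum(config$ontology_path)))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_with_meta(results, file.path(config$out_dir, "case_results.tsv"),
                      config,
                      list(max_descent = md,
                           ontology_checksum = file_checksum(config$ontology_path)))
  summary_df <- data.frame(
    source = report$source, n = report$n_cases,
    t(round(report$top_k, 3)),
    params = paste0("threshold=", config$fuzzy_threshold,
                    ";max_descent=", md),
    stringsAsFactors = FALSE)
  write_tsv_with_meta(summary_df, file.path(config$out_dir, "summary.tsv"),
                      config)
  report
}
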