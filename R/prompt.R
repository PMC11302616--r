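# Deterministic rendering of a case record into a clinical-narrative prompt
# requesting a ranked differential diagnosis.

# HPO onset classes -> canonical phrase and an approximate age in days used
# only to order per-age feature groups chronologically.
ONSET_CLASSES <- data.frame(
  id = c("HP:0030674", "HP:0011460", "HP:0011461", "HP:0003577",
         "HP:0003623", "HP:0003593", "HP:0011463", "HP:0003621",
         "HP:0011462", "HP:0003581", "HP:0003596", "HP:0003584"),
  phrase = c("before birth", "in the embryonal period", "in the fetal period",
             "at birth", "in the neonatal period", "in infancy",
             "in childhood", "in adolescence", "in young adulthood",
             "in adulthood", "in middle age", "in late adulthood"),
  approx_days = c(-180, -230, -120, 0, 14, 180, 365 * 5, 365 * 12,
                  365 * 25, 365 * 35, 365 * 50, 365 * 65),
  stringsAsFactors = FALSE)

parse_iso_duration <- function(x) {
  m <- regmatches(x, regexec(
    "^P(?:([0-9]+)Y)?(?:([0-9]+)M)?(?:([0-9]+)W)?(?:([0-9]+)D)?$", x))[[1]]
  if (!length(m) || all(m[-1] == "")) {
    stop("unparseable ISO-8601 duration: ", x)
  }
  v <- suppressWarnings(as.integer(m[-1]))
  v[is.na(v)] <- 0L
  names(v) <- c("years", "months", "weeks", "days")
  v
}

onset_sort_key <- function(onset) {
  # days-since-birth surrogate used only for chronological group ordering
  vapply(onset, function(x) {
    if (is.na(x)) return(Inf)
    i <- match(x, ONSET_CLASSES$id)
    if (!is.na(i)) return(ONSET_CLASSES$approx_days[i])
    v <- parse_iso_duration(x)
    sum(v * c(365.25, 30.44, 7, 1))
  }, 0)
}

#' Render an age for use in prompt text
#'
#' Accepts an ISO-8601 duration (`P3Y6M`) or an HPO onset-class CURIE.
#' Durations render their two largest nonzero units (`"3 years, 6 months"`);
#' a zero duration and the Congenital onset class both render `"at birth"`;
#' onset classes use a fixed phrase table (e.g. Infantile onset renders
#' `"in infancy"`).
#'
#' @param duration Character scalar: ISO-8601 duration or onset-class CURIE.
#' @return Character scalar.
#' @export
#' @examples
#' render_age("P3Y")
#' render_age("P2Y3M10D")
#' render_age("HP:0003593")
render_age <- function(duration) {
  stopifnot(length(duration) == 1, !is.na(duration))
  i <- match(duration, ONSET_CLASSES$id)
  if (!is.na(i)) return(ONSET_CLASSES$phrase[i])
  if (grepl("^HP:", duration)) stop("unknown onset class: ", duration)
  v <- parse_iso_duration(duration)
  nz <- v[v > 0]
  if (!length(nz)) return("at birth")
  nz <- nz[seq_len(min(2L, length(nz)))]
  unit <- ifelse(nz == 1L, sub("s$", "", names(nz)), names(nz))
  paste(paste(nz, unit), collapse = ", ")
}

age_phrase <- function(onset) {
  # "at birth" / "before birth" / "in infancy" stand alone; durations get
  # "at the age of" prepended
  p <- render_age(onset)
  if (onset %in% ONSET_CLASSES$id || p == "at birth") p
  else paste("at the age of", p)
}

#' Load a prompt template
#'
#' Templates are plain-text files with `{{slot}}` placeholders
#' (`{{sex_phrase}}`, `{{onset_sentence}}`, `{{encounter_sentence}}`,
#' `{{observed_block}}`, `{{excluded_block}}`). The shipped `"v1"` template
#' states the subject's sex, age of onset and age at last examination, then
#' lists observed clinical features (split into per-age lists when feature
#' onsets differ) and explicitly excluded features, and instructs the model
#' to reply with a numbered list of candidate diagnoses, most likely first —
#' the format the response parser expects.
#'
#' @param template_id Name of a shipped template (currently `"v1"`), or a
#'   path to a template file.
#' @return A `prompt_template` (list with `template_id` and `text`).
#' @export
load_prompt_template <- function(template_id = "v1") {
  path <- if (file.exists(template_id)) template_id else
    system.file("templates", paste0(template_id, ".txt"),
                package = "phenodxbench")
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown prompt template: ", template_id)
  }
  txt <- paste(readLines(path, encoding = "UTF-8"), collapse = "\n")
  if (!grepl("numbered list of candidate diagnoses, most likely first", txt)) {
    stop("template must instruct a numbered list of candidate diagnoses, most likely first")
  }
  structure(list(template_id = if (file.exists(template_id))
    tools::file_path_sans_ext(basename(template_id)) else template_id,
    text = txt), class = "prompt_template")
}

sex_phrase <- function(sex) {
  switch(sex, FEMALE = "a female", MALE = "a male", "an individual")
}

feature_list_phrase <- function(labels) paste(labels, collapse = "; ")

#' Render a clinical-narrative prompt for one case
#'
#' Produces deterministic text (same inputs give byte-identical output).
#' Observed features are grouped by distinct onset age when at least two
#' distinct feature onsets exist, each group introduced by its rendered age
#' and groups ordered chronologically; features without their own onset fall
#' into the last-encounter group. Excluded features appear in a separate
#' exclusion section. Only feature labels appear (never HP identifiers), and
#' the gold diagnosis is never mentioned.
#'
#' @param case A `case_record`.
#' @param template A `prompt_template` from [load_prompt_template()].
#' @return A `prompt_document` (list with `case_id`, `template_id`, `text`).
#' @export
render_prompt <- function(case, template = load_prompt_template("v1")) {
  stopifnot(inherits(case, "case_record"), inherits(template, "prompt_template"))
  obs <- Filter(function(f) !f$excluded, case$features)
  exc <- Filter(function(f) f$excluded, case$features)

  onsets <- vapply(obs, `[[`, "", "onset")
  distinct <- unique(onsets[!is.na(onsets)])
  if (length(distinct) >= 2) {
    keys <- onset_sort_key(as.list(onsets))
    groups <- split(seq_along(obs), onsets)           # NA onsets drop out
    ord <- order(onset_sort_key(as.list(names(groups))))
    blocks <- vapply(names(groups)[ord], function(on) {
      labs <- vapply(obs[sort(groups[[on]])], `[[`, "", "label")
      paste0("The following clinical features were observed ",
             age_phrase(on), ": ", feature_list_phrase(labs), ".")
    }, "")
    no_onset <- which(is.na(onsets))
    if (length(no_onset)) {
      labs <- vapply(obs[no_onset], `[[`, "", "label")
      intro <- if (!is.na(case$age_at_last_encounter)) {
        paste0("The following clinical features were present ",
               age_phrase(case$age_at_last_encounter),
               ", at the last encounter: ")
      } else "The following clinical features were also present: "
      blocks <- c(blocks, paste0(intro, feature_list_phrase(labs), "."))
    }
    observed_block <- paste(blocks, collapse = "\n")
  } else {
    labs <- vapply(obs, `[[`, "", "label")
    observed_block <- paste0("The following clinical features were observed: ",
                             feature_list_phrase(labs), ".")
  }

  excluded_block <- if (length(exc)) {
    labs <- vapply(exc, `[[`, "", "label")
    paste0("\nThe following clinical features were investigated and explicitly excluded: ",
           feature_list_phrase(labs), ".\n")
  } else ""

  onset_sentence <- if (!is.na(case$age_of_onset)) {
    paste0(" The disease manifested ", age_phrase(case$age_of_onset), ".")
  } else ""
  encounter_sentence <- if (!is.na(case$age_at_last_encounter)) {
    paste0(" The patient was last examined ",
           age_phrase(case$age_at_last_encounter), ".")
  } else ""

  slots <- c(sex_phrase = sex_phrase(case$sex),
             onset_sentence = onset_sentence,
             encounter_sentence = encounter_sentence,
             observed_block = observed_block,
             excluded_block = excluded_block)
  text <- template$text
  for (nm in names(slots)) {
    text <- gsub(paste0("{{", nm, "}}"), slots[[nm]], text, fixed = TRUE)
  }
  if (grepl("\\{\\{", text)) {
    stop("unfilled placeholder in template ", template$template_id)
  }
  text <- gsub("\n{3,}", "\n\n", text)
  structure(list(case_id = case$case_id, template_id = template$template_id,
                 text = text), class = "prompt_document")
}

#' Write prompts for a cohort
#'
#' One UTF-8 text file per case, named `<case_id>.txt`, plus a deterministic
#' manifest. Refuses to overwrite an existing file with different content
#' unless `force = TRUE`.
#'
#' @param cohort List of `case_record` objects.
#' @param template A `prompt_template`.
#' @param out_dir Output directory (created if needed).
#' @param force Overwrite differing existing files.
#' @return Data frame manifest (`case_id`, `path`, `checksum`), invisibly
#'   written to `prompt_manifest.tsv` in `out_dir`.
#' @export
write_prompts <- function(cohort, template = load_prompt_template("v1"),
                          out_dir, force = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(case) {
    doc <- render_prompt(case, template)
    path <- file.path(out_dir, paste0(doc$case_id, ".txt"))
    if (file.exists(path) && !force) {
      old <- paste(readLines(path, encoding = "UTF-8"), collapse = "\n")
      if (!identical(old, doc$text)) {
        stop("refusing to overwrite differing prompt ", path,
             " (use force = TRUE)")
      }
    }
    writeLines(doc$text, path, useBytes = TRUE)
    data.frame(case_id = doc$case_id, path = path,
               checksum = unname(tools::md5sum(path)),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "prompt_manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
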