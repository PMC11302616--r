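test_that("ages render with the two largest nonzero units", {
  expect_identical(render_age("P3Y"), "3 years")
  expect_identical(render_age("P0Y6M"), "6 months")
  expect_identical(render_age("P2Y3M10D"), "2 years, 3 months")
  expect_identical(render_age("P1Y1M"), "1 year, 1 month")
  expect_identical(render_age("P0D"), "at birth")
  expect_identical(render_age("HP:0003577"), "at birth")
  expect_identical(render_age("HP:0003593"), "in infancy")
  expect_error(render_age("3 years"), "unparseable")
  expect_error(render_age("HP:0000001"), "unknown onset class")
})

make_case <- function(features, sex = "FEMALE", onset = "P3Y",
                      last = "P10Y", gold = "OMIM:614185",
                      gold_label = "geleophysic dysplasia 2") {
  phenodxbench:::new_case_record(
    "case-x", sex, features, gold, gold_label,
    age_of_onset = onset, age_at_last_encounter = last)
}

feat <- function(id, label, excluded = FALSE, onset = NA_character_) {
  phenodxbench:::new_phenotypic_feature(id, label, excluded, onset)
}

test_that("a rendered prompt carries sex, ages and feature sections", {
  case <- make_case(list(
    feat("HP:0000001", "tall stature"),
    feat("HP:0000002", "long fingers"),
    feat("HP:0000003", "cleft palate", excluded = TRUE)))
  doc <- render_prompt(case)
  txt <- doc$text
  expect_match(txt, "a female")
  expect_match(txt, "3 years")
  expect_match(txt, "numbered list of candidate diagnoses, most likely first")
  for (lab in c("tall stature", "long fingers", "cleft palate")) {
    expect_identical(lengths(regmatches(txt, gregexpr(lab, txt, fixed = TRUE))),
                     1L)
  }
  # excluded label sits in the exclusion section
  parts <- strsplit(txt, "explicitly excluded", fixed = TRUE)[[1]]
  expect_length(parts, 2)
  expect_false(grepl("cleft palate", parts[1], fixed = TRUE))
  expect_match(parts[2], "cleft palate")
  # no HP identifiers and no gold leakage
  expect_false(grepl("HP:", txt, fixed = TRUE))
  expect_false(grepl("geleophysic", txt, ignore.case = TRUE))
  expect_false(grepl("614185", txt, fixed = TRUE))
})

test_that("the exclusion section is omitted when nothing was excluded", {
  case <- make_case(list(feat("HP:0000001", "tall stature")))
  expect_false(grepl("excluded", render_prompt(case)$text))
})

test_that("unknown sex renders neutral phrasing", {
  case <- make_case(list(feat("HP:0000001", "tall stature")), sex = "UNKNOWN")
  expect_match(render_prompt(case)$text, "an individual")
})

test_that("distinct feature onsets produce chronological per-age groups", {
  case <- make_case(list(
    feat("HP:0000001", "late finding", onset = "P5Y"),
    feat("HP:0000002", "early finding", onset = "P1Y"),
    feat("HP:0000003", "undated finding")))
  txt <- render_prompt(case)$text
  i_early <- regexpr("observed at the age of 1 year:", txt, fixed = TRUE)
  i_late <- regexpr("observed at the age of 5 years:", txt, fixed = TRUE)
  i_last <- regexpr("at the last encounter", txt, fixed = TRUE)
  expect_true(all(c(i_early, i_late, i_last) > 0))
  expect_lt(i_early, i_late)
  expect_lt(i_late, i_last)
  expect_true(grepl("early finding", substr(txt, i_early, i_late)))
  # onset classes order before late durations
  case2 <- make_case(list(
    feat("HP:0000001", "late finding", onset = "P9Y"),
    feat("HP:0000002", "congenital finding", onset = "HP:0003577")))
  txt2 <- render_prompt(case2)$text
  expect_lt(regexpr("congenital finding", txt2),
            regexpr("late finding", txt2))
})

test_that("rendering is deterministic and write_prompts is reproducible", {
  spec <- fixture_spec(seed = 9, n_cases = 6, n_disease_groups = 3)
  g <- make_toy_ontology(spec)
  cohort <- make_cohort(spec, g)
  tpl <- load_prompt_template("v1")
  for (case in cohort$cases) {
    expect_identical(render_prompt(case, tpl)$text,
                     render_prompt(case, tpl)$text)
  }
  dir <- withr::local_tempdir()
  m1 <- write_prompts(cohort$cases, tpl, dir)
  m2 <- write_prompts(cohort$cases, tpl, dir)
  expect_identical(m1, m2)
  expect_length(list.files(dir, pattern = "\\.txt$"), 6)
  # differing existing file is protected
  writeLines("something else", file.path(dir, "case-0001.txt"))
  expect_error(write_prompts(cohort$cases, tpl, dir), "refusing")
  expect_silent(write_prompts(cohort$cases, tpl, dir, force = TRUE))
})

test_that("feature labels are recoverable from prompts for random cases", {
  # completeness sweep: every observed label appears exactly once outside the
  # exclusion section, every excluded label exactly once inside it
  spec <- fixture_spec(seed = 10, n_cases = 500, n_disease_groups = 6,
                       excluded_fraction = 0.2)
  g <- make_toy_ontology(spec)
  cohort <- make_cohort(spec, g)
  tpl <- load_prompt_template("v1")
  bad <- 0L
  for (case in cohort$cases) {
    txt <- render_prompt(case, tpl)$text
    parts <- strsplit(txt, "explicitly excluded", fixed = TRUE)[[1]]
    obs_part <- parts[1]
    exc_part <- if (length(parts) > 1) parts[2] else ""
    for (f in case$features) {
      n_obs <- lengths(regmatches(obs_part,
                                  gregexpr(f$label, obs_part, fixed = TRUE)))
      n_exc <- lengths(regmatches(exc_part,
                                  gregexpr(f$label, exc_part, fixed = TRUE)))
      ok <- if (f$excluded) n_obs == 0 && n_exc == 1 else n_obs == 1 && n_exc == 0
      if (!ok) bad <- bad + 1L
    }
    # leakage: gold label and id never appear
    if (grepl(case$gold_diagnosis_label, txt, ignore.case = TRUE) ||
        grepl(case$gold_diagnosis_id, txt, fixed = TRUE)) {
      bad <- bad + 1L
    }
  }
  expect_identical(bad, 0L)
})
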