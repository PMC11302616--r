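---
title: "Ontology-based scoring of ranked differential diagnoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-based scoring of ranked differential diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The evaluation problem

Tools that propose differential diagnoses for rare-disease cases come in two
shapes. Phenotype-prioritization software such as Exomiser emits ranked lists
of disease identifiers (OMIM or Orphanet codes); large language models emit
free text. Deciding whether either "got the diagnosis right" by hand is
subjective — published inter-rater agreement on such judgements is poor — and
is confounded by disease nomenclature: the same clinical entity may be coded
as an OMIM genetic subtype, an Orphanet entry, or a general clinical term,
and a clinically reasonable answer ("geleophysic dysplasia") may be more
general than the genetically precise gold diagnosis ("geleophysic dysplasia
2", OMIM:614185).

phenodxbench operationalizes a fully computational evaluation. Both routes
are mapped onto one disease ontology (in real use, Mondo, which integrates
OMIM and Orphanet through cross-references), correctness is decided by a
three-clause ontological rule, and performance is summarized as Top-k
accuracy: the fraction of cases whose first correct candidate appears within
the first k positions of the differential.

## The scoring rule

For a predicted identifier $p$ and gold diagnosis $g$, `is_correct()`
evaluates, in order:

1. **exact** — $p = g$;
2. **equivalent** — $p$ and $g$ fall in the same equivalence class. Classes
   are built at ontology load time from OMIM/Orphanet cross-references and
   closed under transitivity with a union–find pass, because cross-references
   between three nomenclatures naming one disease form a class, not a set of
   independent pairs;
3. **rollup** — $g$ (or an equivalent of it) lies within `max_descent`
   *is_a* hops **below** $p$ (or an equivalent of it). This credits an
   answer that names the disease group when the gold standard is one of its
   genetic subtypes.

The first satisfied clause determines the match type. "Close descendant" is
deliberately a parameter: subtype roll-ups in disease ontologies are almost
always one level deep, so the default is `max_descent = 1`; `Inf` accepts any
descendant, and `max_descent = 0` disables the clause entirely
(equivalence-only scoring), which is also how tests probe that the descent
bound is respected. Reports always record the setting, since the two
readings of "close" are both defensible and change the measured accuracy.

Within a differential, the **first** correct candidate defines the case's
rank — the minimum rank is what Top-k accuracy needs when both a group term
and its subtype appear. Rank 0 encodes "not found". Candidates that failed
to ground still occupy positions by default: a grounding failure then can
only hurt, never help, a tool's measured rank. The alternative reading
(`drop_ungrounded = TRUE`) renumbers after removing them; both are exposed
because the choice is not decidable from first principles, and it keeps the
denominator (`n_cases`) identical across tools either way.

## Grounding free text

Each response is first reduced to its candidate list: the longest contiguous
enumerated block (markers `1.`, `1)`, `-`, `*`), since models habitually wrap
the list in prose. Markers, markdown bold, and trailing rationales after a
spaced dash are stripped. A response with no enumerated block yields an
empty, flagged differential that scores rank 0 — it still counts in the
denominator.

Each item is then grounded in two stages:

* **Exact**: `normalize_label()` (case folding, NFKD accent folding,
  punctuation to spaces, whitespace collapse) is applied to both the query
  and the index of primary labels and exact-scope synonyms of non-obsolete
  terms. Ambiguous hits resolve deterministically: primary-label match beats
  synonym match, then the lexicographically smallest CURIE.
* **Fuzzy**, for the remainder: the best-scoring term under
  `token_set_similarity()`, kept only when the similarity reaches the
  threshold (default 0.85). The measure is the maximum of the Sørensen–Dice
  coefficient of the two token sets (rewarding shared vocabulary and
  scoring a subtype mention higher against the subtype label than against
  the shorter group label) and the normalized Levenshtein similarity of the
  sorted token strings (rescuing in-token misspellings that break token
  identity). Both components are order-insensitive, so a permuted disease
  name scores 1 — intended behaviour for clinical nomenclature, where word
  order is unstable ("dysplasia, geleophysic").

The matcher is lexical by design and pluggable in principle; the threshold
is configurable and is recorded in every output header, because grounding
sensitivity is a property of the run, not of the corpus. The grounding rate
(grounded items / items) is reported per run as a diagnostic; around 94 %
is what the package's own noise-injection tests target.

## Prompt construction

`render_prompt()` turns the phenopacket subset into a deterministic clinical
narrative: sex first, then age of onset and age at last examination, then
observed features, then explicitly excluded features, followed by an
instruction to answer with a numbered list of candidate diagnoses, most
likely first — the downstream parser depends on that instruction, so
`load_prompt_template()` refuses templates that drop it. When at least two
distinct feature-level onsets exist, observed features are split into
per-age lists ordered chronologically (onset classes such as "congenital"
are given nominal day values only for this ordering); features without their
own onset join the last-encounter list. Excluded features are listed once,
last, in a single section — the alternative (exclusions per age group) is
plausible but less common in clinical summaries. Feature order within a
group preserves phenopacket order rather than alphabetizing: any ordering is
defensible, and preservation is the least surprising. Ages render as the two
largest nonzero ISO-8601 units ("2 years, 3 months"), with zero durations
and the congenital onset class both rendering "at birth". Only feature
labels appear — never HP identifiers, and never the gold diagnosis.

Templates are data files with `{{slot}}` placeholders, so alternate prompt
styles can be added without code changes; the package ships one canonical
English template, `v1`.

## Ranked-table adapter

Identifier-native tools are consumed through a minimal normalized TSV
(`rank`, `disease_id`, optional `score`) rather than any tool's native
output format, decoupling the benchmark from version churn. Rows are sorted
by rank, consecutive repeats of one disease are collapsed keeping the first
occurrence, and entries are renumbered 1..n so ranks are strictly
increasing without gaps (original rank numbers are not retained after
deduplication). Both `ORPHA:` and `Orphanet:` prefixes are accepted and
normalized to `ORPHA:`, since the dialect in the wild varies.

## What the synthetic generator emulates — and what it does not

`fixture_spec()` + `make_toy_ontology()` + `make_cohort()` +
`make_mock_responses()` generate, deterministically from one seed, the three
artifacts the pipeline needs:

* an ontology with the group/subtype shape of disease nomenclature — one
  root, disease groups, subtypes one *is_a* hop below their group, each
  subtype cross-referenced to a unique OMIM id, every term carrying exact
  synonyms, all labels globally unique. The geleophysic dysplasia group
  (MONDO:0000127; subtypes 1–3; subtype 2 ↔ OMIM:614185) is always included
  verbatim so worked examples are stable;
* a cohort whose per-case feature counts are Poisson with mean 16 — the
  scale of deeply phenotyped case-report corpora — with a configurable
  excluded fraction, per-feature onsets, and a gold subtype diagnosis coded
  as its OMIM id, exactly as case-level corpora record it;
* mock responses in which the correct answer is injected at a rank drawn
  from a configured bucket distribution (`rank1`, `rank2_3`, `rank4_10`,
  `notfound`), rendered as the primary label, an exact synonym, or the
  parent group's label (forcing a roll-up match), with filler diseases from
  other groups and optional ungroundable garbage items. The truth table of
  injected ranks is a first-class output: parameter recovery against it is
  the package's acceptance surface.

The default injection distribution (0.30 / 0.15 / 0.15 / 0.40) produces
Top-1/3/10 magnitudes of roughly 30 / 45 / 60 %, the scale at which
phenotype-only prioritization tools operate.

The generator deliberately does **not** model disease–phenotype
co-occurrence structure (features are drawn uniformly, so cases carry no
diagnostic signal — which is exactly why injected ranks are known), tool
score distributions, multi-diagnosis cases, or free-text responses that
deviate from an enumerated list. Passing the recovery tests therefore shows
that the harness measures *faithfully* — it never loses, shifts, or
mis-scores a case whose answer is recoverable — not that any particular tool
performs well on real data, and not that grounding would absorb the full
messiness of real model prose.

## Numerical and degenerate-input choices

* Every generator is a pure function of `(spec, seed)`; the cohort and
  response generators use fixed small offsets of the seed so the three
  artifacts are decorrelated but jointly reproducible.
* Fuzzy ties within `1e-9` of the best similarity are broken like exact
  ties (primary label, then smallest CURIE).
* An empty response, an empty candidate list, or a grounding rate over zero
  items: rank 0, rate flagged `NA` rather than 1 or 0.
* A gold diagnosis that neither appears in the ontology nor reaches it
  through an equivalence is a configuration error, not a silent rank 0 —
  the benchmark cannot score that case and says so.
* Cycles in *is_a*, edges to undeclared nodes, duplicate case ids and
  features recorded both observed and excluded all fail loudly at load
  time.

## Validation problem sizes

The shipped test-and-acceptance suite validates at sizes chosen to give the
statistics room while keeping runs interactive: oracle agreement of the
scoring rule against brute-force enumeration over 200 random DAGs of 8–60
terms (all ordered term pairs, `max_descent` ∈ {1, 2, ∞}); end-to-end rank
recovery on a 1000-case simulated cohort (exact, case by case, plus a
3-binomial-SD check of the Top-k proportions against the configured
injection probabilities); grounding soundness over a ~200-term ontology
(every label and synonym, 100 % required) and a 2,500-item noise run at 6 %
garbage. The 5,000-case scale of real corpora is one `fixture_spec`
argument away but adds nothing to correctness.

## Known limitations

* Grounding is lexical; an embedding-based matcher could absorb
  paraphrases ("Riley–Day syndrome" for familial dysautonomia) that token
  overlap cannot. The matcher sits behind a narrow interface precisely so
  that it can be swapped.
* Only *is_a* is traversed; logical axioms and other relations are out of
  scope, as are statistical comparisons between tools (the package reports
  proportions, not confidence intervals).
* The phenopacket reader covers the benchmarking subset (subject, features,
  first disease); measurements, biosamples, interpretations and pedigrees
  are ignored, and multi-disease packets are rejected rather than
  truncated.
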