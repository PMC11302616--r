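Package: phenodxbench
Title: Ontology-Based Benchmarking of Ranked Differential Diagnoses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating phenotype-driven differential-diagnosis
    generators against gold-standard rare-disease diagnoses. Builds clinical
    narrative prompts from GA4GH Phenopacket Schema v2 documents, grounds
    free-text ranked disease lists to a disease ontology (exact label and
    synonym matching with a thresholded token-set fuzzy fallback), scores
    candidates with exact, equivalence-mapping and ancestor roll-up rules
    over the ontology's is_a hierarchy and OMIM/Orphanet cross-references,
    and reports Top-k diagnostic accuracy. Includes a seeded synthetic
    fixture generator (toy ontologies, case cohorts, mock tool responses
    with injected ranks) so the full pipeline can be validated end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringi,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
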