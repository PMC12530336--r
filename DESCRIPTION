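Package: trialsql
Title: Clinical Trial Eligibility Criteria to OMOP CDM Cohort SQL with
    Hallucination Auditing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms free-text clinical-trial eligibility criteria into
    OMOP Common Data Model (v5.3) cohort SQL: three-stage preprocessing
    (segmentation, filtration, simplification), seven-element information
    extraction, standard-vocabulary concept mapping with ancestor-closure
    expansion, and INTERSECT/EXCEPT cohort assembly.  Audits candidate SQL
    for concept-identifier hallucinations using a five-category severity
    taxonomy (nonexistent IDs, wrong-domain concepts, natural-language
    substitutions, placeholders, schema errors), and provides the matching
    evaluation framework: generation/hallucination/effective rates with
    confidence intervals, McNemar paired comparisons, cohort set-concordance
    metrics (Jaccard, overlap coefficient), and dual-rater score
    aggregation.  Ships synthetic generators for a limited-coverage concept
    inventory inside a larger vocabulary universe, a patient-level mini CDM,
    and seeded error injection with ground-truth manifests, so the whole
    toolkit runs and tests offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    e1071,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
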