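# trialsql

Transforming free-text clinical-trial eligibility criteria into OMOP CDM
cohort SQL, auditing the result for concept-identifier hallucinations,
and scoring the whole pipeline — offline, deterministically, and with a
synthetic test bed.

## Who this is for

Clinical research informaticists running trial-feasibility assessments
against OMOP Common Data Model (v5.3) databases, and anyone evaluating
text-model systems that generate cohort SQL. Generators of such SQL —
LLM-based ones in particular — have a well-known failure family: concept
references that are not real. `trialsql` provides both sides: a
reference pipeline that produces OMOP-conformant cohort queries, and an
automated auditor plus evaluation framework for any candidate SQL,
yours or a model's.

## What it does

**Pipeline** — three-stage preprocessing of criteria text
(*segmentation → filtration → simplification*), seven-element
information extraction (clinical terms, terminology system, codes,
value, attributes, temporal, negation), concept mapping with a
Levenshtein baseline mapper and `concept_ancestor` descendant
expansion, and cohort assembly:

```
cohort = (I₁ ∩ I₂ ∩ … )  \  (E₁ ∪ E₂ ∪ … )
```

rendered as per-criterion `SELECT person_id FROM <event table> WHERE
<concept column> IN (…)` subqueries merged with `INTERSECT` and
`EXCEPT` (or `NOT IN` — provably set-identical). Every text stage goes
through a pluggable backend; the shipped default is a deterministic
rule backend, so everything runs offline.

**Auditor** — every literal compared against a `*_concept_id` column is
a site, classified into a five-category severity taxonomy:

| Category | Severity | Meaning |
|---|---|---|
| A | Critical | nonexistent concept ID |
| B | Major | valid concept, wrong domain column |
| C | Major | natural language where an ID belongs |
| D | Moderate | placeholder value |
| E | Minor | syntax/schema error |

with documented precedence D → C → A → B, validation against a loadable
concept inventory and an embedded CDM v5.3 catalog, and per-query
verdicts (`hallucinated`, `effective = generated ∧ hallucination-free`).

**Metrics** — rates with Wald/Wilson CIs, McNemar paired comparison,
domain-stratified mapping accuracy, cohort concordance (Jaccard index
and overlap coefficient: `|A∩B|/|A∪B|` vs `|A∩B|/min(|A|,|B|)`), and
dual-rater score aggregation with Cohen's kappa.

**Synthetic test bed** — a limited-coverage inventory inside a larger
concept universe (the mechanism that elicits nonexistent-ID references
on datasets like SynPUF), a patient-level mini CDM executable via
SQLite, seeded error injection with ground-truth manifests, and cohort
pairs with a target Jaccard.

## Worked example

```r
library(trialsql)

trial <- list(
  trial_id = "NCT-EXAMPLE",
  inclusion = "1. Age 18 years or older (adults)\n2. Type 2 diabetes\n3. Hemoglobin less than 10 g/dL",
  exclusion = "1. Pregnancy\n2. Provided written informed consent\n3. history of MI within the past six months")
res <- preprocess_trial(trial)
res$stage_stats
#>            stage n_criteria total_tokens mean_tokens
#> 1   segmentation          6           31    5.166667
#> 2      filtering          5           27    5.400000
#> 3 simplification          5           20    4.000000
res$pct_token_reduction
#> [1] 35.48387
res$criteria[c(1, 5, 6), c("segmented_text", "queryable", "simplified_text")]
#>                             segmented_text queryable          simplified_text
#> 1           Age 18 years or older (adults)      TRUE           Age ≥ 18 years
#> 5        Provided written informed consent     FALSE                     <NA>
#> 6 history of MI within the past six months      TRUE history of MI ≤ 6 months
```

The consent criterion is filtered (non-queryable, reason `consent`);
temporal phrases and comparator words are normalized; token counts only
ever fall. Extraction turns a criterion into the seven-element record:

```r
str(extract_elements(res$criteria[3, ])[c("clinical_terms", "value", "negation")])
#> List of 3
#>  $ clinical_terms: chr "Hemoglobin"
#>  $ value         :List of 3
#>   ..$ comparator: chr "<"
#>   ..$ number    : num 10
#>   ..$ unit      : chr "g/dL"
#>  $ negation      : logi FALSE
```

With a concept inventory (here a four-concept toy; real use loads OMOP
`CONCEPT`/`CONCEPT_ANCESTOR` files via `load_inventory()`), the builder
expands a mapped concept through the ancestor closure and assembles the
cohort:

```r
inv <- concept_inventory(
  data.frame(concept_id   = c(201826L, 4193704L, 4195498L, 1503297L),
             concept_name = c("Type 2 diabetes mellitus",
                              "Type 2 diabetes mellitus without complication",
                              "Type 2 diabetes mellitus with kidney complication",
                              "Metformin"),
             domain_id = c("Condition", "Condition", "Condition", "Drug"),
             vocabulary_id = c("SNOMED", "SNOMED", "SNOMED", "RxNorm"),
             standard_concept = "S"),
  data.frame(ancestor_concept_id = c(201826L, 201826L),
             descendant_concept_id = c(4193704L, 4195498L)))

q  <- build_criterion_query(extract_elements(res$criteria[2, ]), 201826L,
                            domain_to_rule("Condition"), inv)   # expansion ON
ex <- build_criterion_query(extraction_record("metformin"), 1503297L,
                            domain_to_rule("Drug"), inv)
cat(assemble_cohort(list(q), list(ex), mode = "except")$sql_text)
#> SELECT person_id FROM (
#> SELECT person_id FROM condition_occurrence WHERE condition_concept_id IN (201826, 4193704, 4195498)
#> ) AS included
#> EXCEPT
#> SELECT person_id FROM (
#> SELECT person_id FROM drug_exposure WHERE drug_concept_id IN (1503297)
#> ) AS excluded
```

The auditor, pointed at any SQL:

```r
audit_query(
  "SELECT person_id FROM condition_occurrence
   WHERE condition_concept_id IN (201826, 999999, <INSERT_ID>)", inv)
#> <query_audit> parse_ok=TRUE instances=2 hallucinated=TRUE effective=FALSE [policy default]
#>   [A/Critical] concept_id 999999 does not exist in the inventory
#>   [D/Moderate] placeholder value <INSERT_ID> requires manual intervention

rate_with_ci(249, 760)
#> 249/760 = 32.8% (95% CI 29.4%-36.1%, wald)
```

A thin command-line front end wraps the same functions
(`exec/trialsql`): `preprocess`, `map`, `vocab-stats`, `build`,
`audit`, `synth-vocab`, `rate`.

## Package layout

- `R/` — modules: `cdm_schema` (embedded CDM v5.3 catalog + identifier
  validation), `vocabulary` (inventory, ancestor closure, baseline
  mapper), `criteria_pipeline`, `sql_builder`, `audit`, `metrics`,
  `synth`, and the SQL scanner they share.
- `inst/extdata/cdm_catalog_v5_3.json` — the versioned schema asset
  (overridable via `cdm_catalog(path)` / `--cdm-catalog`).
- `vignettes/trialsql-methods.Rmd` — the methods vignette: model,
  assumptions, parameter defaults, numerical choices, limitations.
- `tests/testthat/` — unit, property and acceptance suites.
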