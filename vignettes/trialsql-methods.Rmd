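---
title: "From eligibility criteria to audited OMOP cohort SQL: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From eligibility criteria to audited OMOP cohort SQL: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialsql)
```

## The problem

Trial feasibility assessment against real-world data needs the free-text
inclusion/exclusion criteria of a clinical trial expressed as a database
query. On an OMOP CDM database that means: each criterion becomes a
subquery on a domain event table (`condition_occurrence`,
`drug_exposure`, ...) selecting person IDs whose events match a set of
standardized concept IDs, and the per-criterion person sets are combined
by set algebra — inclusions intersected, exclusions subtracted.

Text-model-based generators of such SQL have a characteristic failure
mode: they emit *concept references that are not real* — IDs that do not
exist in the target vocabulary, real concepts placed in the wrong domain
column, concept *names* where an ID belongs, or explicit placeholders.
`trialsql` implements the full transformation pipeline with a
deterministic rule backend, an automated auditor that detects and
classifies those failures against a loadable concept inventory, and the
evaluation statistics used to report them. A pluggable backend contract
(`backend_rules()`, `mock_backend()`) keeps the text-model stage
swappable while everything in this package runs offline and
bit-reproducibly.

## The preprocessing pipeline

Criteria text passes through three stages, each of which only ever
removes or normalizes material, never adds it:

1. **Segmentation** (`segment_criteria()`): bullets, numbered items and
   semicolon-delimited clauses become individual criteria; nested items
   inherit their parent header as a prefix, so Boolean structure
   survives the split.
2. **Filtration** (`filter_queryable()`): criteria with no possible
   representation in observational data are flagged with a reason code.
   The shipped rule list covers consent, willingness/compliance,
   investigator judgment, contraception agreement and co-enrollment
   restrictions. Only the consent family is canonical; the other four
   codes are our documented generalization of the same administrative
   family, and the list is user-extensible (`extra_rules`) because no
   fixed list can be complete.
3. **Simplification** (`simplify_criteria()`): temporal phrases are
   rewritten to `≤/≥ N unit` form, comparator words become symbols,
   parentheticals and courtesy lead-ins are dropped. The rules are
   idempotent, and per-criterion token counts (`token_count()`: isolate
   punctuation, split on whitespace) are non-increasing across stages —
   both properties are enforced by tests. The token measure itself is a
   documented proxy; only *relative* reduction is ever reported
   (`token_reduction_pct()`), never absolute counts, because tokenizers
   differ.

`extract_elements()` then parses each simplified criterion into the
seven-element record: clinical terms, terminology system, codes, a value
constraint `(comparator, number, unit)`, attributes, a temporal
constraint `(quantity, unit, anchor)`, and a negation flag (cue list:
"no history of", "without", "excluding", "absence of", ...). Every
backend output — including the shipped rule backend's own — passes
through `validate_extraction_record()` before use; structurally invalid
output stops at that gate.

## Concept mapping

`baseline_map()` is a deliberately simple string mapper in the USAGI
style: normalize both sides (lowercase, strip punctuation, collapse
whitespace), score by `1 − Levenshtein / max(length)`, return the top-k.
It makes no claim of bit-compatibility with USAGI, whose internals are
not published in enough detail; it is the package's internal comparator
for mapping evaluations. Ties are broken by lower `concept_id` so
output is deterministic — a choice that matters exactly in the situation
the evaluation highlights, where several near-identical concept names
(infection vs. contact forms of the same term) score equally.

## SQL generation

`build_criterion_query()` renders one subquery per criterion:

```
SELECT person_id FROM <event table>
WHERE <concept column> IN (<ids>) [AND <value>] [AND <date>]
```

* **Descendant expansion.** The ID list is the union of
  `descendants()` of the mapped concepts when expansion is on. The
  ancestor closure is computed once at inventory load (reflexive +
  transitive, the OMOP `concept_ancestor` convention), making expansion
  a pure lookup. Expansion defaults ON for Condition and Drug and OFF
  elsewhere: missed descendants in those two domains are the classic
  silent-cohort-shrinkage failure (the Type-2-diabetes pattern — perfect
  overlap coefficient, tiny Jaccard), while Measurement/Observation
  concepts are usually referenced exactly. Overridable per criterion.
* **Temporal constraints** render on the domain's date column relative
  to a *fixed, configurable index date* (default `2023-12-31`), not
  "today": reproducibility requires the same query text tomorrow.
  Month and year units render as 30/365-day offsets — an explicit,
  testable choice where calendar arithmetic has no single answer.
* **Demographic age** renders on `person.year_of_birth` as whole-year
  age at the index date (`age ≥ 18` with index year Y becomes
  `year_of_birth ≤ Y − 18`), since birth dates, not ages, are stored.
* **Negation routing** (`negation_route()`): a negated inclusion is the
  same cohort operation as an exclusion and is routed there; a negated
  *exclusion* is flagged for manual review instead of being silently
  double-negated.

`assemble_cohort()` merges inclusion fragments with `INTERSECT` and
applies exclusions either with `EXCEPT` or as `NOT IN` — two renderings
of the same set difference, and the test suite executes both against
in-memory SQLite databases to confirm set-identical results and
agreement with brute-force set algebra computed directly on the data
frames. The dialect is a portable ANSI subset; no vendor extensions.

## The hallucination auditor

`audit_query()` combines three checks:

1. a structural parse check (unparseable text is a *generation
   failure*, recorded as `parse_ok = FALSE` with no instances — it never
   contributes hallucination instances);
2. concept-site classification: every literal compared against a
   `*_concept_id` column is one site, classified into at most one of
   five categories ordered by severity — A/Critical (nonexistent ID),
   B/Major (wrong domain), C/Major (natural language), D/Moderate
   (placeholder), E/Minor (schema errors);
3. schema validation against the embedded CDM v5.3 catalog
   (`validate_identifiers()`), which yields the E instances.

**Precedence D → C → A → B.** The categories are described as disjoint
but are not mutually exclusive as predicates: a placeholder is also
non-numeric, and a natural-language string is also absent from the
inventory. An explicit order is therefore required; we test the most
specific syntactic property first (placeholder pattern), then
non-numerals, then existence, then domain. A quoted integer (`'201826'`)
is treated as a numeral, since SQL engines coerce it — only genuinely
non-numeric text lands in C.

**Hallucination policy.** Published usage of "hallucination rate" mixes
a narrow definition (queries containing invalid concept IDs) with
category tables that count all five classes. The package makes the
choice explicit: `default` counts A–D (schema errors are tracked
separately), `strict` counts only A, `broad` counts A–E; all three are
reportable, and `effective = parse_ok ∧ ¬hallucinated` under the active
policy. Relatedly, published per-model effective-SQL figures are not
always consistent with the stated formula *generation × (1 −
hallucination)*; `effective_rate()` implements the stated formula, and
no table-level published effective values are treated as reference
points.

**Category distributions count sites, not queries** (`audit_batch()`,
`category_tally()`), matching how per-model error-distribution tables
are tabulated; a query with three bad literals contributes three
instances.

## The synthetic test bed

`generate_vocabulary()` reproduces the mechanism that makes limited-
coverage claims datasets (such as SynPUF, which loads roughly 27,000 of
the >2 million OMOP concepts) a natural hallucination elicitor: a
universe of concepts of which only a fraction is "loaded". Category-A
injections draw from universe ∖ loaded — real concepts the target
database has never seen — with fabricated IDs as a fallback option.
Defaults: a 10,000-concept universe with 10% loaded, domain weights
following the empirical domain distribution of extracted trial concepts
(Condition-heavy), and per-domain concept forests of depth 3 and
branching 3 feeding the ancestor closure. Desk-scale tests use a
1,000-concept universe; the acceptance script uses 10 corpora of 100
queries and mini CDMs of 50–500 persons — sizes chosen so the whole
suite runs in well under a minute while still exercising every category
and merge mode.

`generate_mini_cdm()` materializes person/event tables with independent
per-concept event draws; its draw log is the execution oracle.
`inject_errors()` perturbs audit-clean queries site by site under a
per-category probability profile, at most one injection per site, and
records every edit in a manifest. The package's central correctness
property is the round trip: **the auditor must recover the injected
manifest exactly — 100% sensitivity and specificity — across seeds**.
This is by construction the detector's correctness surface: it shows the
detector is exact on the error taxonomy, not that the taxonomy captures
every real-world LLM failure.

What the synthetic data does *not* emulate: comorbidity structure,
visit patterns, missingness, coding variation, or any specific SynPUF
release. Passing tests therefore demonstrate correctness of the
machinery (parsing, expansion, set algebra, classification arithmetic),
not real-world retrieval performance.

## Evaluation statistics

* `rate_with_ci()` defaults to the Wald interval because that is the
  interval form the reported rates carry (249/760 → 32.7%, CI
  29.4–36.1%); Wilson is available behind a flag as the better-behaved
  option at extreme rates.
* `mcnemar_test()` defaults to the uncorrected chi-squared on the
  discordant cells; continuity-corrected and exact-binomial variants are
  selectable since the variant used in any given report is rarely
  stated. On the mapping comparison (b = 61, c = 2) all three agree on
  significance.
* `cohort_concordance()` returns Jaccard and overlap; for an empty set
  the 0/0 forms are defined as 0 with a warning, matching the convention
  used for complete retrieval failures.
* `aggregate_expert_scores()` averages the two raters per item and
  reports unweighted Cohen's kappa on the 4-level scale (no weighting
  scheme is assumed where none is specified).

## Known limitations

* The SQL scanner targets the ANSI subset the builder emits plus the
  error shapes the auditor classifies; it is not a general SQL parser,
  and exotic vendor syntax will fail its parse check (and be counted,
  correctly for this pipeline, as a generation failure).
* The rule backend is a deterministic stand-in for a text model: it is
  the offline reference implementation of the pipeline contract, not a
  claim that rules match LLM extraction quality.
* The filtration and simplification rule lists are documented supersets
  of the canonical examples; real criteria corpora will contain
  administrative phrasings they miss, which is why both are extensible.
* Strata in mapping evaluations are treated as independent counts; no
  assumption is made that per-domain denominators partition the overall
  term set.
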