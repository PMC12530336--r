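test_that("criterion fragments render the domain table and concept IN-list", {
  inv <- tiny_inventory()
  rec <- extraction_record("type 2 diabetes")
  q <- build_criterion_query(rec, 2L, domain_to_rule("Condition"), inv,
                             expand = FALSE)
  expect_identical(q$sql_fragment,
    "SELECT person_id FROM condition_occurrence WHERE condition_concept_id IN (2)")
  expect_false(q$expanded)

  # expansion through the ancestor closure: 7-node tree -> 7 IDs
  q7 <- build_criterion_query(rec, 10L, domain_to_rule("Condition"), inv,
                              expand = TRUE)
  expect_identical(q7$concept_ids, 10:16)
  expect_match(q7$sql_fragment, "IN \\(10, 11, 12, 13, 14, 15, 16\\)")
  # Condition defaults to expansion ON
  expect_true(build_criterion_query(rec, 10L, domain_to_rule("Condition"), inv)$expanded)
  expect_false(build_criterion_query(rec, 200L, domain_to_rule("Measurement"), inv)$expanded)
})

test_that("value and temporal constraints render on the domain's columns", {
  inv <- tiny_inventory()
  hb <- extraction_record("hemoglobin",
                          value = list(comparator = "<", number = 10, unit = "g/dL"))
  q <- build_criterion_query(hb, 200L, domain_to_rule("Measurement"), inv)
  expect_match(q$sql_fragment, "value_as_number < 10", fixed = TRUE)

  mi <- extraction_record("myocardial infarction",
                          temporal = list(quantity = 6, unit = "month",
                                          anchor = "index", comparator = "≤"))
  qt <- build_criterion_query(mi, 13L, domain_to_rule("Condition"), inv,
                              expand = FALSE, index_date = "2023-12-31")
  # 6 months = 180 days before the index date
  expect_match(qt$sql_fragment, "condition_start_date >= '2023-07-04'", fixed = TRUE)

  # value constraint on a domain without a value column is a build error
  bad <- extraction_record("stroke", value = list(comparator = ">", number = 1))
  expect_error(build_criterion_query(bad, 15L, domain_to_rule("Condition"), inv),
               class = "trialsql_build_error")
  expect_error(build_criterion_query(extraction_record("x"), integer(0),
                                     domain_to_rule("Condition"), inv),
               class = "trialsql_build_error")
  expect_error(build_criterion_query(extraction_record("x"), 424242L,
                                     domain_to_rule("Condition"), inv),
               class = "trialsql_build_error")
})

test_that("demographic age criteria render as a year_of_birth bound", {
  inv <- tiny_inventory()
  age <- extraction_record("age", value = list(comparator = "≥", number = 18))
  q <- build_criterion_query(age, integer(0), domain_to_rule("Demographic"), inv,
                             index_date = "2023-12-31")
  expect_identical(q$sql_fragment,
                   "SELECT person_id FROM person WHERE year_of_birth <= 2005")
})

test_that("negation routing sends absence criteria to the exclusion arm", {
  no_stroke <- extraction_record("stroke", negation = TRUE,
                                 criterion_ref = list(polarity = "inclusion"))
  expect_identical(negation_route(no_stroke)$placement, "exclusion")
  pregnancy <- extraction_record("pregnancy",
                                 criterion_ref = list(polarity = "exclusion"))
  expect_identical(negation_route(pregnancy)$placement, "exclusion")
  dbl <- extraction_record("consent capability", negation = TRUE,
                           criterion_ref = list(polarity = "exclusion"))
  expect_identical(negation_route(dbl)$placement, "manual_review")
  plain <- extraction_record("diabetes",
                             criterion_ref = list(polarity = "inclusion"))
  expect_identical(negation_route(plain)$placement, "inclusion")
})

test_that("a lone inclusion assembles to its wrapped fragment and zero fail", {
  inv <- tiny_inventory()
  q <- build_criterion_query(extraction_record("x"), 2L,
                             domain_to_rule("Condition"), inv, expand = FALSE)
  cq <- assemble_cohort(list(q))
  expect_identical(cq$sql_text,
                   paste0("SELECT person_id FROM (\n", q$sql_fragment,
                          "\n) AS included"))
  expect_error(assemble_cohort(list()), class = "trialsql_build_error")
})

test_that("assembled cohorts equal brute-force set algebra on the mini CDM", {
  voc <- shared_vocab()
  inv <- voc$loaded
  for (s in 1:5) {
    cdm <- generate_mini_cdm(inv, n_persons = 60, n_concepts = 8, seed = s)
    cids <- as.integer(names(cdm$draw_log))
    picks <- cids[seq_len(3)]
    qs <- lapply(picks, function(cid)
      build_criterion_query(extraction_record("x"), cid,
                            domain_to_rule(concept_domain(inv, cid)), inv,
                            expand = FALSE))
    except <- assemble_cohort(qs[1:2], qs[3], mode = "except")
    notin <- assemble_cohort(qs[1:2], qs[3], mode = "notin")
    got_e <- execute_cohort(except, cdm)
    got_n <- execute_cohort(notin, cdm)
    oracle <- setdiff(intersect(persons_with_concept(cdm, picks[1], inv),
                                persons_with_concept(cdm, picks[2], inv)),
                      persons_with_concept(cdm, picks[3], inv))
    expect_identical(got_e, sort(oracle))
    expect_identical(got_n, got_e)   # EXCEPT and NOT IN are set-identical
  }
})

test_that("descendant expansion matches the union of per-descendant cohorts", {
  voc <- shared_vocab()
  inv <- voc$loaded
  cond <- inv$concepts$concept_id[inv$concepts$domain_id == "Condition"]
  root <- cond[which.max(vapply(cond, function(i) length(descendants(inv, i)),
                                numeric(1)))]
  expect_gt(length(descendants(inv, root)), 1L)
  rates <- data.frame(concept_id = descendants(inv, root), rate = 0.3)
  cdm <- generate_mini_cdm(inv, n_persons = 80, event_rates = rates, seed = 9)
  q <- build_criterion_query(extraction_record("x"), root,
                             domain_to_rule("Condition"), inv, expand = TRUE)
  got <- execute_cohort(assemble_cohort(list(q)), cdm)
  expect_identical(got, persons_with_concept(cdm, descendants(inv, root), inv))
})

test_that("adding criteria never enlarges the cohort", {
  voc <- shared_vocab()
  inv <- voc$loaded
  cdm <- generate_mini_cdm(inv, n_persons = 60, n_concepts = 8, seed = 3)
  cids <- as.integer(names(cdm$draw_log))[1:3]
  qs <- lapply(cids, function(cid)
    build_criterion_query(extraction_record("x"), cid,
                          domain_to_rule(concept_domain(inv, cid)), inv,
                          expand = FALSE))
  base <- execute_cohort(assemble_cohort(qs[1]), cdm)
  two_inc <- execute_cohort(assemble_cohort(qs[1:2]), cdm)
  with_exc <- execute_cohort(assemble_cohort(qs[1:2], qs[3]), cdm)
  expect_true(all(two_inc %in% base))
  expect_true(all(with_exc %in% two_inc))
})

test_that("temporal constraints filter events by date at execution", {
  inv <- tiny_inventory()
  cdm <- generate_mini_cdm(inv, n_persons = 40,
                           event_rates = data.frame(concept_id = 13L, rate = 0.8),
                           seed = 2, date_window = c("2023-01-01", "2023-12-31"))
  rec <- extraction_record("myocardial infarction",
                           temporal = list(quantity = 6, unit = "month",
                                           anchor = "index", comparator = "≤"))
  q <- build_criterion_query(rec, 13L, domain_to_rule("Condition"), inv,
                             expand = FALSE, index_date = "2023-12-31")
  got <- execute_cohort(assemble_cohort(list(q)), cdm)
  ev <- cdm$tables$condition_occurrence
  oracle <- sort(unique(ev$person_id[ev$condition_concept_id == 13L &
                                     as.Date(ev$condition_start_date) >=
                                       as.Date("2023-12-31") - 180]))
  expect_identical(got, oracle)
})
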