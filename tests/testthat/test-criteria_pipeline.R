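test_that("segmentation splits items and inherits nested context", {
  expect_identical(segment_criteria("1. Age ≥ 18\n2. Pregnancy", "T")$segmented_text,
                   c("Age ≥ 18", "Pregnancy"))
  expect_identical(
    segment_criteria("Diabetes with: a) HbA1c > 7%; b) on metformin", "T")$segmented_text,
    c("Diabetes with: HbA1c > 7%", "Diabetes with: on metformin"))
  # multiline sublist under a colon header behaves the same
  expect_identical(
    segment_criteria("Diabetes with:\na) HbA1c > 7%\nb) on metformin", "T")$segmented_text,
    c("Diabetes with: HbA1c > 7%", "Diabetes with: on metformin"))
  one <- "An unstructured sentence about prior anticoagulant use"
  expect_identical(segment_criteria(one, "T")$segmented_text, one)
  # AND/OR connectors are kept verbatim
  both <- segment_criteria("- Hypertension AND diabetes", "T")$segmented_text
  expect_match(both, "AND", fixed = TRUE)
})

test_that("filtration flags administrative criteria with reason codes", {
  crit <- segment_criteria(paste(
    "Provided written informed consent",
    "Type 1 diabetes",
    "Willing to comply with study visits",
    "Hemoglobin < 10 g/dL",
    "Use of effective contraception during the study",
    "In the opinion of the investigator, unlikely to complete the trial",
    "Myocardial infarction within the past 6 months",
    "Currently enrolled in another clinical trial",
    "Age ≥ 18",
    "eGFR < 30", sep = "\n"), "T")
  crit <- filter_queryable(crit)
  expect_identical(sum(crit$queryable), 5L)       # 10 criteria, 5 administrative
  expect_identical(crit$non_queryable_reason[1], "consent")
  expect_identical(crit$non_queryable_reason[3], "willingness")
  expect_identical(crit$non_queryable_reason[5], "contraception")
  expect_identical(crit$non_queryable_reason[6], "investigator_judgment")
  expect_identical(crit$non_queryable_reason[8], "co_enrollment")
  expect_true(crit$queryable[2])
  expect_identical(crit$segmented_text, crit$raw_text)   # ordering preserved
  # user-extensible rules
  crit2 <- filter_queryable(segment_criteria("Lives near the study site", "T"),
                            extra_rules = list(geography = "lives near"))
  expect_identical(crit2$non_queryable_reason, "geography")
})

test_that("simplification normalizes temporals/comparators and never adds tokens", {
  txts <- c("history of MI within the past six months",
            "age 18 years or older (adults)",
            "hemoglobin less than 10 g/dL",
            "Patients must have documented type 2 diabetes",
            "stroke in the last 2 years")
  crit <- filter_queryable(segment_criteria(paste(txts, collapse = "\n"), "T"))
  crit <- simplify_criteria(crit)
  expect_identical(crit$simplified_text[1], "history of MI ≤ 6 months")
  expect_identical(crit$simplified_text[2], "age ≥ 18 years")
  expect_identical(crit$simplified_text[3], "hemoglobin < 10 g/dL")
  expect_identical(crit$simplified_text[5], "stroke ≤ 2 years")
  expect_true(all(crit$tokens_simplification <= crit$tokens_filtering))
  # idempotence: simplified text is a fixed point of the rules
  again <- simplify_criteria(filter_queryable(segment_criteria(
    paste(crit$simplified_text, collapse = "\n"), "T")))
  expect_identical(again$simplified_text, crit$simplified_text)
})

test_that("token counting isolates punctuation then splits on whitespace", {
  expect_identical(token_count(""), 0L)
  expect_identical(token_count("Age ≥ 18"), 3L)
  expect_identical(token_count("hemoglobin < 10 g/dL"), 6L)  # "/" separates
  expect_identical(token_count("Type 2 diabetes, uncontrolled"), 5L)
  expect_identical(token_count("  spaced   out  "), 2L)
})

test_that("seven-element extraction parses values, temporals and negation", {
  rec <- extract_elements(data.frame(simplified_text = "hemoglobin < 10 g/dL"))
  expect_identical(rec$value, list(comparator = "<", number = 10, unit = "g/dL"))
  expect_identical(rec$clinical_terms, "hemoglobin")
  expect_false(rec$negation)

  rec2 <- extract_elements(data.frame(simplified_text = "no history of stroke"))
  expect_true(rec2$negation)
  expect_identical(rec2$clinical_terms, "stroke")

  rec3 <- extract_elements(data.frame(simplified_text = "Type 1 diabetes"))
  expect_identical(rec3$clinical_terms, "Type 1 diabetes")
  expect_null(rec3$value)
  expect_null(rec3$temporal)
  expect_identical(rec3$codes, character(0))

  rec4 <- extract_elements(data.frame(simplified_text = "myocardial infarction ≤ 6 months"))
  expect_identical(rec4$temporal$quantity, 6)
  expect_identical(rec4$temporal$unit, "month")
  expect_identical(rec4$clinical_terms, "myocardial infarction")

  rec5 <- extract_elements(data.frame(simplified_text = "uncontrolled hypertension"))
  expect_identical(rec5$attributes, "uncontrolled")
})

test_that("the schema gate rejects malformed backend output", {
  bad <- mock_backend(stats::setNames(
    list(list(clinical_terms = character(0))),   # empty terms: schema-invalid
    backend_script_key("extract", list(text = "x"))))
  expect_error(extract_elements(data.frame(simplified_text = "x"), backend = bad),
               class = "trialsql_schema_error")
  expect_error(extraction_record("stroke", value = list(comparator = "~", number = 1)),
               class = "trialsql_schema_error")
  expect_error(extraction_record("stroke", temporal = list(quantity = 1, unit = "fortnight")),
               class = "trialsql_schema_error")
})

test_that("a scripted mock backend reproduces the rules pipeline on a fixture", {
  block <- "1. Age ≥ 18\n2. Pregnancy"
  rules_out <- segment_criteria(block, "T")
  script <- stats::setNames(
    list(list(segments = rules_out$segmented_text)),
    backend_script_key("segment", list(block = block)))
  mock <- mock_backend(script)
  expect_identical(segment_criteria(block, "T", backend = mock), rules_out)
  expect_error(segment_criteria("something else", "T", backend = mock),
               class = "trialsql_scripted_miss")
})

test_that("trial preprocessing reports consistent stage statistics", {
  trial <- list(
    trial_id = "NCT-TEST",
    inclusion = c("1. Age 18 years or older (adults)\n2. Type 2 diabetes\n3. Willing to comply with the protocol"),
    exclusion = c("1. Pregnancy\n2. Provided written informed consent\n3. history of MI within the past six months"))
  res <- preprocess_trial(trial)
  st <- res$stage_stats
  expect_identical(st$stage, c("segmentation", "filtering", "simplification"))
  expect_identical(st$n_criteria, c(6L, 4L, 4L))
  # stats equal direct recomputation from the per-criterion counts
  keep <- !is.na(res$criteria$queryable) & res$criteria$queryable
  expect_identical(st$total_tokens[1], sum(res$criteria$tokens_segmentation))
  expect_identical(st$total_tokens[2], sum(res$criteria$tokens_filtering[keep]))
  expect_identical(st$total_tokens[3], sum(res$criteria$tokens_simplification[keep]))
  expect_equal(res$pct_token_reduction,
               100 * (1 - st$total_tokens[3] / st$total_tokens[1]))
  # token monotonicity for every retained criterion
  expect_true(all(res$criteria$tokens_simplification[keep] <=
                  res$criteria$tokens_filtering[keep]))
  # determinism of the whole path
  expect_identical(preprocess_trial(trial), res)

  expect_equal(preprocess_trial(list(trial_id = "noop",
                                     inclusion = "stroke"))$pct_token_reduction, 0)
  expect_error(preprocess_trial(list(trial_id = "empty")),
               class = "trialsql_input_error")
})
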