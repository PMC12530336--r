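test_that("concept-reference sites are extracted per literal, in order", {
  refs <- extract_concept_refs(
    "SELECT person_id FROM condition_occurrence WHERE condition_concept_id IN (201826, 4058243)")
  expect_identical(nrow(refs), 2L)
  expect_identical(refs$literal, c("201826", "4058243"))
  expect_identical(refs$column, rep("condition_concept_id", 2))
  expect_true(all(diff(refs$position) > 0))

  ph <- extract_concept_refs(
    "SELECT person_id FROM drug_exposure WHERE drug_concept_id = <INSERT_ID>")
  expect_identical(ph$literal, "<INSERT_ID>")

  expect_identical(nrow(extract_concept_refs(
    "SELECT person_id FROM person WHERE year_of_birth < 1990")), 0L)
  # IN (SELECT ...) subqueries contribute no literal sites
  expect_identical(nrow(extract_concept_refs(
    "SELECT person_id FROM condition_occurrence WHERE condition_concept_id IN (SELECT descendant_concept_id FROM concept_ancestor WHERE ancestor_concept_id = 2)")),
    1L)  # only the ancestor literal
  # BETWEEN contributes both endpoints
  btw <- extract_concept_refs(
    "SELECT person_id FROM condition_occurrence WHERE condition_concept_id BETWEEN 100 AND 200")
  expect_identical(btw$literal, c("100", "200"))
})

test_that("site classification follows the D -> C -> A -> B precedence", {
  inv <- tiny_inventory()
  site <- function(lit, col = "condition_concept_id")
    list(table = NA_character_, column = col, literal = lit, position = 1L)
  cat_of <- function(lit, col = "condition_concept_id") {
    inst <- classify_site(site(lit, col), inv)
    if (is.null(inst)) NA_character_ else inst$category
  }
  # D: placeholders of every shipped shape (also non-numeric: D wins over C)
  for (lit in c("?", "{concept_id}", "<INSERT_CONCEPT_ID>", ":concept_id",
                "CONCEPT_ID_HERE", "'PLACEHOLDER'"))
    expect_identical(cat_of(lit), "D")
  # C: natural language in a concept field
  expect_identical(cat_of("'type 2 diabetes'"), "C")
  expect_identical(cat_of("diabetes"), "C")
  # A: integer absent from the inventory
  expect_identical(cat_of("999999"), "A")
  # B: real concept, wrong domain (Drug concept in a condition column)
  expect_identical(cat_of("100"), "B")
  # clean: existing concept, matching domain
  expect_true(is.na(cat_of("2")))
  # quoted integers are numerals, not natural language
  expect_true(is.na(cat_of("'2'")))
  # unregistered concept columns get existence checks only
  expect_identical(cat_of("999999", "condition_type_concept_id"), "A")
  expect_true(is.na(cat_of("100", "condition_type_concept_id")))
  # severity mapping is fixed
  expect_identical(classify_site(site("999999"), inv)$severity, "Critical")
  expect_identical(classify_site(site("100"), inv)$severity, "Major")
  expect_identical(classify_site(site("?"), inv)$severity, "Moderate")
})

test_that("query audits combine parse, concept and schema checks", {
  inv <- tiny_inventory()
  clean <- "SELECT person_id FROM condition_occurrence WHERE condition_concept_id IN (2, 3)"
  a <- audit_query(clean, inv)
  expect_true(a$parse_ok)
  expect_length(a$instances, 0)
  expect_true(a$effective)
  expect_false(a$hallucinated)

  garbled <- audit_query("I am unable to produce SQL here.", inv)
  expect_false(garbled$parse_ok)
  expect_false(garbled$effective)
  expect_length(garbled$instances, 0)

  schema_bad <- audit_query(
    "SELECT person_id FROM condition_table WHERE condition_concept_id = 2", inv)
  expect_identical(schema_bad$categories, "E")
  expect_true(schema_bad$effective)       # default policy: E is not a hallucination
  expect_false(audit_query(
    "SELECT person_id FROM condition_table WHERE condition_concept_id = 2",
    inv, policy = "broad")$effective)

  mixed <- audit_query(
    "SELECT person_id FROM condition_occurrence WHERE condition_concept_id IN (999999, 100)",
    inv)
  expect_setequal(mixed$categories, c("A", "B"))
  expect_false(mixed$effective)
  expect_true(audit_query(
    "SELECT person_id FROM condition_occurrence WHERE condition_concept_id = 100",
    inv, policy = "strict")$effective)    # strict counts only A
  # idempotence
  expect_identical(audit_query(clean, inv), audit_query(clean, inv))
})

test_that("batch tallies match single-query audits and manifest ground truth", {
  voc <- shared_vocab()
  qs <- generate_valid_queries(voc$loaded, 30, seed = 21)
  inj <- inject_errors(qs, c(A = .2, B = .2, C = .1, D = .2, E = .2),
                       voc$universe, voc$loaded, seed = 8)
  res <- audit_batch(inj$queries, voc$loaded,
                     groups = rep(c("m1", "m2"), each = 15))
  # count identity: per-category sums across groups == total instances
  total_inst <- sum(vapply(res$audits, function(a) length(a$instances), numeric(1)))
  expect_identical(sum(res$tally$total), as.integer(total_inst))
  for (cc in c("A", "B", "C", "D", "E"))
    expect_identical(sum(res$tally[[cc]]),
                     as.integer(sum(inj$manifest$category == cc)))
  expect_equal(rowSums(res$tally[paste0("pct_", c("A", "B", "C", "D", "E"))]),
               rep(100, 2), ignore_attr = TRUE)
  empty <- audit_batch(character(0), voc$loaded)
  expect_null(empty$tally)
})

test_that("category tallies format shares of the instance total", {
  tal <- category_tally(c(A = 0, B = 12, C = 0, D = 12, E = 8))
  expect_identical(tal$n, c(0L, 12L, 0L, 12L, 8L))
  expect_equal(tal$pct, c(0, 37.5, 0, 37.5, 25.0))
  expect_equal(category_tally(integer(0))$pct, rep(0, 5))
})

test_that("injected corpora are recovered with full sensitivity and specificity", {
  voc <- shared_vocab()
  qs <- generate_valid_queries(voc$loaded, 40, seed = 77)
  for (s in 1:3) {
    inj <- inject_errors(qs, c(A = .2, B = .2, C = .15, D = .15, E = .25),
                         voc$universe, voc$loaded, seed = s)
    for (i in seq_along(inj$queries)) {
      a <- audit_query(inj$queries[i], voc$loaded)
      want <- sort(inj$manifest$category[inj$manifest$query_id == i])
      expect_identical(sort(a$categories), as.character(want))
    }
  }
})
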