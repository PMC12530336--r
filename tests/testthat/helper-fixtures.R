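# In-code fixtures shared across test files.

# A small hand-built inventory: a 3-concept chain (1 -> 2 -> 3), a 7-node
# binary tree rooted at 10, a drug, a measurement, and named concepts for
# the string mapper.
tiny_inventory <- function() {
  concepts <- data.frame(
    concept_id = c(1L, 2L, 3L, 10L, 11L, 12L, 13L, 14L, 15L, 16L,
                   100L, 200L, 301L, 302L),
    concept_name = c("Diabetes mellitus", "Type 2 diabetes mellitus",
                     "Type 2 diabetes mellitus with complication",
                     "Cardiovascular disease", "Ischemic heart disease",
                     "Cerebrovascular disease", "Myocardial infarction",
                     "Angina pectoris", "Stroke", "Transient ischemic attack",
                     "Metformin", "Hemoglobin measurement",
                     "Human immunodeficiency virus infection",
                     "Human immunodeficiency virus contact"),
    domain_id = c(rep("Condition", 10), "Drug", "Measurement",
                  "Condition", "Observation"),
    vocabulary_id = "SNOMED",
    standard_concept = "S",
    stringsAsFactors = FALSE)
  pairs <- data.frame(
    ancestor_concept_id   = c(1L, 2L, 10L, 10L, 11L, 11L, 12L, 12L),
    descendant_concept_id = c(2L, 3L, 11L, 12L, 13L, 14L, 15L, 16L))
  concept_inventory(concepts, pairs)
}

# Reference Levenshtein distance: textbook dynamic programming, kept
# independent of the implementation under test.
dp_editdist <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  m <- length(a); n <- length(b)
  d <- matrix(0L, m + 1, n + 1)
  d[, 1] <- 0:m; d[1, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (a[i] != b[j]))
  d[m + 1, n + 1]
}

# Shared synthetic vocabulary + fixture queries (built once per test run).
shared_vocab <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_vocabulary(1000, 0.1, seed = 42)
    cache
  }
})
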