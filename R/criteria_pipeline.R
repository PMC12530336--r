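# Three-stage preprocessing of free-text eligibility criteria
# (segmentation -> filtration -> simplification) and seven-element
# information extraction.  Every stage delegates to a pluggable text-model
# backend; the shipped default is a deterministic rule-based backend so
# the whole path runs offline and bit-stably.

# ---------------------------------------------------------------------------
# backend contract

#' The deterministic rule-based text backend
#'
#' A backend is a list `{name, deterministic, transform(task, input)}`
#' where `transform` takes a task tag (`"segment"`, `"filter"`,
#' `"simplify"`, `"extract"`) and a structured input (JSON-serializable
#' list) and returns a structured output.  This rule backend implements
#' every task with documented pattern rules and is the package default;
#' scripted mocks (see [mock_backend()]) share the same contract, so
#' production text-model adapters can be swapped in without touching the
#' pipeline.
#'
#' @return A backend object (class `trialsql_backend`).
#' @export
backend_rules <- function() {
  structure(list(
    name = "rules",
    deterministic = TRUE,
    transform = function(task, input) {
      switch(task,
        segment  = list(segments = .seg_rules(input$block)),
        filter   = .filter_rules(input$text),
        simplify = list(text = .simplify_rules(input$text)),
        extract  = .extract_rules(input$text),
        stop("unknown task: ", task))
    }),
    class = "trialsql_backend")
}

backend_transform <- function(backend, task, input) {
  stopifnot(inherits(backend, "trialsql_backend"))
  backend$transform(task, input)
}

# ---------------------------------------------------------------------------
# tokenizer

#' Count tokens in a text
#'
#' The token measure used throughout the preprocessing statistics:
#' punctuation characters (plus the comparison glyphs `< > = ≤ ≥ ±`)
#' are isolated as separate tokens, then the text is split on whitespace.
#' `token_count("Age ≥ 18")` is 3.
#'
#' @param text Character scalar.
#' @return Integer token count (0 for empty/blank text).
#' @export
token_count <- function(text) {
  vapply(text, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(0L)
    y <- gsub("([[:punct:]]|[<>=≤≥±])", " \\1 ", x)
    length(strsplit(trimws(y), "[[:space:]]+")[[1]])
  }, integer(1), USE.NAMES = FALSE)
}

# ---------------------------------------------------------------------------
# stage 1: segmentation

.seg_rules <- function(block) {
  lines <- trimws(strsplit(block, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  out <- character(0)
  prefix <- ""
  marker <- "^(\\d+[.)]|[a-z][.)]|[-*•])[[:space:]]+"
  for (ln in lines) {
    rest <- sub("^[^:]*:", "", ln)
    # inline sublist: "Intro: a) x; b) y"  ->  items prefixed with "Intro:"
    if (grepl(":", ln, fixed = TRUE) && nzchar(trimws(rest)) &&
        (grepl(";", rest, fixed = TRUE) || grepl("\\b[a-z][.)][[:space:]]", rest))) {
      intro <- trimws(sub("(:).*$", "\\1", ln))
      parts <- trimws(strsplit(rest, ";", fixed = TRUE)[[1]])
      parts <- sub("^[a-z][.)][[:space:]]*", "", parts)
      parts <- parts[nzchar(parts)]
      out <- c(out, paste(intro, parts))
      prefix <- ""
      next
    }
    is_sub <- grepl("^[a-z][.)][[:space:]]", ln)
    txt <- sub(marker, "", ln)
    if (grepl(":[[:space:]]*$", ln)) {            # header line opens a sublist
      prefix <- trimws(txt)
      next
    }
    if (is_sub && nzchar(prefix)) txt <- paste(prefix, txt)
    if (!is_sub) prefix <- ""
    parts <- trimws(strsplit(txt, ";", fixed = TRUE)[[1]])
    out <- c(out, parts[nzchar(parts)])
  }
  out
}

#' Segment a free-text criteria block into individual criteria
#'
#' Each bullet, numbered item or semicolon-delimited clause becomes one
#' criterion.  Nested items (lettered sub-lists, or items under a line
#' ending in a colon) inherit the parent context as a prefix, preserving
#' the Boolean/hierarchical structure of the source text; AND/OR
#' connectors are kept verbatim.  Empty lines are dropped.
#'
#' @param block Free-text criteria block (one string, possibly multiline).
#' @param trial_id,polarity Metadata attached to each criterion
#'   (`polarity` is `"inclusion"` or `"exclusion"`).
#' @param backend A text backend; default [backend_rules()].
#' @return A criteria data.frame: `trial_id`, `index`, `polarity`,
#'   `raw_text`, `segmented_text`, `queryable`, `non_queryable_reason`,
#'   `simplified_text`, `tokens_segmentation`, `tokens_filtering`,
#'   `tokens_simplification`.
#' @examples
#' segment_criteria("1. Age ≥ 18\n2. Pregnancy", "T1", "inclusion")$segmented_text
#' @export
segment_criteria <- function(block, trial_id = "trial", polarity = "inclusion",
                             backend = backend_rules()) {
  stopifnot(is.character(block), length(block) == 1L, nzchar(block))
  polarity <- match.arg(polarity, c("inclusion", "exclusion"))
  out <- backend_transform(backend, "segment", list(block = block))
  segs <- as.character(out$segments)
  if (!is.character(segs)) stop("backend returned invalid segmentation output")
  data.frame(
    trial_id = trial_id,
    index = seq_along(segs),
    polarity = polarity,
    raw_text = segs,
    segmented_text = segs,
    queryable = NA,
    non_queryable_reason = NA_character_,
    simplified_text = NA_character_,
    tokens_segmentation = token_count(segs),
    tokens_filtering = NA_integer_,
    tokens_simplification = NA_integer_,
    stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# stage 2: filtration

# Rule list for non-queryable, trial-specific criteria.  The canonical
# example is the informed-consent requirement; the other reason codes
# cover the same family of administrative criteria that have no
# representation in observational data.
.default_nonqueryable_rules <- list(
  consent = "informed consent|consent form|(written|signed|provide[ds]?|able to give|giving) consent",
  willingness = "willing(ness)? to|ability to comply|able to comply|complian(t|ce) with (the )?(protocol|study|visit)",
  investigator_judgment = "(opinion|judge?ment|discretion) of the (investigator|sponsor)|investigator'?s? (opinion|judge?ment|discretion)",
  contraception = "contracept|birth control",
  co_enrollment = "(participat|enroll)[a-z]* in (an)?other (clinical )?(trial|stud)|current(ly)? (participat|enroll)[a-z]* in a (trial|stud)")

.filter_rules <- function(text, rules = .default_nonqueryable_rules) {
  for (reason in names(rules)) {
    if (grepl(rules[[reason]], text, ignore.case = TRUE))
      return(list(queryable = FALSE, reason = reason))
  }
  list(queryable = TRUE, reason = NA_character_)
}

#' Flag non-queryable criteria
#'
#' Annotates each segmented criterion as queryable or not, with a reason
#' code from a documented, user-extensible rule list: `consent`,
#' `willingness`, `investigator_judgment`, `contraception`,
#' `co_enrollment`.  Ordering is preserved; nothing is dropped (downstream
#' stages skip non-queryable rows).
#'
#' @param criteria A criteria data.frame from [segment_criteria()].
#' @param backend A text backend.
#' @param extra_rules Optional named list of extra `reason = regex` rules,
#'   consulted after the defaults.
#' @return The criteria data.frame with `queryable`,
#'   `non_queryable_reason` and `tokens_filtering` filled in.
#' @export
filter_queryable <- function(criteria, backend = backend_rules(),
                             extra_rules = NULL) {
  rules <- c(.default_nonqueryable_rules, extra_rules)
  for (i in seq_len(nrow(criteria))) {
    res <- if (identical(backend$name, "rules") && !is.null(extra_rules)) {
      .filter_rules(criteria$segmented_text[i], rules)
    } else {
      backend_transform(backend, "filter", list(text = criteria$segmented_text[i]))
    }
    if (!is.logical(res$queryable))
      stop("backend returned invalid filtration output")
    criteria$queryable[i] <- res$queryable
    criteria$non_queryable_reason[i] <-
      if (res$queryable) NA_character_ else res$reason
    criteria$tokens_filtering[i] <-
      if (res$queryable) criteria$tokens_segmentation[i] else NA_integer_
  }
  criteria
}

# ---------------------------------------------------------------------------
# stage 3: simplification

.word_numbers <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
                   seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11,
                   twelve = 12)

.simplify_rules <- function(x) {
  # 1. drop parenthetical elaborations
  x <- gsub("[[:space:]]*\\([^()]*\\)", "", x)
  # 2. spell word numbers as digits in temporal contexts
  for (w in names(.word_numbers))
    x <- gsub(paste0("\\b", w, "\\b(?=[[:space:]]+(day|week|month|year)s?\\b)"),
              .word_numbers[[w]], x, ignore.case = TRUE, perl = TRUE)
  # 3. normalize temporal phrases to "<=/>= N unit"
  u <- "(days?|weeks?|months?|years?)"
  x <- gsub(paste0("\\bwithin (the )?(past|last|previous|next)?[[:space:]]*(\\d+)[[:space:]]+", u),
            "≤ \\3 \\4", x, ignore.case = TRUE)
  x <- gsub(paste0("\\b(in|during|over) the (past|last|previous) (\\d+)[[:space:]]+", u),
            "≤ \\3 \\4", x, ignore.case = TRUE)
  x <- gsub(paste0("\\bat least (\\d+)[[:space:]]+", u, " (ago|prior|before|earlier)"),
            "≥ \\1 \\2", x, ignore.case = TRUE)
  x <- gsub(paste0("\\bmore than (\\d+)[[:space:]]+", u, " (ago|prior|before|earlier)"),
            "> \\1 \\2", x, ignore.case = TRUE)
  # 4. comparator words -> symbols
  x <- gsub("(\\d+(\\.\\d+)?)[[:space:]]*(years?|months?|weeks?|days?|kg|cm)?[[:space:]]+or (older|more|greater|above|higher)",
            "≥ \\1 \\3", x, ignore.case = TRUE)
  x <- gsub("(\\d+(\\.\\d+)?)[[:space:]]*(years?|months?|weeks?|days?|kg|cm)?[[:space:]]+or (younger|less|fewer|below|lower)",
            "≤ \\1 \\3", x, ignore.case = TRUE)
  x <- gsub("\\bgreater than or equal to\\b", "≥", x, ignore.case = TRUE)
  x <- gsub("\\bless than or equal to\\b", "≤", x, ignore.case = TRUE)
  x <- gsub("\\bgreater than\\b", ">", x, ignore.case = TRUE)
  x <- gsub("\\bless than\\b", "<", x, ignore.case = TRUE)
  x <- gsub("\\bat least\\b", "≥", x, ignore.case = TRUE)
  x <- gsub("\\b(at most|no more than)\\b", "≤", x, ignore.case = TRUE)
  # 5. courtesy / lead-in phrases carry no queryable content
  x <- gsub("^(patients?|subjects?|participants?|individuals?)([[:space:]]+(must|should|will))?([[:space:]]+(be|have|with))?[[:space:]]+",
            "", x, ignore.case = TRUE)
  x <- gsub("^(must|should)[[:space:]]+(be|have)[[:space:]]+", "", x, ignore.case = TRUE)
  x <- gsub("^(diagnosed with|diagnosis of|documented|known|confirmed)[[:space:]]+", "", x,
            ignore.case = TRUE)
  # move a post-fixed comparator produced by rule 4 in front of its number:
  # "age ≥ 18 years" stays; "age 18 years ≥" cannot occur (rule 4 rewrites
  # the full phrase), so only whitespace cleanup remains.
  x <- gsub("[[:space:]]+", " ", x)
  x <- sub("[[:space:].]+$", "", x)
  trimws(x)
}

#' Simplify a queryable criterion
#'
#' Standardizes temporal expressions into `≤/≥ N unit` form, rewrites
#' comparator words as symbols, and removes parenthetical elaborations
#' and courtesy lead-in phrases, per a documented rule table.  Token
#' count never increases, and the rules are idempotent (already-minimal
#' text is a fixed point).
#'
#' @param criteria A criteria data.frame that has passed
#'   [filter_queryable()].
#' @param backend A text backend.
#' @return The criteria data.frame with `simplified_text` and
#'   `tokens_simplification` filled for queryable rows.
#' @export
simplify_criteria <- function(criteria, backend = backend_rules()) {
  for (i in seq_len(nrow(criteria))) {
    if (!isTRUE(criteria$queryable[i])) next
    out <- backend_transform(backend, "simplify",
                             list(text = criteria$segmented_text[i]))
    if (!is.character(out$text) || length(out$text) != 1L)
      stop("backend returned invalid simplification output")
    criteria$simplified_text[i] <- out$text
    criteria$tokens_simplification[i] <- token_count(out$text)
  }
  criteria
}

# ---------------------------------------------------------------------------
# seven-element extraction

.negation_cues <- c("no history of", "without", "excluding", "absence of",
                    "no prior", "no current", "no evidence of")

.temporal_units <- c(day = "day", week = "week", month = "month", year = "year")

.attribute_words <- c("severe", "acute", "chronic", "uncontrolled", "active",
                      "metastatic", "symptomatic", "unstable", "recurrent")

.extract_rules <- function(text) {
  work <- text
  negation <- FALSE
  for (cue in .negation_cues) {
    pat <- paste0("\\b", cue, "\\b[[:space:]]*")
    if (grepl(pat, work, ignore.case = TRUE)) {
      negation <- TRUE
      work <- gsub(pat, "", work, ignore.case = TRUE)
      break
    }
  }

  temporal <- NULL
  tm <- regmatches(work, regexec(
    "([≤≥<>])[[:space:]]*(\\d+(\\.\\d+)?)[[:space:]]*(day|week|month|year)s?\\b",
    work, ignore.case = TRUE))[[1]]
  if (length(tm)) {
    temporal <- list(quantity = as.numeric(tm[3]),
                     unit = tolower(tm[5]),
                     anchor = "index",
                     comparator = tm[2])
    work <- sub("[[:space:],]*([≤≥<>])[[:space:]]*\\d+(\\.\\d+)?[[:space:]]*(day|week|month|year)s?\\b",
                "", work, ignore.case = TRUE)
  }

  value <- NULL
  vm <- regmatches(work, regexec(
    "([A-Za-z][A-Za-z0-9 .-]*?)[[:space:]]*(<=|>=|[<>=≤≥])[[:space:]]*(\\d+(\\.\\d+)?)[[:space:]]*([%A-Za-z/µμ][%A-Za-z0-9/µμ]*)?",
    work, perl = TRUE))[[1]]
  if (length(vm)) {
    comp <- c("<=" = "≤", ">=" = "≥")[vm[3]]
    if (is.na(comp)) comp <- vm[3]
    value <- list(comparator = unname(comp),
                  number = as.numeric(vm[4]),
                  unit = if (is.na(vm[6]) || !nzchar(vm[6])) NA_character_ else vm[6])
    work <- sub(vm[1], vm[2], work, fixed = TRUE)   # keep the measured entity
  }

  codes <- regmatches(work,
    gregexpr("\\b[A-TV-Z][0-9]{2}(\\.[0-9A-Z]{1,3})?\\b", work))[[1]]
  system <- regmatches(work, regexec(
    "\\b(SNOMED( ?CT)?|ICD-?10(-?CM)?|RxNorm|LOINC)\\b", work,
    ignore.case = TRUE))[[1]]
  terminology <- if (length(system)) {
    s <- toupper(gsub("[ -]", "", system[2]))
    if (startsWith(s, "SNOMED")) "SNOMED CT"
    else if (startsWith(s, "ICD10")) "ICD-10"
    else if (s == "RXNORM") "RxNorm" else "LOINC"
  } else NA_character_

  attrs <- .attribute_words[vapply(.attribute_words, function(w)
    grepl(paste0("\\b", w, "\\b"), work, ignore.case = TRUE), logical(1))]

  term <- trimws(gsub("[[:space:]]+", " ",
                      gsub("^[[:space:],;:-]+|[[:space:],;:.-]+$", "", work)))
  if (!nzchar(term)) term <- trimws(text)

  list(clinical_terms = term,
       terminology_system = terminology,
       codes = as.character(codes),
       value = value,
       attributes = unname(attrs),
       temporal = temporal,
       negation = negation)
}

#' Construct / validate an extraction record
#'
#' The seven-element structured form of one criterion: clinical terms,
#' terminology system, codes, value constraint, attributes, temporal
#' constraint, and negation.  `validate_extraction_record()` is the
#' schema gate applied to every backend output before it is used
#' downstream.
#'
#' @param clinical_terms Character vector of clinical terms.
#' @param terminology_system One of `"SNOMED CT"`, `"ICD-10"`,
#'   `"RxNorm"`, `"LOINC"` or `NA`.
#' @param codes Character vector of terminology codes.
#' @param value `NULL` or list `(comparator, number, unit)` with
#'   comparator one of `<  ≤  =  ≥  >`.
#' @param attributes Character vector of qualifiers.
#' @param temporal `NULL` or list `(quantity, unit, anchor)` with unit in
#'   day/week/month/year.
#' @param negation Logical flag.
#' @param criterion_ref Optional reference to the source criterion.
#' @return A list of class `extraction_record`.
#' @export
extraction_record <- function(clinical_terms, terminology_system = NA_character_,
                              codes = character(0), value = NULL,
                              attributes = character(0), temporal = NULL,
                              negation = FALSE, criterion_ref = NULL) {
  rec <- list(criterion_ref = criterion_ref,
              clinical_terms = as.character(clinical_terms),
              terminology_system = terminology_system,
              codes = as.character(codes),
              value = value,
              attributes = as.character(attributes),
              temporal = temporal,
              negation = isTRUE(negation))
  class(rec) <- "extraction_record"
  validate_extraction_record(rec)
  rec
}

#' @rdname extraction_record
#' @param rec An object to validate.
#' @export
validate_extraction_record <- function(rec) {
  fail <- function(msg)
    stop(structure(class = c("trialsql_schema_error", "error", "condition"),
                   list(message = paste0("extraction record schema: ", msg),
                        call = NULL)))
  if (!is.list(rec)) fail("not a list")
  req <- c("clinical_terms", "terminology_system", "codes", "value",
           "attributes", "temporal", "negation")
  miss <- setdiff(req, names(rec))
  if (length(miss)) fail(paste("missing field(s):", paste(miss, collapse = ", ")))
  if (!is.character(rec$clinical_terms) || length(rec$clinical_terms) < 1L)
    fail("clinical_terms must be a nonempty character vector")
  if (!is.na(rec$terminology_system) &&
      !rec$terminology_system %in% c("SNOMED CT", "ICD-10", "RxNorm", "LOINC"))
    fail("unknown terminology_system")
  if (!is.null(rec$value)) {
    if (!all(c("comparator", "number") %in% names(rec$value)))
      fail("value needs comparator and number")
    if (!rec$value$comparator %in% c("<", "≤", "=", "≥", ">"))
      fail("invalid value comparator")
    if (!is.numeric(rec$value$number)) fail("value number must be numeric")
  }
  if (!is.null(rec$temporal)) {
    if (!all(c("quantity", "unit") %in% names(rec$temporal)))
      fail("temporal needs quantity and unit")
    if (!rec$temporal$unit %in% .temporal_units) fail("invalid temporal unit")
    if (!is.numeric(rec$temporal$quantity)) fail("temporal quantity must be numeric")
  }
  if (!is.logical(rec$negation) || length(rec$negation) != 1L)
    fail("negation must be a logical scalar")
  invisible(rec)
}

#' Extract the seven structured elements from a criterion
#'
#' Runs the backend's extraction task on the simplified text of a
#' criterion and validates the result against the extraction-record
#' schema.  With the default rule backend: the value constraint
#' (comparator, number, unit) is parsed by pattern rules; negation is set
#' from a cue list ("no history of", "without", "excluding", "absence
#' of", ...); the temporal constraint is parsed from the normalized
#' `≤/≥ N unit` form.  A backend output that fails the schema signals a
#' `trialsql_schema_error` and never propagates downstream.
#'
#' @param criterion One row of a criteria data.frame (simplified), or a
#'   list with at least `simplified_text`.
#' @param backend A text backend.
#' @return An [extraction_record()].
#' @examples
#' cr <- data.frame(simplified_text = "hemoglobin < 10 g/dL")
#' extract_elements(cr)$value
#' @export
extract_elements <- function(criterion, backend = backend_rules()) {
  text <- if (is.data.frame(criterion)) criterion$simplified_text[1]
          else criterion$simplified_text
  if (is.null(text) || is.na(text))
    text <- if (is.data.frame(criterion)) criterion$segmented_text[1]
            else criterion$segmented_text
  stopifnot(is.character(text), length(text) == 1L)
  out <- backend_transform(backend, "extract", list(text = text))
  rec <- extraction_record(
    clinical_terms = out$clinical_terms,
    terminology_system = out$terminology_system %||% NA_character_,
    codes = out$codes %||% character(0),
    value = out$value,
    attributes = out$attributes %||% character(0),
    temporal = out$temporal,
    negation = out$negation %||% FALSE,
    criterion_ref = if (is.data.frame(criterion))
      list(trial_id = criterion$trial_id[1], index = criterion$index[1],
           polarity = criterion$polarity[1]) else criterion$criterion_ref)
  rec
}

# ---------------------------------------------------------------------------
# whole-trial driver

#' Preprocess one trial end to end
#'
#' Runs segmentation, filtration and simplification over a trial record
#' and reports per-stage statistics: criterion count, total and mean
#' token counts, and the overall percent token reduction
#' `100 * (1 - final / initial)`.
#'
#' @param trial A list with `trial_id` and at least one of `inclusion` /
#'   `exclusion` (character vectors of criteria text blocks).
#' @param backend A text backend.
#' @return A list with `criteria` (the annotated criteria data.frame) and
#'   `stage_stats` (data.frame: stage, n_criteria, total_tokens,
#'   mean_tokens) plus `pct_token_reduction`.
#' @export
preprocess_trial <- function(trial, backend = backend_rules()) {
  if (is.null(trial$inclusion) && is.null(trial$exclusion))
    stop(structure(class = c("trialsql_input_error", "error", "condition"),
                   list(message = "trial has no criteria", call = NULL)))
  tid <- trial$trial_id %||% "trial"
  crit <- list()
  for (pol in c("inclusion", "exclusion")) {
    for (blk in trial[[pol]]) {
      if (nzchar(trimws(blk)))
        crit[[length(crit) + 1L]] <- segment_criteria(blk, tid, pol, backend)
    }
  }
  if (!length(crit))
    stop(structure(class = c("trialsql_input_error", "error", "condition"),
                   list(message = "trial has no nonempty criteria", call = NULL)))
  criteria <- do.call(rbind, crit)
  criteria$index <- seq_len(nrow(criteria))
  criteria <- filter_queryable(criteria, backend)
  criteria <- simplify_criteria(criteria, backend)

  keep <- isTRUE_v(criteria$queryable)
  stage_stats <- data.frame(
    stage = c("segmentation", "filtering", "simplification"),
    n_criteria = c(nrow(criteria), sum(keep), sum(keep)),
    total_tokens = c(sum(criteria$tokens_segmentation),
                     sum(criteria$tokens_filtering[keep]),
                     sum(criteria$tokens_simplification[keep])),
    stringsAsFactors = FALSE)
  stage_stats$mean_tokens <- ifelse(stage_stats$n_criteria > 0,
                                    stage_stats$total_tokens / stage_stats$n_criteria,
                                    0)
  list(criteria = criteria,
       stage_stats = stage_stats,
       pct_token_reduction = token_reduction_pct(
         stage_stats$total_tokens[1], stage_stats$total_tokens[3]))
}

isTRUE_v <- function(x) !is.na(x) & x

#' Percent token reduction between two stages
#'
#' `100 * (1 - final / initial)`; the headline preprocessing statistic.
#'
#' @param initial,final Token counts (scalars or equal-length vectors).
#' @return Percent reduction.
#' @examples
#' token_reduction_pct(331.4, 138.57)
#' @export
token_reduction_pct <- function(initial, final) {
  stopifnot(all(initial > 0))
  100 * (1 - final / initial)
}
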