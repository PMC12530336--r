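# Assembles OMOP-conformant cohort SQL from extraction records and
# concept mappings: one subquery per criterion on the domain's event
# table with a (optionally descendant-expanded) concept IN-list, value
# and temporal predicates, inclusion merging via INTERSECT and exclusion
# via EXCEPT or NOT IN.  The dialect is a portable ANSI subset accepted
# by the embedded SQLite engine used for execution.

.unit_days <- c(day = 1L, week = 7L, month = 30L, year = 365L)

#' Route a criterion to the inclusion or exclusion arm
#'
#' Negated inclusion criteria ("no history of X") are routed to the
#' exclusion arm: requiring the absence of X is the same cohort operation
#' as excluding patients with X.  Plain criteria keep their stated arm.
#' The ambiguous double-negative case - an *exclusion* criterion that is
#' itself negated - is flagged for manual review rather than silently
#' double-negated.
#'
#' @param record An [extraction_record()].
#' @param polarity `"inclusion"` or `"exclusion"`; defaults to the
#'   polarity recorded in `record$criterion_ref`.
#' @return A list with `placement` (`"inclusion"`, `"exclusion"` or
#'   `"manual_review"`) and a human-readable `note`.
#' @export
negation_route <- function(record, polarity = NULL) {
  polarity <- polarity %||% record$criterion_ref$polarity %||% "inclusion"
  polarity <- match.arg(polarity, c("inclusion", "exclusion"))
  if (polarity == "inclusion" && record$negation)
    list(placement = "exclusion",
         note = "negated inclusion routed to exclusion arm (absence-of-X == exclude has-X)")
  else if (polarity == "exclusion" && record$negation)
    list(placement = "manual_review",
         note = "negated exclusion criterion: double negative flagged for manual review")
  else
    list(placement = polarity, note = "direct placement")
}

render_date_predicate <- function(rule, temporal, index_date) {
  offset <- round(temporal$quantity * .unit_days[[temporal$unit]])
  cutoff <- as.Date(index_date) - offset
  comp <- temporal$comparator %||% "≤"
  # "within the last N units" (≤): event date on/after the cutoff;
  # "at least N units ago" (≥): event date on/before the cutoff
  op <- if (comp %in% c("≤", "<")) ">=" else "<="
  sprintf("%s %s '%s'", rule$date_column, op, format(cutoff, "%Y-%m-%d"))
}

render_value_predicate <- function(rule, value) {
  op <- c("<" = "<", "≤" = "<=", "=" = "=", "≥" = ">=", ">" = ">")[value$comparator]
  sprintf("%s %s %s", rule$value_column, op, format(value$number))
}

#' Build the per-criterion cohort subquery
#'
#' Renders `SELECT person_id FROM <event table> WHERE <concept column>
#' IN (<ids>)`, where the ID list is the union of all descendants of the
#' mapped concepts when `expand = TRUE` (hierarchical expansion through
#' the ancestor closure).  A value constraint from the extraction record
#' is rendered on the domain's value column (Measurement/Observation
#' only) and a temporal constraint on the date column, relative to a
#' fixed, configurable index date.  Expansion defaults ON for Condition
#' and Drug criteria - the domains where missed descendants silently
#' shrink cohorts - and OFF otherwise.
#'
#' Demographic age criteria are rendered on `person.year_of_birth` as
#' age-in-whole-years at the index date (e.g. age ≥ 18 with index year Y
#' becomes `year_of_birth <= Y - 18`).
#'
#' @param record An [extraction_record()].
#' @param concept_ids Integer vector of mapped concept IDs (all must
#'   exist in `inventory`); may be empty only for demographic criteria.
#' @param rule A [domain_to_rule()] result.
#' @param inventory A [concept_inventory()] (ground truth + hierarchy).
#' @param expand Logical; `NULL` means the domain default
#'   (Condition/Drug TRUE, otherwise FALSE).
#' @param index_date Reference date for temporal/age predicates.
#' @return A list of class `criterion_query`: `domain_id`, `concept_ids`
#'   (after expansion), `expanded`, `sql_fragment`, `constraints`.
#' @export
build_criterion_query <- function(record, concept_ids, rule, inventory,
                                  expand = NULL, index_date = "2023-12-31") {
  stopifnot(inherits(rule, "domain_rule"))
  validate_extraction_record(record)
  build_err <- function(msg)
    stop(structure(class = c("trialsql_build_error", "error", "condition"),
                   list(message = msg, call = NULL)))

  if (rule$event_table == "person") {
    if (is.null(record$value) ||
        !any(grepl("\\bage\\b", record$clinical_terms, ignore.case = TRUE)))
      build_err("demographic criteria support age constraints only")
    yr <- as.integer(format(as.Date(index_date), "%Y"))
    n <- record$value$number
    pred <- switch(record$value$comparator,
                   "≥" = sprintf("year_of_birth <= %d", yr - ceiling(n)),
                   ">" = sprintf("year_of_birth <= %d", yr - floor(n) - 1L),
                   "≤" = sprintf("year_of_birth >= %d", yr - floor(n)),
                   "<" = sprintf("year_of_birth >= %d", yr - ceiling(n) + 1L),
                   "=" = sprintf("year_of_birth = %d", yr - floor(n)))
    frag <- sprintf("SELECT person_id FROM person WHERE %s", pred)
    out <- list(domain_id = rule$domain_id, concept_ids = integer(0),
                expanded = FALSE, sql_fragment = frag,
                constraints = list(list(kind = "value", predicate = pred)))
    class(out) <- "criterion_query"
    return(out)
  }

  concept_ids <- as.integer(concept_ids)
  if (length(concept_ids) == 0L)
    build_err("empty concept set for a concept-backed criterion")
  if (!all(concept_exists(inventory, concept_ids)))
    build_err(paste0("concept_id(s) not in inventory: ",
                     paste(concept_ids[!concept_exists(inventory, concept_ids)],
                           collapse = ", ")))
  if (is.null(expand))
    expand <- rule$domain_id %in% c("Condition", "Drug")
  ids <- if (expand)
    sort(unique(unlist(lapply(concept_ids, descendants, inventory = inventory))))
  else sort(unique(concept_ids))

  constraints <- list()
  preds <- sprintf("%s IN (%s)", rule$concept_column,
                   paste(ids, collapse = ", "))
  if (!is.null(record$value)) {
    if (is.na(rule$value_column))
      build_err(paste0("value constraint on domain '", rule$domain_id,
                       "' which has no value column"))
    vp <- render_value_predicate(rule, record$value)
    preds <- c(preds, vp)
    constraints[[length(constraints) + 1L]] <- list(kind = "value", predicate = vp)
  }
  if (!is.null(record$temporal)) {
    if (is.na(rule$date_column))
      build_err("temporal constraint on a domain without a date column")
    tp <- render_date_predicate(rule, record$temporal, index_date)
    preds <- c(preds, tp)
    constraints[[length(constraints) + 1L]] <- list(kind = "temporal", predicate = tp)
  }
  frag <- sprintf("SELECT person_id FROM %s WHERE %s",
                  rule$event_table, paste(preds, collapse = " AND "))
  out <- list(domain_id = rule$domain_id, concept_ids = ids,
              expanded = expand, sql_fragment = frag,
              constraints = constraints)
  class(out) <- "criterion_query"
  out
}

fragment_of <- function(x) {
  if (inherits(x, "criterion_query")) x$sql_fragment
  else if (is.character(x)) x
  else stop("expected a criterion_query or SQL string")
}

#' Assemble a full cohort query
#'
#' Combines inclusion subqueries with `INTERSECT` and applies exclusions
#' as a set difference over the inclusion result, either with `EXCEPT`
#' or with `NOT IN` - the two modes are set-identical on any database.
#' The output is deterministic given the fragments and mode.
#'
#' @param inclusions List of `criterion_query` objects (or SQL fragment
#'   strings); at least one required.
#' @param exclusions List of `criterion_query` objects / fragments
#'   (possibly empty).
#' @param mode `"except"` or `"notin"`.
#' @param trial_id Label stored on the result.
#' @return A list of class `cohort_query`: `trial_id`, `sql_text`,
#'   `inclusion_fragments`, `exclusion_fragments`, `mode`, `build_log`.
#' @export
assemble_cohort <- function(inclusions, exclusions = list(),
                            mode = c("except", "notin"), trial_id = "trial") {
  mode <- match.arg(mode)
  if (inherits(inclusions, "criterion_query")) inclusions <- list(inclusions)
  if (inherits(exclusions, "criterion_query")) exclusions <- list(exclusions)
  if (length(inclusions) == 0L)
    stop(structure(class = c("trialsql_build_error", "error", "condition"),
                   list(message = "a cohort needs at least one inclusion criterion",
                        call = NULL)))
  inc <- vapply(inclusions, fragment_of, character(1))
  exc <- vapply(exclusions, fragment_of, character(1))
  log <- c(sprintf("%d inclusion fragment(s) merged with INTERSECT", length(inc)),
           if (length(exc))
             sprintf("%d exclusion fragment(s) applied via %s", length(exc),
                     if (mode == "except") "EXCEPT" else "NOT IN"))

  inc_block <- paste(inc, collapse = "\nINTERSECT\n")
  if (length(exc) == 0L) {
    sql <- sprintf("SELECT person_id FROM (\n%s\n) AS included", inc_block)
  } else if (mode == "except") {
    exc_block <- paste(exc, collapse = "\nUNION\n")
    sql <- sprintf(
      "SELECT person_id FROM (\n%s\n) AS included\nEXCEPT\nSELECT person_id FROM (\n%s\n) AS excluded",
      inc_block, exc_block)
  } else {
    exc_block <- paste(exc, collapse = "\nUNION\n")
    sql <- sprintf(
      "SELECT person_id FROM (\n%s\n) AS included\nWHERE person_id NOT IN (\n%s\n)",
      inc_block, exc_block)
  }
  if (!sql_parses(sql)) stop("internal error: assembled SQL failed the parse check")
  out <- list(trial_id = trial_id, inclusion_fragments = inc,
              exclusion_fragments = exc, mode = mode,
              sql_text = sql, build_log = log)
  class(out) <- "cohort_query"
  out
}

#' @export
print.cohort_query <- function(x, ...) {
  cat("<cohort_query> trial ", x$trial_id, " (", length(x$inclusion_fragments),
      " inclusion, ", length(x$exclusion_fragments), " exclusion, mode ",
      x$mode, ")\n", sep = "")
  cat(x$sql_text, "\n")
  invisible(x)
}

#' Execute cohort SQL against an in-memory CDM
#'
#' Loads the tables of a mini CDM (see [generate_mini_cdm()]) into an
#' in-memory SQLite database and runs the query.  Dates are stored as
#' ISO-8601 text, which compares correctly under SQLite's string
#' ordering.
#'
#' @param sql A `cohort_query`, `criterion_query` or SQL string.
#' @param cdm A `mini_cdm` object or a named list of data.frames.
#' @return Sorted integer vector of person IDs.
#' @export
execute_cohort <- function(sql, cdm) {
  if (inherits(sql, "cohort_query")) sql <- sql$sql_text
  if (inherits(sql, "criterion_query")) sql <- sql$sql_fragment
  tables <- if (inherits(cdm, "mini_cdm")) cdm$tables else cdm
  con <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  for (nm in names(tables)) {
    tb <- tables[[nm]]
    for (cl in names(tb)) if (inherits(tb[[cl]], "Date"))
      tb[[cl]] <- format(tb[[cl]], "%Y-%m-%d")
    DBI::dbWriteTable(con, nm, tb)
  }
  res <- DBI::dbGetQuery(con, sql)
  sort(unique(as.integer(res[[1]])))
}
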