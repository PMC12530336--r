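# package-local cache (catalog asset is read once per session)
.trialsql_env <- new.env(parent = emptyenv())

#' Load the embedded OMOP CDM v5.3 catalog
#'
#' The toolkit targets a fixed subset of the OMOP Common Data Model v5.3:
#' the person table, the seven domain event tables (condition_occurrence,
#' drug_exposure, procedure_occurrence, measurement, observation,
#' device_exposure, visit_occurrence) and the two vocabulary tables
#' (concept, concept_ancestor).  The catalog records table/column names,
#' the person-ID join key of each table, the domain -> (event table,
#' concept column, date column, value column) conventions, and the
#' expected concept domain of every `*_concept_id` column.  It is shipped
#' as a static JSON asset for reproducibility; an alternative catalog
#' (e.g. a site extension) can be supplied via `path`.
#'
#' @param path Path to a catalog JSON file. Default: the packaged v5.3 asset.
#' @return An object of class `cdm_catalog`: a list with elements
#'   `cdm_version`, `tables` (named list of character column vectors),
#'   `join_keys`, `domain_rules` and `concept_column_domains`.
#' @examples
#' cat53 <- cdm_catalog()
#' names(cat53$tables)
#' @export
cdm_catalog <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.trialsql_env$catalog)) return(.trialsql_env$catalog)
    path <- system.file("extdata", "cdm_catalog_v5_3.json", package = "trialsql")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cat <- list(
    cdm_version = raw$cdm_version,
    tables = lapply(raw$tables, as.character),
    join_keys = unlist(raw$join_keys),
    domain_rules = raw$domain_rules,
    concept_column_domains = unlist(raw$concept_column_domains)
  )
  class(cat) <- "cdm_catalog"
  # every join key must resolve to a column of its table
  for (tb in names(cat$join_keys)) {
    if (!cat$join_keys[[tb]] %in% cat$tables[[tb]])
      stop("catalog integrity: join key '", cat$join_keys[[tb]],
           "' is not a column of table '", tb, "'")
  }
  if (is.null(attr(path, "custom")) && grepl("cdm_catalog_v5_3", path))
    .trialsql_env$catalog <- cat
  cat
}

#' Resolve an OMOP domain to its event-table conventions
#'
#' Maps a domain identifier (Condition, Drug, Procedure, Measurement,
#' Observation, Device, Visit, Demographic) to the event table, concept
#' column, date column and - for value-bearing domains - the numeric value
#' column that cohort subqueries on that domain use.  Demographic criteria
#' (age, gender) map to the `person` table rather than an event table.
#'
#' @param domain_id Domain identifier, e.g. `"Condition"`.
#' @param catalog A [cdm_catalog()] object.
#' @return A list of class `domain_rule` with fields `domain_id`,
#'   `event_table`, `concept_column`, `date_column`, `value_column`.
#' @examples
#' domain_to_rule("Drug")$event_table
#' @export
domain_to_rule <- function(domain_id, catalog = cdm_catalog()) {
  stopifnot(is.character(domain_id), length(domain_id) == 1L)
  r <- catalog$domain_rules[[domain_id]]
  if (is.null(r))
    stop(structure(class = c("trialsql_unknown_domain", "error", "condition"),
                   list(message = paste0("unknown OMOP domain: '", domain_id, "'"),
                        call = sys.call(-1))))
  rule <- list(domain_id = domain_id,
               event_table = r$event_table,
               concept_column = r$concept_column,
               date_column = if (is.null(r$date_column)) NA_character_ else r$date_column,
               value_column = if (is.null(r$value_column)) NA_character_ else r$value_column)
  class(rule) <- "domain_rule"
  rule
}

#' Expected concept domain of a concept-ID column
#'
#' Returns the OMOP domain a `*_concept_id` column is expected to hold
#' (e.g. `condition_concept_id` -> Condition, `gender_concept_id` ->
#' Gender), or `NA` for concept-ID columns without a registered domain
#' (e.g. `*_type_concept_id`), which are then checked for existence only.
#'
#' @param column Column name (case-insensitive).
#' @param catalog A [cdm_catalog()] object.
#' @return Domain string or `NA_character_`.
#' @export
concept_column_domain <- function(column, catalog = cdm_catalog()) {
  d <- catalog$concept_column_domains[tolower(column)]
  if (is.na(names(d)[1] %||% NA)) return(NA_character_)
  unname(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check SQL identifiers against the CDM catalog
#'
#' Static schema validation of a query: every referenced table must exist
#' in the catalog, every referenced column must exist in (one of) the
#' referenced tables, and join `ON` equalities must use each table's
#' person-ID join key.  These are the "easily correctable syntax or schema
#' errors" class of defects (severity Minor in the audit taxonomy).
#' Matching is case-insensitive and quoted identifiers are unquoted before
#' lookup.  Derived-table aliases and SELECT output aliases are tracked so
#' that compound cohort queries validate cleanly.
#'
#' @param sql SQL text (must parse; unparseable input signals a
#'   `trialsql_parse_error` condition, distinct from a violation list).
#' @param catalog A [cdm_catalog()] object.
#' @return A data.frame with columns `kind` (`unknown_table`,
#'   `unknown_column`, `non_key_join`), `table`, `column`, `detail`,
#'   `position`; zero rows iff the query is fully schema-conformant.
#' @examples
#' validate_identifiers("SELECT person_id FROM person")
#' validate_identifiers("SELECT person_id FROM conditions_table")
#' @export
validate_identifiers <- function(sql, catalog = cdm_catalog()) {
  sc <- sql_scan(sql)                       # signals trialsql_parse_error on failure
  viol <- list()
  add <- function(kind, table, column, detail, position) {
    viol[[length(viol) + 1L]] <<- data.frame(
      kind = kind, table = table, column = column,
      detail = detail, position = position, stringsAsFactors = FALSE)
  }
  tabs <- sc$tables
  known_tables <- character(0)
  any_unknown <- FALSE
  for (i in seq_len(nrow(tabs))) {
    nm <- tolower(tabs$name[i])
    if (!nm %in% names(catalog$tables)) {
      any_unknown <- TRUE
      add("unknown_table", tabs$name[i], NA_character_,
          paste0("table '", tabs$name[i], "' not in CDM catalog"), tabs$position[i])
    } else known_tables <- c(known_tables, nm)
  }
  alias_map <- sc$alias_map                 # alias -> table (lowercased)
  derived <- sc$derived_aliases
  visible_cols <- tolower(unique(c(
    unlist(catalog$tables[known_tables], use.names = FALSE), sc$select_aliases)))
  for (i in seq_len(nrow(sc$columns))) {
    qual <- sc$columns$qualifier[i]
    col <- sc$columns$column[i]
    if (!is.na(qual)) {
      q <- tolower(qual)
      tb <- if (q %in% names(alias_map)) alias_map[[q]] else q
      if (tb %in% derived) next             # derived-table columns pass through
      if (!tb %in% names(catalog$tables)) next  # unknown table already reported
      if (!tolower(col) %in% tolower(catalog$tables[[tb]]))
        add("unknown_column", tb, col,
            paste0("unknown column '", col, "' in '", tb, "'"), sc$columns$position[i])
    } else {
      # with an unknown table in scope the visible column set is unknowable;
      # report only the table to avoid cascading column reports
      if (any_unknown) next
      if (length(known_tables) == 0L && length(derived) > 0L) next
      if (!tolower(col) %in% visible_cols)
        add("unknown_column",
            if (length(known_tables)) known_tables[1] else NA_character_, col,
            paste0("unknown column '", col, "' in referenced tables"),
            sc$columns$position[i])
    }
  }
  for (i in seq_len(nrow(sc$join_ons))) {
    lhs <- sc$join_ons[i, ]
    resolve <- function(qual) {
      q <- tolower(qual)
      if (q %in% names(alias_map)) alias_map[[q]] else q
    }
    t1 <- resolve(lhs$l_qual); t2 <- resolve(lhs$r_qual)
    ok1 <- t1 %in% names(catalog$join_keys) &&
      tolower(lhs$l_col) == tolower(catalog$join_keys[[t1]])
    ok2 <- t2 %in% names(catalog$join_keys) &&
      tolower(lhs$r_col) == tolower(catalog$join_keys[[t2]])
    if (t1 %in% names(catalog$tables) && t2 %in% names(catalog$tables) && !(ok1 && ok2))
      add("non_key_join", t1, lhs$l_col,
          paste0("join on non-key column: ", lhs$l_qual, ".", lhs$l_col,
                 " = ", lhs$r_qual, ".", lhs$r_col), lhs$position)
  }
  if (length(viol) == 0L)
    return(data.frame(kind = character(0), table = character(0),
                      column = character(0), detail = character(0),
                      position = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, viol)
}
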