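# Automated hallucination detection and classification for candidate
# cohort SQL.  Every literal compared against a *_concept_id column is a
# "site"; each site is classified into at most one of five categories,
# ordered by severity:
#   A (Critical)  nonexistent concept ID
#   B (Major)     valid concept assigned to an incompatible domain
#   C (Major)     natural language where an identifier belongs
#   D (Moderate)  placeholder value requiring manual intervention
#   E (Minor)     easily correctable syntax/schema errors
# Classification precedence is D -> C -> A -> B: a placeholder is also
# non-numeric and a natural-language string is also absent from the
# inventory, so an explicit order is required for the categories to be
# disjoint.

.category_severity <- c(A = "Critical", B = "Major", C = "Major",
                        D = "Moderate", E = "Minor")

#' Category/severity table of the hallucination taxonomy
#' @return data.frame with `category`, `severity`, `description`.
#' @export
hallucination_categories <- function() {
  data.frame(
    category = names(.category_severity),
    severity = unname(.category_severity),
    description = c("nonexistent concept ID",
                    "valid concept in incompatible domain",
                    "natural language in a concept field",
                    "placeholder value",
                    "syntax/schema error"),
    stringsAsFactors = FALSE)
}

# Placeholder pattern set (user-extensible): bracketed markers, bare "?",
# ":name" parameters, and ALL-CAPS marker words.
.default_placeholder_patterns <- c(
  "^<.*>$", "^\\{.*\\}$", "^\\?$", "^:[A-Za-z_]",
  "ID_HERE$", "PLACEHOLDER", "^INSERT_", "^TODO", "^XXX+$", "^CONCEPT_ID$")

is_placeholder_literal <- function(literal,
                                   patterns = .default_placeholder_patterns) {
  bare <- gsub("^'|'$", "", literal)
  any(vapply(patterns, function(p)
    grepl(p, literal) || grepl(p, bare), logical(1)))
}

#' Extract concept-reference sites from SQL
#'
#' Finds every literal compared against a `*_concept_id` column - in
#' `IN (...)` lists, `=`/comparison predicates and `BETWEEN` ranges -
#' and returns one site per literal, ordered by character position.
#' Literals are captured verbatim, including quoting and placeholder
#' markers.  `IN (SELECT ...)` subqueries contribute no sites.
#'
#' @param sql SQL text (must parse; a `trialsql_parse_error` condition is
#'   signalled otherwise).
#' @param catalog A [cdm_catalog()] (reserved for site/column metadata).
#' @return data.frame with `table` (qualifier if written, else `NA`),
#'   `column`, `literal`, `position`.
#' @examples
#' extract_concept_refs(
#'   "SELECT person_id FROM condition_occurrence
#'    WHERE condition_concept_id IN (201826, 4058243)")
#' @export
extract_concept_refs <- function(sql, catalog = cdm_catalog()) {
  sc <- sql_scan(sql)
  tok <- sc$tokens
  n <- nrow(tok)
  lower <- tolower(tok$text)
  literalish <- c("number", "string", "placeholder")
  sites <- list()
  add <- function(column, qualifier, literal, position)
    sites[[length(sites) + 1L]] <<- data.frame(
      table = qualifier, column = column, literal = literal,
      position = position, stringsAsFactors = FALSE)

  i <- 1L
  while (i <= n) {
    if (tok$type[i] %in% c("ident", "qident") &&
        grepl("_concept_id$", tolower(sql_unquote(tok$text[i])))) {
      col <- sql_unquote(tok$text[i])
      qual <- if (i >= 3L && tok$text[i - 1L] == "." &&
                  tok$type[i - 2L] %in% c("ident", "qident"))
        sql_unquote(tok$text[i - 2L]) else NA_character_
      j <- i + 1L
      if (j <= n && tok$type[j] == "ident" && lower[j] == "not") j <- j + 1L
      if (j <= n) {
        if (tok$type[j] == "ident" && lower[j] == "in" &&
            j + 1L <= n && tok$text[j + 1L] == "(") {
          k <- j + 2L
          if (k <= n && tok$type[k] == "ident" && lower[k] == "select") {
            i <- k; next                     # subquery: no literal sites
          }
          while (k <= n && tok$text[k] != ")") {
            if (tok$type[k] %in% literalish ||
                (tok$type[k] == "ident" && !lower[k] %in% .sql_keywords))
              add(col, qual, tok$text[k], tok$position[k])
            k <- k + 1L
          }
          i <- k
        } else if (tok$text[j] %in% c("=", "<", ">", "<=", ">=", "<>", "!=")) {
          k <- j + 1L
          if (k <= n && (tok$type[k] %in% literalish ||
                         (tok$type[k] == "ident" && !lower[k] %in% .sql_keywords)))
            add(col, qual, tok$text[k], tok$position[k])
          i <- k
        } else if (tok$type[j] == "ident" && lower[j] == "between") {
          for (k in (j + 1L):min(n, j + 3L)) {
            if (tok$type[k] %in% literalish) add(col, qual, tok$text[k], tok$position[k])
          }
          i <- j + 3L
        }
      }
    }
    i <- i + 1L
  }
  if (!length(sites))
    return(data.frame(table = character(0), column = character(0),
                      literal = character(0), position = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, sites)
  out[order(out$position), , drop = FALSE]
}

#' Classify one concept-reference site
#'
#' Applies the documented precedence: (1) placeholder pattern match gives
#' D; (2) a literal that is not an integer numeral gives C; (3) an
#' integer absent from the inventory gives A; (4) a present concept whose
#' domain is incompatible with the column's expected domain gives B;
#' (5) otherwise the site is clean and `NULL` is returned.  A quoted
#' integer (`'201826'`) is treated as a numeral - SQL engines coerce it -
#' so only genuinely non-numeric text lands in C.  Columns with no
#' registered domain (e.g. `*_type_concept_id`) get checks 1-3 only.
#'
#' @param site One row of [extract_concept_refs()] output (data.frame or
#'   list with `column`, `literal`, `position`).
#' @param inventory The [concept_inventory()] ground truth.
#' @param catalog A [cdm_catalog()] supplying the column -> domain map.
#' @param placeholder_patterns Regex vector overriding the default
#'   placeholder pattern set.
#' @return `NULL` for a clean site, else a list of class
#'   `hallucination_instance` with `site`, `category`, `severity`,
#'   `explanation`.
#' @export
classify_site <- function(site, inventory, catalog = cdm_catalog(),
                          placeholder_patterns = .default_placeholder_patterns) {
  if (is.data.frame(site)) site <- as.list(site[1, ])
  lit <- site$literal
  instance <- function(category, explanation)
    structure(list(site = site, category = category,
                   severity = unname(.category_severity[category]),
                   explanation = explanation),
              class = "hallucination_instance")

  if (is_placeholder_literal(lit, placeholder_patterns))
    return(instance("D", paste0("placeholder value ", lit,
                                " requires manual intervention")))
  bare <- gsub("^'|'$", "", lit)
  if (!grepl("^[0-9]+$", bare))
    return(instance("C", paste0("natural language in concept field: ", lit)))
  id <- as.integer(bare)
  if (!concept_exists(inventory, id))
    return(instance("A", paste0("concept_id ", id, " does not exist in the inventory")))
  expected <- concept_column_domain(site$column, catalog)
  if (!is.na(expected)) {
    actual <- concept_domain(inventory, id)
    if (!identical(actual, expected))
      return(instance("B", paste0("concept ", id, " has domain '", actual,
                                  "' but column ", site$column,
                                  " expects '", expected, "'")))
  }
  NULL
}

#' Audit one SQL query for hallucinations
#'
#' Combines the parse check, concept-site extraction and classification
#' (categories A-D), and schema validation (category E, one instance per
#' identifier violation).  Unparseable text is a generation failure: the
#' audit records `parse_ok = FALSE`, no instances, `effective = FALSE`.
#'
#' The hallucination policy controls which categories make a query count
#' as hallucinated: `"default"` counts A-D (category E is tracked as a
#' schema error, not a concept hallucination), `"strict"` counts only A
#' (nonexistent IDs - the narrow reading of "invalid concept IDs"),
#' `"broad"` counts A-E.  `effective` is `parse_ok` and not hallucinated
#' under the active policy.
#'
#' @param sql SQL text.
#' @param inventory The [concept_inventory()] to validate against.
#' @param catalog A [cdm_catalog()].
#' @param policy `"default"`, `"strict"` or `"broad"`.
#' @param placeholder_patterns Optional placeholder regex override.
#' @return A list of class `query_audit`: `sql`, `parse_ok`, `instances`
#'   (list of `hallucination_instance`), `schema_violations` (data.frame),
#'   `categories` (character vector), `hallucinated`, `effective`,
#'   `policy`.
#' @export
audit_query <- function(sql, inventory, catalog = cdm_catalog(),
                        policy = c("default", "strict", "broad"),
                        placeholder_patterns = .default_placeholder_patterns) {
  policy <- match.arg(policy)
  counted <- switch(policy, default = c("A", "B", "C", "D"),
                    strict = "A", broad = c("A", "B", "C", "D", "E"))
  parse_ok <- sql_parses(sql)
  if (!parse_ok) {
    out <- list(sql = sql, parse_ok = FALSE, instances = list(),
                schema_violations = NULL, categories = character(0),
                hallucinated = FALSE, effective = FALSE, policy = policy)
    class(out) <- "query_audit"
    return(out)
  }
  sites <- extract_concept_refs(sql, catalog)
  instances <- list()
  for (i in seq_len(nrow(sites))) {
    inst <- classify_site(sites[i, ], inventory, catalog, placeholder_patterns)
    if (!is.null(inst)) instances[[length(instances) + 1L]] <- inst
  }
  viol <- validate_identifiers(sql, catalog)
  for (i in seq_len(nrow(viol))) {
    instances[[length(instances) + 1L]] <- structure(
      list(site = list(table = viol$table[i], column = viol$column[i],
                       literal = viol$detail[i], position = viol$position[i]),
           category = "E", severity = "Minor",
           explanation = viol$detail[i]),
      class = "hallucination_instance")
  }
  cats <- vapply(instances, `[[`, character(1), "category")
  hallucinated <- any(cats %in% counted)
  out <- list(sql = sql, parse_ok = TRUE, instances = instances,
              schema_violations = viol, categories = cats,
              hallucinated = hallucinated,
              effective = !hallucinated, policy = policy)
  class(out) <- "query_audit"
  out
}

#' @export
print.query_audit <- function(x, ...) {
  cat("<query_audit> parse_ok=", x$parse_ok, " instances=",
      length(x$instances), " hallucinated=", x$hallucinated,
      " effective=", x$effective, " [policy ", x$policy, "]\n", sep = "")
  for (inst in x$instances)
    cat("  [", inst$category, "/", inst$severity, "] ", inst$explanation,
        "\n", sep = "")
  invisible(x)
}

#' Audit a batch of queries and tally categories
#'
#' Audits every query and aggregates per-site category counts and
#' percentages per group label (e.g. a model name), matching the shape
#' of per-model hallucination-distribution tables.  Counting is per
#' instance (site), not per query.
#'
#' @param queries Character vector of SQL texts.
#' @param inventory,catalog,policy As in [audit_query()].
#' @param groups Group label per query (recycled if length 1).
#' @return A list with `audits` (list of `query_audit`) and `tally`
#'   (data.frame: group, total, A, B, C, D, E, pct_A .. pct_E, plus
#'   per-group query counts `n_queries`, `n_parsed`, `n_hallucinated`,
#'   `n_effective`).
#' @export
audit_batch <- function(queries, inventory, catalog = cdm_catalog(),
                        policy = "default", groups = "all") {
  groups <- rep_len(groups, length(queries))
  audits <- lapply(queries, audit_query, inventory = inventory,
                   catalog = catalog, policy = policy)
  tall <- lapply(unique(groups), function(g) {
    sel <- audits[groups == g]
    cats <- unlist(lapply(sel, `[[`, "categories"))
    counts <- vapply(c("A", "B", "C", "D", "E"),
                     function(cc) sum(cats == cc), integer(1))
    total <- sum(counts)
    pct <- if (total > 0) 100 * counts / total else counts * 0
    cbind(data.frame(group = g, total = total, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)),
          stats::setNames(as.data.frame(as.list(pct)),
                          paste0("pct_", names(counts))),
          data.frame(n_queries = length(sel),
                     n_parsed = sum(vapply(sel, `[[`, logical(1), "parse_ok")),
                     n_hallucinated = sum(vapply(sel, `[[`, logical(1), "hallucinated")),
                     n_effective = sum(vapply(sel, `[[`, logical(1), "effective"))))
  })
  list(audits = audits, tally = do.call(rbind, tall))
}

#' Category tally from instance counts
#'
#' Formats per-category counts into the share table used for
#' per-model hallucination distributions (counts and percentages of the
#' instance total).
#'
#' @param counts Named integer vector with names among A-E.
#' @return data.frame with `category`, `n`, `pct`.
#' @examples
#' category_tally(c(A = 0, B = 12, C = 0, D = 12, E = 8))
#' @export
category_tally <- function(counts) {
  full <- stats::setNames(integer(5), c("A", "B", "C", "D", "E"))
  full[names(counts)] <- as.integer(counts)
  total <- sum(full)
  data.frame(category = names(full), n = unname(full),
             pct = if (total > 0) unname(100 * full / total) else rep(0, 5),
             stringsAsFactors = FALSE)
}
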