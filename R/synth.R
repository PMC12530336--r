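# Offline generators for everything the toolkit consumes: a
# limited-coverage concept inventory inside a larger vocabulary universe
# (the situation of claims datasets that load only a fraction of the
# standardized vocabulary - the mechanism that elicits nonexistent-ID
# references), a patient-level mini CDM for executing cohort SQL, valid
# fixture queries with seeded hallucination injection and ground-truth
# manifests, cohort pairs with a target Jaccard, and a scripted mock
# text backend.  Every generator is bit-reproducible under a fixed seed.

# Domain weights follow the empirical distribution of extracted clinical
# concepts across OMOP domains in trial eligibility criteria
# (Condition-dominated, then Drug and Procedure).
.default_domain_weights <- c(Condition = 0.495, Drug = 0.154, Procedure = 0.128,
                             Measurement = 0.096, Observation = 0.074,
                             Device = 0.030, Visit = 0.023)

.gender_concepts <- data.frame(
  concept_id = c(8507L, 8532L),
  concept_name = c("MALE", "FEMALE"),
  domain_id = "Gender", vocabulary_id = "Gender", standard_concept = "S",
  stringsAsFactors = FALSE)

#' Generate a synthetic vocabulary universe with a loadable subset
#'
#' Builds `universe_size` concepts distributed across the OMOP event
#' domains, organised as a forest of `depth`-level trees with the given
#' branching factor (parent-child pairs feed the ancestor closure), and
#' samples a "loaded" inventory of `round(universe_size *
#' loaded_fraction)` concepts - the limited-coverage situation in which
#' a query may reference a perfectly real concept that the target
#' database has never loaded.  The two standard gender concepts are
#' always present in both inventories.  Reproducible under `seed`.
#'
#' @param universe_size Number of concepts in the universe.
#' @param loaded_fraction Fraction (0, 1] loaded into the inventory.
#' @param domains Named weight vector over event domains.
#' @param depth,branching Hierarchy shape (tree depth below each root and
#'   children per node).
#' @param seed Integer seed.
#' @return A list with `universe` and `loaded`, both
#'   [concept_inventory()] objects.
#' @export
generate_vocabulary <- function(universe_size = 10000, loaded_fraction = 0.1,
                                domains = .default_domain_weights,
                                depth = 3, branching = 3, seed = 1L) {
  if (loaded_fraction <= 0 || loaded_fraction > 1)
    input_err("loaded_fraction must be in (0, 1]")
  if (universe_size < length(domains)) input_err("universe too small")
  withr::with_seed(seed, {
    n_dom <- round(universe_size * domains / sum(domains))
    n_dom[1] <- n_dom[1] + universe_size - sum(n_dom)
    ids <- sample.int(50L * universe_size, universe_size) + 100L
    dom_vec <- rep(names(n_dom), n_dom)
    concepts <- data.frame(
      concept_id = ids,
      concept_name = paste0(dom_vec, " concept ", ids),
      domain_id = dom_vec,
      vocabulary_id = ifelse(dom_vec == "Drug", "RxNorm",
                      ifelse(dom_vec == "Measurement", "LOINC", "SNOMED")),
      standard_concept = "S", stringsAsFactors = FALSE)

    # forest of complete trees per domain: ids are assigned in order, so
    # tree structure is deterministic given the multinomial split
    tree_size <- sum(branching^(0:depth))
    pairs <- list()
    for (d in names(n_dom)) {
      dom_ids <- concepts$concept_id[concepts$domain_id == d]
      i <- 1L
      while (i + 1L <= length(dom_ids)) {
        nodes <- dom_ids[i:min(length(dom_ids), i + tree_size - 1L)]
        for (k in seq_along(nodes)) {
          first_child <- (k - 1L) * branching + 2L
          if (first_child > length(nodes)) break
          kids <- nodes[first_child:min(length(nodes), first_child + branching - 1L)]
          pairs[[length(pairs) + 1L]] <-
            data.frame(ancestor_concept_id = nodes[k], descendant_concept_id = kids)
        }
        i <- i + tree_size
      }
    }
    edges <- if (length(pairs)) do.call(rbind, pairs) else
      data.frame(ancestor_concept_id = integer(0), descendant_concept_id = integer(0))

    concepts <- rbind(concepts, .gender_concepts)
    universe <- concept_inventory(concepts, edges)

    n_loaded <- round(universe_size * loaded_fraction)
    loaded_ids <- sort(sample(ids, n_loaded))
    loaded_concepts <- rbind(concepts[concepts$concept_id %in% loaded_ids, ],
                             .gender_concepts)
    keep <- edges$ancestor_concept_id %in% loaded_ids &
      edges$descendant_concept_id %in% loaded_ids
    loaded <- concept_inventory(loaded_concepts, edges[keep, , drop = FALSE])
    list(universe = universe, loaded = loaded)
  })
}

#' Generate a patient-level mini CDM
#'
#' Materializes a `person` table and the domain event tables for a set
#' of concepts: each (concept, rate) pair assigns the event to every
#' person independently with the given probability, with a random event
#' date in the configured window and, for value-bearing domains, a
#' numeric result.  The generator's own person draws are kept as a draw
#' log so that query execution can be checked against ground truth.
#' All event concept IDs come from the supplied inventory (referential
#' integrity by construction).
#'
#' @param inventory A [concept_inventory()] supplying concepts.
#' @param n_persons Number of persons.
#' @param event_rates data.frame (`concept_id`, `rate`) or `NULL` to
#'   sample `n_concepts` concepts with rates uniform in `rate_range`.
#' @param n_concepts,rate_range Used when `event_rates` is `NULL`.
#' @param seed Integer seed.
#' @param date_window Character vector of two ISO dates.
#' @return A list of class `mini_cdm`: `tables` (named list of
#'   data.frames), `draw_log` (concept_id -> person IDs drawn),
#'   `event_rates`, `seed`.
#' @export
generate_mini_cdm <- function(inventory, n_persons = 500, event_rates = NULL,
                              n_concepts = 20, rate_range = c(0.05, 0.4),
                              seed = 1L,
                              date_window = c("2018-01-01", "2020-12-31")) {
  stopifnot(inherits(inventory, "concept_inventory"), n_persons >= 1)
  event_domains <- names(.default_domain_weights)
  pool <- inventory$concepts[inventory$concepts$domain_id %in% event_domains, ]
  if (nrow(pool) == 0L) input_err("inventory has no event-domain concepts")
  withr::with_seed(seed, {
    if (is.null(event_rates)) {
      pick <- pool[sample.int(nrow(pool), min(n_concepts, nrow(pool))), ]
      event_rates <- data.frame(concept_id = pick$concept_id,
                                rate = stats::runif(nrow(pick), rate_range[1],
                                                    rate_range[2]))
    }
    if (any(event_rates$rate < 0 | event_rates$rate > 1))
      input_err("event rates must lie in [0, 1]")

    person <- data.frame(
      person_id = seq_len(n_persons),
      gender_concept_id = sample(c(8507L, 8532L), n_persons, replace = TRUE),
      year_of_birth = sample(1930:2005, n_persons, replace = TRUE),
      month_of_birth = sample(1:12, n_persons, replace = TRUE),
      day_of_birth = sample(1:28, n_persons, replace = TRUE),
      race_concept_id = 0L, ethnicity_concept_id = 0L)

    cat53 <- cdm_catalog()
    tables <- list(person = person)
    for (d in event_domains) {
      rule <- domain_to_rule(d, cat53)
      tables[[rule$event_table]] <- NULL
    }
    rows_by_table <- list()
    draw_log <- list()
    d0 <- as.Date(date_window[1]); d1 <- as.Date(date_window[2])
    for (i in seq_len(nrow(event_rates))) {
      cid <- as.integer(event_rates$concept_id[i])
      dom <- concept_domain(inventory, cid)
      if (!dom %in% event_domains) next
      rule <- domain_to_rule(dom, cat53)
      hit <- which(stats::runif(n_persons) < event_rates$rate[i])
      draw_log[[as.character(cid)]] <- hit
      if (!length(hit)) next
      ev <- data.frame(person_id = hit, concept_id = cid,
                       date = format(d0 + sample.int(as.integer(d1 - d0) + 1L,
                                                     length(hit), replace = TRUE) - 1L,
                                     "%Y-%m-%d"),
                       value = if (!is.na(rule$value_column))
                         round(stats::rnorm(length(hit), 10, 3), 2) else NA_real_)
      rows_by_table[[rule$event_table]] <-
        rbind(rows_by_table[[rule$event_table]], cbind(ev, domain = dom))
    }
    for (d in event_domains) {
      rule <- domain_to_rule(d, cat53)
      tb <- rule$event_table
      ev <- rows_by_table[[tb]]
      cols <- cat53$tables[[tb]]
      if (is.null(ev)) {
        out <- as.data.frame(stats::setNames(rep(list(integer(0)), length(cols)), cols))
      } else {
        out <- data.frame(row_id = seq_len(nrow(ev)))
        names(out) <- cols[1]
        out$person_id <- ev$person_id
        out[[rule$concept_column]] <- ev$concept_id
        out[[rule$date_column]] <- ev$date
        if (!is.na(rule$value_column)) out[[rule$value_column]] <- ev$value
        for (cl in setdiff(cols, names(out))) out[[cl]] <- NA
        out <- out[cols]
      }
      tables[[tb]] <- out
    }
    out <- list(tables = tables, draw_log = draw_log,
                event_rates = event_rates, seed = seed)
    class(out) <- "mini_cdm"
    out
  })
}

#' Persons with a given concept, straight from a mini CDM's tables
#'
#' Brute-force (non-SQL) lookup used as the oracle for SQL execution.
#'
#' @param cdm A `mini_cdm`.
#' @param concept_ids Concept IDs to match (any).
#' @param inventory Inventory used to resolve each concept's table.
#' @return Sorted integer person IDs.
#' @export
persons_with_concept <- function(cdm, concept_ids, inventory) {
  cat53 <- cdm_catalog()
  hits <- integer(0)
  for (cid in as.integer(concept_ids)) {
    dom <- concept_domain(inventory, cid)
    rule <- domain_to_rule(dom, cat53)
    tb <- cdm$tables[[rule$event_table]]
    hits <- c(hits, tb$person_id[tb[[rule$concept_column]] == cid])
  }
  sort(unique(hits))
}

#' Generate audit-clean fixture cohort queries
#'
#' Builds `n` single-criterion cohort queries over random loaded
#' concepts (1-3 IDs of one event domain each, no descendant expansion
#' so the literal sites are exactly the chosen IDs).  By construction
#' every query parses, is schema-conformant, and references only
#' existing, domain-correct concept IDs - the valid baseline that
#' [inject_errors()] perturbs.
#'
#' @param inventory The loaded [concept_inventory()].
#' @param n Number of queries.
#' @param seed Integer seed.
#' @return Character vector of SQL texts.
#' @export
generate_valid_queries <- function(inventory, n = 50, seed = 1L) {
  event_domains <- names(.default_domain_weights)
  pool <- inventory$concepts[inventory$concepts$domain_id %in% event_domains, ]
  if (nrow(pool) == 0L) input_err("inventory has no event-domain concepts")
  cat53 <- cdm_catalog()
  withr::with_seed(seed, {
    vapply(seq_len(n), function(i) {
      dom <- .draw(unique(pool$domain_id))
      dom_ids <- pool$concept_id[pool$domain_id == dom]
      ids <- .draw(dom_ids, min(sample(1:3, 1L), length(dom_ids)))
      rec <- extraction_record(clinical_terms = paste(dom, "criterion", i))
      q <- build_criterion_query(rec, ids, domain_to_rule(dom, cat53),
                                 inventory, expand = FALSE)
      assemble_cohort(list(q), trial_id = paste0("fixture_", i))$sql_text
    }, character(1))
  })
}

.placeholder_pool <- c("<INSERT_CONCEPT_ID>", "{concept_id}", "?",
                       ":concept_id", "CONCEPT_ID_HERE")

# size-safe single/multi draw (sample() treats a length-1 numeric as 1:n)
.draw <- function(x, k = 1L) x[sample.int(length(x), k)]

#' Inject labelled hallucinations into valid queries
#'
#' Perturbs audit-clean queries site by site with the given per-category
#' probabilities and records every edit in a ground-truth manifest:
#' A swaps a concept ID for one in the universe but not the loaded
#' inventory (or a fabricated ID if that set is empty); B swaps in a
#' loaded ID of a different domain; C substitutes a concept's name as a
#' quoted string; D substitutes a placeholder token; E corrupts the
#' event-table name (at most one E per query).  At most one injection
#' is applied per site, so the manifest <-> audit comparison is exact.
#'
#' @param valid_queries Character vector of audit-clean SQL (see
#'   [generate_valid_queries()]).
#' @param profile Named probabilities for categories A-E (missing = 0;
#'   site-level sum of A-D must be <= 1).
#' @param universe,loaded The paired inventories from
#'   [generate_vocabulary()].
#' @param seed Integer seed.
#' @param catalog A [cdm_catalog()].
#' @return A list with `queries` (modified SQL) and `manifest`
#'   (data.frame: query_id, site_index, position, category).
#' @export
inject_errors <- function(valid_queries, profile, universe, loaded, seed = 1L,
                          catalog = cdm_catalog()) {
  pr <- stats::setNames(numeric(5), c("A", "B", "C", "D", "E"))
  pr[names(profile)] <- profile
  if (any(pr < 0) || sum(pr[c("A", "B", "C", "D")]) > 1)
    input_err("invalid injection profile: site-level probability mass > 1")
  not_loaded <- setdiff(universe$concepts$concept_id, loaded$concepts$concept_id)
  manifest <- list()
  queries <- valid_queries
  withr::with_seed(seed, {
    for (qi in seq_along(queries)) {
      sql <- queries[qi]
      sites <- extract_concept_refs(sql, catalog)
      edits <- list()
      for (si in seq_len(nrow(sites))) {
        u <- stats::runif(1)
        cum <- cumsum(pr[c("A", "B", "C", "D")])
        cat_pick <- names(cum)[u < cum][1]
        if (is.na(cat_pick)) next
        col_dom <- concept_column_domain(sites$column[si], catalog)
        repl <- switch(cat_pick,
          A = as.character(if (length(not_loaded)) .draw(not_loaded)
                           else max(universe$concepts$concept_id) + qi * 97L + si),
          B = {
            other <- loaded$concepts$concept_id[
              loaded$concepts$domain_id != col_dom &
              loaded$concepts$domain_id %in% names(.default_domain_weights)]
            if (!length(other)) next
            as.character(.draw(other))
          },
          C = paste0("'", sub("'", "", .draw(loaded$concepts$concept_name)),
                     "'"),
          D = .draw(.placeholder_pool))
        edits[[length(edits) + 1L]] <- list(
          pos = sites$position[si], len = nchar(sites$literal[si]),
          repl = repl, site_index = si, category = cat_pick)
      }
      # apply right-to-left so recorded positions stay valid
      if (length(edits)) {
        ord <- order(vapply(edits, `[[`, numeric(1), "pos"), decreasing = TRUE)
        for (e in edits[ord]) {
          sql <- paste0(substr(sql, 1L, e$pos - 1L), e$repl,
                        substr(sql, e$pos + e$len, nchar(sql)))
        }
        for (e in edits) {
          manifest[[length(manifest) + 1L]] <- data.frame(
            query_id = qi, site_index = e$site_index, position = e$pos,
            category = e$category, stringsAsFactors = FALSE)
        }
      }
      if (stats::runif(1) < pr[["E"]]) {
        sc <- sql_scan(sql)
        tabs <- sc$tables[tolower(sc$tables$name) %in% names(catalog$tables), ,
                          drop = FALSE]
        tabs <- tabs[tolower(tabs$name) != "person", , drop = FALSE]
        if (nrow(tabs)) {
          t1 <- tabs[1, ]
          bad <- paste0(t1$name, "_tbl")
          sql <- paste0(substr(sql, 1L, t1$position - 1L), bad,
                        substr(sql, t1$position + nchar(t1$name), nchar(sql)))
          manifest[[length(manifest) + 1L]] <- data.frame(
            query_id = qi, site_index = NA_integer_, position = t1$position,
            category = "E", stringsAsFactors = FALSE)
        }
      }
      queries[qi] <- sql
    }
  })
  manifest <- if (length(manifest)) do.call(rbind, manifest) else
    data.frame(query_id = integer(0), site_index = integer(0),
               position = integer(0), category = character(0),
               stringsAsFactors = FALSE)
  list(queries = queries, manifest = manifest)
}

#' Generate a pair of patient-ID sets with a target Jaccard index
#'
#' Chooses the intersection size whose Jaccard
#' `i / (n_a + n_b - i)` is closest to the target; if no integer
#' intersection comes within ±0.01 a feasibility error reporting the
#' nearest achievable value is raised.  IDs are drawn reproducibly under
#' the seed.
#'
#' @param n_a,n_b Set sizes.
#' @param target_jaccard Desired Jaccard index in `[0, 1]`.
#' @param seed Integer seed.
#' @param tolerance Acceptable |achieved - target| (default 0.01).
#' @return A list with `set_a`, `set_b`, `achieved_jaccard`.
#' @export
generate_cohort_pair <- function(n_a, n_b, target_jaccard, seed = 1L,
                                 tolerance = 0.01) {
  stopifnot(n_a >= 1, n_b >= 1, target_jaccard >= 0, target_jaccard <= 1)
  i_cand <- 0:min(n_a, n_b)
  j_cand <- i_cand / (n_a + n_b - i_cand)
  best <- which.min(abs(j_cand - target_jaccard))
  if (abs(j_cand[best] - target_jaccard) > tolerance)
    stop(structure(class = c("trialsql_feasibility_error", "error", "condition"),
                   list(message = sprintf(
                     "target jaccard %.3f infeasible for sizes (%d, %d); nearest achievable: %.4f",
                     target_jaccard, n_a, n_b, j_cand[best]), call = NULL)))
  i <- i_cand[best]
  withr::with_seed(seed, {
    ids <- sample.int(10L * (n_a + n_b) + 100L, n_a + n_b - i)
    common <- ids[seq_len(i)]
    rest <- if (i > 0L) ids[-seq_len(i)] else ids
    set_a <- c(common, rest[seq_len(n_a - i)])
    set_b <- c(common, rest[seq.int(n_a - i + 1L, length.out = n_b - i)])
    list(set_a = set_a, set_b = set_b, achieved_jaccard = j_cand[best])
  })
}

#' Scripted mock text backend
#'
#' A deterministic backend whose `transform` answers only inputs present
#' in its script: a named list mapping `"<task>::<canonical input JSON>"`
#' to the structured output to return.  An unscripted input raises a
#' `trialsql_scripted_miss` error - never a silent fallthrough - so
#' fixture drift is caught immediately.  Use [backend_script_key()] to
#' build keys.
#'
#' @param script Named list of outputs keyed by [backend_script_key()].
#' @return A backend object (class `trialsql_backend`).
#' @export
mock_backend <- function(script) {
  stopifnot(is.list(script), !is.null(names(script)))
  structure(list(
    name = "mock",
    deterministic = TRUE,
    transform = function(task, input) {
      key <- backend_script_key(task, input)
      if (!key %in% names(script))
        stop(structure(class = c("trialsql_scripted_miss", "error", "condition"),
                       list(message = paste0("mock backend has no script for: ", key),
                            call = NULL)))
      script[[key]]
    }),
    class = "trialsql_backend")
}

#' @rdname mock_backend
#' @param task Task tag (`"segment"`, `"filter"`, `"simplify"`,
#'   `"extract"`).
#' @param input Structured input list.
#' @export
backend_script_key <- function(task, input) {
  paste0(task, "::", jsonlite::toJSON(input, auto_unbox = TRUE, digits = NA))
}
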