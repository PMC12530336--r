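# Concept inventory: the queryable slice of the standardized vocabulary
# that generated SQL is validated against, plus the ancestor closure used
# for hierarchical concept-set expansion and a string-similarity baseline
# mapper in the style of OHDSI's USAGI.

#' Construct a concept inventory
#'
#' An inventory holds a set of standardized-vocabulary concepts and the
#' hierarchy among them.  The ancestor relation is closed at construction
#' time: reflexive pairs (every concept is its own zero-level ancestor,
#' the OMOP convention) are added if absent and the transitive closure of
#' the supplied pairs is computed, so that [descendants()] is a pure
#' lookup afterwards.
#'
#' @param concepts data.frame with columns `concept_id` (unique positive
#'   integers), `concept_name`, `domain_id`, `vocabulary_id`,
#'   `standard_concept` (`"S"`/`""` or logical).
#' @param ancestor_pairs data.frame with columns `ancestor_concept_id`,
#'   `descendant_concept_id`; both endpoints must exist in `concepts`.
#' @return An object of class `concept_inventory`.
#' @export
concept_inventory <- function(concepts,
                              ancestor_pairs = data.frame(
                                ancestor_concept_id = integer(0),
                                descendant_concept_id = integer(0))) {
  req <- c("concept_id", "concept_name", "domain_id", "vocabulary_id",
           "standard_concept")
  miss <- setdiff(req, names(concepts))
  if (length(miss))
    stop(structure(class = c("trialsql_format_error", "error", "condition"),
                   list(message = paste0("concept table missing required column(s): ",
                                         paste(miss, collapse = ", ")), call = NULL)))
  concepts <- as.data.frame(concepts)[req]
  concepts$concept_id <- as.integer(concepts$concept_id)
  for (cl in c("concept_name", "domain_id", "vocabulary_id"))
    concepts[[cl]] <- as.character(concepts[[cl]])
  if (anyDuplicated(concepts$concept_id))
    stop(structure(class = c("trialsql_integrity_error", "error", "condition"),
                   list(message = "duplicate concept_id in concept table", call = NULL)))
  if (any(is.na(concepts$concept_id)) || any(concepts$concept_id <= 0L))
    stop("concept_id must be a positive integer")
  if (is.logical(concepts$standard_concept))
    concepts$standard_concept <- ifelse(concepts$standard_concept, "S", "")

  anc <- as.integer(ancestor_pairs$ancestor_concept_id)
  des <- as.integer(ancestor_pairs$descendant_concept_id)
  ids <- concepts$concept_id
  if (length(anc) && !all(c(anc, des) %in% ids))
    stop(structure(class = c("trialsql_integrity_error", "error", "condition"),
                   list(message = "ancestor pair endpoint not present in concept table",
                        call = NULL)))

  # transitive closure via reachability on the (sparse, forest-like) DAG
  desc_map <- as.list(setNames(as.list(ids), as.character(ids)))
  edges <- unique(data.frame(anc = anc, des = des)[anc != des, , drop = FALSE])
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges$anc), to = as.character(edges$des)),
      directed = TRUE, vertices = data.frame(name = as.character(ids)))
    reach <- igraph::ego(g, order = igraph::vcount(g), mode = "out")
    nm <- igraph::V(g)$name
    for (k in seq_along(nm))
      desc_map[[nm[k]]] <- sort(as.integer(names(reach[[k]])))
  }
  closure_n <- sum(lengths(desc_map))
  inv <- list(concepts = concepts, desc_map = desc_map, n_pairs = closure_n)
  class(inv) <- "concept_inventory"
  inv
}

#' @export
print.concept_inventory <- function(x, ...) {
  cat("<concept_inventory> ", nrow(x$concepts), " concepts, ",
      x$n_pairs, " closed ancestor pairs\n", sep = "")
  print(utils::head(table(x$concepts$domain_id)))
  invisible(x)
}

#' Load an inventory from OMOP-format CONCEPT / CONCEPT_ANCESTOR files
#'
#' Reads two delimited files (tab or comma separated, header row required)
#' following the OMOP vocabulary layout and builds a closed inventory.
#' Extra columns are ignored; missing required columns raise a format
#' error naming the column; duplicated `concept_id` raises an integrity
#' error.
#'
#' @param concept_file Path to a CONCEPT table (needs `concept_id`,
#'   `concept_name`, `domain_id`, `vocabulary_id`, `standard_concept`).
#' @param ancestor_file Optional path to a CONCEPT_ANCESTOR table (needs
#'   `ancestor_concept_id`, `descendant_concept_id`); `NULL` for none.
#' @return A [concept_inventory()].
#' @export
load_inventory <- function(concept_file, ancestor_file = NULL) {
  con <- data.table::fread(concept_file, sep = "auto", header = TRUE,
                           data.table = FALSE)
  if (is.null(ancestor_file)) {
    anc <- data.frame(ancestor_concept_id = integer(0),
                      descendant_concept_id = integer(0))
  } else {
    anc <- data.table::fread(ancestor_file, sep = "auto", header = TRUE,
                             data.table = FALSE)
    miss <- setdiff(c("ancestor_concept_id", "descendant_concept_id"), names(anc))
    if (length(miss))
      stop(structure(class = c("trialsql_format_error", "error", "condition"),
                     list(message = paste0("ancestor table missing required column(s): ",
                                           paste(miss, collapse = ", ")), call = NULL)))
  }
  concept_inventory(con, anc)
}

#' Write an inventory back to OMOP-format delimited files
#'
#' Serializes the concept table and the *closed* ancestor-pair relation
#' (reflexive pairs included) as tab-delimited files, so that
#' load -> write -> load round-trips to an identical inventory.
#'
#' @param inventory A [concept_inventory()].
#' @param concept_file,ancestor_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_inventory <- function(inventory, concept_file, ancestor_file) {
  stopifnot(inherits(inventory, "concept_inventory"))
  con <- inventory$concepts[order(inventory$concepts$concept_id), ]
  data.table::fwrite(con, concept_file, sep = "\t")
  pairs <- inventory_pairs(inventory)
  data.table::fwrite(pairs, ancestor_file, sep = "\t")
  invisible(c(concept_file, ancestor_file))
}

#' All (ancestor, descendant) pairs of the closed hierarchy
#' @param inventory A [concept_inventory()].
#' @return data.frame with `ancestor_concept_id`, `descendant_concept_id`.
#' @export
inventory_pairs <- function(inventory) {
  a <- rep(as.integer(names(inventory$desc_map)), lengths(inventory$desc_map))
  d <- unlist(inventory$desc_map, use.names = FALSE)
  out <- data.frame(ancestor_concept_id = a, descendant_concept_id = d)
  out[order(out$ancestor_concept_id, out$descendant_concept_id), ]
}

#' Is a concept ID present in the inventory?
#'
#' Set membership against the loaded inventory; a reference to an absent
#' ID in generated SQL is the critical (category A) hallucination.
#'
#' @param inventory A [concept_inventory()].
#' @param concept_id Integer vector of IDs.
#' @return Logical vector.
#' @export
concept_exists <- function(inventory, concept_id) {
  as.integer(concept_id) %in% inventory$concepts$concept_id
}

#' Look up a concept's domain
#' @param inventory A [concept_inventory()].
#' @param concept_id Single concept ID (must exist).
#' @return The concept's `domain_id`.
#' @export
concept_domain <- function(inventory, concept_id) {
  i <- match(as.integer(concept_id), inventory$concepts$concept_id)
  if (anyNA(i)) stop_unknown_concept(concept_id[is.na(i)][1])
  inventory$concepts$domain_id[i]
}

stop_unknown_concept <- function(id) {
  stop(structure(class = c("trialsql_unknown_concept", "error", "condition"),
                 list(message = paste0("unknown concept_id: ", id), call = NULL)))
}

#' Descendants of a concept (self included)
#'
#' Returns every descendant of `concept_id` in the closed hierarchy,
#' including the concept itself (zero-level pair).  This is the expansion
#' the SQL builder applies through the concept_ancestor table when a
#' criterion should cover a whole concept subtree.
#'
#' @param inventory A [concept_inventory()].
#' @param concept_id Single concept ID (must exist).
#' @return Sorted integer vector of descendant concept IDs.
#' @export
descendants <- function(inventory, concept_id) {
  concept_id <- as.integer(concept_id)
  if (!concept_exists(inventory, concept_id)) stop_unknown_concept(concept_id)
  inventory$desc_map[[as.character(concept_id)]]
}

#' Normalize a clinical term for string matching
#'
#' Lowercases, replaces punctuation with spaces, collapses runs of
#' whitespace and trims.  Both sides of every comparison in
#' [baseline_map()] go through this normalization.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_term <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:punct:]]", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

#' String-similarity baseline concept mapper
#'
#' Maps a free-text clinical term to inventory concepts by normalized
#' Levenshtein similarity, in the style of OHDSI's USAGI (string
#' normalization + edit-distance scoring; no claim of bit-compatibility
#' with USAGI, whose internals are not public in detail).  The score is
#' `1 - editdistance(norm(term), norm(name)) / max(nchar(norm(term)),
#' nchar(norm(name)))`, so identical normalized strings score 1.  Ties
#' are broken deterministically by lower `concept_id`.
#'
#' @param term Nonempty query term.
#' @param inventory A [concept_inventory()].
#' @param top_k Number of candidates to return.
#' @return data.frame with columns `query_term`, `concept_id`,
#'   `concept_name`, `score`, `rank`.
#' @examples
#' inv <- concept_inventory(data.frame(
#'   concept_id = 1:2,
#'   concept_name = c("Type 1 diabetes mellitus", "Type 2 diabetes mellitus"),
#'   domain_id = "Condition", vocabulary_id = "SNOMED", standard_concept = "S"))
#' baseline_map("type 2 diabetes mellitus", inv, top_k = 1)
#' @export
baseline_map <- function(term, inventory, top_k = 5L) {
  if (!is.character(term) || length(term) != 1L || !nzchar(trimws(term)))
    stop(structure(class = c("trialsql_input_error", "error", "condition"),
                   list(message = "term must be a nonempty string", call = NULL)))
  q <- normalize_term(term)
  names_n <- normalize_term(inventory$concepts$concept_name)
  d <- as.integer(utils::adist(q, names_n)[1, ])
  denom <- pmax(nchar(q), nchar(names_n))
  score <- ifelse(denom == 0L, 1, 1 - d / denom)
  ord <- order(-score, inventory$concepts$concept_id)
  k <- min(top_k, length(ord))
  sel <- ord[seq_len(k)]
  data.frame(query_term = term,
             concept_id = inventory$concepts$concept_id[sel],
             concept_name = inventory$concepts$concept_name[sel],
             score = score[sel],
             rank = seq_len(k),
             stringsAsFactors = FALSE)
}
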