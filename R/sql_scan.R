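# Lightweight scanner for the ANSI SQL subset the builder emits and the
# audit inspects.  Not a general SQL parser: it tokenizes, checks basic
# well-formedness (balanced parentheses/quotes, SELECT/WITH head, FROM
# present), and recovers the structure the toolkit needs - referenced
# tables and aliases, column references, SELECT outputs, JOIN..ON
# equalities, and literal positions.  Placeholder markers (<ID>, {id},
# ?, :name) are kept as single verbatim tokens so the audit can see them.

.sql_keywords <- c(
  "select", "from", "where", "and", "or", "not", "in", "between", "as",
  "on", "join", "inner", "left", "right", "full", "outer", "cross",
  "intersect", "except", "union", "all", "distinct", "group", "by",
  "order", "having", "limit", "case", "when", "then", "else", "end",
  "null", "is", "like", "exists", "asc", "desc", "with")

stop_parse <- function(msg) {
  stop(structure(class = c("trialsql_parse_error", "error", "condition"),
                 list(message = paste0("SQL parse failure: ", msg), call = NULL)))
}

sql_unquote <- function(x) gsub('^"|"$', "", x)

sql_tokenize <- function(sql) {
  pat <- paste0(
    "'(?:[^']|'')*'",                # string literal ('' escape)
    "|\"[^\"]*\"",                   # quoted identifier
    "|<[A-Za-z_][A-Za-z0-9_]*>",     # angle-bracket placeholder
    "|\\{[^{}]*\\}",                 # curly-brace placeholder
    "|:[A-Za-z_][A-Za-z0-9_]*",      # named parameter
    "|<=|>=|<>|!=",
    "|[0-9]+(?:\\.[0-9]+)?",
    "|[A-Za-z_][A-Za-z0-9_]*",
    "|[(),;=<>.*+?/-]")
  m <- gregexpr(pat, sql, perl = TRUE)[[1]]
  if (m[1] == -1L) stop_parse("no tokens found")
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  texts <- substring(sql, starts, starts + lens - 1L)
  covered <- rep(FALSE, nchar(sql))
  for (i in seq_along(starts))
    covered[seq.int(starts[i], length.out = lens[i])] <- TRUE
  chars <- strsplit(sql, "")[[1]]
  bad <- which(!covered & !grepl("[[:space:]]", chars))
  if (length(bad))
    stop_parse(paste0("unexpected character '", chars[bad[1]],
                      "' at position ", bad[1]))
  first <- substr(texts, 1L, 1L)
  type <- ifelse(first == "'", "string",
          ifelse(first == '"', "qident",
          ifelse(texts == "?" | first %in% c("{", ":") |
                   (first == "<" & nchar(texts) > 2L), "placeholder",
          ifelse(grepl("^[0-9]", texts), "number",
          ifelse(grepl("^[A-Za-z_]", texts), "ident", "punct")))))
  data.frame(text = texts, type = type, position = starts,
             stringsAsFactors = FALSE)
}

#' Scan a SQL statement into its structural parts
#'
#' Tokenizes `sql` and recovers referenced tables, alias bindings,
#' column references, SELECT output names and JOIN `ON` equalities.
#' Malformed input (unbalanced parentheses or quotes, a statement not
#' headed by SELECT/WITH, missing FROM, characters outside the accepted
#' lexicon) signals a condition of class `trialsql_parse_error`; callers
#' that treat unparseable text as a generation failure catch that class.
#'
#' @param sql A single SQL statement.
#' @return A list with elements `tokens`, `tables`, `alias_map`,
#'   `derived_aliases`, `columns`, `select_outputs`, `join_ons`.
#' @keywords internal
#' @export
sql_scan <- function(sql) {
  if (!is.character(sql) || length(sql) != 1L || is.na(sql) ||
      !nzchar(trimws(sql)))
    stop_parse("empty input")
  tok <- sql_tokenize(sql)
  n <- nrow(tok)

  depth <- 0L
  for (t in tok$text) {
    if (t == "(") depth <- depth + 1L
    else if (t == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_parse("unbalanced parentheses")
    }
  }
  if (depth != 0L) stop_parse("unbalanced parentheses")
  first_ident <- tok$text[tok$type == "ident"][1]
  if (is.na(first_ident) || !tolower(first_ident) %in% c("select", "with"))
    stop_parse("statement must begin with SELECT or WITH")
  if (!any(tok$type == "ident" & tolower(tok$text) == "from"))
    stop_parse("no FROM clause")

  is_kw <- tok$type == "ident" & tolower(tok$text) %in% .sql_keywords
  role <- rep("", n)
  lower <- tolower(tok$text)

  tables <- list(); alias_map <- list(); derived <- character(0)
  nameish <- function(j) tok$type[j] %in% c("ident", "qident") &&
    !tolower(sql_unquote(tok$text[j])) %in% .sql_keywords

  # matching-paren map (needed to find a derived table's alias while still
  # descending into the subquery so inner FROM clauses are scanned too)
  match_close <- integer(n)
  stack <- integer(0)
  for (k in seq_len(n)) {
    if (tok$text[k] == "(") stack <- c(stack, k)
    else if (tok$text[k] == ")") {
      match_close[stack[length(stack)]] <- k
      stack <- stack[-length(stack)]
    }
  }

  i <- 1L
  while (i <= n) {
    if (tok$type[i] == "ident" && lower[i] %in% c("from", "join")) {
      j <- i + 1L
      if (j <= n && tok$text[j] == "(") {
        jj <- match_close[j] + 1L
        if (jj <= n && tok$type[jj] == "ident" && lower[jj] == "as") jj <- jj + 1L
        if (jj <= n && nameish(jj)) {
          derived <- c(derived, tolower(sql_unquote(tok$text[jj])))
          role[jj] <- "alias"
        }
        i <- j + 1L     # descend into the subquery
        next
      }
      repeat {
        if (j > n) break
        if (nameish(j)) {
          nm <- sql_unquote(tok$text[j])
          tables[[length(tables) + 1L]] <-
            data.frame(name = nm, position = tok$position[j],
                       stringsAsFactors = FALSE)
          role[j] <- "table"
          alias_map[[tolower(nm)]] <- tolower(nm)
          j <- j + 1L
          if (j <= n && tok$type[j] == "ident" && lower[j] == "as") j <- j + 1L
          if (j <= n && nameish(j) && !(j < n && tok$text[j + 1L] == ".")) {
            alias_map[[tolower(sql_unquote(tok$text[j]))]] <- tolower(nm)
            role[j] <- "alias"; j <- j + 1L
          }
        } else break
        if (j <= n && tok$text[j] == ",") j <- j + 1L else break
      }
      i <- j
    } else i <- i + 1L
  }

  # function names: identifier immediately followed by "("
  for (k in seq_len(n - 1L)) {
    if (tok$type[k] == "ident" && !is_kw[k] && role[k] == "" &&
        tok$text[k + 1L] == "(")
      role[k] <- "func"
  }

  # SELECT list outputs (bare columns or AS aliases feeding the outer scope)
  select_outputs <- character(0)
  select_aliases <- character(0)
  sel_idx <- which(tok$type == "ident" & lower == "select")
  for (s in sel_idx) {
    d <- 0L; k <- s + 1L
    while (k <= n) {
      t <- tok$text[k]
      if (t == "(") d <- d + 1L
      else if (t == ")") { if (d == 0L) break; d <- d - 1L }
      else if (d == 0L && tok$type[k] == "ident" && lower[k] == "from") break
      else if (d == 0L && tok$type[k] %in% c("ident", "qident") && !is_kw[k]) {
        nxt_dot <- k < n && tok$text[k + 1L] == "."
        prev_dot <- k > 1L && tok$text[k - 1L] == "."
        if (!nxt_dot)   # qualified ref contributes its column part only
          select_outputs <- c(select_outputs, sql_unquote(tok$text[k]))
        if (k > 1L && tok$type[k - 1L] == "ident" && lower[k - 1L] == "as" &&
            !prev_dot) {
          role[k] <- "alias"
          select_aliases <- c(select_aliases, sql_unquote(tok$text[k]))
        }
      }
      k <- k + 1L
    }
  }

  # IN (...) value lists hold literals, not column references; bare-word
  # placeholders there must not be mistaken for columns
  in_list <- logical(n)
  for (k in which(tok$type == "ident" & lower == "in")) {
    if (k < n && tok$text[k + 1L] == "(") {
      inside <- k + 2L
      if (inside <= n && !(tok$type[inside] == "ident" && lower[inside] == "select"))
        in_list[seq.int(k + 2L, max(k + 2L, match_close[k + 1L] - 1L))] <- TRUE
    }
  }

  # column references
  cols <- list()
  k <- 1L
  while (k <= n) {
    if (in_list[k]) { k <- k + 1L; next }
    if (tok$type[k] %in% c("ident", "qident") && role[k] == "" && !is_kw[k]) {
      if (k > 1L && tok$text[k - 1L] == ".") { k <- k + 1L; next }
      if (k + 1L <= n && tok$text[k + 1L] == "." && k + 2L <= n &&
          tok$type[k + 2L] %in% c("ident", "qident")) {
        cols[[length(cols) + 1L]] <- data.frame(
          qualifier = sql_unquote(tok$text[k]),
          column = sql_unquote(tok$text[k + 2L]),
          position = tok$position[k + 2L], stringsAsFactors = FALSE)
        k <- k + 3L; next
      }
      if (k > 1L && tok$type[k - 1L] == "ident" && lower[k - 1L] == "as") {
        role[k] <- "alias"; k <- k + 1L; next
      }
      cols[[length(cols) + 1L]] <- data.frame(
        qualifier = NA_character_, column = sql_unquote(tok$text[k]),
        position = tok$position[k], stringsAsFactors = FALSE)
    }
    k <- k + 1L
  }

  # JOIN ... ON a.x = b.y equalities
  join_ons <- list()
  on_idx <- which(tok$type == "ident" & lower == "on")
  for (o in on_idx) {
    if (o + 7L <= n &&
        tok$type[o + 1L] %in% c("ident", "qident") && tok$text[o + 2L] == "." &&
        tok$type[o + 3L] %in% c("ident", "qident") && tok$text[o + 4L] == "=" &&
        tok$type[o + 5L] %in% c("ident", "qident") && tok$text[o + 6L] == "." &&
        tok$type[o + 7L] %in% c("ident", "qident")) {
      join_ons[[length(join_ons) + 1L]] <- data.frame(
        l_qual = sql_unquote(tok$text[o + 1L]), l_col = sql_unquote(tok$text[o + 3L]),
        r_qual = sql_unquote(tok$text[o + 5L]), r_col = sql_unquote(tok$text[o + 7L]),
        position = tok$position[o], stringsAsFactors = FALSE)
    }
  }

  empty_cols <- data.frame(qualifier = character(0), column = character(0),
                           position = integer(0), stringsAsFactors = FALSE)
  list(
    tokens = tok,
    tables = if (length(tables)) do.call(rbind, tables) else
      data.frame(name = character(0), position = integer(0),
                 stringsAsFactors = FALSE),
    alias_map = alias_map,
    derived_aliases = unique(derived),
    columns = if (length(cols)) do.call(rbind, cols) else empty_cols,
    select_outputs = unique(select_outputs),
    select_aliases = unique(select_aliases),
    join_ons = if (length(join_ons)) do.call(rbind, join_ons) else
      data.frame(l_qual = character(0), l_col = character(0),
                 r_qual = character(0), r_col = character(0),
                 position = integer(0), stringsAsFactors = FALSE))
}

#' Does a SQL statement pass the structural parse check?
#'
#' @param sql SQL text.
#' @return `TRUE` if [sql_scan()] accepts the statement, else `FALSE`.
#' @export
sql_parses <- function(sql) {
  tryCatch({ sql_scan(sql); TRUE },
           trialsql_parse_error = function(e) FALSE)
}
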