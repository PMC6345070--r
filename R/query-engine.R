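#' @title Boolean query language
#' @description One query syntax for all portals: case-insensitive terms,
#'   quoted exact phrases, uppercase `AND`/`OR`/`NOT` operators and parentheses
#'   for priority. Example:
#'   `(morphology OR "neuromorpho.org") AND "neuronal reconstruction"`.
#' @name query-engine
NULL

query_node <- function(kind, text = NULL, children = NULL) {
  structure(list(kind = kind, text = text, children = children), class = "query_ast")
}

#' @export
print.query_ast <- function(x, ...) {
  cat(deparse_ast(x), "\n")
  invisible(x)
}

deparse_ast <- function(node, depth = 0) {
  pad <- strrep("  ", depth)
  switch(node$kind,
    TERM = paste0(pad, "TERM ", node$text),
    PHRASE = paste0(pad, "PHRASE \"", node$text, "\""),
    NOT = paste0(pad, "NOT\n", deparse_ast(node$children[[1]], depth + 1)),
    paste0(pad, node$kind, "\n",
           paste(vapply(node$children, deparse_ast, "", depth = depth + 1),
                 collapse = "\n")))
}

parse_error <- function(msg, pos) {
  stop(structure(class = c("litscout_parse_error", "error", "condition"),
                 list(message = sprintf("query parse error at position %d: %s", pos, msg),
                      call = NULL, position = pos)))
}

# Tokens: LPAREN, RPAREN, AND, OR, NOT, TERM, PHRASE — each with its start
# position in the original string (1-based) for error reporting.
tokenize_query <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  tokens <- list()
  i <- 1L
  push <- function(type, value, pos) tokens[[length(tokens) + 1L]] <<- list(type = type, value = value, pos = pos)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("[[:space:]]", ch)) { i <- i + 1L; next }
    if (ch == "(") { push("LPAREN", "(", i); i <- i + 1L; next }
    if (ch == ")") { push("RPAREN", ")", i); i <- i + 1L; next }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n && chars[j] != "\"") j <- j + 1L
      if (j > n) parse_error("unbalanced quote", i)
      payload <- paste0(chars[seq(i + 1L, length.out = j - i - 1L)], collapse = "")
      if (!nzchar(trimws(payload))) parse_error("empty phrase", i)
      push("PHRASE", payload, i)
      i <- j + 1L
      next
    }
    j <- i
    while (j <= n && !grepl("[[:space:]\"()]", chars[j])) j <- j + 1L
    word <- paste0(chars[i:(j - 1L)], collapse = "")
    # operator keywords only in uppercase; lowercase forms are ordinary terms
    if (word %in% c("AND", "OR", "NOT")) push(word, word, i)
    else push("TERM", word, i)
    i <- j
  }
  tokens
}

#' Parse a Boolean query into its syntax tree
#'
#' Grammar: terms and quoted phrases are leaves; `NOT` binds tighter than
#' `AND`, which binds tighter than `OR`; all operators are left-associative and
#' runs of the same operator collapse into one n-ary node; parentheses override
#' precedence. `a NOT b` is accepted as the conventional shorthand for
#' `a AND NOT b`. Operator keywords are recognized only in uppercase —
#' lowercase `and`/`or`/`not` are ordinary search terms. Adjacent atoms
#' without an operator are an error.
#'
#' @param text Non-empty query string.
#' @return A `query_ast` with node kinds `TERM`, `PHRASE`, `AND`, `OR`, `NOT`.
#' @examples
#' parse_query('(morphology OR "neuromorpho.org") AND "neuronal reconstruction"')
#' @export
parse_query <- function(text) {
  if (!is_nonempty_string(text)) stop("parse_query: empty query", call. = FALSE)
  tokens <- tokenize_query(text)
  if (!length(tokens)) parse_error("empty query", 1L)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[[pos]] else NULL
  take <- function() { tk <- peek(); pos <<- pos + 1L; tk }
  end_pos <- nchar(text) + 1L

  parse_or <- function() {
    children <- list(parse_and())
    while (!is.null(tk <- peek()) && tk$type == "OR") {
      take()
      children <- c(children, list(parse_and()))
    }
    if (length(children) == 1L) children[[1]] else query_node("OR", children = children)
  }
  parse_and <- function() {
    children <- list(parse_not())
    # infix NOT ('a NOT b') is the conventional shorthand for 'a AND NOT b'
    while (!is.null(tk <- peek()) && tk$type %in% c("AND", "NOT")) {
      if (tk$type == "AND") {
        take()
        children <- c(children, list(parse_not()))
      } else {
        children <- c(children, list(parse_not()))
      }
    }
    if (length(children) == 1L) children[[1]] else query_node("AND", children = children)
  }
  parse_not <- function() {
    tk <- peek()
    if (!is.null(tk) && tk$type == "NOT") {
      take()
      query_node("NOT", children = list(parse_not()))
    } else parse_atom()
  }
  parse_atom <- function() {
    tk <- take()
    if (is.null(tk)) parse_error("dangling operator: expected a term, phrase or '('", end_pos)
    switch(tk$type,
      TERM = query_node("TERM", text = tk$value),
      PHRASE = query_node("PHRASE", text = tk$value),
      LPAREN = {
        inner <- parse_or()
        closing <- take()
        if (is.null(closing) || closing$type != "RPAREN")
          parse_error("unbalanced parenthesis", tk$pos)
        inner
      },
      parse_error(sprintf("unexpected '%s'", tk$value), tk$pos))
  }

  ast <- parse_or()
  if (!is.null(tk <- peek()))
    parse_error(sprintf("unexpected '%s' after end of expression", tk$value), tk$pos)
  ast
}

#' Portal dialect: capabilities and serialization rules
#'
#' Each publisher portal speaks its own variant of the query language and
#' payload format. A dialect declares what the portal can express
#' (`supports_not`), how multi-word phrases are joined (`word_joiner`; e.g.
#' `"+"` where a portal wants `neuronal+reconstruction`), the phrase
#' delimiters, the date granularity the portal filters on server-side, the
#' payload format of its responses, and whether HTML scraping is allowed
#' (disabled by default; scrape-only portals are skipped while it is off).
#'
#' @param name Portal name.
#' @param supports_not Does the portal accept the `NOT` operator?
#' @param word_joiner String placed between words inside a multi-word phrase
#'   when serializing (default `" "`).
#' @param phrase_delimiters Character pair wrapped around phrases.
#' @param date_granularity `year`, `year_month` or `year_month_day` — the
#'   finest date filter the portal itself applies; the engine re-filters
#'   client-side at full precision regardless.
#' @param payload_format `xml`, `json` or `html_scrape`.
#' @param scraping_enabled Allow searches on `html_scrape` portals.
#' @param api_root URL template the translated query is appended to.
#' @param page_size Result page size the portal serves (default 100).
#' @param active Include this portal in search runs.
#' @return A `portal_dialect` object.
#' @export
portal_dialect <- function(name = "default", supports_not = TRUE,
                           word_joiner = " ", phrase_delimiters = c("\"", "\""),
                           date_granularity = "year_month_day",
                           payload_format = "json", scraping_enabled = FALSE,
                           api_root = "mock://portal", page_size = 100L,
                           active = TRUE) {
  stopifnot(date_granularity %in% c("year", "year_month", "year_month_day"),
            payload_format %in% c("xml", "json", "html_scrape"),
            length(phrase_delimiters) == 2L)
  structure(list(name = name, supports_not = isTRUE(supports_not),
                 word_joiner = word_joiner,
                 phrase_delimiters = as.character(phrase_delimiters),
                 date_granularity = date_granularity,
                 payload_format = payload_format,
                 scraping_enabled = isTRUE(scraping_enabled),
                 api_root = api_root, page_size = as.integer(page_size),
                 active = isTRUE(active)),
            class = "portal_dialect")
}

#' Check that a query is expressible in a portal dialect
#'
#' The one capability that varies across real portals is `NOT` support (some
#' umbrella search engines lack it). A `NOT` node against a dialect with
#' `supports_not = FALSE` raises a capability error naming the portal.
#'
#' @param ast A [parse_query()] tree.
#' @param dialect A [portal_dialect()].
#' @return `TRUE`, invisibly, when expressible.
#' @export
validate_for_portal <- function(ast, dialect) {
  has_not <- function(node) {
    if (node$kind == "NOT") return(TRUE)
    if (!is.null(node$children)) return(any(vapply(node$children, has_not, TRUE)))
    FALSE
  }
  if (!dialect$supports_not && has_not(ast))
    stop(structure(class = c("litscout_capability_error", "error", "condition"),
                   list(message = sprintf("portal '%s' does not support the NOT operator",
                                          dialect$name),
                        call = NULL, portal = dialect$name)))
  invisible(TRUE)
}

#' Serialize a query tree for a portal
#'
#' Deterministic serialization: phrases are wrapped in the dialect's delimiters
#' with `word_joiner` replacing the spaces between their words; every non-leaf
#' child is parenthesized, so the default-dialect output re-parses to a
#' structurally identical tree.
#'
#' @inheritParams validate_for_portal
#' @return Portal query string.
#' @examples
#' nature_like <- portal_dialect("nature", word_joiner = "+")
#' translate_query(parse_query('"neuronal reconstruction"'), nature_like)
#' @export
translate_query <- function(ast, dialect = portal_dialect()) {
  validate_for_portal(ast, dialect)
  ser <- function(node) {
    wrap <- function(child) {
      s <- ser(child)
      if (child$kind %in% c("AND", "OR", "NOT")) paste0("(", s, ")") else s
    }
    switch(node$kind,
      TERM = node$text,
      PHRASE = paste0(dialect$phrase_delimiters[1],
                      gsub(" ", dialect$word_joiner, node$text, fixed = TRUE),
                      dialect$phrase_delimiters[2]),
      NOT = paste0("NOT ", wrap(node$children[[1]])),
      AND = paste(vapply(node$children, wrap, ""), collapse = " AND "),
      OR = paste(vapply(node$children, wrap, ""), collapse = " OR "))
  }
  ser(ast)
}

#' Expand a search term to its singular/plural variants
#'
#' Small English suffix-rule table emulating the lemma handling real portals do
#' server-side: the first matching rule of `-ies` (→ `-y`), `-es` (dropped when
#' the stem ends in s/x/z/ch/sh) and `-s` (dropped unless the word ends in
#' `-ss`) contributes the singular counterpart. The term itself is always in
#' the set; a word no rule covers expands to itself alone.
#'
#' @param term A single token.
#' @return Character vector of variants (the term first).
#' @examples
#' expand_lemma("neurons")   # neuron, neurons
#' expand_lemma("branches")  # branch, branches
#' expand_lemma("sheep")     # sheep
#' @export
expand_lemma <- function(term) {
  t <- term
  variants <- t
  lower <- tolower(t)
  n <- nchar(lower)
  if (n > 3 && endsWith(lower, "ies")) {
    variants <- c(paste0(substr(t, 1, n - 3), "y"), variants)
  } else if (n > 2 && endsWith(lower, "es") &&
             grepl("(s|x|z|ch|sh)es$", lower)) {
    variants <- c(substr(t, 1, n - 2), variants)
  } else if (n > 1 && endsWith(lower, "s") && !endsWith(lower, "ss")) {
    variants <- c(substr(t, 1, n - 1), variants)
  }
  unique(variants)
}

# Case-folded, whitespace-normalized text used for matching. Punctuation is
# preserved (phrases must match it literally).
fold_text <- function(text) {
  x <- tolower(enc2utf8(text))
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# A leaf matches as a whole word: no letter or digit may touch either side.
leaf_matches <- function(payload, text_folded) {
  needle <- fold_text(payload)
  if (!nzchar(needle)) return(FALSE)
  pat <- paste0("(?<![[:alnum:]])", escape_regex(needle), "(?![[:alnum:]])")
  grepl(pat, text_folded, perl = TRUE)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Evaluate a query against a document
#'
#' Pure Boolean evaluation over plain text, used by the mock portal and by
#' tests. Matching is case-insensitive on whitespace-normalized text; a `TERM`
#' matches as a whole word, a `PHRASE` requires the contiguous word sequence
#' (punctuation inside the phrase must match literally). With
#' `lemma_expansion` a `TERM` matches if any of its [expand_lemma()] variants
#' does.
#'
#' @param ast A [parse_query()] tree.
#' @param document Plain-text document.
#' @param lemma_expansion Expand terms to singular/plural variants first.
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_query <- function(ast, document, lemma_expansion = FALSE) {
  folded <- fold_text(document)
  ev <- function(node) {
    switch(node$kind,
      TERM = {
        variants <- if (lemma_expansion) expand_lemma(node$text) else node$text
        any(vapply(variants, leaf_matches, TRUE, text_folded = folded))
      },
      PHRASE = leaf_matches(node$text, folded),
      NOT = !ev(node$children[[1]]),
      AND = all(vapply(node$children, ev, TRUE)),
      OR = any(vapply(node$children, ev, TRUE)))
  }
  ev(ast)
}
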