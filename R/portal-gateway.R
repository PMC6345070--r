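#' @title Portal adapters and the mock portal
#' @description One adapter contract for every publisher portal: a transport
#'   object with a `fetch(query, page)` function returning a raw payload in the
#'   dialect's format. Responses are parsed into normalized hits, re-filtered
#'   by date client-side (portals differ in the granularity they filter on),
#'   and handed to deduplication. A fully functional mock portal serves a
#'   synthetic corpus through exactly the same contract, so the whole pipeline
#'   runs offline.
#' @name portal-gateway
NULL

#' A raw, untrusted hit as delivered by a portal
#'
#' @param title Title string (possibly perturbed/truncated by the portal).
#' @param pmid,pmcid,doi Optional identifiers.
#' @param journal Optional journal name.
#' @param published Optional [partial_date()] or `"YYYY[-MM[-DD]]"` string.
#' @param authors Character vector.
#' @param contact_email Optional email.
#' @param is_preprint Preprint-server flag.
#' @param source_portal Name of the delivering portal.
#' @param full_text Optional plain-text body (mock portals carry it so
#'   downstream checks can re-evaluate queries).
#' @param no_date_flag Set when the portal delivered no publication date; such
#'   hits are kept through date filtering but flagged.
#' @return A `raw_portal_hit`.
#' @export
raw_portal_hit <- function(title = "", pmid = NULL, pmcid = NULL, doi = NULL,
                           journal = NULL, published = NULL,
                           authors = character(), contact_email = NULL,
                           is_preprint = FALSE, source_portal = "",
                           full_text = NULL, no_date_flag = FALSE) {
  if (!is.null(published) && !is_partial_date(published))
    published <- parse_partial_date(published)
  if (empty_field(title) && empty_field(pmid) && empty_field(pmcid) && empty_field(doi))
    stop("raw_portal_hit: a title or at least one identifier is required", call. = FALSE)
  structure(list(title = as.character(title), pmid = pmid, pmcid = pmcid, doi = doi,
                 journal = journal, published = published,
                 authors = as.character(authors), contact_email = contact_email,
                 is_preprint = isTRUE(is_preprint), source_portal = source_portal,
                 full_text = full_text, no_date_flag = isTRUE(no_date_flag)),
            class = "raw_portal_hit")
}

hit_field <- function(x) if (is.null(x) || !nzchar(as.character(x)[1])) NULL else as.character(x)[1]

#' Parse a portal response payload into normalized hits
#'
#' Applies a field-path mapping to an XML or JSON payload. For XML the mapping
#' values are XPath expressions relative to each record node; for JSON they are
#' object keys. Missing optional fields become empty; encodings are normalized
#' to UTF-8. Malformed payloads raise a parse error naming the portal.
#'
#' @param payload Character scalar (or raw vector) holding the response body.
#' @param format `"xml"` or `"json"`.
#' @param mapping Named list with at least `records` (record-set path) and
#'   `title`; optional `pmid`, `pmcid`, `doi`, `journal`, `published`,
#'   `authors`, `contact_email`, `is_preprint`, `full_text`. Defaults to the
#'   mock portal schema.
#' @param portal Portal name used in error messages and hit provenance.
#' @return List of [raw_portal_hit()]s.
#' @export
parse_response <- function(payload, format = c("json", "xml"),
                           mapping = default_field_mapping(format), portal = "unknown") {
  format <- match.arg(format)
  if (is.raw(payload)) payload <- rawToChar(payload)
  payload <- enc2utf8(payload)
  if (format == "json") parse_response_json(payload, mapping, portal)
  else parse_response_xml(payload, mapping, portal)
}

#' Default field mapping of the mock portal schema
#' @param format `"json"` or `"xml"`.
#' @return Named list of field paths.
#' @export
default_field_mapping <- function(format = "json") {
  if (identical(format, "xml"))
    list(records = "//record", title = "title", pmid = "pmid", pmcid = "pmcid",
         doi = "doi", journal = "journal", published = "published",
         authors = "authors/author", contact_email = "contact_email",
         is_preprint = "is_preprint", full_text = "full_text")
  else
    list(records = "records", title = "title", pmid = "pmid", pmcid = "pmcid",
         doi = "doi", journal = "journal", published = "published",
         authors = "authors", contact_email = "contact_email",
         is_preprint = "is_preprint", full_text = "full_text")
}

portal_parse_error <- function(portal, msg) {
  stop(structure(class = c("litscout_portal_parse_error", "error", "condition"),
                 list(message = sprintf("portal '%s': malformed payload: %s", portal, msg),
                      call = NULL, portal = portal)))
}

parse_response_json <- function(payload, mapping, portal) {
  obj <- tryCatch(jsonlite::fromJSON(payload, simplifyVector = FALSE),
                  error = function(e) portal_parse_error(portal, conditionMessage(e)))
  recs <- obj[[mapping$records]] %||% list()
  lapply(recs, function(r) {
    pub <- r[[mapping$published %||% "published"]]
    raw_portal_hit(
      title = r[[mapping$title]] %||% "",
      pmid = hit_field(r[[mapping$pmid %||% "pmid"]]),
      pmcid = hit_field(r[[mapping$pmcid %||% "pmcid"]]),
      doi = hit_field(r[[mapping$doi %||% "doi"]]),
      journal = hit_field(r[[mapping$journal %||% "journal"]]),
      published = if (!is.null(pub) && nzchar(pub)) pub else NULL,
      authors = as.character(unlist(r[[mapping$authors %||% "authors"]] %||% character())),
      contact_email = hit_field(r[[mapping$contact_email %||% "contact_email"]]),
      is_preprint = isTRUE(r[[mapping$is_preprint %||% "is_preprint"]]),
      full_text = hit_field(r[[mapping$full_text %||% "full_text"]]),
      source_portal = portal,
      no_date_flag = is.null(pub) || !nzchar(pub))
  })
}

parse_response_xml <- function(payload, mapping, portal) {
  doc <- tryCatch(xml2::read_xml(payload),
                  error = function(e) portal_parse_error(portal, conditionMessage(e)))
  nodes <- xml2::xml_find_all(doc, mapping$records)
  lapply(nodes, function(nd) {
    field <- function(path) {
      hit <- xml2::xml_find_first(nd, path)
      if (inherits(hit, "xml_missing")) return(NULL)
      txt <- xml2::xml_text(hit)
      if (nzchar(txt)) txt else NULL
    }
    authors <- vapply(xml2::xml_find_all(nd, mapping$authors %||% "authors/author"),
                      xml2::xml_text, "")
    pub <- field(mapping$published %||% "published")
    raw_portal_hit(
      title = field(mapping$title) %||% "",
      pmid = field(mapping$pmid %||% "pmid"),
      pmcid = field(mapping$pmcid %||% "pmcid"),
      doi = field(mapping$doi %||% "doi"),
      journal = field(mapping$journal %||% "journal"),
      published = pub,
      authors = authors,
      contact_email = field(mapping$contact_email %||% "contact_email"),
      is_preprint = identical(field(mapping$is_preprint %||% "is_preprint"), "true"),
      full_text = field(mapping$full_text %||% "full_text"),
      source_portal = portal,
      no_date_flag = is.null(pub))
  })
}

#' Filter hits by publication date range
#'
#' A hit is retained when its (possibly partial) publication date overlaps the
#' inclusive range — a year-only date overlaps any range touching that year.
#' Hits without a date are retained and flagged (`no_date_flag`) rather than
#' dropped.
#'
#' @param hits List of [raw_portal_hit()]s.
#' @param from,to Range endpoints as [partial_date()]s (either may be `NULL`).
#' @return Filtered list.
#' @export
filter_by_date <- function(hits, from = NULL, to = NULL) {
  if (!is.null(from) && !is_partial_date(from)) from <- parse_partial_date(from)
  if (!is.null(to) && !is_partial_date(to)) to <- parse_partial_date(to)
  Filter(function(h) {
    if (is.null(h$published)) return(TRUE)
    partial_date_in_range(h$published, from, to)
  }, lapply(hits, function(h) {
    if (is.null(h$published)) h$no_date_flag <- TRUE
    h
  }))
}

portal_error <- function(portal, msg) {
  structure(class = c("litscout_portal_error", "error", "condition"),
            list(message = sprintf("portal '%s': %s", portal, msg),
                 call = NULL, portal = portal))
}

#' Run one query against one portal
#'
#' Validates and translates the query for the dialect, fetches pages through
#' the transport until exhaustion, parses and date-filters the results. An
#' empty result list is a normal outcome. Scrape-only portals are skipped
#' (with a message-condition notice) while scraping is disabled. Transport
#' failures surface as `litscout_portal_error` conditions for the orchestrator
#' to log; the multi-query run continues.
#'
#' @param dialect A [portal_dialect()].
#' @param ast A parsed query.
#' @param from,to Date range as [partial_date()]s.
#' @param client Transport: a list with `fetch(query_string, page)` returning a
#'   payload (character or raw) in `dialect$payload_format`, and optionally a
#'   `mapping` field-path table.
#' @return List of [raw_portal_hit()]s (possibly empty).
#' @export
run_portal_search <- function(dialect, ast, from = NULL, to = NULL, client) {
  validate_for_portal(ast, dialect)
  if (identical(dialect$payload_format, "html_scrape") && !dialect$scraping_enabled) {
    message(sprintf("portal '%s' requires scraping, which is disabled; skipped", dialect$name))
    return(structure(list(), skipped = TRUE))
  }
  q <- translate_query(ast, dialect)
  hits <- list()
  page <- 0L
  mapping <- client$mapping %||% default_field_mapping(dialect$payload_format)
  repeat {
    payload <- tryCatch(client$fetch(q, page),
                        error = function(e) stop(portal_error(dialect$name, conditionMessage(e))))
    batch <- parse_response(payload, dialect$payload_format, mapping, dialect$name)
    hits <- c(hits, batch)
    if (length(batch) < dialect$page_size) break
    page <- page + 1L
  }
  filter_by_date(hits, from, to)
}

# Parse a query already serialized in a dialect (what the mock portal receives
# on the wire): undo phrase-internal word joining, then parse normally.
parse_dialect_query <- function(raw_query, dialect) {
  if (!identical(dialect$word_joiner, " ")) {
    d1 <- escape_regex(dialect$phrase_delimiters[1])
    d2 <- escape_regex(dialect$phrase_delimiters[2])
    m <- gregexpr(paste0(d1, "[^\"]*?", d2), raw_query)
    regmatches(raw_query, m) <- lapply(regmatches(raw_query, m), function(ph)
      gsub(dialect$word_joiner, " ", ph, fixed = TRUE))
  }
  parse_query(raw_query)
}

#' Serve a query from a synthetic corpus, as a portal would
#'
#' The mock portal: parses the translated query in the portal's dialect,
#' evaluates it (with lemma expansion, as real portals do server-side) against
#' each article's full text, and serializes the matching records in the
#' dialect's payload format. Deterministic: the same query yields a
#' byte-identical payload.
#'
#' @param corpus List of article-like lists (the per-portal variants from
#'   [generate_corpus()], or [article_record()]s) carrying `full_text`.
#' @param dialect The portal's [portal_dialect()].
#' @param raw_query Query string as translated for this dialect.
#' @param page Zero-based page index.
#' @return Payload string in `dialect$payload_format`.
#' @export
mock_portal_serve <- function(corpus, dialect, raw_query, page = 0L) {
  ast <- tryCatch(parse_dialect_query(raw_query, dialect), error = function(e) e)
  if (inherits(ast, "error")) {
    # portal-style error payload
    if (identical(dialect$payload_format, "xml"))
      return(sprintf("<error><message>%s</message></error>", conditionMessage(ast)))
    return(jsonlite::toJSON(list(error = conditionMessage(ast)), auto_unbox = TRUE))
  }
  matches <- Filter(function(a) {
    txt <- a$full_text %||% a$title %||% ""
    evaluate_query(ast, txt, lemma_expansion = TRUE)
  }, corpus)
  lo <- page * dialect$page_size + 1L
  hi <- min(length(matches), (page + 1L) * dialect$page_size)
  matches <- if (lo > length(matches)) list() else matches[lo:hi]
  serialize_hits(matches, dialect$payload_format)
}

# Serialize article-like lists into the mock portal wire schema.
serialize_hits <- function(articles, format) {
  recs <- lapply(articles, function(a) {
    out <- list(title = a$title %||% "")
    for (f in c("pmid", "pmcid", "doi", "journal", "contact_email", "full_text"))
      if (!empty_field(a[[f]])) out[[f]] <- as.character(a[[f]])
    if (!is.null(a$published)) {
      pd <- if (is_partial_date(a$published)) a$published else parse_partial_date(a$published)
      out$published <- format(pd)
    }
    if (length(a$authors)) out$authors <- as.list(as.character(a$authors))
    if (isTRUE(a$is_preprint)) out$is_preprint <- TRUE
    out
  })
  if (identical(format, "json"))
    return(as.character(jsonlite::toJSON(list(records = recs), auto_unbox = TRUE)))
  doc <- xml2::xml_new_root("records")
  for (r in recs) {
    nd <- xml2::xml_add_child(doc, "record")
    for (f in setdiff(names(r), c("authors", "is_preprint")))
      xml2::xml_add_child(nd, f, r[[f]])
    if (!is.null(r$authors)) {
      au <- xml2::xml_add_child(nd, "authors")
      for (a in r$authors) xml2::xml_add_child(au, "author", a)
    }
    if (isTRUE(r$is_preprint)) xml2::xml_add_child(nd, "is_preprint", "true")
  }
  as.character(doc)
}

#' Build a transport client serving a corpus through the mock portal
#'
#' Returns the transport contract [run_portal_search()] expects, backed by
#' [mock_portal_serve()]. Use `fail_with` to simulate a transport outage.
#'
#' @param corpus Per-portal article list.
#' @param dialect The portal's dialect.
#' @param fail_with Optional error message; when set, every fetch fails.
#' @return A transport list with a `fetch(query, page)` function.
#' @export
mock_portal_client <- function(corpus, dialect, fail_with = NULL) {
  list(
    fetch = function(query, page = 0L) {
      if (!is.null(fail_with)) stop(fail_with, call. = FALSE)
      mock_portal_serve(corpus, dialect, query, page)
    },
    mapping = default_field_mapping(dialect$payload_format)
  )
}

#' A registry of portal adapters keyed by portal name
#'
#' Portals are constructed once from their dialect plus transport and looked up
#' by name at run time.
#'
#' @param ... Named arguments: `name = list(dialect = , client = )`.
#' @return A `portal_registry` list.
#' @export
portal_registry <- function(...) {
  entries <- list(...)
  stopifnot(length(entries) == 0L || !is.null(names(entries)))
  structure(entries, class = "portal_registry")
}
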