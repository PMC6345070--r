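#' @title Bibliographic records and their lifecycle state
#' @description Core domain types: one `article_record` per publication, with
#'   identifiers, bibliography, provenance of every search that found it, PDF
#'   download status and triage position.
#' @name records-model
NULL

#' Triage states of the curation lifecycle
#'
#' Every record sits in exactly one of five collections: `Evaluate` (PDF in
#' hand, awaiting a curator verdict), `Inaccessible` (PDF could not be
#' downloaded; retried on every future run), `Positive` (relevant), `Negative`
#' (irrelevant) and `Review` (deferred, with a mandatory note).
#'
#' @format Character vector of the five state names.
#' @export
TRIAGE_STATES <- c("Evaluate", "Inaccessible", "Positive", "Negative", "Review")

#' PDF download statuses
#' @format Character vector: `not_attempted`, `downloaded`, `inaccessible`.
#' @export
PDF_STATUSES <- c("not_attempted", "downloaded", "inaccessible")

#' Record the provenance of one search hit
#'
#' A hit ties a record to the portal and keyword query that found it. Hits
#' accumulate set-wise on a record: delivering the same `(portal, query_id)`
#' pair twice never creates a duplicate entry.
#'
#' @param portal Portal name (non-empty).
#' @param query_id Identifier of the keyword query (non-empty).
#' @param keywords The query text that matched.
#' @param hit_date Timestamp string; defaults to now.
#' @return A `search_hit` object.
#' @export
search_hit <- function(portal, query_id, keywords = "", hit_date = iso_now()) {
  if (!is_nonempty_string(portal)) stop("search_hit: 'portal' must be non-empty", call. = FALSE)
  if (!is_nonempty_string(query_id)) stop("search_hit: 'query_id' must be non-empty", call. = FALSE)
  structure(list(portal = portal, query_id = as.character(query_id),
                 keywords = as.character(keywords), hit_date = hit_date),
            class = "search_hit")
}

iso_now <- function() format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z")

is_nonempty_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) && nzchar(trimws(x))
}

empty_field <- function(x) is.null(x) || length(x) == 0L || (length(x) == 1L && (is.na(x) || !nzchar(x)))

#' Construct a bibliographic article record
#'
#' The unit of storage: one publication with identifiers (PMID, PMCID, DOI),
#' bibliography (title, journal, authors, publication date, contact email),
#' search provenance, PDF status and triage state. At least one of PMID,
#' PMCID, DOI or a non-empty title must be present. The `record_id` is a
#' deterministic content hash of DOI, PMID and normalized title, so
#' re-ingesting the same publication reproduces the same key.
#'
#' @param title Article title.
#' @param pmid,pmcid,doi Optional identifiers.
#' @param journal Optional journal name.
#' @param published Optional [partial_date()] (or `"YYYY[-MM[-DD]]"` string).
#' @param authors Character vector of author names, in order.
#' @param contact_email Optional corresponding-author email.
#' @param is_preprint Is this a preprint-server record?
#' @param search_hits List of [search_hit()]s.
#' @param found_date Timestamp the record was first found.
#' @param pdf_status One of `r paste(PDF_STATUSES, collapse = ", ")`.
#' @param pdf_path Path of the downloaded PDF; required iff
#'   `pdf_status == "downloaded"`.
#' @param triage One of the five [TRIAGE_STATES].
#' @param triage_note Free-text note; required when `triage == "Review"`.
#' @param evaluated_date Timestamp of the curator verdict; present iff triage
#'   is Positive or Negative.
#' @param target_collection User-defined label of the collection the
#'   originating query routes into.
#' @param full_text Optional plain-text body (used by the mock portal).
#' @return An `article_record`, validated against its invariants.
#' @export
article_record <- function(title = "", pmid = NULL, pmcid = NULL, doi = NULL,
                           journal = NULL, published = NULL,
                           authors = character(), contact_email = NULL,
                           is_preprint = FALSE, search_hits = list(),
                           found_date = iso_now(), pdf_status = "not_attempted",
                           pdf_path = NULL, triage = "Evaluate",
                           triage_note = NULL, evaluated_date = NULL,
                           target_collection = "default", full_text = NULL) {
  if (!is.null(published) && !is_partial_date(published))
    published <- parse_partial_date(published)
  rec <- structure(list(
    record_id = NA_character_,
    pmid = if (empty_field(pmid)) NULL else as.character(pmid),
    pmcid = if (empty_field(pmcid)) NULL else as.character(pmcid),
    doi = if (empty_field(doi)) NULL else as.character(doi),
    title = as.character(title),
    journal = if (empty_field(journal)) NULL else as.character(journal),
    published = published,
    authors = as.character(authors),
    contact_email = if (empty_field(contact_email)) NULL else as.character(contact_email),
    is_preprint = isTRUE(is_preprint),
    search_hits = search_hits,
    found_date = found_date,
    evaluated_date = evaluated_date,
    pdf_status = pdf_status,
    pdf_path = if (empty_field(pdf_path)) NULL else as.character(pdf_path),
    triage = triage,
    triage_note = if (empty_field(triage_note)) NULL else as.character(triage_note),
    target_collection = as.character(target_collection),
    full_text = if (empty_field(full_text)) NULL else as.character(full_text)
  ), class = "article_record")
  rec$record_id <- record_content_id(rec)
  validate_record(rec)
  rec
}

#' Validate an article record against its invariants
#'
#' Checks the closed value sets (triage state, PDF status), the presence rules
#' (at least one identifier or a title; `pdf_path` iff downloaded;
#' `evaluated_date` iff Positive/Negative; Review requires a note) and
#' uniqueness of `(portal, query_id)` among search hits. Errors name the
#' offending field.
#'
#' @param rec An `article_record`.
#' @return The record, invisibly, if valid; otherwise an error of class
#'   `litscout_validation_error`.
#' @export
validate_record <- function(rec) {
  fail <- function(field, msg) {
    stop(structure(class = c("litscout_validation_error", "error", "condition"),
                   list(message = sprintf("invalid article_record [%s]: %s", field, msg),
                        call = NULL, field = field)))
  }
  if (empty_field(rec$pmid) && empty_field(rec$pmcid) && empty_field(rec$doi) &&
      !is_nonempty_string(rec$title))
    fail("title", "at least one of pmid, pmcid, doi or a non-empty title is required")
  if (!rec$triage %in% TRIAGE_STATES)
    fail("triage", paste("must be one of", paste(TRIAGE_STATES, collapse = ", ")))
  if (!rec$pdf_status %in% PDF_STATUSES)
    fail("pdf_status", paste("must be one of", paste(PDF_STATUSES, collapse = ", ")))
  if (identical(rec$pdf_status, "downloaded") && empty_field(rec$pdf_path))
    fail("pdf_path", "required when pdf_status is 'downloaded'")
  if (!identical(rec$pdf_status, "downloaded") && !empty_field(rec$pdf_path))
    fail("pdf_path", "only allowed when pdf_status is 'downloaded'")
  if (rec$triage %in% c("Positive", "Negative") && empty_field(rec$evaluated_date))
    fail("evaluated_date", "required for Positive/Negative records")
  if (!rec$triage %in% c("Positive", "Negative") && !empty_field(rec$evaluated_date))
    fail("evaluated_date", "only allowed for Positive/Negative records")
  if (identical(rec$triage, "Review") && empty_field(rec$triage_note))
    fail("triage_note", "Review requires a note")
  if (length(rec$search_hits)) {
    keys <- vapply(rec$search_hits, function(h) paste0(h$portal, "\r", h$query_id), "")
    if (anyDuplicated(keys))
      fail("search_hits", "duplicate (portal, query_id) entries")
  }
  if (!is.null(rec$published) && !is_partial_date(rec$published))
    fail("published", "must be a partial_date")
  invisible(rec)
}

# FNV-1a, evaluated twice with different offset bases for a 16-hex-digit key.
# Arithmetic is split into 16-bit halves so every product stays exact in a
# double. Deterministic across platforms; collisions negligible at desk scale.
fnv1a32 <- function(bytes, offset) {
  h <- offset
  for (b in bytes) {
    lo <- h %% 65536
    hi <- h %/% 65536
    lo <- (lo %/% 256) * 256 + bitwXor(lo %% 256, b)
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

content_hash <- function(x) {
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  hex32 <- function(h) sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
  paste0(hex32(fnv1a32(bytes, 2166136261)), hex32(fnv1a32(bytes, 31356277)))
}

record_content_id <- function(rec) {
  content_hash(paste(tolower(rec$doi %||% ""), rec$pmid %||% "",
                     normalize_title(rec$title %||% ""), sep = "|"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.article_record <- function(x, ...) {
  cat("<article_record> ", x$record_id, "\n", sep = "")
  cat("  title:   ", x$title, "\n", sep = "")
  ids <- c(pmid = x$pmid %||% "", pmcid = x$pmcid %||% "", doi = x$doi %||% "")
  ids <- ids[nzchar(ids)]
  if (length(ids)) cat("  ids:     ", paste(names(ids), ids, sep = "=", collapse = "  "), "\n", sep = "")
  if (!is.null(x$journal)) cat("  journal: ", x$journal, if (x$is_preprint) " [preprint]", "\n", sep = "")
  if (!is.null(x$published)) cat("  date:    ", format(x$published), "\n", sep = "")
  cat("  triage:  ", x$triage, " (pdf: ", x$pdf_status, ")\n", sep = "")
  cat("  hits:    ", length(x$search_hits), " search hit(s)\n", sep = "")
  invisible(x)
}

# --- JSON (de)serialization of records ------------------------------------

record_to_list <- function(rec) {
  out <- unclass(rec)
  out$published <- partial_date_to_list(rec$published)
  out$search_hits <- lapply(rec$search_hits, unclass)
  out[!vapply(out, is.null, TRUE)]
}

record_from_list <- function(x) {
  rec <- structure(list(
    record_id = x$record_id,
    pmid = x$pmid, pmcid = x$pmcid, doi = x$doi,
    title = x$title %||% "",
    journal = x$journal,
    published = partial_date_from_list(x$published),
    authors = as.character(unlist(x$authors %||% character())),
    contact_email = x$contact_email,
    is_preprint = isTRUE(x$is_preprint),
    search_hits = lapply(x$search_hits %||% list(), function(h)
      search_hit(h$portal, h$query_id, h$keywords %||% "", h$hit_date %||% "")),
    found_date = x$found_date,
    evaluated_date = x$evaluated_date,
    pdf_status = x$pdf_status %||% "not_attempted",
    pdf_path = x$pdf_path,
    triage = x$triage %||% "Evaluate",
    triage_note = x$triage_note,
    target_collection = x$target_collection %||% "default",
    full_text = x$full_text
  ), class = "article_record")
  validate_record(rec)
  rec
}
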