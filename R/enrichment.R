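#' @title Bibliographic enrichment services
#' @description Equivalents of the PubMed-style index service (identifiers,
#'   extended bibliography and contact email, looked up by title or by id) and
#'   the CrossRef-style registry service (DOI to full-text URL resolution).
#'   Every network interaction goes through an injected transport contract, so
#'   the suite runs fully offline against the mock clients below.
#' @name enrichment
NULL

lookup_result <- function(pmid = NULL, pmcid = NULL, doi = NULL,
                          contact_email = NULL, title = NULL, journal = NULL,
                          published = NULL, authors = character(),
                          match_score = NULL) {
  structure(list(pmid = pmid, pmcid = pmcid, doi = doi,
                 contact_email = contact_email, title = title,
                 journal = journal, published = published, authors = authors,
                 match_score = match_score),
            class = "lookup_result")
}

transport_error <- function(service, msg) {
  structure(class = c("litscout_transport_error", "error", "condition"),
            list(message = sprintf("%s: transport failure: %s", service, msg),
                 call = NULL, service = service))
}

#' Look a record up in a bibliographic index by title
#'
#' Title searches against an index that performs synonym expansion return a fan
#' of candidates; each is scored with Jaro-Winkler over normalized titles via
#' [best_title_match()] and the best is accepted only at or above the hard
#' `pubmed_best_match_threshold` (default 0.9).
#'
#' @param title Non-empty title.
#' @param client Index transport: list with `search_title(title)` returning a
#'   list of candidate records and `get_id(id)` for keyed retrieval.
#' @param cfg A [similarity_config()].
#' @return A `lookup_result` with `match_score`, or `NULL` when nothing
#'   reaches the threshold. Transport failures raise
#'   `litscout_transport_error`.
#' @export
lookup_by_title <- function(title, client, cfg = similarity_config()) {
  stopifnot(is_nonempty_string(title))
  candidates <- tryCatch(client$search_title(title),
                         error = function(e) stop(transport_error("bibliographic index",
                                                                  conditionMessage(e))))
  best <- best_title_match(title, candidates, cfg)
  if (is.null(best)) return(NULL)
  lookup_result(pmid = best$pmid, pmcid = best$pmcid, doi = best$doi,
                contact_email = best$contact_email, title = best$title,
                journal = best$journal, published = best$published,
                authors = as.character(best$authors %||% character()),
                match_score = attr(best, "match_score"))
}

#' Identifier syntax rules
#'
#' PMIDs are all digits; PMCIDs are `PMC` followed by digits; DOIs start with
#' `10.` and contain a slash. Malformed ids are rejected before any transport
#' call.
#'
#' @param id Identifier string.
#' @return One of `"pmid"`, `"pmcid"`, `"doi"`, or an error.
#' @export
classify_identifier <- function(id) {
  if (!is_nonempty_string(id))
    stop(structure(class = c("litscout_validation_error", "error", "condition"),
                   list(message = "identifier must be a non-empty string", call = NULL)))
  if (grepl("^[0-9]+$", id)) return("pmid")
  if (grepl("^PMC[0-9]+$", id)) return("pmcid")
  if (grepl("^10\\.[^/]+/.+", id)) return("doi")
  stop(structure(class = c("litscout_validation_error", "error", "condition"),
                 list(message = sprintf("malformed identifier '%s' (expected PMID digits, PMCnnn or 10.x/y DOI)", id),
                      call = NULL)))
}

#' Look a record up by PMID, PMCID or DOI
#'
#' Feeds the manual-add pathway. The id is syntax-checked first; unknown ids
#' raise a not-found error.
#'
#' @param id Identifier string.
#' @param client Index transport (see [lookup_by_title()]).
#' @return A complete `lookup_result`.
#' @export
lookup_by_id <- function(id, client) {
  classify_identifier(id)
  rec <- tryCatch(client$get_id(id),
                  error = function(e) stop(transport_error("bibliographic index",
                                                           conditionMessage(e))))
  if (is.null(rec))
    stop(structure(class = c("litscout_not_found_error", "error", "condition"),
                   list(message = sprintf("identifier '%s' not found in index", id),
                        call = NULL, id = id)))
  lookup_result(pmid = rec$pmid, pmcid = rec$pmcid, doi = rec$doi,
                contact_email = rec$contact_email, title = rec$title,
                journal = rec$journal, published = rec$published,
                authors = as.character(rec$authors %||% character()))
}

#' Resolve a DOI to its full-text PDF URL
#'
#' Asks the registry transport for the full-text pointer registered with the
#' DOI. `NULL` when the registry lists none. Transport failures raise a
#' `litscout_resolution_error`, which the calling run treats as inaccessible
#' for this round.
#'
#' @param doi DOI string.
#' @param client Registry transport: list with `full_text_url(doi)`.
#' @return URL string or `NULL`.
#' @export
resolve_pdf_url <- function(doi, client) {
  stopifnot(is_nonempty_string(doi))
  tryCatch(client$full_text_url(doi),
           error = function(e)
             stop(structure(class = c("litscout_resolution_error", "error", "condition"),
                            list(message = sprintf("registry: could not resolve '%s': %s",
                                                   doi, conditionMessage(e)),
                                 call = NULL, doi = doi))))
}

#' Attempt to download a record's PDF
#'
#' On success the bytes land at `<pdf_dir>/<record_id>.pdf`, `pdf_status`
#' becomes `downloaded` and `pdf_path` is set; on access denial or transport
#' failure the status becomes `inaccessible`. Retry-safe: a repeated success
#' overwrites the same path; repeated failures leave a single `inaccessible`
#' status.
#'
#' @param record The [article_record()] being fetched.
#' @param url URL from [resolve_pdf_url()], or `NULL` (treated as
#'   inaccessible).
#' @param client Download transport: list with `download(url)` returning raw
#'   bytes, or signalling an error on denial.
#' @param pdf_dir Directory for PDFs, created if missing.
#' @return The record with updated `pdf_status`/`pdf_path`.
#' @export
attempt_download <- function(record, url, client, pdf_dir) {
  if (is.null(url)) {
    record$pdf_status <- "inaccessible"
    record$pdf_path <- NULL
    return(record)
  }
  bytes <- tryCatch(client$download(url), error = function(e) NULL)
  if (is.null(bytes)) {
    record$pdf_status <- "inaccessible"
    record$pdf_path <- NULL
    return(record)
  }
  if (!dir.exists(pdf_dir)) dir.create(pdf_dir, recursive = TRUE)
  path <- file.path(pdf_dir, paste0(record$record_id, ".pdf"))
  ok <- tryCatch({ writeBin(as.raw(bytes), path); TRUE },
                 error = function(e) stop("attempt_download: write failure at ", path,
                                          ": ", conditionMessage(e), call. = FALSE))
  record$pdf_status <- "downloaded"
  record$pdf_path <- path
  record
}

#' Enrich and fetch: the per-record pipeline step
#'
#' Fills missing identifiers/email from the index (by id when one is known,
#' else by title), then resolves the DOI and attempts the PDF download.
#' Enrichment never overwrites a non-empty stored field with a different value.
#'
#' @param record An [article_record()].
#' @param services List with `index` (bibliographic index transport), optional
#'   `registry` (full-text registry transport), optional `pdf` (download
#'   transport), `pdf_dir`, and `cfg` ([similarity_config()]).
#' @return The enriched record with download status applied.
#' @export
enrich_record <- function(record, services) {
  cfg <- services$cfg %||% similarity_config()
  res <- NULL
  if (!is.null(services$index)) {
    safe <- function(expr) tryCatch(expr, error = function(e) NULL)
    if (!empty_field(record$pmid))
      res <- safe(lookup_by_id(record$pmid, services$index))
    if (is.null(res) && !empty_field(record$doi))
      res <- safe(lookup_by_id(record$doi, services$index))
    if (is.null(res) && is_nonempty_string(record$title))
      res <- safe(lookup_by_title(record$title, services$index, cfg))
  }
  if (!is.null(res)) {
    for (f in c("pmid", "pmcid", "doi", "contact_email", "journal")) {
      if (empty_field(record[[f]]) && !empty_field(res[[f]]))
        record[[f]] <- res[[f]]
    }
    if (is.null(record$published) && !is.null(res$published))
      record$published <- if (is_partial_date(res$published)) res$published
                          else parse_partial_date(res$published)
    if (!length(record$authors) && length(res$authors))
      record$authors <- res$authors
  }
  if (!is.null(services$registry) && !is.null(services$pdf) && !empty_field(record$doi)) {
    url <- tryCatch(resolve_pdf_url(record$doi, services$registry),
                    error = function(e) NULL)
    record <- attempt_download(record, url, services$pdf, services$pdf_dir %||% tempdir())
  } else if (record$pdf_status == "not_attempted") {
    record$pdf_status <- "inaccessible"
  }
  record
}

# --- mock services ----------------------------------------------------------

#' Mock bibliographic index
#'
#' In-memory stand-in for a PubMed-style index. `search_title` emulates
#' synonym-expansion fan-out by returning the whole candidate table (the true
#' record among decoys); `get_id` is keyed retrieval over PMID/PMCID/DOI.
#'
#' @param entries List of record-like lists (fields `title`, `pmid`, `pmcid`,
#'   `doi`, `journal`, `published`, `authors`, `contact_email`).
#' @return An index transport.
#' @export
mock_bibliographic_index <- function(entries = list()) {
  list(
    entries = entries,
    search_title = function(title) entries,
    get_id = function(id) {
      for (e in entries) {
        if (identical(e$pmid, id) || identical(e$pmcid, id) ||
            identical(tolower(e$doi %||% ""), tolower(id))) return(e)
      }
      NULL
    }
  )
}

#' Mock full-text registry and PDF server
#'
#' `urls` maps DOI to full-text URL; `open_access` is an environment mapping
#' URL to `TRUE`/`FALSE` so tests can flip a paywalled article open between
#' runs (delayed open-access release).
#'
#' @param urls Named character vector/list: DOI -> URL.
#' @param open Character vector of URLs that are openly downloadable.
#' @return List with `registry` and `pdf` transports plus `set_open(url, flag)`.
#' @export
mock_fulltext_service <- function(urls = list(), open = character()) {
  state <- new.env(parent = emptyenv())
  state$open <- open
  list(
    registry = list(full_text_url = function(doi) {
      u <- urls[[doi]]
      if (is.null(u)) NULL else u
    }),
    pdf = list(download = function(url) {
      if (!url %in% state$open) stop("access denied: ", url, call. = FALSE)
      charToRaw(paste0("%PDF-1.4 mock body for ", url))
    }),
    set_open = function(url, flag = TRUE) {
      state$open <- if (flag) union(state$open, url) else setdiff(state$open, url)
      invisible(state$open)
    }
  )
}
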