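#' Open (or create) a record store
#'
#' The store holds the three desk-scale databases the engine needs: the
#' literature records themselves, the portal/keyword/metadata configuration,
#' and the activity log. Persistence is plain JSON in a directory
#' (`literature.json`, `config.json`, `metadata.json`, `activity.json`), one
#' schema documented in the package vignette; with `dir = NULL` the store lives
#' in memory only, which is what the test suite uses. Every mutating operation
#' writes through immediately, so a reopened store is field-identical to the
#' one that was closed.
#'
#' @param dir Directory for the JSON files, created if missing; `NULL` for an
#'   in-memory store.
#' @return A `record_store` object (an environment).
#' @export
store_open <- function(dir = NULL) {
  st <- new.env(parent = emptyenv())
  st$dir <- dir
  st$records <- new.env(parent = emptyenv())
  st$pmid_index <- new.env(parent = emptyenv())
  st$pmcid_index <- new.env(parent = emptyenv())
  st$doi_index <- new.env(parent = emptyenv())
  st$categories <- default_metadata_categories()
  st$annotations <- new.env(parent = emptyenv())
  st$portals <- list()
  st$queries <- list()
  st$activity <- list()
  class(st) <- "record_store"
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    store_load(st)
  }
  st
}

#' @export
print.record_store <- function(x, ...) {
  counts <- store_counts(x)
  cat("<record_store> ", if (is.null(x$dir)) "(in memory)" else x$dir, "\n", sep = "")
  cat("  records: ", sum(counts), " (",
      paste(names(counts), counts, sep = "=", collapse = ", "), ")\n", sep = "")
  cat("  portals: ", length(x$portals), "  queries: ", length(x$queries),
      "  metadata categories: ", length(x$categories),
      "  log entries: ", length(x$activity), "\n", sep = "")
  invisible(x)
}

store_ids <- function(store) ls(store$records)

store_size <- function(store) length(store_ids(store))

store_get <- function(store, record_id) {
  if (!exists(record_id, envir = store$records, inherits = FALSE)) return(NULL)
  get(record_id, envir = store$records)
}

#' Insert or replace a record in the store
#'
#' The record is validated, indexed by its identifiers and persisted. The key
#' is the record's deterministic content id.
#'
#' @param store A [store_open()] store.
#' @param record A valid [article_record()].
#' @return The `record_id`, invisibly.
#' @export
store_put <- function(store, record) {
  validate_record(record)
  old <- store_get(store, record$record_id)
  if (!is.null(old)) deindex_record(store, old)
  assign(record$record_id, record, envir = store$records)
  index_record(store, record)
  store_save(store)
  invisible(record$record_id)
}

index_record <- function(store, rec) {
  if (!empty_field(rec$pmid)) assign(rec$pmid, rec$record_id, envir = store$pmid_index)
  if (!empty_field(rec$pmcid)) assign(rec$pmcid, rec$record_id, envir = store$pmcid_index)
  if (!empty_field(rec$doi)) assign(tolower(rec$doi), rec$record_id, envir = store$doi_index)
}

deindex_record <- function(store, rec) {
  if (!empty_field(rec$pmid) && exists(rec$pmid, envir = store$pmid_index, inherits = FALSE))
    rm(list = rec$pmid, envir = store$pmid_index)
  if (!empty_field(rec$pmcid) && exists(rec$pmcid, envir = store$pmcid_index, inherits = FALSE))
    rm(list = rec$pmcid, envir = store$pmcid_index)
  if (!empty_field(rec$doi) && exists(tolower(rec$doi), envir = store$doi_index, inherits = FALSE))
    rm(list = tolower(rec$doi), envir = store$doi_index)
}

# Replace a record under a possibly changed id (merges can add identifiers but
# the content id is fixed at first ingestion, so ids are stable; this guards
# the general case anyway).
store_replace <- function(store, old_id, record) {
  old <- store_get(store, old_id)
  if (!is.null(old)) {
    deindex_record(store, old)
    rm(list = old_id, envir = store$records)
  }
  record$record_id <- old_id
  validate_record(record)
  assign(old_id, record, envir = store$records)
  index_record(store, record)
  store_save(store)
  invisible(old_id)
}

SORT_KEYS <- c("published", "identifier", "title", "found_date")
FILTER_FIELDS <- c("pmid", "pmcid", "doi", "title", "author")

primary_identifier <- function(rec) {
  rec$pmid %||% rec$pmcid %||% rec$doi %||% ""
}

#' Query the literature store
#'
#' Returns records from one triage collection (or all), sorted by a stable
#' total order and optionally filtered and paginated. Filters are conjunctive;
#' `title` and `author` filters are case-insensitive substring matches,
#' identifier filters are exact. Ties in the sort key are broken by
#' `record_id`, so the order is total and pagination covers every matching
#' record exactly once. Page boundaries are half-open: page `i` of size `s`
#' holds matches `[i*s, (i+1)*s)` (zero-based).
#'
#' @param store A record store.
#' @param collection A triage state or target-collection label to restrict to,
#'   or `NULL` for all records.
#' @param sort_key One of `published`, `identifier`, `title`, `found_date`.
#' @param filters Named list over `pmid`, `pmcid`, `doi`, `title`, `author`.
#' @param page Zero-based page index, or `NULL` for everything.
#' @param page_size Page size (default 50).
#' @return List of `article_record`s.
#' @export
store_query <- function(store, collection = NULL, sort_key = "found_date",
                        filters = list(), page = NULL, page_size = 50L) {
  if (!sort_key %in% SORT_KEYS)
    stop("store_query: unknown sort_key '", sort_key, "' (use ",
         paste(SORT_KEYS, collapse = ", "), ")", call. = FALSE)
  if (length(filters) && (is.null(names(filters)) || !all(names(filters) %in% FILTER_FIELDS)))
    stop("store_query: unknown filter field(s): ",
         paste(setdiff(names(filters), FILTER_FIELDS), collapse = ", "), call. = FALSE)
  recs <- lapply(store_ids(store), store_get, store = store)
  if (!is.null(collection)) {
    recs <- Filter(function(r) identical(r$triage, collection) ||
                     identical(r$target_collection, collection), recs)
  }
  for (f in names(filters)) {
    val <- filters[[f]]
    recs <- switch(f,
      pmid = Filter(function(r) identical(r$pmid, val), recs),
      pmcid = Filter(function(r) identical(r$pmcid, val), recs),
      doi = Filter(function(r) identical(tolower(r$doi %||% ""), tolower(val)), recs),
      title = Filter(function(r) grepl(tolower(val), tolower(r$title), fixed = TRUE), recs),
      author = Filter(function(r) any(grepl(tolower(val), tolower(r$authors), fixed = TRUE)), recs)
    )
  }
  if (length(recs)) {
    key <- switch(sort_key,
      published = vapply(recs, function(r) partial_date_sort_key(r$published), 0),
      identifier = vapply(recs, primary_identifier, ""),
      title = vapply(recs, function(r) normalize_title(r$title), ""),
      found_date = vapply(recs, function(r) r$found_date %||% "", ""))
    tie <- vapply(recs, function(r) r$record_id, "")
    recs <- recs[order(key, tie, method = "radix")]
  }
  if (!is.null(page)) {
    lo <- page * page_size + 1L
    hi <- min(length(recs), (page + 1L) * page_size)
    recs <- if (lo > length(recs)) list() else recs[lo:hi]
  }
  recs
}

#' Per-collection record counts
#'
#' @param store A record store.
#' @return Named integer vector over the five triage states; sums to the store
#'   size (the lifecycle states partition the store).
#' @export
store_counts <- function(store) {
  states <- vapply(store_ids(store), function(id) store_get(store, id)$triage, "")
  vapply(TRIAGE_STATES, function(s) sum(states == s), 0L)
}

#' Reset the whole database
#'
#' Empties all three stores (literature, portal/keyword config, metadata) and
#' appends a `success` entry to the activity log. Refuses without explicit
#' confirmation.
#'
#' @param store A record store.
#' @param confirm Must be `TRUE`; anything else refuses and leaves the store
#'   untouched.
#' @return The store, invisibly.
#' @export
store_reset <- function(store, confirm = FALSE) {
  if (!isTRUE(confirm))
    stop("store_reset: refusing to reset without confirm = TRUE", call. = FALSE)
  rm(list = ls(store$records), envir = store$records)
  rm(list = ls(store$pmid_index), envir = store$pmid_index)
  rm(list = ls(store$pmcid_index), envir = store$pmcid_index)
  rm(list = ls(store$doi_index), envir = store$doi_index)
  rm(list = ls(store$annotations), envir = store$annotations)
  store$categories <- default_metadata_categories()
  store$portals <- list()
  store$queries <- list()
  entry <- activity_entry("reset", status = "success", detail = "database reset")
  store$activity <- c(store$activity, list(entry))
  store_save(store)
  invisible(store)
}

activity_entry <- function(kind, status = "running", detail = "") {
  list(run_id = content_hash(paste(kind, iso_now(), stats::runif(1))),
       kind = kind, started = iso_now(),
       ended = if (status == "running") NULL else iso_now(),
       status = status, detail = detail)
}

close_activity_entry <- function(entry, status, detail = entry$detail) {
  stopifnot(status %in% c("success", "error", "interrupted"))
  entry$ended <- iso_now()
  entry$status <- status
  entry$detail <- detail
  entry
}

append_activity <- function(store, entry) {
  store$activity <- c(store$activity, list(entry))
  store_save(store)
  invisible(entry)
}

# --- persistence ------------------------------------------------------------

store_save <- function(store) {
  if (is.null(store$dir)) return(invisible(store))
  recs <- lapply(store_ids(store), function(id) record_to_list(store_get(store, id)))
  jsonlite::write_json(recs, file.path(store$dir, "literature.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  jsonlite::write_json(list(portals = store$portals, queries = store$queries),
                       file.path(store$dir, "config.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  ann <- mget(ls(store$annotations), envir = store$annotations)
  jsonlite::write_json(list(categories = store$categories, annotations = ann),
                       file.path(store$dir, "metadata.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  jsonlite::write_json(store$activity, file.path(store$dir, "activity.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(store)
}

store_load <- function(store) {
  lit <- file.path(store$dir, "literature.json")
  if (file.exists(lit)) {
    recs <- jsonlite::read_json(lit)
    for (x in recs) {
      rec <- record_from_list(x)
      assign(rec$record_id, rec, envir = store$records)
      index_record(store, rec)
    }
  }
  cfgf <- file.path(store$dir, "config.json")
  if (file.exists(cfgf)) {
    cfg <- jsonlite::read_json(cfgf)
    store$portals <- cfg$portals %||% list()
    store$queries <- cfg$queries %||% list()
  }
  mdf <- file.path(store$dir, "metadata.json")
  if (file.exists(mdf)) {
    md <- jsonlite::read_json(mdf)
    if (length(md$categories)) store$categories <- md$categories
    for (id in names(md$annotations %||% list()))
      assign(id, md$annotations[[id]], envir = store$annotations)
  }
  actf <- file.path(store$dir, "activity.json")
  if (file.exists(actf)) store$activity <- jsonlite::read_json(actf)
  invisible(store)
}
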