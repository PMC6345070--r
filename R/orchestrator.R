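#' @title Search-run orchestration
#' @description One run walks every active portal crossed with every configured
#'   query: validate and translate the query, search, date-filter, deduplicate
#'   and merge, enrich, attempt the PDF download, ingest into the query's
#'   target collection — then retry all inaccessible records. The run writes
#'   exactly one activity-log entry with a terminal status; portal-level
#'   failures are logged and skipped so one broken portal never aborts the
#'   others.
#' @name orchestrator
NULL

#' Assemble a run configuration
#'
#' @param portals List of [portal_dialect()]s (those with `active = TRUE` are
#'   searched).
#' @param queries List of queries, each
#'   `list(query_id = , text = , target_collection = )`; every text must parse.
#' @param start_date,end_date Search window as [partial_date()]s (or strings);
#'   `end_date` may be `NULL` for open-ended.
#' @param auto_advance After a successful run, advance `start_date` to the run
#'   date so the next run only covers the gap (overridable here).
#' @param cfg A [similarity_config()].
#' @return A `run_config`.
#' @export
run_config <- function(portals, queries, start_date = NULL, end_date = NULL,
                       auto_advance = TRUE, cfg = similarity_config()) {
  stopifnot(length(portals) >= 1L, length(queries) >= 1L)
  for (q in queries) {
    stopifnot(is_nonempty_string(q$query_id), is_nonempty_string(q$text))
    parse_query(q$text)  # must parse; errors propagate with position info
  }
  if (!is.null(start_date) && !is_partial_date(start_date))
    start_date <- parse_partial_date(start_date)
  if (!is.null(end_date) && !is_partial_date(end_date))
    end_date <- parse_partial_date(end_date)
  structure(list(portals = portals, queries = queries, start_date = start_date,
                 end_date = end_date, auto_advance = isTRUE(auto_advance),
                 cfg = cfg),
            class = "run_config")
}

#' Execute one search run
#'
#' @param cfg A [run_config()].
#' @param store A [store_open()] record store.
#' @param services List with per-portal transports in `portal_clients` (named
#'   by portal), plus optional `index`, `registry`, `pdf`, `pdf_dir` as in
#'   [enrich_record()].
#' @return The closed activity-log entry (status `success`, `error` — when a
#'   whole portal failed — or `interrupted`).
#' @export
run_search <- function(cfg, store, services) {
  entry <- activity_entry("search", status = "running")
  portal_failed <- FALSE
  interrupted <- FALSE
  notes <- character()

  active <- Filter(function(p) isTRUE(p$active), cfg$portals)
  res <- tryCatch({
    for (dialect in active) {
      client <- services$portal_clients[[dialect$name]]
      portal_errors <- 0L
      for (q in cfg$queries) {
        step <- tryCatch({
          ast <- parse_query(q$text)
          hits <- withCallingHandlers(
            run_portal_search(dialect, ast, from = cfg$start_date,
                              to = cfg$end_date, client = client),
            message = function(m) invokeRestart("muffleMessage"))
          if (isTRUE(attr(hits, "skipped"))) {
            notes <- c(notes, sprintf("portal %s: scraping disabled, query %s skipped",
                                      dialect$name, q$query_id))
          }
          for (h in hits) {
            rec <- hit_to_record(h, portal = dialect$name, query_id = q$query_id,
                                 keywords = q$text,
                                 target_collection = q$target_collection %||% "default")
            up <- dedup_upsert(store, rec, cfg$cfg)
            if (!up$merged) {
              enriched <- enrich_record(store_get(store, up$record$record_id), services)
              stored <- store_get(store, enriched$record_id)
              enriched$triage <- stored$triage  # placement decided by ingest
              store_replace(store, enriched$record_id, enriched)
              ingest_record(store, store_get(store, enriched$record_id),
                            target_collection = q$target_collection %||% "default")
            }
          }
          "ok"
        },
        litscout_capability_error = function(e) conditionMessage(e),
        litscout_portal_error = function(e) { portal_errors <<- portal_errors + 1L; conditionMessage(e) },
        litscout_portal_parse_error = function(e) { portal_errors <<- portal_errors + 1L; conditionMessage(e) },
        interrupt = function(e) { interrupted <<- TRUE; "interrupted" })
        if (!identical(step, "ok")) notes <- c(notes, step)
        if (interrupted) break
      }
      if (portal_errors == length(cfg$queries) && length(cfg$queries) > 0L)
        portal_failed <- TRUE
      if (interrupted) break
    }
    TRUE
  }, interrupt = function(e) { interrupted <<- TRUE; FALSE })

  if (!interrupted && !is.null(services$registry) && !is.null(services$pdf)) {
    promoted <- recheck_inaccessible(store, services)
    if (length(promoted))
      notes <- c(notes, sprintf("%d inaccessible record(s) promoted to Evaluate",
                                length(promoted)))
  }

  status <- if (interrupted) "interrupted" else if (portal_failed) "error" else "success"
  entry <- close_activity_entry(entry, status,
                                detail = paste(notes, collapse = " | "))
  append_activity(store, entry)
  entry
}

#' Add a publication by identifier or by full fields
#'
#' The semi-manual pathway: with a PMID/PMCID/DOI the bibliographic index
#' supplies the record; with `fields` the caller supplies everything. The
#' record is deduplicated against the store (a duplicate merges — reported,
#' not an error), downloaded when possible, and ingested with a
#' `portal = "manual"` provenance hit.
#'
#' @param store A record store.
#' @param id Optional PMID, PMCID or DOI.
#' @param fields Optional named list of [article_record()] fields.
#' @param services Service list (needs `index` for id lookup; `registry`,
#'   `pdf`, `pdf_dir` for download).
#' @param cfg A [similarity_config()].
#' @return List with `record` and `merged` flag.
#' @export
add_manual <- function(store, id = NULL, fields = NULL, services = list(),
                       cfg = similarity_config()) {
  if (is.null(id) && is.null(fields))
    stop("add_manual: supply an identifier or full fields", call. = FALSE)
  if (!is.null(id)) {
    kind <- classify_identifier(id)
    res <- lookup_by_id(id, services$index)  # not-found errors propagate
    fields <- list(title = res$title %||% "", pmid = res$pmid, pmcid = res$pmcid,
                   doi = res$doi, journal = res$journal,
                   published = res$published, authors = res$authors,
                   contact_email = res$contact_email)
    if (is.null(fields[[kind]])) fields[[kind]] <- id
  }
  fields$search_hits <- list(search_hit("manual", "manual",
                                        keywords = id %||% "manual entry"))
  rec <- do.call(article_record, fields)
  up <- dedup_upsert(store, rec, cfg)
  if (!up$merged) {
    enriched <- enrich_record(store_get(store, up$record$record_id), services)
    store_replace(store, enriched$record_id, enriched)
    ingest_record(store, store_get(store, enriched$record_id))
    message("added new record ", enriched$record_id)
  } else {
    message("already known: merged into record ", up$record$record_id)
  }
  list(record = store_get(store, up$record$record_id), merged = up$merged)
}

#' Summarize the store and recent runs
#'
#' @param store A record store.
#' @param n_runs How many recent activity entries to include.
#' @return List with `counts` (per-collection, summing to `total`), `total`,
#'   and `last_runs`.
#' @export
show_status <- function(store, n_runs = 5L) {
  counts <- store_counts(store)
  runs <- utils::tail(store$activity, n_runs)
  out <- list(counts = counts, total = store_size(store), last_runs = runs)
  stopifnot(sum(counts) == out$total)  # lifecycle states partition the store
  class(out) <- "litscout_status"
  out
}

#' @export
print.litscout_status <- function(x, ...) {
  cat("records:", x$total, "\n")
  for (s in names(x$counts)) cat(sprintf("  %-13s %d\n", s, x$counts[[s]]))
  if (length(x$last_runs)) {
    cat("recent runs:\n")
    for (r in x$last_runs)
      cat(sprintf("  [%s] %s %s %s\n", r$status, r$kind %||% "run",
                  r$started, r$detail %||% ""))
  }
  invisible(x)
}
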