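#' Export a collection as RIS
#'
#' Minimal reference-manager interchange: `TY` (JOUR), `TI`, `AU` (one per
#' author), `JO`, `PY`, `DO`, closed by `ER`.
#'
#' @param store A record store.
#' @param collection Triage state or collection label, `NULL` for all.
#' @param path Output file, or `NULL` to return the lines.
#' @return The RIS lines, invisibly when written to `path`.
#' @export
export_ris <- function(store, collection = NULL, path = NULL) {
  recs <- store_query(store, collection = collection, sort_key = "title")
  lines <- unlist(lapply(recs, function(r) {
    out <- c("TY  - JOUR", paste0("TI  - ", r$title))
    out <- c(out, vapply(r$authors, function(a) paste0("AU  - ", a), ""))
    if (!empty_field(r$journal)) out <- c(out, paste0("JO  - ", r$journal))
    if (!is.null(r$published)) out <- c(out, paste0("PY  - ", r$published$year))
    if (!empty_field(r$doi)) out <- c(out, paste0("DO  - ", r$doi))
    c(out, "ER  - ", "")
  }))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Export records (with annotations) as JSON
#'
#' One object per record in the documented store schema, with the record's
#' metadata annotations attached under `annotations`.
#'
#' @inheritParams export_ris
#' @export
export_json <- function(store, collection = NULL, path = NULL) {
  recs <- store_query(store, collection = collection, sort_key = "title")
  objs <- lapply(recs, function(r) {
    x <- record_to_list(r)
    ann <- record_annotations(store, r$record_id)
    if (length(ann)) x$annotations <- ann
    x
  })
  if (is.null(path)) return(jsonlite::toJSON(objs, auto_unbox = TRUE, null = "null"))
  jsonlite::write_json(objs, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Read a run configuration file
#'
#' One YAML file declares everything a run needs: the portal dialects (keys as
#' in [portal_dialect()]), the queries (`query_id`, `text`,
#' `target_collection`), the search window, similarity thresholds and optional
#' metadata category definitions. See the packaged example
#' `system.file("extdata", "example-config.yaml", package = "litscout")`.
#'
#' @param path YAML file path.
#' @return List with `run` (a [run_config()]) and `metadata_categories`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  portals <- lapply(y$portals, function(p)
    portal_dialect(name = p$name,
                   supports_not = p$supports_not %||% TRUE,
                   word_joiner = p$word_joiner %||% " ",
                   phrase_delimiters = unlist(p$phrase_delimiters %||% c("\"", "\"")),
                   date_granularity = p$date_granularity %||% "year_month_day",
                   payload_format = p$payload_format %||% "json",
                   scraping_enabled = p$scraping_enabled %||% FALSE,
                   api_root = p$api_root %||% "mock://portal",
                   page_size = p$page_size %||% 100L,
                   active = p$active %||% TRUE))
  queries <- lapply(y$queries, function(q)
    list(query_id = as.character(q$query_id), text = q$text,
         target_collection = q$target_collection %||% "default"))
  sim <- similarity_config(
    title_match_threshold = y$similarity$title_match_threshold %||% 0.85,
    pubmed_best_match_threshold = y$similarity$pubmed_best_match_threshold %||% 0.9,
    winkler_prefix_scale = y$similarity$winkler_prefix_scale %||% 0.1,
    max_prefix_length = y$similarity$max_prefix_length %||% 4L)
  run <- run_config(portals = portals, queries = queries,
                    start_date = y$start_date, end_date = y$end_date,
                    auto_advance = y$auto_advance %||% TRUE, cfg = sim)
  list(run = run, metadata_categories = y$metadata_categories %||% list())
}
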