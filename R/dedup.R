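#' @title Duplicate detection and record merging
#' @description Recurrent searches return the same publication from several
#'   portals and at several times, often with perturbed titles and with
#'   identifiers that arrive months after publication. Each incoming record is
#'   matched against every stored record — in all collections, including
#'   Negative and Inaccessible — by three parallel methods: exact PMID/PMCID,
#'   exact DOI, and Jaro-Winkler similarity of normalized titles at or above
#'   the configured threshold (0.85 by default).
#' @name dedup
NULL

PREPRINT_SERVERS <- c("biorxiv", "medrxiv", "arxiv", "ssrn", "peerj preprints",
                      "research square", "preprints.org")

looks_preprint <- function(rec) {
  isTRUE(rec$is_preprint) ||
    (!empty_field(rec$journal) && tolower(rec$journal) %in% PREPRINT_SERVERS)
}

#' Find the stored duplicate of an incoming record, if any
#'
#' Exact identifier matches win over title similarity; PMID/PMCID is checked
#' before DOI. When no identifier matches, the highest-scoring title match at
#' or above `cfg$title_match_threshold` is returned; ties and everything below
#' threshold yield `NULL`. The scan spans all collections.
#'
#' @param incoming A valid [article_record()].
#' @param store A [store_open()] record store.
#' @param cfg A [similarity_config()].
#' @return The matching stored `article_record`, or `NULL`.
#' @export
find_duplicate <- function(incoming, store, cfg = similarity_config()) {
  for (idx in list(c("pmid", "pmid_index"), c("pmcid", "pmcid_index"))) {
    val <- incoming[[idx[1]]]
    if (!empty_field(val) && exists(val, envir = store[[idx[2]]], inherits = FALSE))
      return(store_get(store, get(val, envir = store[[idx[2]]])))
  }
  if (!empty_field(incoming$doi)) {
    key <- tolower(incoming$doi)
    if (exists(key, envir = store$doi_index, inherits = FALSE))
      return(store_get(store, get(key, envir = store$doi_index)))
  }
  if (!is_nonempty_string(incoming$title)) return(NULL)
  norm_in <- normalize_title(incoming$title)
  best <- NULL
  best_score <- -Inf
  for (id in store_ids(store)) {
    cand <- store_get(store, id)
    if (!is_nonempty_string(cand$title)) next
    s <- jaro_winkler(norm_in, normalize_title(cand$title), cfg)
    if (s >= cfg$title_match_threshold && s > best_score) {
      best <- cand
      best_score <- s
    }
  }
  best
}

#' Merge an incoming duplicate into its stored record
#'
#' Field-filling semantics: every non-empty stored field is preserved; empty
#' fields are filled from the incoming record (this is how delayed PMIDs and
#' DOIs arrive). Search hits take the set-union keyed by `(portal, query_id)`,
#' so redelivery of the same hit never grows the set. When the stored record is
#' a preprint and the incoming one is its published version (non-preprint, with
#' newly appearing identifiers or a non-preprint journal), the bibliographic
#' fields upgrade to the published values and `is_preprint` drops. Triage state
#' and annotations are never touched by merging. Two different non-empty DOIs
#' do not auto-merge silently: the stored DOI is kept and the discrepancy is
#' reported in the `conflicts` attribute of the result (and as a warning) for
#' human review.
#'
#' @param existing The stored record.
#' @param incoming The newly found duplicate.
#' @return The merged `article_record`; attribute `conflicts` lists any field
#'   discrepancies left unresolved.
#' @export
merge_records <- function(existing, incoming) {
  merged <- existing
  conflicts <- list()

  upgrade <- looks_preprint(existing) && !looks_preprint(incoming) &&
    (!empty_field(incoming$doi) || !empty_field(incoming$pmid) ||
       !empty_field(incoming$pmcid) || !empty_field(incoming$journal))

  fill <- c("pmid", "pmcid", "doi", "journal", "contact_email", "published",
            "title", "pdf_path")
  for (f in fill) {
    if (upgrade && f %in% c("pmid", "pmcid", "doi", "journal", "published") &&
        !empty_field(incoming[[f]]) && !is.null(incoming[[f]])) {
      merged[[f]] <- incoming[[f]]
      next
    }
    ex <- existing[[f]]
    inc <- incoming[[f]]
    if (empty_field(ex) && !empty_field(inc)) merged[[f]] <- inc
  }
  if (!upgrade && !empty_field(existing$doi) && !empty_field(incoming$doi) &&
      tolower(existing$doi) != tolower(incoming$doi)) {
    conflicts$doi <- c(existing = existing$doi, incoming = incoming$doi)
    warning(sprintf("DOI conflict for record %s: stored '%s' vs incoming '%s' (kept stored)",
                    existing$record_id, existing$doi, incoming$doi), call. = FALSE)
  }
  if (upgrade) merged$is_preprint <- FALSE
  if (!length(merged$authors) && length(incoming$authors))
    merged$authors <- incoming$authors
  if (empty_field(merged$full_text) && !empty_field(incoming$full_text))
    merged$full_text <- incoming$full_text

  # addToSet on (portal, query_id)
  have <- vapply(merged$search_hits, function(h) paste0(h$portal, "\r", h$query_id), "")
  for (h in incoming$search_hits) {
    key <- paste0(h$portal, "\r", h$query_id)
    if (!key %in% have) {
      merged$search_hits <- c(merged$search_hits, list(h))
      have <- c(have, key)
    }
  }
  if (!empty_field(merged$pdf_path)) merged$pdf_status <- "downloaded"
  attr(merged, "conflicts") <- conflicts
  validate_record(merged)
  merged
}

#' Best title match among candidates
#'
#' Scores every candidate with Jaro-Winkler over normalized titles and returns
#' the argmax if it reaches `cfg$pubmed_best_match_threshold` (0.9 by default —
#' the hard threshold used when a bibliographic index returns a fan of
#' synonym-expansion candidates). Ties break toward the earliest candidate.
#'
#' @param title Query title.
#' @param candidates List of records (anything with a `title` element).
#' @param cfg A [similarity_config()].
#' @return The winning candidate with attribute `match_score`, or `NULL`.
#' @export
best_title_match <- function(title, candidates, cfg = similarity_config()) {
  if (!length(candidates)) return(NULL)
  norm <- normalize_title(title)
  scores <- vapply(candidates, function(cand)
    jaro_winkler(norm, normalize_title(cand$title %||% ""), cfg), 0)
  i <- which.max(scores)  # first index on ties
  if (scores[i] < cfg$pubmed_best_match_threshold) return(NULL)
  out <- candidates[[i]]
  attr(out, "match_score") <- scores[i]
  out
}

#' Convert a portal hit into an article record with provenance
#'
#' @param hit A [raw_portal_hit()].
#' @param portal Portal name for the provenance entry.
#' @param query_id,keywords The originating query's id and text.
#' @param target_collection Label of the query's target collection.
#' @return An [article_record()] in the default (`not_attempted`) state.
#' @export
hit_to_record <- function(hit, portal = hit$source_portal, query_id = "q1",
                          keywords = "", target_collection = "default") {
  article_record(
    title = hit$title, pmid = hit$pmid, pmcid = hit$pmcid, doi = hit$doi,
    journal = hit$journal, published = hit$published, authors = hit$authors,
    contact_email = hit$contact_email, is_preprint = hit$is_preprint,
    search_hits = list(search_hit(portal, query_id, keywords)),
    target_collection = target_collection, full_text = hit$full_text)
}

#' Deduplicate-or-insert one record
#'
#' The store-level upsert: looks for a duplicate, merges into it when found
#' (keeping the stored record's triage state), inserts otherwise.
#'
#' @param store A record store.
#' @param record Incoming [article_record()].
#' @param cfg A [similarity_config()].
#' @return List with `record` (as stored) and `merged` (logical).
#' @export
dedup_upsert <- function(store, record, cfg = similarity_config()) {
  dup <- find_duplicate(record, store, cfg)
  if (is.null(dup)) {
    store_put(store, record)
    list(record = record, merged = FALSE)
  } else {
    merged <- merge_records(dup, record)
    store_replace(store, dup$record_id, merged)
    list(record = store_get(store, dup$record_id), merged = TRUE)
  }
}
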