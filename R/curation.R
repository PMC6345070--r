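#' @title Triage lifecycle and metadata annotation
#' @description Records enter the store in `Evaluate` (PDF in hand) or
#'   `Inaccessible` (download failed; retried on every later run). Curators
#'   move `Evaluate` records to `Positive`, `Negative`, or the stand-by
#'   `Review` collection (with a mandatory note); `Review` records are then
#'   resolved to `Positive` or `Negative`. No other transitions exist, apart
#'   from an explicit, logged reversal operation. Metadata annotation is typed
#'   and optionally constrained by a controlled vocabulary, validated at the
#'   operation boundary.
#' @name curation
NULL

# state -> legal verdicts (via triage_record); Inaccessible moves only through
# recheck_inaccessible, and Positive/Negative only through retriage_record.
TRIAGE_TRANSITIONS <- list(
  Evaluate = c("Positive", "Negative", "Review"),
  Review = c("Positive", "Negative"),
  Inaccessible = character(),
  Positive = character(),
  Negative = character()
)

state_error <- function(msg) {
  stop(structure(class = c("litscout_state_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Place a deduplicated record into its lifecycle collection
#'
#' New records land in `Evaluate` when their PDF downloaded and `Inaccessible`
#' otherwise. A record merged into an existing one keeps the stored triage
#' state — placement is untouched by merging.
#'
#' @param store A record store.
#' @param record A deduplicated/merged [article_record()].
#' @param target_collection Label from the originating query's configuration.
#' @return The placed record.
#' @export
ingest_record <- function(store, record, target_collection = record$target_collection) {
  record$target_collection <- target_collection
  existing <- store_get(store, record$record_id)
  fresh <- is.null(existing) || existing$triage %in% c("Evaluate", "Inaccessible")
  if (fresh) {
    record$triage <- if (identical(record$pdf_status, "downloaded")) "Evaluate" else "Inaccessible"
    record$evaluated_date <- NULL
  } else {
    record$triage <- existing$triage
    record$evaluated_date <- existing$evaluated_date
    record$triage_note <- existing$triage_note
  }
  if (is.null(existing)) store_put(store, record)
  else store_replace(store, existing$record_id, record)
  store_get(store, record$record_id)
}

#' Retry every inaccessible record
#'
#' Called during every search run: each `Inaccessible` record is re-resolved
#' and re-downloaded; successes move to `Evaluate` with their PDF attached,
#' failures stay put. Per-record errors are swallowed so the loop always
#' completes. Search provenance and annotations are preserved.
#'
#' @param store A record store.
#' @param services Service list as in [enrich_record()] (needs `registry`,
#'   `pdf`, `pdf_dir`).
#' @return List of promoted records (possibly empty).
#' @export
recheck_inaccessible <- function(store, services) {
  promoted <- list()
  for (id in store_ids(store)) {
    rec <- store_get(store, id)
    if (!identical(rec$triage, "Inaccessible")) next
    upd <- tryCatch({
      if (empty_field(rec$doi)) rec
      else {
        url <- tryCatch(resolve_pdf_url(rec$doi, services$registry),
                        error = function(e) NULL)
        attempt_download(rec, url, services$pdf, services$pdf_dir %||% tempdir())
      }
    }, error = function(e) rec)
    if (identical(upd$pdf_status, "downloaded")) {
      upd$triage <- "Evaluate"
      store_replace(store, id, upd)
      promoted <- c(promoted, list(store_get(store, id)))
    }
  }
  promoted
}

#' Record a curator's triage verdict
#'
#' Legal transitions: `Evaluate` to `Positive`/`Negative`/`Review`, and
#' `Review` to `Positive`/`Negative`. A `Review` verdict requires a note.
#' `Positive`/`Negative` set `evaluated_date`; the transition is appended to
#' the activity log with the acting user.
#'
#' @param store A record store.
#' @param record_id Record key.
#' @param verdict `"Positive"`, `"Negative"` or `"Review"`.
#' @param note Free-text note (required for `Review`).
#' @param user Curator name for the log.
#' @return The updated record.
#' @export
triage_record <- function(store, record_id, verdict, note = NULL, user = "curator") {
  rec <- store_get(store, record_id)
  if (is.null(rec)) state_error(paste("no record", record_id))
  if (!verdict %in% c("Positive", "Negative", "Review"))
    state_error(paste("invalid verdict", verdict))
  if (!verdict %in% TRIAGE_TRANSITIONS[[rec$triage]])
    state_error(sprintf("illegal transition %s -> %s for record %s",
                        rec$triage, verdict, record_id))
  if (identical(verdict, "Review") && !is_nonempty_string(note))
    stop(structure(class = c("litscout_validation_error", "error", "condition"),
                   list(message = "Review requires a note", call = NULL)))
  from_state <- rec$triage
  rec$triage <- verdict
  if (verdict %in% c("Positive", "Negative")) {
    rec$evaluated_date <- iso_now()
  } else {
    rec$evaluated_date <- NULL
  }
  if (!is.null(note)) rec$triage_note <- note
  store_replace(store, record_id, rec)
  append_activity(store, activity_entry(
    "triage", status = "success",
    detail = sprintf("%s: %s -> %s by %s", record_id, from_state, verdict, user)))
  store_get(store, record_id)
}

#' Reverse a Positive/Negative verdict (privileged)
#'
#' Ordinary triage never leaves `Positive`/`Negative`. This explicit operation
#' returns such a record to `Evaluate`, logs the reversal with the acting user,
#' and keeps a note recording the prior verdict and its timestamp.
#'
#' @inheritParams triage_record
#' @return The updated record.
#' @export
retriage_record <- function(store, record_id, user = "curator", note = NULL) {
  rec <- store_get(store, record_id)
  if (is.null(rec)) state_error(paste("no record", record_id))
  if (!rec$triage %in% c("Positive", "Negative"))
    state_error("retriage applies only to Positive/Negative records")
  prior <- sprintf("reversed %s verdict of %s", rec$triage, rec$evaluated_date)
  rec$triage <- "Evaluate"
  rec$evaluated_date <- NULL
  rec$triage_note <- paste(c(note, prior), collapse = "; ")
  store_replace(store, record_id, rec)
  append_activity(store, activity_entry(
    "retriage", status = "success",
    detail = sprintf("%s: %s by %s", record_id, prior, user)))
  store_get(store, record_id)
}

# --- metadata ---------------------------------------------------------------

METADATA_TYPES <- c("integer", "string", "boolean", "list", "set", "nested_list")

default_metadata_categories <- function() {
  list(
    IsMetadataFinished = list(name = "IsMetadataFinished", value_type = "boolean",
                              vocabulary = NULL, required = FALSE),
    Note = list(name = "Note", value_type = "string", vocabulary = NULL,
                required = FALSE)
  )
}

#' Define a metadata category
#'
#' Categories are typed (`integer`, `string`, `boolean`, `list`, `set`,
#' `nested_list`) and may carry a controlled vocabulary (meaningful for
#' string-valued kinds). Two categories exist from initialization:
#' `IsMetadataFinished` (boolean) and `Note` (free text). Names are unique;
#' redefining one is a conflict error.
#'
#' @param store A record store.
#' @param name Category name.
#' @param value_type One of the six types.
#' @param vocabulary Optional closed set of allowed atomic values.
#' @param required Is the category mandatory for finished annotation?
#' @return The category definition, invisibly.
#' @export
define_metadata_category <- function(store, name, value_type,
                                     vocabulary = NULL, required = FALSE) {
  stopifnot(is_nonempty_string(name))
  if (!value_type %in% METADATA_TYPES)
    stop("define_metadata_category: value_type must be one of ",
         paste(METADATA_TYPES, collapse = ", "), call. = FALSE)
  if (!is.null(vocabulary) && !value_type %in% c("string", "list", "set"))
    stop("define_metadata_category: vocabulary only applies to string/list/set", call. = FALSE)
  if (name %in% names(store$categories))
    stop(structure(class = c("litscout_conflict_error", "error", "condition"),
                   list(message = sprintf("metadata category '%s' already defined", name),
                        call = NULL)))
  cat_def <- list(name = name, value_type = value_type,
                  vocabulary = vocabulary, required = isTRUE(required))
  store$categories[[name]] <- cat_def
  store_save(store)
  invisible(cat_def)
}

check_metadata_value <- function(cat_def, value) {
  bad <- function(msg)
    stop(structure(class = c("litscout_validation_error", "error", "condition"),
                   list(message = sprintf("annotation '%s': %s", cat_def$name, msg),
                        call = NULL)))
  atoms <- switch(cat_def$value_type,
    integer = {
      if (!(is.numeric(value) && length(value) == 1L && value == as.integer(value)))
        bad("expected a single integer")
      value
    },
    boolean = {
      if (!(is.logical(value) && length(value) == 1L && !is.na(value)))
        bad("expected TRUE or FALSE")
      value
    },
    string = {
      if (!is_nonempty_string(value)) bad("expected a single non-empty string")
      value
    },
    list = ,
    set = {
      if (!is.character(value) || !length(value)) bad("expected a character vector")
      if (cat_def$value_type == "set" && anyDuplicated(value)) bad("set values must be unique")
      value
    },
    nested_list = {
      if (!is.list(value)) bad("expected a list of character vectors")
      unlist(value)
    })
  vocab <- cat_def$vocabulary
  if (!is.null(vocab) && length(vocab)) {
    out <- setdiff(as.character(atoms), as.character(unlist(vocab)))
    if (length(out)) bad(sprintf("value '%s' not in controlled vocabulary", out[1]))
  }
  invisible(TRUE)
}

#' Annotate a record with a metadata value
#'
#' The value is checked against the category's type and vocabulary before
#' storage; an offending atom is named in the error. A new value overwrites the
#' previous one for the same `(record, category)` pair. Annotations survive
#' merges, promotions and triage changes, since they are keyed by record id.
#'
#' @param store A record store.
#' @param record_id Record key.
#' @param category Defined category name.
#' @param value The typed value.
#' @return The stored annotation, invisibly.
#' @export
annotate_record <- function(store, record_id, category, value) {
  if (is.null(store_get(store, record_id)))
    state_error(paste("no record", record_id))
  cat_def <- store$categories[[category]]
  if (is.null(cat_def))
    stop("annotate_record: undefined category '", category, "'", call. = FALSE)
  check_metadata_value(cat_def, value)
  ann <- if (exists(record_id, envir = store$annotations, inherits = FALSE))
    get(record_id, envir = store$annotations) else list()
  ann[[category]] <- value
  assign(record_id, ann, envir = store$annotations)
  store_save(store)
  invisible(list(record_id = record_id, category = category, value = value))
}

#' Read a record's annotations
#'
#' @param store A record store.
#' @param record_id Record key.
#' @return Named list of annotation values (empty when none).
#' @export
record_annotations <- function(store, record_id) {
  if (exists(record_id, envir = store$annotations, inherits = FALSE))
    get(record_id, envir = store$annotations) else list()
}

#' Records whose metadata is not yet finished
#'
#' Convenience filter over the default `IsMetadataFinished` flag.
#'
#' @param store A record store.
#' @return Character vector of record ids.
#' @export
unfinished_records <- function(store) {
  Filter(function(id) {
    ann <- record_annotations(store, id)
    !isTRUE(ann$IsMetadataFinished)
  }, store_ids(store))
}
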