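place <- function(st, title, downloaded = TRUE, doi = NULL) {
  rec <- article_record(title = title, doi = doi,
                        pdf_status = if (downloaded) "downloaded" else "inaccessible",
                        pdf_path = if (downloaded) tempfile(fileext = ".pdf"))
  ingest_record(st, rec)
}

test_that("ingestion places downloaded records in Evaluate, failures in Inaccessible", {
  st <- store_open()
  ok <- place(st, "an accessible article")
  expect_equal(ok$triage, "Evaluate")
  no <- place(st, "a paywalled article", downloaded = FALSE)
  expect_equal(no$triage, "Inaccessible")

  # merging a duplicate of a Positive record leaves placement untouched
  pos <- place(st, "a decided article")
  triage_record(st, pos$record_id, "Positive")
  dup <- article_record(title = "a decided article",
                        search_hits = list(search_hit("two", "q9")))
  dedup_upsert(st, dup)
  ingest_record(st, litscout:::store_get(st, pos$record_id))
  expect_equal(litscout:::store_get(st, pos$record_id)$triage, "Positive")
})

test_that("only the legal lifecycle transitions are accepted, exhaustively", {
  legal <- list(Evaluate = c("Positive", "Negative", "Review"),
                Review = c("Positive", "Negative"),
                Inaccessible = character(), Positive = character(),
                Negative = character())
  verdicts <- c("Positive", "Negative", "Review")
  for (from in TRIAGE_STATES) {
    for (to in verdicts) {
      st <- store_open()
      rec <- place(st, paste("transition probe", from, to),
                   downloaded = from != "Inaccessible")
      # drive the record into the source state
      if (from == "Review") triage_record(st, rec$record_id, "Review", note = "n")
      if (from %in% c("Positive", "Negative")) triage_record(st, rec$record_id, from)
      expect_equal(litscout:::store_get(st, rec$record_id)$triage, from)

      if (to %in% legal[[from]]) {
        out <- triage_record(st, rec$record_id, to,
                             note = if (to == "Review") "deferred")
        expect_equal(out$triage, to)
        if (to %in% c("Positive", "Negative")) expect_false(is.null(out$evaluated_date))
        else expect_null(out$evaluated_date)
      } else {
        expect_error(triage_record(st, rec$record_id, to,
                                   note = if (to == "Review") "deferred"),
                     class = "litscout_state_error")
        expect_equal(litscout:::store_get(st, rec$record_id)$triage, from)
      }
      # partition invariant after every attempt
      expect_equal(sum(store_counts(st)), length(litscout:::store_ids(st)))
    }
  }
})

test_that("a Review verdict requires a note; notes are stored", {
  st <- store_open()
  rec <- place(st, "needs discussion")
  expect_error(triage_record(st, rec$record_id, "Review"),
               class = "litscout_validation_error")
  out <- triage_record(st, rec$record_id, "Review", note = "close call, ask team")
  expect_equal(out$triage, "Review")
  expect_equal(out$triage_note, "close call, ask team")
  expect_null(out$evaluated_date)
})

test_that("privileged retriage reverses a verdict and logs it", {
  st <- store_open()
  rec <- place(st, "mistakenly judged")
  triage_record(st, rec$record_id, "Negative")
  expect_error(triage_record(st, rec$record_id, "Positive"),
               class = "litscout_state_error")
  out <- retriage_record(st, rec$record_id, user = "pi")
  expect_equal(out$triage, "Evaluate")
  expect_null(out$evaluated_date)
  expect_match(out$triage_note, "reversed Negative")
  expect_match(st$activity[[length(st$activity)]]$detail, "pi")
})

test_that("rechecking inaccessible records promotes newly open articles only", {
  st <- store_open()
  dir <- withr::local_tempdir()
  dois <- sprintf("10.5/ia.%d", 1:3)
  urls <- stats::setNames(as.list(sprintf("mock://pdf/ia%d", 1:3)), dois)
  ft <- mock_fulltext_service(urls = urls, open = character())
  for (i in 1:3) {
    rec <- article_record(title = paste("locked article", i), doi = dois[i],
                          pdf_status = "inaccessible")
    ingest_record(st, rec)
  }
  annotate_record(st, litscout:::store_ids(st)[1], "Note", "seen before")

  svc <- list(registry = ft$registry, pdf = ft$pdf, pdf_dir = dir)
  expect_equal(length(recheck_inaccessible(st, svc)), 0L)

  ft$set_open("mock://pdf/ia2")
  promoted <- recheck_inaccessible(st, svc)
  expect_equal(length(promoted), 1L)
  expect_equal(promoted[[1]]$doi, "10.5/ia.2")
  expect_equal(promoted[[1]]$triage, "Evaluate")
  expect_equal(unname(store_counts(st)[c("Evaluate", "Inaccessible")]), c(1L, 2L))

  # provenance and annotations survive promotion
  first_id <- litscout:::store_ids(st)[1]
  expect_equal(record_annotations(st, first_id)$Note, "seen before")
})

test_that("metadata categories: defaults exist, duplicates conflict, types bind", {
  st <- store_open()
  expect_named(st$categories, c("IsMetadataFinished", "Note"))
  expect_error(define_metadata_category(st, "Note", "string"),
               class = "litscout_conflict_error")

  define_metadata_category(st, "Species", "string",
                           vocabulary = c("mouse", "rat", "human"))
  define_metadata_category(st, "NCells", "integer")
  define_metadata_category(st, "Regions", "set", vocabulary = c("CA1", "CA3", "DG"))
  expect_error(define_metadata_category(st, "BadVocab", "integer",
                                        vocabulary = c("x")), "vocabulary")

  rec <- place(st, "annotated article")
  annotate_record(st, rec$record_id, "Species", "mouse")
  expect_equal(record_annotations(st, rec$record_id)$Species, "mouse")

  expect_error(annotate_record(st, rec$record_id, "Species", "gerbil"),
               "gerbil")
  expect_error(annotate_record(st, rec$record_id, "NCells", "many"), "integer")
  expect_error(annotate_record(st, rec$record_id, "Regions", c("CA1", "CA1")),
               "unique")
  expect_error(annotate_record(st, rec$record_id, "Regions", c("CA1", "CA9")),
               "CA9")
  annotate_record(st, rec$record_id, "Regions", c("CA1", "DG"))
  expect_error(annotate_record(st, rec$record_id, "Undefined", 1), "undefined")

  # overwrite semantics
  annotate_record(st, rec$record_id, "Species", "rat")
  expect_equal(record_annotations(st, rec$record_id)$Species, "rat")
})

test_that("IsMetadataFinished gates the unfinished-record listing", {
  st <- store_open()
  a <- place(st, "finished one")
  b <- place(st, "unfinished one")
  annotate_record(st, a$record_id, "IsMetadataFinished", TRUE)
  left <- unfinished_records(st)
  expect_setequal(unlist(left), b$record_id)
})

test_that("annotations and categories persist across store reopen", {
  dir <- withr::local_tempdir()
  st <- store_open(dir)
  define_metadata_category(st, "Species", "string", vocabulary = c("mouse", "rat"))
  rec <- place(st, "persistent annotations")
  annotate_record(st, rec$record_id, "Species", "mouse")
  annotate_record(st, rec$record_id, "IsMetadataFinished", TRUE)

  st2 <- store_open(dir)
  expect_true("Species" %in% names(st2$categories))
  ann <- record_annotations(st2, rec$record_id)
  expect_equal(ann$Species, "mouse")
  expect_true(isTRUE(ann$IsMetadataFinished))
})
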