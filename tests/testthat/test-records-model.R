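test_that("partial dates validate, format and compare at common granularity", {
  expect_equal(format(partial_date(2016)), "2016")
  expect_equal(format(partial_date(2016, 3)), "2016-03")
  expect_equal(format(partial_date(2016, 2, 29)), "2016-02-29")
  expect_error(partial_date(2017, 2, 29), "not a valid calendar date")
  expect_error(partial_date(2016, day = 5), "requires 'month'")
  expect_error(partial_date(2016, 13), "month")

  # year-only overlaps anything inside that year, nothing outside
  expect_true(partial_date_overlaps(partial_date(2016), partial_date(2016, 6, 1)))
  expect_true(partial_date_overlaps(partial_date(2016, 6, 1), partial_date(2016)))
  expect_false(partial_date_overlaps(partial_date(2015, 6), partial_date(2016)))

  expect_true(partial_date_in_range(partial_date(2016),
                                    parse_partial_date("2016-03"),
                                    parse_partial_date("2016-09")))
  expect_false(partial_date_in_range(partial_date(2015, 6),
                                     parse_partial_date("2016-01"),
                                     parse_partial_date("2016-12")))
  # inclusive boundaries
  expect_true(partial_date_in_range(partial_date(2016, 1, 1),
                                    partial_date(2016, 1, 1),
                                    partial_date(2016, 1, 1)))
})

test_that("article records enforce their invariants with named fields", {
  r <- article_record(title = "Only a title")
  expect_equal(r$pdf_status, "not_attempted")
  expect_equal(r$triage, "Evaluate")

  expect_error(article_record(title = ""), "title")
  expect_error(article_record(title = "x", pdf_status = "downloaded"), "pdf_path")
  expect_error(article_record(title = "x", triage = "Review"), "note")
  expect_error(article_record(title = "x", triage = "Positive"), "evaluated_date")
  dup_hits <- list(search_hit("p", "q1"), search_hit("p", "q1"))
  expect_error(article_record(title = "x", search_hits = dup_hits),
               "duplicate \\(portal, query_id\\)")
  # identifier-only records are fine
  expect_silent(article_record(doi = "10.1/x"))
})

test_that("record ids are deterministic content hashes", {
  a <- article_record(title = "Some Title", doi = "10.1/abc")
  b <- article_record(title = "  some  TITLE ", doi = "10.1/ABC")
  expect_identical(a$record_id, b$record_id)
  c <- article_record(title = "Some Title", doi = "10.1/other")
  expect_false(identical(a$record_id, c$record_id))
})

test_that("a put store round-trips records field-identically across reopen", {
  dir <- withr::local_tempdir()
  st <- store_open(dir)
  set.seed(42)
  originals <- lapply(1:100, function(i) {
    article_record(
      title = paste("Article", i, paste(sample(letters, 6), collapse = "")),
      doi = sprintf("10.9999/rt.%03d", i),
      pmid = if (i %% 3 == 0) as.character(20000000 + i) else NULL,
      journal = sample(c("J One", "J Two"), 1),
      published = partial_date(2010 + i %% 9,
                               month = if (i %% 2 == 0) (i %% 12) + 1 else NULL),
      authors = c("A Author", "B Author"),
      is_preprint = i %% 10 == 0)
  })
  for (r in originals) store_put(st, r)

  st2 <- store_open(dir)
  expect_equal(length(litscout:::store_ids(st2)), 100L)
  for (r in originals) {
    got <- litscout:::store_get(st2, r$record_id)
    expect_false(is.null(got))
    expect_identical(got$title, r$title)
    expect_identical(got$doi, r$doi)
    expect_identical(got$pmid, r$pmid)
    expect_identical(got$authors, r$authors)
    expect_identical(got$is_preprint, r$is_preprint)
    expect_identical(format(got$published), format(r$published))
  }
})

test_that("store_query sorts stably, filters conjunctively and rejects unknown keys", {
  st <- store_open()
  store_put(st, article_record(title = "zeta study", authors = "Maria Ascoli",
                               doi = "10.1/z"))
  store_put(st, article_record(title = "Alpha study", authors = "John Smith",
                               doi = "10.1/a"))
  store_put(st, article_record(title = "midway study", authors = "Jane Ascot",
                               doi = "10.1/m"))

  titles <- vapply(store_query(st, sort_key = "title"), `[[`, "", "title")
  expect_equal(titles, c("Alpha study", "midway study", "zeta study"))

  hits <- store_query(st, filters = list(author = "Asc"))
  expect_setequal(vapply(hits, `[[`, "", "title"), c("zeta study", "midway study"))
  hits2 <- store_query(st, filters = list(author = "Asc", title = "zeta"))
  expect_equal(length(hits2), 1L)

  expect_error(store_query(st, sort_key = "nope"), "sort_key")
  expect_error(store_query(st, filters = list(color = "red")), "filter")
})

test_that("pagination covers each record exactly once with half-open pages", {
  st <- store_open()
  for (i in 1:5) store_put(st, article_record(title = paste("rec", i),
                                              doi = sprintf("10.1/p%d", i)))
  pages <- lapply(0:2, function(p) store_query(st, sort_key = "title",
                                               page = p, page_size = 2L))
  expect_equal(lengths(pages), c(2L, 2L, 1L))
  ids <- unlist(lapply(pages, function(pg) vapply(pg, `[[`, "", "record_id")))
  expect_equal(length(ids), 5L)
  expect_false(anyDuplicated(ids) > 0)

  # property: any sort key, any page size, full coverage with no overlap
  for (sk in c("published", "identifier", "title", "found_date")) {
    got <- character()
    p <- 0L
    repeat {
      pg <- store_query(st, sort_key = sk, page = p, page_size = 3L)
      if (!length(pg)) break
      got <- c(got, vapply(pg, `[[`, "", "record_id"))
      p <- p + 1L
    }
    expect_setequal(got, litscout:::store_ids(st))
    expect_equal(length(got), 5L)
  }
})

test_that("reset empties all three stores only when confirmed, and logs", {
  dir <- withr::local_tempdir()
  st <- store_open(dir)
  for (i in 1:10) store_put(st, article_record(title = paste("r", i),
                                               doi = sprintf("10.1/rst%d", i)))
  define_metadata_category(st, "Species", "string", vocabulary = c("mouse", "rat"))
  st$portals <- list(list(name = "one"))

  expect_error(store_reset(st, confirm = FALSE), "confirm")
  expect_equal(length(litscout:::store_ids(st)), 10L)

  n_log_before <- length(st$activity)
  store_reset(st, confirm = TRUE)
  expect_equal(length(store_query(st)), 0L)
  expect_equal(length(st$portals), 0L)
  expect_named(st$categories, c("IsMetadataFinished", "Note"))
  expect_equal(length(st$activity), n_log_before + 1L)
  last <- st$activity[[length(st$activity)]]
  expect_equal(last$status, "success")
})
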