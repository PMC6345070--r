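test_that("the two-portal three-query scenario yields 6 unique records, 5+1", {
  fx <- fixture_scenario()
  dialects <- fixture_dialects()
  st <- store_open()
  svc <- fixture_services(fx, dialects, pdf_dir = withr::local_tempdir())
  cfg <- fixture_run_config(dialects)

  entry <- run_search(cfg, st, svc)
  expect_equal(entry$status, "success")

  counts <- store_counts(st)
  expect_equal(sum(counts), fx$n_unique)
  expect_equal(unname(counts["Evaluate"]), fx$n_evaluate)
  expect_equal(unname(counts["Inaccessible"]), fx$n_inaccessible)

  # the two cross-portal duplicates carry one hit per portal
  n_hits <- vapply(store_query(st), function(r) length(r$search_hits), 0L)
  expect_equal(sum(n_hits == 2L), 2L)
  expect_equal(sum(n_hits), 8L)

  # the paywalled record is the inaccessible one
  ia <- store_query(st, collection = "Inaccessible")
  expect_equal(ia[[1]]$doi, fx$paywalled_doi)
})

test_that("rerunning an identical scenario is a store no-op", {
  fx <- fixture_scenario()
  dialects <- fixture_dialects()
  st <- store_open()
  svc <- fixture_services(fx, dialects, pdf_dir = withr::local_tempdir())
  cfg <- fixture_run_config(dialects)

  run_search(cfg, st, svc)
  snapshot <- lapply(store_query(st, sort_key = "title"), function(r) {
    r$found_date <- NULL  # timestamps aside, fields must be identical
    lapply(r$search_hits, function(h) h$hit_date <- NULL)
    r
  })
  run_search(cfg, st, svc)
  snapshot2 <- lapply(store_query(st, sort_key = "title"), function(r) {
    r$found_date <- NULL
    lapply(r$search_hits, function(h) h$hit_date <- NULL)
    r
  })
  expect_equal(length(snapshot2), length(snapshot))
  for (i in seq_along(snapshot)) {
    expect_identical(snapshot2[[i]]$record_id, snapshot[[i]]$record_id)
    expect_identical(snapshot2[[i]]$title, snapshot[[i]]$title)
    expect_identical(snapshot2[[i]]$triage, snapshot[[i]]$triage)
    expect_identical(length(snapshot2[[i]]$search_hits),
                     length(snapshot[[i]]$search_hits))
  }
})

test_that("the paywalled record is promoted once the portal flips open access", {
  fx <- fixture_scenario()
  dialects <- fixture_dialects()
  st <- store_open()
  svc <- fixture_services(fx, dialects, pdf_dir = withr::local_tempdir())
  run_search(fixture_run_config(dialects), st, svc)
  expect_equal(unname(store_counts(st)["Inaccessible"]), 1L)

  svc$fulltext$set_open(fx$urls[[fx$paywalled_doi]])
  run_search(fixture_run_config(dialects), st, svc)
  counts <- store_counts(st)
  expect_equal(unname(counts["Inaccessible"]), 0L)
  expect_equal(unname(counts["Evaluate"]), fx$n_unique)
})

test_that("zero-match queries finish successfully with an empty delta", {
  dialects <- fixture_dialects()
  fx <- fixture_scenario()
  st <- store_open()
  svc <- fixture_services(fx, dialects, pdf_dir = withr::local_tempdir())
  cfg <- run_config(portals = dialects,
                    queries = list(list(query_id = "q0", text = "xylophone",
                                        target_collection = "main")))
  entry <- run_search(cfg, st, svc)
  expect_equal(entry$status, "success")
  expect_equal(length(litscout:::store_ids(st)), 0L)
})

test_that("a failing portal is logged as error while the other completes", {
  fx <- fixture_scenario()
  dialects <- fixture_dialects()
  st <- store_open()
  svc <- fixture_services(fx, dialects, pdf_dir = withr::local_tempdir())
  svc$portal_clients$two <- mock_portal_client(fx$portal_two, dialects$two,
                                               fail_with = "refused")
  entry <- run_search(fixture_run_config(dialects), st, svc)
  expect_equal(entry$status, "error")
  # portal one still contributed its four articles
  expect_equal(length(litscout:::store_ids(st)), 4L)
  expect_match(entry$detail, "refused")
})

test_that("every run writes exactly one terminal activity entry", {
  fx <- fixture_scenario()
  dialects <- fixture_dialects()
  st <- store_open()
  svc <- fixture_services(fx, dialects, pdf_dir = withr::local_tempdir())
  n0 <- length(st$activity)
  run_search(fixture_run_config(dialects), st, svc)
  runs <- Filter(function(e) identical(e$kind, "search"), st$activity)
  expect_equal(length(runs), 1L)
  expect_true(runs[[1]]$status %in% c("success", "error", "interrupted"))
  expect_false(is.null(runs[[1]]$ended))
})

test_that("manual additions dedupe, enrich and ingest with manual provenance", {
  fx <- fixture_scenario()
  dialects <- fixture_dialects()
  st <- store_open()
  svc <- fixture_services(fx, dialects, pdf_dir = withr::local_tempdir())
  run_search(fixture_run_config(dialects), st, svc)
  n_before <- length(litscout:::store_ids(st))

  # index over the fixture articles for id lookup
  idx <- mock_bibliographic_index(lapply(fx$portal_one, function(a)
    list(title = a$title, doi = a$doi, journal = a$journal,
         published = format(a$published), authors = a$authors)))
  svc$index <- idx

  # a DOI already in the store merges instead of inserting
  known_doi <- fx$portal_one[[1]]$doi
  expect_message(out <- add_manual(st, id = known_doi, services = svc), "merged")
  expect_true(out$merged)
  expect_equal(length(litscout:::store_ids(st)), n_before)
  expect_true(any(vapply(out$record$search_hits,
                         function(h) h$portal == "manual", TRUE)))

  # unknown PMID -> not-found, nothing stored
  expect_error(add_manual(st, id = "99999999", services = svc),
               class = "litscout_not_found_error")
  expect_equal(length(litscout:::store_ids(st)), n_before)

  # fully manual fields insert a new Evaluate record when a PDF is in hand
  pdf <- withr::local_tempfile(fileext = ".pdf"); writeLines("x", pdf)
  out2 <- add_manual(st, fields = list(title = "a hand-entered report",
                                       pdf_status = "downloaded", pdf_path = pdf),
                     services = list())
  expect_false(out2$merged)
  expect_equal(out2$record$triage, "Evaluate")
})

test_that("status counts always sum to the store size", {
  fx <- fixture_scenario()
  dialects <- fixture_dialects()
  st <- store_open()
  expect_equal(show_status(st)$total, 0L)
  expect_true(all(show_status(st)$counts == 0L))

  svc <- fixture_services(fx, dialects, pdf_dir = withr::local_tempdir())
  run_search(fixture_run_config(dialects), st, svc)
  s <- show_status(st)
  expect_equal(unname(s$counts[c("Evaluate", "Inaccessible")]), c(5L, 1L))
  expect_equal(sum(s$counts), s$total)

  # fuzz: random triage walks keep the partition intact
  set.seed(77)
  for (i in 1:25) {
    ids <- litscout:::store_ids(st)
    id <- sample(ids, 1)
    rec <- litscout:::store_get(st, id)
    v <- sample(c("Positive", "Negative", "Review"), 1)
    try(triage_record(st, id, v, note = "fuzz"), silent = TRUE)
    s <- show_status(st)
    expect_equal(sum(s$counts), s$total)
  }
})

test_that("run configs insist on parseable queries and a portal", {
  d <- portal_dialect("one")
  expect_error(run_config(portals = list(), queries = list(list(query_id = "q", text = "a"))))
  expect_error(run_config(portals = list(d),
                          queries = list(list(query_id = "q", text = "a AND ("))),
               class = "litscout_parse_error")
  cfg <- run_config(portals = list(d),
                    queries = list(list(query_id = "q", text = "a AND b")),
                    start_date = "2016", end_date = "2018-06")
  expect_s3_class(cfg$start_date, "partial_date")
})

test_that("exports carry the expected reference fields", {
  st <- store_open()
  rec <- article_record(title = "exported article", doi = "10.2/exp",
                        journal = "J Exp", authors = c("A One", "B Two"),
                        published = "2017")
  store_put(st, rec)
  ris <- export_ris(st)
  expect_true(any(grepl("^TI  - exported article$", ris)))
  expect_equal(sum(grepl("^AU  - ", ris)), 2L)
  expect_true(any(grepl("^PY  - 2017$", ris)))
  expect_true(any(grepl("^ER  -", ris)))

  define_metadata_category(st, "Species", "string")
  annotate_record(st, rec$record_id, "Species", "mouse")
  j <- jsonlite::fromJSON(export_json(st), simplifyVector = FALSE)
  expect_equal(j[[1]]$annotations$Species, "mouse")
})
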