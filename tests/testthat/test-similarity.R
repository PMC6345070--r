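test_that("title normalization folds case, accents and whitespace, idempotently", {
  expect_equal(normalize_title("Neuronal  Morphology"), "neuronal morphology")
  expect_equal(normalize_title("Dendritic café"), "dendritic cafe")
  expect_equal(normalize_title("  \tSpaced  out \n"), normalize_title("Spaced  out"))
  expect_equal(normalize_title("gránule CÉLLS"), "granule cells")

  set.seed(11)
  pool <- c(letters, LETTERS, " ", "  ", "\t", "é", "ü", "Ñ", ".", "-")
  for (i in 1:1000) {
    s <- paste0(sample(pool, sample(0:25, 1), replace = TRUE), collapse = "")
    n1 <- normalize_title(s)
    expect_identical(normalize_title(n1), n1)
  }
})

test_that("jaro reproduces the hand-computed reference pairs", {
  # MARTHA/MARHTA: m = 6, t = 1 -> (1 + 1 + 5/6)/3
  expect_equal(jaro("MARTHA", "MARHTA"), (1 + 1 + 5 / 6) / 3, tolerance = 1e-12)
  expect_equal(round(jaro("MARTHA", "MARHTA"), 4), 0.9444)
  # DIXON/DICKSONX: m = 4, t = 0
  expect_equal(round(jaro("DIXON", "DICKSONX"), 4), 0.7667)
  expect_equal(jaro("abc", "abc"), 1)
  expect_equal(jaro("", "abc"), 0)
  expect_equal(jaro("", ""), 1)
})

test_that("jaro_winkler reproduces the hand-computed values and prefix rules", {
  # l = 3 common prefix, p = 0.1
  jw <- jaro_winkler("MARTHA", "MARHTA")
  expect_equal(round(jw, 4), 0.9611)
  expect_equal(jw, jaro("MARTHA", "MARHTA") + 3 * 0.1 * (1 - jaro("MARTHA", "MARHTA")),
               tolerance = 1e-12)
  # zero common prefix -> identical to jaro
  expect_equal(jaro_winkler("XMARTHA", "MARHTA"), jaro("XMARTHA", "MARHTA"))
  # prefix cap at 4
  cfg <- similarity_config()
  expect_equal(litscout:::common_prefix_length("abcdef", "abcdxx", cfg$max_prefix_length), 4L)
})

test_that("similarity functions are symmetric, bounded and discriminate equality", {
  set.seed(22)
  for (i in 1:300) {
    s1 <- rand_string()
    s2 <- if (i %% 5 == 0) s1 else rand_string()
    j <- jaro(s1, s2)
    jw <- jaro_winkler(s1, s2)
    expect_gte(j, 0); expect_lte(j, 1)
    expect_gte(jw, j)
    expect_lte(jw, 1)
    expect_equal(j, jaro(s2, s1), tolerance = 1e-15)
    expect_equal(jw, jaro_winkler(s2, s1), tolerance = 1e-15)
    if (identical(s1, s2)) expect_equal(jw, 1)
    if (jw == 1 && nchar(s1) > 0) expect_identical(s1, s2)
  }
})

test_that("implementation matches the brute-force oracle on random pairs", {
  set.seed(33)
  for (i in 1:1000) {
    s1 <- rand_string(0, 14)
    s2 <- rand_string(0, 14)
    expect_equal(jaro(s1, s2), oracle_jaro(s1, s2), tolerance = 1e-12,
                 label = sprintf("jaro('%s','%s')", s1, s2))
    expect_equal(jaro_winkler(s1, s2), oracle_jaro_winkler(s1, s2),
                 tolerance = 1e-12,
                 label = sprintf("jw('%s','%s')", s1, s2))
  }
})

test_that("find_duplicate spans every collection and prioritizes identifiers", {
  st <- store_open()
  neg <- article_record(title = "an archived negative result", doi = "10.7/neg",
                        triage = "Negative", evaluated_date = litscout:::iso_now())
  store_put(st, neg)
  inc <- article_record(title = "completely different words here", doi = "10.7/neg")
  expect_identical(find_duplicate(inc, st)$record_id, neg$record_id)

  # title-only match across accent/spacing perturbation
  store_put(st, article_record(title = "quantitative granule cell reconstruction atlas",
                               doi = "10.7/t1"))
  probe <- article_record(title = "Quantitative  gránule cell reconstruction atlas")
  hit <- find_duplicate(probe, st)
  expect_false(is.null(hit))
  expect_identical(hit$doi, "10.7/t1")

  # unrelated record matches nothing
  none <- find_duplicate(article_record(title = "zebra crossing acoustics",
                                        doi = "10.7/none"), st)
  expect_null(none)

  # identifier match wins over a higher-similarity title elsewhere
  store_put(st, article_record(title = "alpha beta gamma delta", pmid = "123"))
  by_id <- find_duplicate(article_record(title = "quantitative granule cell reconstruction atlas",
                                         pmid = "123"), st)
  expect_identical(by_id$pmid, "123")
})

test_that("merge fills missing fields, unions hits and preserves triage", {
  ex <- article_record(title = "stored record", doi = "10.8/m1",
                       search_hits = list(search_hit("one", "q1")))
  inc <- article_record(title = "stored record", doi = "10.8/m1",
                        pmid = "555", contact_email = "a@b.org",
                        published = "2017-05",
                        search_hits = list(search_hit("two", "q1")))
  m <- merge_records(ex, inc)
  expect_equal(m$pmid, "555")
  expect_equal(m$contact_email, "a@b.org")
  expect_equal(format(m$published), "2017-05")
  expect_equal(length(m$search_hits), 2L)

  # idempotent and absorbing
  again <- merge_records(m, inc)
  expect_equal(length(again$search_hits), 2L)
  expect_identical(again$pmid, m$pmid)
  self <- merge_records(ex, ex)
  expect_equal(length(self$search_hits), length(ex$search_hits))

  # same (portal, query_id) delivered twice does not grow the set
  rep_hit <- article_record(title = "stored record",
                            search_hits = list(search_hit("one", "q1", "again")))
  expect_equal(length(merge_records(ex, rep_hit)$search_hits), 1L)
})

test_that("a preprint upgrades to its published version on merge", {
  pre <- article_record(title = "early findings on spine turnover",
                        journal = "bioRxiv", is_preprint = TRUE,
                        doi = "10.1101/2017.001")
  pub <- article_record(title = "early findings on spine turnover",
                        journal = "eLife", doi = "10.7554/el.100", pmid = "999",
                        published = "2018-02")
  m <- merge_records(pre, pub)
  expect_false(m$is_preprint)
  expect_equal(m$journal, "eLife")
  expect_equal(m$doi, "10.7554/el.100")
  expect_equal(m$pmid, "999")
})

test_that("conflicting DOIs are surfaced, not silently overwritten", {
  ex <- article_record(title = "conflicted record", doi = "10.9/a")
  inc <- article_record(title = "conflicted record", doi = "10.9/b")
  expect_warning(m <- merge_records(ex, inc), "DOI conflict")
  expect_equal(m$doi, "10.9/a")
  expect_named(attr(m, "conflicts"), "doi")
})

test_that("best_title_match is the thresholded argmax with earliest-tie break", {
  cfg <- similarity_config()
  cands <- list(list(title = "unrelated candidate one"),
                list(title = "neuronal reconstruction of cortical cells"),
                list(title = "another decoy title entirely"))
  hit <- best_title_match("Neuronal reconstruction of cortical cells", cands, cfg)
  expect_identical(hit$title, cands[[2]]$title)
  expect_equal(attr(hit, "match_score"), 1)

  expect_null(best_title_match("completely novel phrasing", cands, cfg))
  expect_null(best_title_match("anything", list(), cfg))

  # agreement with exhaustive scoring on 100 random candidate sets
  set.seed(44)
  for (i in 1:100) {
    cs <- lapply(1:5, function(j) list(title = rand_document(sample(3:8, 1))))
    q <- rand_document(5)
    got <- best_title_match(q, cs, cfg)
    scores <- vapply(cs, function(cand)
      jaro_winkler(normalize_title(q), normalize_title(cand$title), cfg), 0)
    if (max(scores) >= cfg$pubmed_best_match_threshold) {
      expect_identical(got$title, cs[[which.max(scores)]]$title)
    } else {
      expect_null(got)
    }
  }
})

test_that("default thresholds are 0.85 for dedup and 0.9 for index matching", {
  cfg <- similarity_config()
  expect_identical(cfg$title_match_threshold, 0.85)
  expect_identical(cfg$pubmed_best_match_threshold, 0.9)
  expect_identical(cfg$winkler_prefix_scale, 0.1)
  expect_identical(cfg$max_prefix_length, 4L)
})
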