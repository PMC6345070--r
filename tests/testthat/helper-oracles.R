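`%||%` <- function(a, b) if (is.null(a)) b else a

corpus_words <- function(cc) unique(unlist(lapply(cc$articles, `[[`, "keywords")))

# Independent oracles, deliberately written in a different style from the
# package code (scalar while/for loops transliterated from the textbook
# definitions) so agreement is a genuine cross-check.

# Jaro similarity, brute force: explicit double loop over the match window,
# then transposition count over the two matched-character sequences.
oracle_jaro <- function(s1, s2) {
  a <- utf8ToInt(s1)
  b <- utf8ToInt(s2)
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0 && n2 == 0) return(1)
  if (n1 == 0 || n2 == 0) return(0)
  win <- floor(max(n1, n2) / 2) - 1
  if (win < 0) win <- 0
  m1 <- logical(n1)
  m2 <- logical(n2)
  for (i in 1:n1) {
    j <- max(1, i - win)
    while (j <= min(n2, i + win)) {
      if (!m2[j] && a[i] == b[j]) {
        m1[i] <- TRUE
        m2[j] <- TRUE
        break
      }
      j <- j + 1
    }
  }
  m <- sum(m1)
  if (m == 0) return(0)
  sa <- a[m1]
  sb <- b[m2]
  t <- 0
  for (k in seq_len(m)) if (sa[k] != sb[k]) t <- t + 1
  t <- t / 2
  (m / n1 + m / n2 + (m - t) / m) / 3
}

oracle_jaro_winkler <- function(s1, s2, p = 0.1, max_l = 4) {
  j <- oracle_jaro(s1, s2)
  a <- utf8ToInt(s1)
  b <- utf8ToInt(s2)
  l <- 0
  while (l < min(length(a), length(b), max_l) && a[l + 1] == b[l + 1]) l <- l + 1
  j + l * p * (1 - j)
}

# Brute-force Boolean query evaluator: enumerate leaf matches on a tokenized
# document, then fold the operators. Documents handed to it are built from
# space-separated word tokens, where word-level matching is exact.
oracle_evaluate <- function(ast, text, lemma_expansion = FALSE) {
  words <- tolower(strsplit(trimws(gsub("[[:space:]]+", " ", text)), " ")[[1]])
  match_leaf <- function(node) {
    if (node$kind == "PHRASE") {
      needle <- tolower(strsplit(gsub("[[:space:]]+", " ", node$text), " ")[[1]])
      k <- length(needle)
      if (k == 0 || k > length(words)) return(FALSE)
      for (start in 1:(length(words) - k + 1)) {
        if (all(words[start:(start + k - 1)] == needle)) return(TRUE)
      }
      return(FALSE)
    }
    variants <- tolower(if (lemma_expansion) litscout::expand_lemma(node$text) else node$text)
    any(words %in% variants)
  }
  recurse <- function(node) {
    if (node$kind %in% c("TERM", "PHRASE")) return(match_leaf(node))
    if (node$kind == "NOT") return(!recurse(node$children[[1]]))
    vals <- vapply(node$children, recurse, logical(1))
    if (node$kind == "AND") all(vals) else any(vals)
  }
  recurse(ast)
}

# --- random generators (fixed alphabets, driven by the caller's seed) -------

rand_string <- function(min_len = 0, max_len = 12,
                        alphabet = c(LETTERS[1:8], letters[1:6], " ")) {
  n <- sample(min_len:max_len, 1)
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

QUERY_WORDS <- c("neuron", "neurons", "dendrite", "axon", "morphology",
                 "reconstruction", "tracing", "cortex", "mouse", "imaging",
                 "branch", "branches", "spine", "soma")

rand_ast <- function(depth = 3) {
  if (depth == 0 || stats::runif(1) < 0.4) {
    if (stats::runif(1) < 0.3) {
      n <- sample(2:3, 1)
      return(litscout:::query_node("PHRASE",
                                   text = paste(sample(QUERY_WORDS, n), collapse = " ")))
    }
    return(litscout:::query_node("TERM", text = sample(QUERY_WORDS, 1)))
  }
  kind <- sample(c("AND", "OR", "NOT"), 1, prob = c(0.4, 0.4, 0.2))
  if (kind == "NOT")
    return(litscout:::query_node("NOT", children = list(rand_ast(depth - 1))))
  n <- sample(2:3, 1)
  litscout:::query_node(kind, children = lapply(seq_len(n),
                                                function(i) rand_ast(depth - 1)))
}

rand_document <- function(n_words = 30) {
  paste(sample(QUERY_WORDS, n_words, replace = TRUE), collapse = " ")
}

ast_equal <- function(a, b) {
  if (a$kind != b$kind) return(FALSE)
  if (a$kind %in% c("TERM", "PHRASE")) return(identical(a$text, b$text))
  if (length(a$children) != length(b$children)) return(FALSE)
  all(vapply(seq_along(a$children),
             function(i) ast_equal(a$children[[i]], b$children[[i]]), logical(1)))
}

# A tiny hand-built multi-portal scenario: 8 articles across 2 portals, the
# first two present on both (cross-portal duplicates, second sighting with a
# perturbed title and without identifiers), one paywalled. Used by the
# orchestration tests and the acceptance checks.
fixture_scenario <- function() {
  mk <- function(i, title, kw, doi = sprintf("10.5555/fx.%d", i), pmid = NULL,
                 journal = "Neuroinformatics", year = 2017) {
    list(base_id = sprintf("F%02d", i), title = title, doi = doi, pmid = pmid,
         journal = journal, published = litscout::partial_date(year, (i %% 12) + 1),
         authors = c("Ada Lovelace", "Santiago Ramon"),
         full_text = paste(title, "- methods used", kw, "throughout the study."),
         is_preprint = FALSE)
  }
  a1 <- mk(1, "automated dendritic reconstruction of cortical interneurons", "sholl analysis")
  a2 <- mk(2, "comparative morphology atlas of hippocampal granule cells", "sholl analysis")
  a3 <- mk(3, "longitudinal imaging of axonal regeneration in zebrafish", "patch clamp")
  a4 <- mk(4, "quantitative branching statistics for purkinje arbors", "patch clamp")
  a5 <- mk(5, "synaptic connectivity mapping in the mouse retina", "tracing protocol")
  a6 <- mk(6, "a database pipeline for neuronal morphology curation", "tracing protocol")

  # duplicate sightings on portal two: accented/truncated titles, ids missing
  dup1 <- a1
  dup1$title <- "automated dendritic reconstruction of cortical interneur"  # trimmed
  dup1$doi <- NULL
  dup2 <- a2
  dup2$title <- "comparative morphology atlas of hippocampal gránule cells"
  dup2$doi <- NULL

  portal_one <- list(a1, a2, a3, a4)
  portal_two <- list(dup1, dup2, a5, a6)
  paywalled_doi <- a6$doi

  base6 <- list(a1, a2, a3, a4, a5, a6)
  urls <- stats::setNames(
    as.list(sprintf("mock://pdf/%s", vapply(base6, `[[`, "", "doi"))),
    vapply(base6, `[[`, "", "doi"))
  open <- unlist(urls[setdiff(names(urls), paywalled_doi)], use.names = FALSE)

  list(portal_one = portal_one, portal_two = portal_two,
       urls = urls, open = open, paywalled_doi = paywalled_doi,
       n_unique = 6L, n_evaluate = 5L, n_inaccessible = 1L)
}

fixture_services <- function(fx, dialects, pdf_dir = tempfile("pdfs")) {
  ft <- litscout::mock_fulltext_service(urls = fx$urls, open = fx$open)
  list(
    portal_clients = list(
      one = litscout::mock_portal_client(fx$portal_one, dialects$one),
      two = litscout::mock_portal_client(fx$portal_two, dialects$two)),
    registry = ft$registry, pdf = ft$pdf, pdf_dir = pdf_dir,
    fulltext = ft)
}

fixture_run_config <- function(dialects) {
  litscout::run_config(
    portals = dialects,
    queries = list(
      list(query_id = "q1", text = '"sholl analysis"', target_collection = "main"),
      list(query_id = "q2", text = '"patch clamp"', target_collection = "main"),
      list(query_id = "q3", text = '"tracing protocol"', target_collection = "main")))
}

fixture_dialects <- function() {
  list(one = litscout::portal_dialect("one", payload_format = "json"),
       two = litscout::portal_dialect("two", payload_format = "xml", word_joiner = "+"))
}
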