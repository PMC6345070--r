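#' @title Synthetic multi-portal corpus generation
#' @description Deterministic generator of article corpora with known duplicate
#'   ground truth, emulating the phenomena a crawler meets in the wild:
#'   cross-portal duplicates whose titles differ by special-character variants,
#'   trailing truncation, whitespace and case; paywalled articles; preprints
#'   later joined by their published version; and identifiers (PMIDs) that are
#'   assigned months after publication. Perturbations are similarity-bounded:
#'   within a duplicate group every title pair scores at or above the dedup
#'   threshold, and across groups every pair scores below it — verified at
#'   generation time with bounded retries, so downstream tests are sharp rather
#'   than probabilistic.
#' @name corpus
NULL

#' Specification of a synthetic corpus
#'
#' @param n_articles Number of distinct publications.
#' @param portals Portal names articles are distributed over.
#' @param duplicate_rate Fraction of articles present on two or more portals.
#' @param perturbation_kinds Subset of `special_chars`, `truncation`,
#'   `whitespace`, `case` applied to duplicate variants.
#' @param truncation_length Cut length for the `truncation` kind.
#' @param paywalled_rate Fraction of articles whose PDF is initially denied.
#' @param preprint_rate Fraction of articles first seen as preprints.
#' @param delayed_pmid_rate Fraction of articles whose PMID has not been
#'   assigned yet at search time.
#' @param seed Integer seed; the same `(spec, seed)` yields an identical
#'   corpus.
#' @return A `corpus_spec`.
#' @export
corpus_spec <- function(n_articles = 20L,
                        portals = c("alpha", "beta"),
                        duplicate_rate = 0.2,
                        perturbation_kinds = c("special_chars", "truncation",
                                               "whitespace", "case"),
                        truncation_length = 60L,
                        paywalled_rate = 0.1,
                        preprint_rate = 0.1,
                        delayed_pmid_rate = 0.2,
                        seed = 1L) {
  rates <- c(duplicate_rate, paywalled_rate, preprint_rate, delayed_pmid_rate)
  stopifnot(n_articles >= 1L, all(rates >= 0), all(rates <= 1),
            length(portals) >= 1L,
            all(perturbation_kinds %in% c("special_chars", "truncation",
                                          "whitespace", "case")))
  structure(list(n_articles = as.integer(n_articles), portals = portals,
                 duplicate_rate = duplicate_rate,
                 perturbation_kinds = perturbation_kinds,
                 truncation_length = as.integer(truncation_length),
                 paywalled_rate = paywalled_rate, preprint_rate = preprint_rate,
                 delayed_pmid_rate = delayed_pmid_rate, seed = as.integer(seed)),
            class = "corpus_spec")
}

# Word bank for titles and method-section sentences. Titles draw without
# replacement per corpus position so distinct articles share few words.
corpus_word_bank <- function() {
  c("neuronal", "dendritic", "axonal", "cortical", "hippocampal", "cerebellar",
    "morphology", "reconstruction", "arborization", "topology", "branching",
    "imaging", "microscopy", "tracing", "segmentation", "quantification",
    "pyramidal", "granule", "purkinje", "interneuron", "motoneuron", "glial",
    "mouse", "rat", "human", "zebrafish", "drosophila", "macaque",
    "development", "plasticity", "regeneration", "degeneration", "connectivity",
    "network", "circuit", "synapse", "spine", "soma", "neurite", "filament",
    "automated", "comparative", "longitudinal", "quantitative", "statistical",
    "analysis", "atlas", "database", "pipeline", "framework", "algorithm",
    "classification", "clustering", "modeling", "simulation", "visualization",
    "electrophysiology", "transcriptomic", "optogenetic", "confocal", "biphoton",
    "volumetric", "stereology", "registration", "alignment", "annotation",
    "curation", "repository", "benchmark", "validation", "protocol", "assay",
    "retina", "thalamus", "striatum", "amygdala", "olfactory", "spinal",
    "vestibular", "auditory", "somatosensory", "prefrontal", "entorhinal")
}

corpus_method_phrases <- function() {
  c("digital reconstruction of neuronal morphology",
    "semi automated tracing of dendritic arbors",
    "three dimensional confocal image stacks",
    "quantitative branch order statistics",
    "sholl analysis of arbor complexity",
    "sparse labeling with fluorescent reporters",
    "whole cell patch clamp recordings",
    "registration to a common reference atlas")
}

rand_pick <- function(x, n = 1L) x[sample.int(length(x), n)]

make_title <- function(bank) {
  n_words <- sample(6:9, 1L)
  paste(rand_pick(bank, n_words), collapse = " ")
}

#' Perturb a title the way portals do
#'
#' Deterministic given the RNG state. Kinds: `special_chars` substitutes an
#' ASCII vowel-bearing word character with its accented counterpart (or back);
#' `truncation` keeps the first `truncation_length` characters; `whitespace`
#' doubles one inter-word space; `case` upper-cases one word. The similarity of
#' the perturbed title to the original (after normalization) is attached as
#' attribute `similarity`.
#'
#' @param title Source title.
#' @param kind One of the four kinds.
#' @param truncation_length Cut length for `truncation`.
#' @param cfg A [similarity_config()] used to report the similarity.
#' @return Perturbed title with attribute `similarity`.
#' @export
perturb_title <- function(title, kind = c("special_chars", "truncation",
                                          "whitespace", "case"),
                          truncation_length = 60L,
                          cfg = similarity_config()) {
  kind <- match.arg(kind)
  out <- switch(kind,
    special_chars = {
      accents <- c(a = "á", e = "é", i = "í", o = "ó",
                   u = "ú", c = "ç", n = "ñ")
      ch <- strsplit(title, "", fixed = TRUE)[[1]]
      idx <- which(ch %in% names(accents))
      if (length(idx)) {
        i <- rand_pick(idx)
        ch[i] <- accents[[ch[i]]]
      }
      paste0(ch, collapse = "")
    },
    truncation = {
      if (nchar(title) > truncation_length) substr(title, 1L, truncation_length) else title
    },
    whitespace = {
      sp <- gregexpr(" ", title, fixed = TRUE)[[1]]
      if (sp[1] > 0) {
        i <- rand_pick(as.integer(sp))
        paste0(substr(title, 1, i), " ", substr(title, i + 1L, nchar(title)))
      } else title
    },
    case = {
      words <- strsplit(title, " ", fixed = TRUE)[[1]]
      i <- sample.int(length(words), 1L)
      words[i] <- toupper(words[i])
      paste(words, collapse = " ")
    })
  attr(out, "similarity") <- title_similarity(title, out, cfg)
  out
}

#' Generate a synthetic corpus with duplicate ground truth
#'
#' Produces, per article: a base record (title, authors, journal, partial
#' publication date, DOI, possibly delayed PMID, full text embedding known
#' keywords) and one variant per assigned portal, with duplicate variants'
#' titles perturbed. The ground-truth map lists the duplicate groups, paywalled
#' DOIs and preprint pairs. Generation verifies the similarity bounds (intra-
#' group pairs at or above the dedup threshold, inter-group pairs below it) and
#' retries perturbation a bounded number of times, erroring if the spec is
#' unsatisfiable.
#'
#' @param spec A [corpus_spec()].
#' @param cfg A [similarity_config()] (supplies the threshold the bounds are
#'   verified against).
#' @return List with `articles` (base records), `portal_corpora` (named list of
#'   per-portal variant lists), and `ground_truth` (duplicate groups keyed by
#'   base id, paywalled/preprint/delayed-PMID flags, full-text index).
#' @export
generate_corpus <- function(spec = corpus_spec(), cfg = similarity_config()) {
  # verify-and-regenerate: if a perturbed variant happens to cross the
  # similarity bound against another group, the whole corpus is regenerated
  # from a seed derived deterministically from the requested one
  last_err <- NULL
  for (attempt in 0:9) {
    out <- tryCatch(generate_corpus_once(spec, cfg, spec$seed + 7919L * attempt),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
    last_err <- out
  }
  stop("generate_corpus: unsatisfiable spec after bounded retries: ",
       conditionMessage(last_err), call. = FALSE)
}

generate_corpus_once <- function(spec, cfg, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(seed)

  bank <- corpus_word_bank()
  phrases <- corpus_method_phrases()
  n <- spec$n_articles
  n_dup <- round(spec$duplicate_rate * n)
  dup_idx <- if (n_dup > 0) sample.int(n, n_dup) else integer()
  pay_idx <- if (spec$paywalled_rate > 0) sample.int(n, round(spec$paywalled_rate * n)) else integer()
  pre_idx <- if (spec$preprint_rate > 0) sample.int(n, round(spec$preprint_rate * n)) else integer()
  del_idx <- if (spec$delayed_pmid_rate > 0) sample.int(n, round(spec$delayed_pmid_rate * n)) else integer()

  first_names <- c("Ada", "Niels", "Rosalind", "Santiago", "Rita", "Eric",
                   "Camillo", "Brenda", "David", "Patricia", "Torsten", "May")
  last_names <- c("Lovelace", "Bohr", "Franklin", "Ramon", "Montalcini",
                  "Kandel", "Golgi", "Milner", "Hubel", "Goldman", "Wiesel",
                  "Ascoli")
  journals <- c("Journal of Comparative Neurology", "Neuroinformatics",
                "Frontiers in Neuroanatomy", "eLife", "Cerebral Cortex",
                "Brain Structure and Function")

  titles <- character(n)
  articles <- vector("list", n)
  for (i in seq_len(n)) {
    # regenerate a base title until it is dissimilar from all earlier ones
    for (try in 1:50) {
      t <- make_title(bank)
      ok <- all(vapply(titles[seq_len(i - 1)], function(prev)
        title_similarity(t, prev, cfg) < cfg$title_match_threshold - 0.02, TRUE))
      if (ok) break
      if (try == 50) stop("generate_corpus: could not produce a dissimilar base title", call. = FALSE)
    }
    titles[i] <- t
    keywords <- rand_pick(bank, 3L)
    full_text <- paste(
      t, ".",
      "In this study we describe", paste(keywords, collapse = " "), "in detail.",
      rand_pick(phrases), "was performed.",
      "Methods included", rand_pick(phrases), "and",
      paste(rand_pick(bank, 2L), collapse = " "), ".")
    base_id <- sprintf("A%03d", i)
    articles[[i]] <- list(
      base_id = base_id,
      title = t,
      authors = paste(rand_pick(first_names, 2L), rand_pick(last_names, 2L)),
      journal = if (i %in% pre_idx) "bioRxiv" else rand_pick(journals),
      published = partial_date(sample(2014:2018, 1L),
                               month = if (stats::runif(1) < 0.7) sample(1:12, 1L) else NULL),
      doi = sprintf("10.%04d/synth.%03d", 1000 + i %% 50, i),
      pmid = if (i %in% del_idx) NULL else as.character(30000000 + i),
      is_preprint = i %in% pre_idx,
      paywalled = i %in% pay_idx,
      full_text = full_text,
      keywords = keywords
    )
  }

  # assign portals: duplicates to >= 2 portals, the rest to one
  n_portals <- length(spec$portals)
  groups <- list()
  portal_corpora <- stats::setNames(vector("list", n_portals), spec$portals)
  for (p in spec$portals) portal_corpora[[p]] <- list()

  for (i in seq_len(n)) {
    art <- articles[[i]]
    on_portals <- if (i %in% dup_idx && n_portals >= 2L) {
      choices <- 2:min(3L, n_portals)
      rand_pick(spec$portals, choices[sample.int(length(choices), 1L)])
    } else rand_pick(spec$portals)
    variant_titles <- character(0)
    for (k in seq_along(on_portals)) {
      v <- art
      v$portal <- on_portals[k]
      if (k > 1L && length(spec$perturbation_kinds)) {
        # bounded retry keeping the pair within the dedup threshold
        for (try in 1:25) {
          kind <- rand_pick(spec$perturbation_kinds)
          pt <- perturb_title(art$title, kind,
                              truncation_length = spec$truncation_length, cfg = cfg)
          if (attr(pt, "similarity") >= cfg$title_match_threshold) break
          if (try == 25)
            stop("generate_corpus: perturbation cannot stay within the similarity threshold",
                 call. = FALSE)
        }
        v$title <- as.character(pt)
        # half the duplicate sightings arrive before identifier assignment:
        # dedup must then match on title alone
        if (stats::runif(1) < 0.5) {
          v$doi <- NULL
          v$pmid <- NULL
        }
        # a preprint's later sighting is its published version
        if (art$is_preprint) {
          v$is_preprint <- FALSE
          v$journal <- rand_pick(journals)
        }
      }
      variant_titles <- c(variant_titles, v$title)
      portal_corpora[[on_portals[k]]] <- c(portal_corpora[[on_portals[k]]], list(v))
    }
    groups[[art$base_id]] <- list(portals = on_portals, titles = variant_titles,
                                  doi = art$doi)
  }

  gt <- list(
    groups = groups,
    duplicates = vapply(articles[dup_idx], function(a) a$base_id, character(1)),
    paywalled = vapply(articles[pay_idx], function(a) a$doi, character(1)),
    preprints = vapply(articles[pre_idx], function(a) a$base_id, character(1)),
    delayed_pmid = vapply(articles[del_idx], function(a) a$base_id, character(1))
  )

  verify_corpus_bounds(articles, gt, cfg)
  list(articles = articles, portal_corpora = portal_corpora, ground_truth = gt,
       spec = spec)
}

# Intra-group pairs must reach the threshold; inter-group pairs must stay
# below it. Errors rather than returns, so a generated corpus is guaranteed
# sharp.
verify_corpus_bounds <- function(articles, gt, cfg) {
  norm <- lapply(gt$groups, function(g) normalize_title(g$titles))
  ids <- names(norm)
  for (id in ids) {
    ts <- norm[[id]]
    if (length(ts) >= 2L) {
      for (i in 1:(length(ts) - 1L)) for (j in (i + 1L):length(ts)) {
        if (jaro_winkler(ts[i], ts[j], cfg) < cfg$title_match_threshold)
          stop("generate_corpus: intra-group similarity fell below threshold", call. = FALSE)
      }
    }
  }
  # exhaustive cross-group check over every variant title
  flat <- unlist(norm, use.names = FALSE)
  owner <- rep(ids, lengths(norm))
  if (length(flat) >= 2L) {
    for (i in 1:(length(flat) - 1L)) for (j in (i + 1L):length(flat)) {
      if (owner[i] != owner[j] &&
          jaro_winkler(flat[i], flat[j], cfg) >= cfg$title_match_threshold)
        stop("generate_corpus: inter-group similarity reached threshold", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write a corpus to disk as portal payload fixtures
#'
#' One payload file per portal (`<portal>.json` or `.xml` following each
#' dialect) plus `ground_truth.json`.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory.
#' @param dialects Named list of [portal_dialect()]s (defaults to JSON).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir, dialects = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (p in names(corpus$portal_corpora)) {
    d <- dialects[[p]] %||% portal_dialect(p)
    ext <- if (identical(d$payload_format, "xml")) "xml" else "json"
    payload <- serialize_hits(corpus$portal_corpora[[p]], d$payload_format)
    writeLines(payload, file.path(dir, paste0(p, ".", ext)))
  }
  gt <- corpus$ground_truth
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
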