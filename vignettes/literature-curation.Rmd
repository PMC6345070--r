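---
title: "Crawling, deduplicating and curating a literature corpus with litscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crawling, deduplicating and curating a literature corpus with litscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litscout)
```

## The problem

Curation teams behind biomedical databases and knowledge bases must find
*every* new publication in their domain, month after month. The decisive
keywords usually sit in methods sections and figure legends, so the searches
have to be full-text searches against the publishers' own portals — and each
portal speaks a different query dialect, returns a different payload format
(XML or JSON), and filters dates at a different granularity. The same article
then surfaces repeatedly: from several portals, from the same portal at
different times, first as a preprint and later as the journal version, often
with the title subtly altered (special-character substitutions, trailing
truncation) and with identifiers such as the PMID arriving months after
publication.

litscout packages that whole workflow as a library plus a small CLI: one
Boolean query language translated per portal, client-side date filtering,
record-linkage-style duplicate detection, bibliographic enrichment, a triage
lifecycle and typed metadata annotation. Every outward interaction goes
through an injected transport contract, and the package ships complete mock
services plus a synthetic-corpus generator, so the full pipeline runs and is
tested entirely offline.

## The query language and its dialects

Queries are case-insensitive terms, quoted exact phrases, uppercase
`AND`/`OR`/`NOT` and parentheses:

```{r}
ast <- parse_query('(morphology OR "neuromorpho.org") AND "neuronal reconstruction"')
ast
```

Precedence is `NOT` > `AND` > `OR` with left associativity — the conventional
choice for Boolean retrieval engines; the grammar also accepts the idiomatic
infix form `a NOT b` as shorthand for `a AND NOT b`. Lowercase `and`/`or`/
`not` are deliberately ordinary terms, since operator keywords are defined as
uppercase-only. Parse errors carry the character position.

A `portal_dialect()` records what each portal can express and how queries and
payloads are serialized. Two consequential examples: some umbrella search
engines do not support `NOT` (a query using it fails validation for that
portal with a capability error rather than silently changing meaning), and
some portals join the words of a phrase with `+` instead of spaces:

```{r}
translate_query(ast, portal_dialect("nature-like", word_joiner = "+"))
```

`evaluate_query()` gives the language a reference semantics over plain text:
whole-word term matching and contiguous phrase matching on case-folded,
whitespace-normalized text. It drives the mock portal and the property tests
(translation round-trips, agreement with a brute-force evaluator). Real
portals expand a term to its inflectional variants server-side; the mock
reproduces this with `expand_lemma()`, a small suffix-rule table
(`-ies` → `-y`; `-es` dropped when the stem ends in s/x/z/ch/sh; `-s` dropped
unless the word ends `-ss`). The table folds plural query terms onto singular
text, which is the direction the portals' behaviour makes observable
(`neurons` finds `neuron`); it does not invent plurals (`sheep` expands to
itself), and thesaurus-style synonym expansion such as MeSH is deliberately
not emulated — that is portal-side behaviour outside this package's contract.

## Duplicate detection

Each incoming record is compared against **all** stored records — including
those already triaged Negative or Inaccessible, otherwise a rejected article
would be re-imported fresh — by three parallel methods: exact PMID/PMCID
match, exact DOI match, and approximate title match. Exact identifiers win;
PMID/PMCID is consulted before DOI.

Titles are first normalized (`normalize_title()`): case-folded, accented
letters folded to their base letter, whitespace collapsed. Approximate
matching then uses Jaro–Winkler similarity. For strings $s_1, s_2$ with $m$
matching characters (equal, within a window of
$\lfloor \max(|s_1|,|s_2|)/2 \rfloor - 1$ positions) and $t$ transpositions
(half the matched characters out of order):

$$ J = \frac{1}{3}\left(\frac{m}{|s_1|} + \frac{m}{|s_2|} + \frac{m-t}{m}\right), \qquad
   JW = J + \ell\, p\, (1 - J) $$

with common-prefix length $\ell \le 4$ and prefix scale $p = 0.1$. Two titles
are the same publication when $JW \ge 0.85$ — a similarity threshold
(distance $\le 0.15$), chosen to absorb the perturbation modes portals
actually introduce while keeping distinct articles apart. Lookups against a
bibliographic index use a harder floor of $0.9$ (`best_title_match()`),
because index title searches fan out over synonym-expanded candidates and
return many near misses.

```{r}
jaro("MARTHA", "MARHTA")
jaro_winkler("MARTHA", "MARHTA")
title_similarity("Dendritic café models", "dendritic  cafe models")
```

Merging (`merge_records()`) preserves every non-empty stored field, fills
empty ones from the incoming sighting (how late-assigned PMIDs arrive), takes
the set-union of search-provenance hits keyed by `(portal, query_id)`, and
upgrades a stored preprint to its published bibliography when the published
version shows up. Two *different* non-empty DOIs are never auto-merged: the
stored value is kept and the discrepancy surfaced for human review, since a
wrong silent merge is far more expensive than a flagged one.

## The lifecycle

Downloaded records enter `Evaluate`; records whose PDF could not be fetched
enter `Inaccessible` and are retried on every later run (access changes as
embargoes lapse and subscriptions change). Curators move `Evaluate` records
to `Positive`, `Negative`, or park them in `Review` with a mandatory note;
`Review` resolves to `Positive`/`Negative`. Nothing else is legal, so the
five states partition the store at all times — an invariant the test suite
checks exhaustively. Reversing a `Positive`/`Negative` verdict requires the
explicit `retriage_record()`, which logs the reversal; silent reversal
through ordinary triage would destroy the evaluation audit trail. When a
Positive record is re-triaged this way, the prior verdict and its timestamp
are kept in the record's note.

Metadata is typed (`integer`, `string`, `boolean`, `list`, `set`,
`nested_list`) and optionally constrained by a controlled vocabulary.
Validation happens in the library at the operation boundary — there is no GUI
to delegate coherence to, so every entry path is checked. `IsMetadataFinished`
(boolean) and `Note` (free text) exist from initialization; the `Review`-state
note is stored on the record itself and kept distinct from the `Note`
metadata category.

## What a run does

`run_search()` crosses every active portal with every configured query:
validate → translate → fetch pages until exhaustion → parse → date-filter →
dedup/merge → enrich (identifiers, contact email) → resolve DOI and attempt
the PDF → ingest into the query's target collection; then every
`Inaccessible` record is retried. Empty results are normal; a failing portal
is logged and skipped (the run is marked `error` only when a whole portal
failed); scrape-only portals are skipped while scraping is disabled, which is
the default. Each run appends exactly one activity-log entry with a terminal
status (`success`, `error`, `interrupted`). After a successful run the
configured start date advances to the run date (set `auto_advance: false` to
pin the window).

Dates are kept at the granularity the portal delivered (`partial_date`);
comparisons happen at the coarsest common granularity, so a year-only date
overlaps any range touching that year. Hits with no date at all are kept and
flagged rather than dropped — discarding them would silently lose exactly the
records most in need of enrichment.

## The synthetic corpus and what the tests mean

`generate_corpus()` fabricates a multi-portal corpus with known ground truth:
duplicate articles sighted on several portals under four title perturbation
modes (accent substitutions, trailing truncation, doubled whitespace, case
changes), paywalled articles, preprints whose later sighting is the published
version, and delayed identifier assignment (half the duplicate sightings
carry no DOI/PMID, forcing title-only matching). Perturbations are
similarity-bounded by construction: every within-group title pair scores
$\ge 0.85$ and every cross-group pair $< 0.85$ after normalization, verified
exhaustively at generation time; if a random perturbation lands outside the
bounds the corpus is regenerated from a deterministically derived seed. This
makes the dedup tests sharp — 100% precision and recall is the *correct*
answer on these corpora, not a statistical aspiration — at the price that the
generator never produces genuinely ambiguous pairs. Passing them therefore
demonstrates the matching machinery, not the empirical adequacy of 0.85 on
any particular real portal mix; that constant is an operating point to be
revisited per deployment. Titles are drawn from a neuroscience-flavoured word
bank, and full texts are template-assembled around chosen keywords so query
evaluations have known answers; none of it models real abstract language.

Problem sizes used by the shipped checks: 10,000 random string pairs for the
similarity oracle comparison, a 200-article corpus at 30% duplication for
dedup recovery, 200 fuzzed trees for the parse–translate round trip, 500
random query/document pairs for evaluator agreement, and a hand-built
2-portal × 3-query scenario (8 sightings, 2 cross-portal duplicates, 1
paywalled article) for the end-to-end lifecycle.

## Numerical and design notes

* `record_id` is a deterministic content hash of DOI, PMID and normalized
  title, so re-ingestion reproduces the same key; it is fixed at first
  insertion and stable under merges.
* `store_query()` sorting breaks ties by `record_id`, giving a stable total
  order; pagination is half-open and covers each matching record exactly
  once.
* The persistent store is plain JSON in a directory (literature, config,
  metadata, activity log) behind a repository interface — desk-scale by
  design, no external services; swap the backend without touching callers.
* Empty strings, `NULL` and absent fields are all "empty" for merge
  purposes; `jaro("", "") = 1` and `jaro("", x) = 0` for non-empty `x`.
* Downloads are retry-safe: repeated success overwrites the same
  `<record_id>.pdf`; repeated failure leaves a single `inaccessible` status.
* Known limitations: no author-name disambiguation, no abstract-text
  similarity, no MeSH emulation, no live portal adapters (the dialect and
  translation layers are shared; network transports are injected), no
  multi-user concurrency control.
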