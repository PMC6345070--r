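# litscout

Literature scouting, deduplication and curation for database and
knowledge-base projects.

Teams that curate a scientific database must track their domain's literature
exhaustively: the decisive keywords live in methods sections and figure
legends, so coverage means periodic **full-text** searches against many
publisher portals — each with its own query dialect, payload format (XML or
JSON) and date-filter granularity. The same article then returns over and
over: from several portals, at different times, first as a preprint, with
perturbed titles (accent substitutions, trailing truncation) and with
identifiers that arrive months after publication.

litscout implements that workflow as an R library plus a small CLI:

* **one Boolean query language** — terms, quoted phrases, uppercase
  `AND`/`OR`/`NOT`, parentheses — parsed to a syntax tree, validated against
  each portal's capabilities and translated to its dialect;
* **duplicate detection by three parallel methods** — exact PMID/PMCID,
  exact DOI, and Jaro–Winkler similarity of normalized titles at the 0.85
  threshold — followed by field-filling merges with full search provenance
  (`addToSet` semantics on `(portal, query_id)`), including preprint →
  published upgrades;
* **bibliographic enrichment** behind mockable transports: index lookups by
  title (best match accepted at a hard 0.9 floor) or identifier, DOI →
  full-text-URL resolution, PDF download with retry of inaccessible records
  on every later run;
* **a triage lifecycle** (`Evaluate`, `Inaccessible`, `Positive`, `Negative`,
  `Review`) with an enforced transition table, plus typed,
  vocabulary-constrained metadata annotation;
* **a deterministic synthetic-corpus generator** with known duplicate ground
  truth, so everything above is testable with no network access.

The core matcher is the Jaro similarity
*J* = ((m/|s₁|) + (m/|s₂|) + ((m−t)/m)) / 3 — *m* matching characters within a
window of ⌊max(|s₁|,|s₂|)/2⌋−1, *t* transpositions — boosted by the Winkler
prefix bonus *JW* = *J* + ℓ·p·(1−*J*) with prefix length ℓ ≤ 4 and p = 0.1.
Titles are case-folded, accent-folded and whitespace-normalized before
comparison.

## Worked example

```r
library(litscout)

ast <- parse_query('(morphology OR "neuromorpho.org") AND "neuronal reconstruction"')
ast
#> AND
#>   OR
#>     TERM morphology
#>     PHRASE "neuromorpho.org"
#>   PHRASE "neuronal reconstruction"

# a portal that joins phrase words with '+' instead of spaces
translate_query(ast, portal_dialect("nature-like", word_joiner = "+"))
#> [1] "(morphology OR \"neuromorpho.org\") AND \"neuronal+reconstruction\""

jaro_winkler("MARTHA", "MARHTA")
#> [1] 0.9611111
title_similarity("Dendritic café models", "dendritic  cafe models")
#> [1] 1
```

The similarity of 0.9611 is the Jaro value 0.9444 boosted by the 3-character
common prefix; the two café titles normalize to the same string, so they score
a perfect 1 and would merge as duplicates.

A synthetic corpus round trip — 8 articles spread over two portals, two of
them sighted on both portals with perturbed titles:

```r
cc <- generate_corpus(corpus_spec(n_articles = 8, duplicate_rate = 0.25, seed = 11))
st <- store_open()   # in-memory; give a directory for a persistent store
for (p in names(cc$portal_corpora)) {
  for (v in cc$portal_corpora[[p]]) {
    rec <- hit_to_record(
      raw_portal_hit(title = v$title, doi = v$doi, pmid = v$pmid,
                     journal = v$journal, published = v$published,
                     authors = v$authors, is_preprint = v$is_preprint,
                     source_portal = p, full_text = v$full_text),
      portal = p, query_id = "q1")
    dedup_upsert(st, rec)
  }
}
sum(lengths(cc$portal_corpora))   # sightings delivered by the portals
#> [1] 10
print(st)
#> <record_store> (in memory)
#>   records: 8 (Evaluate=8, Inaccessible=0, Positive=0, Negative=0, Review=0)
#>   portals: 0  queries: 0  metadata categories: 2  log entries: 0
```

Ten sightings collapse to the eight true publications: both cross-portal
duplicates were recognized despite their altered titles and missing
identifiers, and each merged record carries one provenance hit per portal.

For a full orchestrated run (`run_search()`), triage (`triage_record()`),
annotation (`annotate_record()`) and the mock portal/index/registry services,
see the vignette in `vignettes/literature-curation.Rmd` and the example
configuration in `inst/extdata/example-config.yaml`. A command-line front end
is installed at `exec/litscout` (subcommands: `search run`, `records list`,
`triage`, `annotate`, `add`, `export`, `config`, `reset`, `status`).

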