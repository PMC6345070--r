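Package: litscout
Title: Literature Scouting, Deduplication and Curation for Knowledge-Base Projects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale literature crawling and curation engine for database and
    knowledge-base teams that must track a research domain exhaustively. Boolean
    full-text queries written once in a single syntax are translated to the dialects
    of heterogeneous publisher portals; returned records are normalized, matched
    against the existing store by exact identifier (PMID/PMCID, DOI) and by
    Jaro-Winkler title similarity, and merged so that each publication exists once
    with full provenance of every portal and query that found it. Records move
    through a triage lifecycle (Evaluate, Inaccessible, Positive, Negative, Review)
    and carry typed, optionally vocabulary-constrained metadata annotations. All
    portal, bibliographic-index and full-text-registry interactions go through
    injected transport contracts, with complete mock implementations and a
    deterministic synthetic-corpus generator so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
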