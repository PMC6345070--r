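# Example litscout run configuration.
# Portals declare their dialect; queries share one Boolean syntax and each
# routes its hits into a target collection label.

start_date: "2016-01"
end_date: ~            # open-ended
auto_advance: true

similarity:
  title_match_threshold: 0.85        # dedup: Jaro-Winkler on normalized titles
  pubmed_best_match_threshold: 0.9   # index lookup: hard best-match floor
  winkler_prefix_scale: 0.1
  max_prefix_length: 4

portals:
  - name: pubmed-like
    payload_format: xml
    supports_not: true
    date_granularity: year_month_day
    api_root: "mock://pubmed-like"
    active: true
  - name: nature-like
    payload_format: json
    word_joiner: "+"                 # phrases serialize as neuronal+reconstruction
    supports_not: true
    date_granularity: year
    api_root: "mock://nature-like"
    active: true
  - name: scholar-like
    payload_format: html_scrape      # scrape-only: skipped until enabled
    supports_not: false              # NOT raises a capability error here
    scraping_enabled: false
    api_root: "mock://scholar-like"
    active: true

queries:
  - query_id: q1
    text: '(morphology OR "neuromorpho.org") AND "neuronal reconstruction"'
    target_collection: reconstructions
  - query_id: q2
    text: '"dendritic spine" AND imaging NOT review'
    target_collection: spines

metadata_categories:
  - name: Species
    value_type: string
    vocabulary: [mouse, rat, human]
  - name: BrainRegion
    value_type: set
    vocabulary: [cortex, hippocampus, cerebellum, retina]
  - name: NCells
    value_type: integer
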