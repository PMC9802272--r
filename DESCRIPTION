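Package: ibdtopics
Title: Dictionary-Based Topic Analysis of Social Media Posts About IBD and Distress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dictionary-based content analysis of social media
    corpora discussing inflammatory bowel disease (IBD) in distress-related
    contexts. Provides corpus ingestion (JSON Lines / CSV), keyword relevance
    and cleaning filters (retweet removal, same-user deduplication, exclusion
    contexts), a distress lexicon filter, classification into eight
    non-mutually-exclusive IBD topics with false-positive phrase elimination,
    intercoder reliability (Krippendorff's nominal alpha, percent agreement,
    stratified validation sampling), topic co-occurrence network analysis with
    weighted-degree centrality and sociogram export, descriptive corpus
    summaries (hashtags, hyperlinks, subreddit rankings, topic prevalence),
    and a seeded synthetic corpus generator with gold labels for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    igraph,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
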