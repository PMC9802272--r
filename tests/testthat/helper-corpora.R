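# Small corpora built in code for filter and IO tests.

make_posts <- function(...) {
  rows <- list(...)
  data.frame(
    post_id = vapply(rows, function(r) r$id, character(1)),
    platform = vapply(rows, function(r) r$platform %||% "reddit", character(1)),
    author = vapply(rows, function(r) r$author %||% "u1", character(1)),
    timestamp = as.POSIXct(
      vapply(rows, function(r) r$ts %||% "2018-01-01 00:00:00", character(1)),
      tz = "UTC"
    ),
    text = vapply(rows, function(r) r$text, character(1)),
    is_retweet = vapply(rows, function(r) {
      if ((r$platform %||% "reddit") == "twitter") isTRUE(r$rt) else NA
    }, logical(1)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

.default_vocabulary_for_test <- function() ibdtopics:::.default_vocabulary()

subset_corpus_for_test <- function(x, idx) ibdtopics:::subset_corpus(x, idx)

tiny_lexicons <- function() {
  list(
    relevance = relevance_config(),
    distress = distress_lexicon(
      unigrams = c("afraid", "scared"),
      phrases = c("feel alone", "hard to manage")
    )
  )
}
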