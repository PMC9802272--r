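## Lexicon configuration types ----------------------------------------------
##
## All entries are stored lower-cased. The shipped YAML lexicons under
## inst/extdata are illustrative stand-ins assembled from the vocabulary the
## study domain uses in print; production users drop in their full curated
## keyword lists through the same YAML surface.

.lower_chr <- function(x) tolower(trimws(as.character(x %||% character())))

#' Relevance filter configuration
#'
#' Keywords are matched case-insensitively as substrings of the normalized
#' text, so `"crohn"` catches `"Crohn's"` and hashtag compounds such as
#' `"#crohnsdisease"`. Exclusion contexts are consecutive-token phrases whose
#' presence removes a post (e.g. animal diagnoses, the *Investor's Business
#' Daily* sense of "IBD").
#'
#' @param keywords Non-empty character vector of IBD keywords.
#' @param exclusion_contexts Character vector of exclusion phrases.
#' @return An object of class `relevance_config`.
#' @export
relevance_config <- function(
    keywords = c("crohn", "ibd", "colitis", "inflammatory bowel disease",
                 "ileitis", "ileoceceal"),
    exclusion_contexts = c("investors business daily", "my dog has", "my cat has")) {
  keywords <- .lower_chr(keywords)
  if (!length(keywords)) stop_data("relevance keywords must be non-empty")
  structure(
    list(keywords = keywords, exclusion_contexts = .lower_chr(exclusion_contexts)),
    class = "relevance_config"
  )
}

#' Distress lexicon
#'
#' Unigrams match as exact normalized tokens (so `"scared"` does not fire
#' inside unrelated compounds); phrases (bigrams or longer) match as
#' consecutive normalized tokens.
#'
#' @param unigrams Character vector of single-word distress terms.
#' @param phrases Character vector of multi-word distress phrases.
#' @return An object of class `distress_lexicon`.
#' @export
distress_lexicon <- function(unigrams, phrases = character()) {
  unigrams <- .lower_chr(unigrams)
  phrases <- .lower_chr(phrases)
  if (!length(unigrams) && !length(phrases)) {
    stop_data("distress lexicon must be non-empty")
  }
  nt <- vapply(phrases, function(p) length(.entry_tokens(p)), integer(1))
  if (any(nt < 2L)) {
    stop_data("distress phrases must contain at least two tokens: ",
              paste(phrases[nt < 2L], collapse = ", "))
  }
  structure(list(unigrams = unigrams, phrases = phrases),
            class = "distress_lexicon")
}

#' Topic dictionary
#'
#' Per-topic term lists for the non-mutually-exclusive topic classifier.
#' `terms` entries are exact-token matches (multi-word entries match as
#' consecutive tokens); `substring_terms` entries match inside a single token
#' (needed for hashtag compounds such as `"#crohnsdisease"`).
#'
#' @param topics Named list; each element a list with character vectors
#'   `terms` and optionally `substring_terms`.
#' @param canonical If `TRUE` (default) validate that the topic set is exactly
#'   the eight canonical IBD topics; set `FALSE` for custom topic inventories.
#' @return An object of class `topic_lexicon`.
#' @export
topic_lexicon <- function(topics, canonical = TRUE) {
  if (!length(topics) || is.null(names(topics))) {
    stop_data("topics must be a named list")
  }
  topics <- lapply(topics, function(t) {
    if (is.character(t)) t <- list(terms = t)
    list(
      terms = .lower_chr(t$terms),
      substring_terms = .lower_chr(t$substring_terms)
    )
  })
  if (canonical && !setequal(names(topics), CANONICAL_TOPICS)) {
    stop_data("canonical topic lexicon must define exactly: ",
              paste(CANONICAL_TOPICS, collapse = ", "))
  }
  structure(list(topics = topics), class = "topic_lexicon")
}

#' False-positive phrase dictionary
#'
#' Per-topic phrases whose occurrence marks a spurious dictionary hit (e.g.
#' "tired of explaining" for the symptoms topic, where "tired" alone is a
#' symptoms term). During classification a topic match whose span overlaps a
#' false-positive phrase span is suppressed.
#'
#' @param entries Named list mapping topic name to a character vector of
#'   phrases. Every name must be a topic of the paired [topic_lexicon()].
#' @return An object of class `fp_lexicon`.
#' @export
fp_lexicon <- function(entries = list()) {
  entries <- lapply(entries, .lower_chr)
  structure(list(entries = entries), class = "fp_lexicon")
}

.validate_fp_against <- function(fp, lexicon) {
  extra <- setdiff(names(fp$entries), names(lexicon$topics))
  if (length(extra)) {
    stop_data("false-positive lexicon names unknown topic(s): ",
              paste(extra, collapse = ", "))
  }
  invisible(TRUE)
}

#' Read cleaning lexicons (relevance + distress) from YAML
#'
#' Expects top-level keys `relevance` (list of keywords), `exclusions`
#' (list of phrases) and `distress` with `unigrams` and `phrases` lists.
#'
#' @param path YAML file; defaults to the illustrative lexicon shipped with
#'   the package.
#' @return List with elements `relevance` ([relevance_config()]) and
#'   `distress` ([distress_lexicon()]).
#' @export
read_cleaning_config <- function(path = system.file("extdata", "cleaning_lexicons.yaml",
                                                    package = "ibdtopics")) {
  if (!file.exists(path)) stop_data("cleaning config not found: ", path)
  y <- yaml::read_yaml(path)
  list(
    relevance = relevance_config(
      keywords = unlist(y$relevance),
      exclusion_contexts = unlist(y$exclusions %||% list())
    ),
    distress = distress_lexicon(
      unigrams = unlist(y$distress$unigrams),
      phrases = unlist(y$distress$phrases %||% list())
    )
  )
}

#' Read the topic dictionary (terms + false positives) from YAML
#'
#' Expects a top-level `topics:` map; each topic may carry `terms:`,
#' `substring_terms:` and `false_positives:` lists.
#'
#' @param path YAML file; defaults to the illustrative dictionary shipped
#'   with the package.
#' @param canonical Passed to [topic_lexicon()].
#' @return List with elements `lexicon` ([topic_lexicon()]) and `fp`
#'   ([fp_lexicon()]).
#' @export
read_topic_dictionary <- function(path = system.file("extdata", "topic_dictionary.yaml",
                                                     package = "ibdtopics"),
                                  canonical = TRUE) {
  if (!file.exists(path)) stop_data("topic dictionary not found: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$topics)) stop_data("topic dictionary YAML needs a 'topics' map")
  lex <- topic_lexicon(
    lapply(y$topics, function(t) list(
      terms = unlist(t$terms %||% list()),
      substring_terms = unlist(t$substring_terms %||% list())
    )),
    canonical = canonical
  )
  fps <- lapply(y$topics, function(t) unlist(t$false_positives %||% list()))
  fps <- fps[vapply(fps, length, integer(1)) > 0L]
  fp <- fp_lexicon(fps)
  .validate_fp_against(fp, lex)
  list(lexicon = lex, fp = fp)
}
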