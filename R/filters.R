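## Cleaning and distress filters --------------------------------------------

#' Filter report
#'
#' Every filter returns a report satisfying the conservation invariant
#' `retained_count + sum(removed_by_rule) == input_count`.
#'
#' @param input_count,retained_count Integer post counts.
#' @param removed_by_rule Named integer vector of removals per rule.
#' @return An object of class `filter_report`.
#' @export
filter_report <- function(input_count, retained_count, removed_by_rule) {
  removed_by_rule <- vapply(removed_by_rule, as.integer, integer(1))
  if (retained_count + sum(removed_by_rule) != input_count) {
    stop_data("filter report violates conservation: ",
              retained_count, " + ", sum(removed_by_rule), " != ", input_count)
  }
  structure(
    list(
      input_count = as.integer(input_count),
      retained_count = as.integer(retained_count),
      removed_by_rule = removed_by_rule
    ),
    class = "filter_report"
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report> %d in, %d retained\n",
              x$input_count, x$retained_count))
  for (r in names(x$removed_by_rule)) {
    cat(sprintf("  removed by %s: %d\n", r, x$removed_by_rule[[r]]))
  }
  invisible(x)
}

.tokenize_corpus <- function(x) lapply(x$posts$text, normalize_text)

#' Keyword relevance filter
#'
#' Retains posts whose normalized text contains at least one relevance
#' keyword (substring match over the space-joined normalized tokens, so
#' `"crohn"` hits `"crohns"` and `"#crohnsdisease"`) and no exclusion-context
#' phrase. Matching is case-insensitive by construction.
#'
#' @param x A `corpus`.
#' @param config A [relevance_config()].
#' @return List with elements `corpus` (retained posts) and `report`
#'   (a [filter_report()] itemizing removals by `no_keyword` and
#'   `exclusion_context`).
#' @export
relevance_filter <- function(x, config) {
  stopifnot(inherits(x, "corpus"), inherits(config, "relevance_config"))
  toks <- .tokenize_corpus(x)
  joined <- vapply(toks, .joined_tokens, character(1))
  has_kw <- Reduce(`|`, lapply(config$keywords, function(k) {
    grepl(k, joined, fixed = TRUE)
  }), init = rep(FALSE, length(joined)))
  excluded <- rep(FALSE, length(joined))
  for (phrase in config$exclusion_contexts) {
    pt <- .entry_tokens(phrase)
    excluded <- excluded | vapply(toks, function(td) {
      nrow(.match_phrase_idx(td$token, pt)) > 0L
    }, logical(1))
  }
  keep <- has_kw & !excluded
  report <- filter_report(
    nrow(x$posts), sum(keep),
    c(no_keyword = sum(!has_kw),
      exclusion_context = sum(has_kw & excluded))
  )
  list(corpus = subset_corpus(x, keep), report = report)
}

#' Remove retweets
#'
#' Drops Twitter posts flagged `is_retweet`, or whose normalized text begins
#' with the token pair `"rt @user"` (fallback for corpora without the flag).
#' Reddit posts are never touched by this rule.
#'
#' @param x A `corpus`.
#' @return List with `corpus` and `report` (rule `retweet`).
#' @export
remove_retweets <- function(x) {
  stopifnot(inherits(x, "corpus"))
  tw <- x$posts$platform == "twitter"
  flagged <- tw & !is.na(x$posts$is_retweet) & x$posts$is_retweet
  prefix <- tw & grepl("^\\s*rt\\s+@", tolower(x$posts$text))
  drop <- flagged | prefix
  report <- filter_report(nrow(x$posts), sum(!drop), c(retweet = sum(drop)))
  list(corpus = subset_corpus(x, !drop), report = report)
}

#' Remove same-user duplicate posts
#'
#' Among posts sharing the same author and identical normalized text, only
#' the earliest-timestamped copy is kept. Identical texts from different
#' authors all survive; posts with empty authors are never deduplicated
#' against each other.
#'
#' @param x A `corpus`.
#' @return List with `corpus` and `report` (rule `same_user_duplicate`).
#' @export
dedup_same_user <- function(x) {
  stopifnot(inherits(x, "corpus"))
  norm <- vapply(.tokenize_corpus(x), .joined_tokens, character(1))
  key <- paste(x$posts$author, norm, sep = "\r")
  keep <- rep(TRUE, nrow(x$posts))
  eligible <- nzchar(x$posts$author)
  for (k in unique(key[eligible])) {
    idx <- which(key == k & eligible)
    if (length(idx) > 1L) {
      ts <- x$posts$timestamp[idx]
      ## earliest timestamp wins; NA timestamps lose to dated copies,
      ## original file order breaks exact ties
      ord <- order(ts, seq_along(idx), na.last = TRUE)
      keep[idx[ord[-1L]]] <- FALSE
    }
  }
  report <- filter_report(nrow(x$posts), sum(keep),
                          c(same_user_duplicate = sum(!keep)))
  list(corpus = subset_corpus(x, keep), report = report)
}

#' Distress lexicon filter
#'
#' Retains posts containing at least one distress unigram as an exact
#' normalized token, or at least one distress phrase as consecutive
#' normalized tokens. The entries that fired per retained post are returned
#' in `matches`.
#'
#' @param x A `corpus`.
#' @param lexicon A [distress_lexicon()].
#' @return List with `corpus`, `report` (rule `no_distress_marker`) and
#'   `matches` (named list, post_id -> character vector of fired entries).
#' @export
distress_filter <- function(x, lexicon) {
  stopifnot(inherits(x, "corpus"), inherits(lexicon, "distress_lexicon"))
  toks <- .tokenize_corpus(x)
  entries <- c(lexicon$unigrams, lexicon$phrases)
  entry_toks <- lapply(entries, .entry_tokens)
  fired <- lapply(toks, function(td) {
    hit <- vapply(entry_toks, function(pt) {
      nrow(.match_phrase_idx(td$token, pt)) > 0L
    }, logical(1))
    entries[hit]
  })
  keep <- vapply(fired, function(f) length(f) > 0L, logical(1))
  report <- filter_report(nrow(x$posts), sum(keep),
                          c(no_distress_marker = sum(!keep)))
  matches <- fired[keep]
  names(matches) <- x$posts$post_id[keep]
  list(corpus = subset_corpus(x, keep), report = report, matches = matches)
}
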