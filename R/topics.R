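## Topic dictionary classification with false-positive elimination ----------

## Precompile lexicon entries (tokenize once) so corpus-scale classification
## does not re-tokenize every dictionary entry for every post.
.compile_topic_lexicon <- function(lexicon) {
  lapply(lexicon$topics, function(spec) {
    list(
      terms = spec$terms,
      term_tokens = lapply(spec$terms, .entry_tokens),
      substring_terms = spec$substring_terms
    )
  })
}

.compile_fp_lexicon <- function(fp, topic_names) {
  out <- lapply(topic_names, function(tp) {
    phrases <- fp$entries[[tp]] %||% character()
    list(phrases = phrases, phrase_tokens = lapply(phrases, .entry_tokens))
  })
  names(out) <- topic_names
  out
}

.empty_match_df <- data.frame(
  term = character(), first = integer(), last = integer(),
  start = integer(), end = integer(), stringsAsFactors = FALSE
)

## Match a set of precompiled entries against one token data frame; returns
## one data frame of matches (term + token-index and character spans).
.match_compiled <- function(tok_df, terms, term_tokens, substring_terms) {
  tokens <- tok_df$token
  term_v <- character(); first_v <- integer(); last_v <- integer()
  for (i in seq_along(terms)) {
    idx <- .match_phrase_idx(tokens, term_tokens[[i]])
    if (nrow(idx)) {
      term_v <- c(term_v, rep(terms[i], nrow(idx)))
      first_v <- c(first_v, idx[, "first"])
      last_v <- c(last_v, idx[, "last"])
    }
  }
  for (sub in substring_terms) {
    hit <- which(grepl(sub, tokens, fixed = TRUE))
    if (length(hit)) {
      term_v <- c(term_v, rep(sub, length(hit)))
      first_v <- c(first_v, hit)
      last_v <- c(last_v, hit)
    }
  }
  if (!length(term_v)) return(.empty_match_df)
  data.frame(
    term = term_v, first = first_v, last = last_v,
    start = tok_df$start[first_v], end = tok_df$end[last_v],
    stringsAsFactors = FALSE
  )
}

.classify_tokens <- function(tok, comp, fp_comp, fp_mode, post_id) {
  topics_out <- character()
  spans <- list()
  suppressed <- list()
  for (topic in names(comp)) {
    cl <- comp[[topic]]
    m <- .match_compiled(tok, cl$terms, cl$term_tokens, cl$substring_terms)
    if (!nrow(m)) next
    fpc <- fp_comp[[topic]]
    fpm <- .match_compiled(tok, fpc$phrases, fpc$phrase_tokens, character())
    if (nrow(fpm)) {
      if (fp_mode == "veto") {
        sup <- rep(TRUE, nrow(m))
      } else {
        sup <- vapply(seq_len(nrow(m)), function(i) {
          any(fpm$first <= m$last[i] & fpm$last >= m$first[i])
        }, logical(1))
      }
    } else {
      sup <- rep(FALSE, nrow(m))
    }
    if (any(!sup)) {
      topics_out <- c(topics_out, topic)
      spans[[topic]] <- m[!sup, , drop = FALSE]
    }
    if (any(sup)) suppressed[[topic]] <- m[sup, , drop = FALSE]
  }
  structure(
    list(post_id = post_id, topics = topics_out,
         match_spans = spans, fp_suppressed = suppressed),
    class = "topic_assignment"
  )
}

#' Classify one post into IBD topics
#'
#' For each topic all dictionary term matches are collected; then all
#' false-positive phrase matches for that topic are located and any term
#' match whose span overlaps a false-positive span is suppressed. The topic
#' is assigned iff at least one match survives. Topics are not mutually
#' exclusive: a single post can carry several.
#'
#' With `fp_mode = "veto"` a topic is dropped outright whenever any of its
#' false-positive phrases occurs in the post, regardless of span overlap.
#' Span overlap is the default because it preserves genuine co-mentions
#' (e.g. "tired of explaining, and the constant diarrhea" keeps symptoms
#' through the surviving "diarrhea" match).
#'
#' @param text Post text (a single string), or a one-row slice of
#'   `corpus$posts`.
#' @param lexicon A [topic_lexicon()].
#' @param fp A [fp_lexicon()] (may be empty).
#' @param fp_mode `"span"` (default) or `"veto"`.
#' @param post_id Identifier recorded on the assignment.
#' @return An object of class `topic_assignment`: list with `post_id`,
#'   `topics` (character vector in canonical order), `match_spans` (named
#'   list of data frames term/first/last/start/end for surviving matches) and
#'   `fp_suppressed` (same shape, suppressed matches).
#' @export
classify_topics <- function(text, lexicon, fp = fp_lexicon(), fp_mode = c("span", "veto"),
                            post_id = NA_character_) {
  fp_mode <- match.arg(fp_mode)
  stopifnot(inherits(lexicon, "topic_lexicon"), inherits(fp, "fp_lexicon"))
  .validate_fp_against(fp, lexicon)
  if (is.data.frame(text)) {
    post_id <- text$post_id[1L]
    text <- text$text[1L]
  }
  comp <- .compile_topic_lexicon(lexicon)
  fp_comp <- .compile_fp_lexicon(fp, names(lexicon$topics))
  .classify_tokens(normalize_text(text), comp, fp_comp, fp_mode, post_id)
}

#' @export
print.topic_assignment <- function(x, ...) {
  cat("<topic_assignment>", x$post_id, "->",
      if (length(x$topics)) paste(x$topics, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Classify every post of a corpus
#'
#' Deterministic given its inputs; assignments are order-aligned with the
#' corpus.
#'
#' @param x A `corpus`.
#' @inheritParams classify_topics
#' @return An object of class `topic_assignments`: a list of
#'   [classify_topics()] results with attributes `post_ids` and `topic_names`.
#' @export
classify_corpus <- function(x, lexicon, fp = fp_lexicon(), fp_mode = c("span", "veto")) {
  fp_mode <- match.arg(fp_mode)
  stopifnot(inherits(x, "corpus"), inherits(lexicon, "topic_lexicon"),
            inherits(fp, "fp_lexicon"))
  .validate_fp_against(fp, lexicon)
  comp <- .compile_topic_lexicon(lexicon)
  fp_comp <- .compile_fp_lexicon(fp, names(lexicon$topics))
  out <- lapply(seq_len(nrow(x$posts)), function(i) {
    .classify_tokens(normalize_text(x$posts$text[i]), comp, fp_comp, fp_mode,
                     post_id = x$posts$post_id[i])
  })
  structure(out,
            class = "topic_assignments",
            post_ids = x$posts$post_id,
            topic_names = names(lexicon$topics))
}

#' @export
print.topic_assignments <- function(x, ...) {
  k <- vapply(x, function(a) length(a$topics), integer(1))
  cat("<topic_assignments>", length(x), "posts;",
      sum(k > 0L), "with >=1 topic;", sum(k >= 2L), "multi-topic\n")
  invisible(x)
}

#' Logical post-by-topic indicator matrix
#'
#' @param assignments A `topic_assignments` object (or plain list of
#'   `topic_assignment`s).
#' @param topics Topic inventory for the columns; defaults to the attribute
#'   stored on `assignments` or the canonical topic set.
#' @return Logical matrix, one row per post (rownames = post ids), one
#'   column per topic.
#' @export
topic_matrix <- function(assignments, topics = NULL) {
  topics <- topics %||% attr(assignments, "topic_names") %||% CANONICAL_TOPICS
  m <- matrix(FALSE, nrow = length(assignments), ncol = length(topics),
              dimnames = list(
                vapply(assignments, function(a) as.character(a$post_id), character(1)),
                topics
              ))
  for (i in seq_along(assignments)) {
    m[i, intersect(assignments[[i]]$topics, topics)] <- TRUE
  }
  m
}

#' Write topic assignments as JSON Lines
#'
#' One record per post: `post_id`, `topics`, and surviving/suppressed match
#' terms per topic.
#'
#' @param assignments A `topic_assignments` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  lines <- vapply(assignments, function(a) {
    jsonlite::toJSON(list(
      post_id = a$post_id,
      topics = as.list(a$topics),
      matches = lapply(a$match_spans, function(df) unique(df$term)),
      fp_suppressed = lapply(a$fp_suppressed, function(df) unique(df$term))
    ), auto_unbox = TRUE, digits = NA)
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
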