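#' Normalize text into a token sequence with character spans
#'
#' Lower-cases text, replaces URLs with a sentinel token, strips apostrophes
#' inside words (`"Crohn's"` becomes `"crohns"`) and splits the remainder into
#' maximal alphanumeric runs. Matching everywhere in the package is
#' case-insensitive because it operates on this normalized stream. Each token
#' keeps the character span it occupied in the original text so dictionary
#' matches can be reported, and suppressed, at the span level.
#'
#' @param text A single character string (`NA` is treated as empty).
#' @return A data frame with columns `token` (normalized token), `start`,
#'   `end` (1-based character positions in the original text, inclusive).
#'   Empty input yields a zero-row data frame.
#' @examples
#' normalize_text("Living with Crohn's is hard")$token
#' normalize_text("see https://example.org for IBD info")$token
#' @export
normalize_text <- function(text) {
  empty <- data.frame(
    token = character(), start = integer(), end = integer(),
    stringsAsFactors = FALSE
  )
  if (length(text) != 1L) stop_data("normalize_text() expects a single string")
  if (is.na(text) || !nzchar(text)) return(empty)

  toks <- character()
  starts <- integer()
  ends <- integer()

  um <- gregexpr(.url_regex, text, perl = TRUE)[[1L]]
  if (um[1L] != -1L) {
    url_start <- as.integer(um)
    url_end <- url_start + attr(um, "match.length") - 1L
  } else {
    url_start <- integer()
    url_end <- integer()
  }

  ## non-URL segments, in order, interleaved with URL sentinels
  seg_start <- c(1L, url_end + 1L)
  seg_end <- c(url_start - 1L, nchar(text))
  for (i in seq_along(seg_start)) {
    if (i <= length(url_start)) {
      ## URL that follows this segment
    }
    s0 <- seg_start[i]
    s1 <- seg_end[i]
    if (s1 >= s0) {
      seg <- substr(text, s0, s1)
      tm <- gregexpr("[[:alnum:]]+(?:['’][[:alnum:]]+)*", seg, perl = TRUE)[[1L]]
      if (tm[1L] != -1L) {
        mstart <- as.integer(tm)
        mlen <- attr(tm, "match.length")
        raw <- substring(seg, mstart, mstart + mlen - 1L)
        toks <- c(toks, gsub("['’]", "", tolower(raw)))
        starts <- c(starts, s0 + mstart - 1L)
        ends <- c(ends, s0 + mstart + mlen - 2L)
      }
    }
    if (i <= length(url_start)) {
      toks <- c(toks, .url_sentinel)
      starts <- c(starts, url_start[i])
      ends <- c(ends, url_end[i])
    }
  }

  ord <- order(starts)
  data.frame(
    token = toks[ord], start = starts[ord], end = ends[ord],
    stringsAsFactors = FALSE
  )
}

## Tokenize a lexicon entry into its normalized token sequence.
.entry_tokens <- function(entry) normalize_text(entry)$token

## Find all occurrences of a normalized phrase (character vector of tokens,
## length >= 1) as consecutive tokens. Returns an integer matrix with columns
## first, last (token indices); zero rows when absent.
.match_phrase_idx <- function(tokens, phrase) {
  k <- length(phrase)
  n <- length(tokens)
  out <- matrix(integer(), ncol = 2L, dimnames = list(NULL, c("first", "last")))
  if (k == 0L || n < k) return(out)
  hits <- which(tokens == phrase[1L])
  if (k > 1L) {
    hits <- hits[hits + k - 1L <= n]
    for (j in seq_len(k - 1L)) {
      hits <- hits[tokens[hits + j] == phrase[j + 1L]]
    }
  }
  if (length(hits)) {
    out <- cbind(first = hits, last = hits + k - 1L)
  }
  out
}

## Match one lexicon entry against a token data frame.
## mode "token": exact-token (or consecutive-token phrase) match.
## mode "substring": entry contained in any single token (hashtag compounds).
## Returns data frame term, first, last, start, end.
.match_entry <- function(tok_df, entry, mode = c("token", "substring")) {
  mode <- match.arg(mode)
  tokens <- tok_df$token
  if (mode == "substring") {
    hit <- which(grepl(entry, tokens, fixed = TRUE))
    idx <- cbind(first = hit, last = hit)
  } else {
    idx <- .match_phrase_idx(tokens, .entry_tokens(entry))
  }
  if (!nrow(idx)) {
    return(data.frame(
      term = character(), first = integer(), last = integer(),
      start = integer(), end = integer(), stringsAsFactors = FALSE
    ))
  }
  data.frame(
    term = entry,
    first = idx[, "first"], last = idx[, "last"],
    start = tok_df$start[idx[, "first"]],
    end = tok_df$end[idx[, "last"]],
    stringsAsFactors = FALSE
  )
}

## Joined normalized text used for substring relevance matching:
## "crohn" hits "crohns" and "#crohnsdisease".
.joined_tokens <- function(tok_df) paste(tok_df$token, collapse = " ")
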