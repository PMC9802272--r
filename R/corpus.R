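## Corpus data model ---------------------------------------------------------
##
## A corpus is a list with:
##   $posts      data frame: post_id, platform, author, timestamp (POSIXct UTC),
##               text, post_type, subreddit, is_retweet, gold_topics (list col),
##               gold_distress (logical), .extra (list col of unknown fields)
##   $provenance free-text description
## N is nrow(posts). Unknown record fields ride along opaquely in .extra and
## are re-emitted on JSONL write.

.required_fields <- c("post_id", "platform", "text")
.known_fields <- c(
  "post_id", "platform", "author", "timestamp", "text", "post_type",
  "subreddit", "is_retweet", "gold_labels"
)

#' Construct a social-media corpus
#'
#' @param posts Data frame with at least `post_id`, `platform` (`"reddit"` or
#'   `"twitter"`) and `text`. Optional: `author`, `timestamp` (POSIXct, UTC),
#'   `post_type` (`"submission"`, `"comment"`, `"tweet"`), `subreddit`
#'   (reddit only), `is_retweet` (twitter only), `gold_topics` (list of
#'   character vectors) and `gold_distress` (logical) for synthetic corpora.
#' @param provenance Free-text description of where the posts came from.
#' @return An object of class `corpus`.
#' @export
corpus <- function(posts, provenance = "") {
  posts <- as.data.frame(posts, stringsAsFactors = FALSE)
  miss <- setdiff(.required_fields, names(posts))
  if (length(miss)) {
    stop_data("corpus posts are missing required field(s): ",
              paste(miss, collapse = ", "))
  }
  dup <- unique(posts$post_id[duplicated(posts$post_id)])
  if (length(dup)) {
    stop_data("duplicate post_id in corpus: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  bad <- setdiff(unique(posts$platform), c("reddit", "twitter"))
  if (length(bad)) stop_data("unknown platform(s): ", paste(bad, collapse = ", "))

  n <- nrow(posts)
  if (is.null(posts$author)) posts$author <- rep("", n)
  posts$author[is.na(posts$author)] <- ""
  if (is.null(posts$timestamp)) {
    posts$timestamp <- rep(as.POSIXct(NA, tz = "UTC"), length.out = n)
  } else {
    posts$timestamp <- as.POSIXct(posts$timestamp, tz = "UTC")
  }
  if (is.null(posts$post_type)) {
    posts$post_type <- ifelse(posts$platform == "twitter", "tweet", "comment")
  }
  if (is.null(posts$subreddit)) posts$subreddit <- rep(NA_character_, n)
  if (is.null(posts$is_retweet)) posts$is_retweet <- rep(NA, n)
  posts$is_retweet <- as.logical(posts$is_retweet)
  posts$is_retweet[posts$platform == "twitter" & is.na(posts$is_retweet)] <- FALSE
  posts$is_retweet[posts$platform == "reddit"] <- NA
  posts$subreddit[posts$platform == "twitter"] <- NA_character_
  if (is.null(posts$gold_topics)) posts$gold_topics <- replicate(n, NULL)
  if (is.null(posts$gold_distress)) posts$gold_distress <- rep(NA, n)
  posts$gold_distress <- as.logical(posts$gold_distress)
  if (is.null(posts$.extra)) posts$.extra <- replicate(nrow(posts), NULL)

  long <- posts$platform == "twitter" & nchar(posts$text) > 280L
  if (any(long)) {
    warning(sum(long), " tweet(s) exceed 280 characters", call. = FALSE)
  }

  structure(
    list(posts = posts, provenance = provenance),
    class = "corpus"
  )
}

#' @export
print.corpus <- function(x, ...) {
  tab <- table(x$posts$platform)
  cat("<corpus> N =", nrow(x$posts),
      paste0("(", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")"),
      "\n")
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of posts in a corpus
#' @param x A `corpus`.
#' @return Integer post count.
#' @export
n_posts <- function(x) nrow(x$posts)

#' @export
length.corpus <- function(x) nrow(x$posts)

.ts_format <- "%Y-%m-%dT%H:%M:%SZ"

.ts_to_chr <- function(ts) {
  out <- format(ts, .ts_format, tz = "UTC")
  out[is.na(ts)] <- NA_character_
  out
}

.chr_to_ts <- function(x) as.POSIXct(x, format = .ts_format, tz = "UTC")

## One post row -> plain list ready for JSON serialization.
.post_to_record <- function(row) {
  rec <- list(post_id = row$post_id, platform = row$platform)
  if (nzchar(row$author)) rec$author <- row$author
  if (!is.na(row$timestamp)) rec$timestamp <- .ts_to_chr(row$timestamp)
  rec$text <- row$text
  if (!is.na(row$post_type)) rec$post_type <- row$post_type
  if (!is.na(row$subreddit)) rec$subreddit <- row$subreddit
  if (!is.na(row$is_retweet)) rec$is_retweet <- row$is_retweet
  gt <- row$gold_topics[[1L]]
  if (!is.null(gt) || !is.na(row$gold_distress)) {
    rec$gold_labels <- list(
      topics = as.list(gt %||% character()),
      distress = isTRUE(row$gold_distress)
    )
  }
  extra <- row$.extra[[1L]]
  if (!is.null(extra) && length(extra)) rec <- c(rec, extra)
  rec
}

#' Write a corpus to disk
#'
#' JSON Lines is the interchange format (one UTF-8 JSON object per line);
#' CSV export flattens the gold topic set to a semicolon-joined string and
#' drops unknown pass-through fields that are not atomic.
#'
#' @param x A `corpus`.
#' @param path Output file path.
#' @param format `"jsonl"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("jsonl", "csv")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "corpus"))
  if (format == "jsonl") {
    lines <- vapply(seq_len(nrow(x$posts)), function(i) {
      jsonlite::toJSON(.post_to_record(x$posts[i, , drop = FALSE]),
                       auto_unbox = TRUE, null = "null", digits = NA)
    }, character(1))
    con <- file(path, open = "wb")
    on.exit(close(con))
    if (length(lines)) writeLines(lines, con, useBytes = TRUE)
  } else {
    df <- x$posts
    df$timestamp <- .ts_to_chr(df$timestamp)
    df$gold_topics <- vapply(df$gold_topics, function(g) {
      if (is.null(g)) NA_character_ else paste(g, collapse = ";")
    }, character(1))
    df$.extra <- NULL
    utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a corpus from disk
#'
#' Malformed JSONL records (unparseable, or missing `post_id`/`platform`/
#' `text`) are skipped and counted in the load report attached as attribute
#' `load_report` (`lines_read`, `well_formed`, `skipped`). Duplicate post ids
#' are an ingest error naming the id. Unknown fields are preserved and
#' round-trip through `write_corpus()`.
#'
#' @param path Input file path.
#' @param format `"jsonl"` or `"csv"`.
#' @param provenance Provenance string recorded on the corpus (defaults to
#'   the file path).
#' @return A `corpus`; attribute `load_report` holds the ingest counts.
#' @export
read_corpus <- function(path, format = c("jsonl", "csv"), provenance = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("corpus file not found: ", path)
  provenance <- provenance %||% path

  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- vector("list", length(lines))
    ok <- logical(length(lines))
    for (i in seq_along(lines)) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                      error = function(e) NULL)
      if (is.null(rec) || !all(.required_fields %in% names(rec))) next
      recs[[i]] <- rec
      ok[i] <- TRUE
    }
    recs <- recs[ok]
    if (length(lines) && !length(recs)) {
      stop_data("no record in ", path, " carries the required fields (",
                paste(.required_fields, collapse = ", "), ")")
    }
    posts <- data.frame(
      post_id = vapply(recs, function(r) as.character(r$post_id), character(1)),
      platform = vapply(recs, function(r) as.character(r$platform), character(1)),
      text = vapply(recs, function(r) as.character(r$text), character(1)),
      author = vapply(recs, function(r) as.character(r$author %||% ""), character(1)),
      post_type = vapply(recs, function(r) as.character(r$post_type %||% NA), character(1)),
      subreddit = vapply(recs, function(r) as.character(r$subreddit %||% NA), character(1)),
      stringsAsFactors = FALSE
    )
    posts$timestamp <- .chr_to_ts(
      vapply(recs, function(r) as.character(r$timestamp %||% NA), character(1))
    )
    posts$is_retweet <- vapply(recs, function(r) {
      v <- r$is_retweet
      if (is.null(v)) NA else as.logical(v)
    }, logical(1))
    posts$gold_topics <- lapply(recs, function(r) {
      gl <- r$gold_labels
      if (is.null(gl)) NULL else as.character(unlist(gl$topics))
    })
    posts$gold_distress <- vapply(recs, function(r) {
      gl <- r$gold_labels
      if (is.null(gl)) NA else isTRUE(gl$distress)
    }, logical(1))
    posts$.extra <- lapply(recs, function(r) {
      r[setdiff(names(r), .known_fields)]
    })
    report <- list(
      lines_read = length(lines),
      well_formed = length(recs),
      skipped = length(lines) - length(recs)
    )
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                          colClasses = "character")
    miss <- setdiff(.required_fields, names(df))
    if (length(miss)) {
      stop_data("CSV corpus missing required column(s): ",
                paste(miss, collapse = ", "))
    }
    posts <- df
    posts$timestamp <- if (is.null(df$timestamp)) {
      as.POSIXct(NA, tz = "UTC")
    } else {
      .chr_to_ts(ifelse(nzchar(df$timestamp), df$timestamp, NA))
    }
    posts$subreddit <- if (is.null(df$subreddit)) NA_character_ else
      ifelse(nzchar(df$subreddit), df$subreddit, NA_character_)
    posts$post_type <- if (is.null(df$post_type)) NA_character_ else
      ifelse(nzchar(df$post_type), df$post_type, NA_character_)
    posts$is_retweet <- if (is.null(df$is_retweet)) NA else
      as.logical(ifelse(nzchar(df$is_retweet), df$is_retweet, NA))
    posts$gold_topics <- if (is.null(df$gold_topics)) {
      replicate(nrow(df), NULL)
    } else {
      lapply(df$gold_topics, function(s) {
        if (is.na(s) || !nzchar(s)) NULL else strsplit(s, ";", fixed = TRUE)[[1L]]
      })
    }
    posts$gold_distress <- if (is.null(df$gold_distress)) NA else
      as.logical(ifelse(nzchar(df$gold_distress), df$gold_distress, NA))
    report <- list(lines_read = nrow(df), well_formed = nrow(df), skipped = 0L)
  }

  dup <- unique(posts$post_id[duplicated(posts$post_id)])
  if (length(dup)) {
    stop_data("duplicate post_id on ingest: ", paste(dup, collapse = ", "))
  }
  out <- corpus(posts, provenance = provenance)
  attr(out, "load_report") <- report
  message(sprintf("read_corpus: %d read, %d well-formed, %d skipped",
                  report$lines_read, report$well_formed, report$skipped))
  out
}

## Subset a corpus by a logical/integer index, preserving provenance.
subset_corpus <- function(x, idx) {
  out <- x
  out$posts <- x$posts[idx, , drop = FALSE]
  rownames(out$posts) <- NULL
  out
}
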