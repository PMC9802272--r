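## Descriptive corpus summaries ---------------------------------------------

#' Extract normalized hashtags
#'
#' Whitespace-delimited tokens beginning with `#`: the `#` is stripped, the
#' tag lower-cased and non-alphanumeric characters removed; tags empty after
#' normalization are dropped. Duplicates are preserved (unique counting
#' happens downstream).
#'
#' @param text A single character string.
#' @return Character vector of normalized hashtags.
#' @examples
#' extract_hashtags("#Crohns awareness day #IBD")
#' @export
extract_hashtags <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(text, "[[:space:]]+")[[1L]]
  tags <- toks[startsWith(toks, "#")]
  norm <- gsub("[^a-z0-9]", "", tolower(sub("^#", "", tags)))
  norm[nzchar(norm)]
}

#' Count hyperlinks in a text
#'
#' Counts maximal substrings matching `http(s)://` or `www.`-prefixed URL
#' patterns; every occurrence counts.
#'
#' @param text A single character string.
#' @return Integer count.
#' @examples
#' count_hyperlinks("see https://a.org and www.b.org")
#' @export
count_hyperlinks <- function(text) {
  if (is.na(text) || !nzchar(text)) return(0L)
  m <- gregexpr(.url_regex, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' Integer percentage with the "<1%" convention
#'
#' `pct_value()` rounds `100 * n / total` half-up to an integer;
#' `pct_label()` renders it, with nonzero proportions that round to 0 shown
#' as `"<1%"`. This pair of conventions reproduces printed n (%) tables
#' from their integer numerators and denominators.
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @return `pct_value()`: numeric; `pct_label()`: character.
#' @export
pct_value <- function(n, total) {
  if (total <= 0) return(NA_real_)
  round_half_up(100 * n / total)
}

#' @rdname pct_value
#' @export
pct_label <- function(n, total) {
  p <- pct_value(n, total)
  if (is.na(p)) return(NA_character_)
  if (n > 0 && p == 0) "<1%" else paste0(p, "%")
}

#' Mean and SD formatted "M ± SD"
#'
#' @param x Numeric vector.
#' @param sd_type `"sample"` (n - 1 denominator, default) or `"population"`.
#' @param digits Decimal places (default 2).
#' @return List with numeric `mean`, `sd` and character `label`.
#' @export
mean_sd <- function(x, sd_type = c("sample", "population"), digits = 2) {
  sd_type <- match.arg(sd_type)
  m <- mean(x)
  s <- stats::sd(x)
  if (sd_type == "population") s <- s * sqrt((length(x) - 1) / length(x))
  list(
    mean = round(m, digits), sd = round(s, digits),
    label = sprintf("%.*f ± %.*f", digits, m, digits, s)
  )
}

#' Rank a count table with n (%) rendering
#'
#' Descending by count, ties broken lexicographically by name; percentages
#' use the half-up integer convention with `"<1%"` for nonzero sub-half
#' proportions. `k` larger than the item count returns the full list.
#'
#' @param items Named integer vector (or data frame with `name`, `count`).
#' @param k Number of rows to keep (>= 1).
#' @param total Denominator for percentages (corpus size).
#' @return Data frame `name`, `count`, `pct` (character labels).
#' @export
rank_table <- function(items, k, total) {
  if (k < 1L) stop_data("k must be >= 1")
  if (is.data.frame(items)) {
    nm <- items$name
    ct <- items$count
  } else {
    nm <- names(items)
    ct <- as.vector(items)
  }
  if (any(ct < 0)) stop_data("counts must be non-negative")
  ord <- order(-ct, nm)
  keep <- utils::head(ord, k)
  data.frame(
    name = nm[keep],
    count = ct[keep],
    pct = vapply(ct[keep], pct_label, character(1), total = total),
    stringsAsFactors = FALSE
  )
}

.summarize_platform <- function(posts, tmat, platform, top_k, sd_type) {
  N <- nrow(posts)
  out <- list(platform = platform, N = N)

  authors <- posts$author[nzchar(posts$author)]
  out$unique_users <- length(unique(authors))
  if (length(authors)) {
    out$posts_per_user <- mean_sd(as.vector(table(authors)), sd_type = sd_type)
  }

  nlinks <- vapply(posts$text, count_hyperlinks, integer(1), USE.NAMES = FALSE)
  out$posts_with_hyperlinks <- list(
    n = sum(nlinks > 0L), pct = pct_label(sum(nlinks > 0L), N)
  )
  out$total_hyperlinks <- sum(nlinks)

  out$post_type_counts <- as.list(table(posts$post_type))

  if (platform == "reddit") {
    subs <- posts$subreddit[!is.na(posts$subreddit)]
    out$unique_subreddits <- length(unique(subs))
    if (length(subs)) {
      out$top_subreddits <- rank_table(table(subs), k = top_k, total = N)
    }
  }

  if (platform == "twitter") {
    tags <- lapply(posts$text, extract_hashtags)
    ntags <- vapply(tags, length, integer(1))
    out$total_hashtags <- sum(ntags)
    out$unique_hashtags <- length(unique(unlist(tags)))
    out$tweets_with_hashtags <- list(
      n = sum(ntags > 0L), pct = pct_label(sum(ntags > 0L), N)
    )
    out$hashtags_per_post <- mean_sd(ntags, sd_type = sd_type)
    if (out$total_hashtags > 0L) {
      out$top_hashtags <- rank_table(table(unlist(tags)), k = top_k, total = N)
    }
  }

  k_per_post <- rowSums(tmat)
  topic_n <- colSums(tmat)
  out$topic_prevalence <- data.frame(
    topic = colnames(tmat),
    n = as.integer(topic_n),
    pct = vapply(as.integer(topic_n), pct_label, character(1), total = N),
    stringsAsFactors = FALSE
  )
  n1 <- sum(k_per_post == 1L)
  n2 <- sum(k_per_post == 2L)
  n3p <- sum(k_per_post >= 3L)
  out$at_least_one_topic <- list(n = n1 + n2 + n3p, pct = pct_label(n1 + n2 + n3p, N))
  out$no_topic <- list(n = N - (n1 + n2 + n3p), pct = pct_label(N - (n1 + n2 + n3p), N))
  out$topic_count_distribution <- list(
    exactly_1 = list(n = n1, pct = pct_label(n1, N)),
    exactly_2 = list(n = n2, pct = pct_label(n2, N)),
    three_plus = list(n = n3p, pct = pct_label(n3p, N))
  )
  out
}

#' Descriptive summary of a classified corpus
#'
#' Per-platform corpus characteristics in the layout of standard
#' content-analysis descriptive tables: users and posts-per-user (M +/- SD),
#' hyperlink counts, post types, subreddit and hashtag rankings, per-topic
#' prevalence, and the single/multi-topic distribution. Percentages are
#' computed from the stored integer counts with the half-up / "<1%"
#' convention; means and SDs are reported to 2 decimals (sample SD by
#' default).
#'
#' @param x A `corpus`.
#' @param assignments A `topic_assignments` object aligned with `x` (same
#'   posts, same order).
#' @param top_k Rows kept in subreddit/hashtag rankings (default 10).
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return An object of class `summary_report`: named list with one block
#'   per platform present in the corpus.
#' @export
summarize_corpus <- function(x, assignments, top_k = 10L,
                             sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  stopifnot(inherits(x, "corpus"))
  ids <- vapply(assignments, function(a) as.character(a$post_id), character(1))
  if (length(assignments) != nrow(x$posts) || !identical(ids, x$posts$post_id)) {
    stop_data("assignments are not aligned with the corpus")
  }
  tmat <- topic_matrix(assignments)
  blocks <- lapply(sort(unique(x$posts$platform)), function(p) {
    sel <- x$posts$platform == p
    .summarize_platform(x$posts[sel, , drop = FALSE],
                        tmat[sel, , drop = FALSE], p, top_k, sd_type)
  })
  names(blocks) <- sort(unique(x$posts$platform))
  structure(blocks, class = "summary_report")
}

#' @export
print.summary_report <- function(x, ...) {
  for (b in x) {
    cat(sprintf("== %s (N = %d) ==\n", b$platform, b$N))
    cat(sprintf("  unique users: %d", b$unique_users))
    if (!is.null(b$posts_per_user)) {
      cat(sprintf("  | posts/user: %s", b$posts_per_user$label))
    }
    cat("\n")
    cat(sprintf("  posts with hyperlinks: %d (%s); total hyperlinks: %d\n",
                b$posts_with_hyperlinks$n, b$posts_with_hyperlinks$pct,
                b$total_hyperlinks))
    if (!is.null(b$hashtags_per_post)) {
      cat(sprintf("  hashtags: %d total, %d unique; tweets with >=1: %d (%s); per post: %s\n",
                  b$total_hashtags, b$unique_hashtags,
                  b$tweets_with_hashtags$n, b$tweets_with_hashtags$pct,
                  b$hashtags_per_post$label))
    }
    cat(sprintf("  at least 1 topic: %d (%s)\n",
                b$at_least_one_topic$n, b$at_least_one_topic$pct))
    tp <- b$topic_prevalence
    for (i in seq_len(nrow(tp))) {
      cat(sprintf("    %-11s %6d (%s)\n", tp$topic[i], tp$n[i], tp$pct[i]))
    }
    d <- b$topic_count_distribution
    cat(sprintf("  1 topic: %d (%s) | 2 topics: %d (%s) | 3+: %d (%s)\n",
                d$exactly_1$n, d$exactly_1$pct,
                d$exactly_2$n, d$exactly_2$pct,
                d$three_plus$n, d$three_plus$pct))
  }
  invisible(x)
}

#' Write a summary report as JSON
#'
#' @param report A [summarize_corpus()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}
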