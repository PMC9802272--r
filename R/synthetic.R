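## Seeded synthetic corpus generator with gold labels -----------------------
##
## The pipeline is purely lexical, so the generator emulates lexical
## structure only: planted topic signal terms, distress markers,
## false-positive trap phrases, platform length regimes, hashtags,
## hyperlinks, same-user duplicates and retweets. Everything flows from one
## seed; identical configs produce byte-identical corpora.

## Vocabulary aligned with the shipped illustrative dictionary. Signal terms
## are pairwise disjoint across topics and disjoint from filler, distress
## markers and trap tokens, so in strict mode the classifier's gold recovery
## is exact by construction.
.default_vocabulary <- function() {
  list(
    signal = list(
      symptoms = c("diarrhea", "cramping", "nausea"),
      medication = c("prednisone", "stelara", "humira"),
      nutrition = c("fodmap", "fiber", "gluten"),
      procedures = c("colonoscopy", "resection", "endoscopy"),
      marijuana = c("cannabis", "weed", "edibles"),
      stigma = c("stigma", "taboo", "embarrassing"),
      ostomy = c("stoma", "ileostomy", "colostomy"),
      intimacy = c("intimacy", "dating", "girlfriend")
    ),
    ## per-topic false-positive traps: phrase planted verbatim; `term` is the
    ## dictionary entry it spuriously contains
    trap = list(
      symptoms = "tired of explaining",
      medication = "drug test",
      nutrition = "diet coke",
      procedures = "rocket surgery",
      marijuana = "pot of coffee",
      stigma = "awkward silence",
      ostomy = "bag of chips",
      intimacy = "date of birth"
    ),
    distress_unigrams = c("afraid", "scared", "anxious", "hopeless"),
    distress_phrases = c("feel alone", "hard to manage"),
    openers = c("living with crohns", "my ibd journey", "ulcerative colitis update"),
    hashtags = c("#crohns", "#ibd", "#colitis", "#crohnsdisease", "#ulcerativecolitis"),
    filler = c("today", "really", "honestly", "just", "another", "week",
               "trying", "keep", "going", "still", "some", "days", "are",
               "better", "than", "others", "figuring", "things", "out",
               "slowly", "one", "step", "at", "a", "time")
  )
}

#' Synthetic corpus generator configuration
#'
#' Defaults emulate the statistical shape of a two-platform IBD/distress
#' study corpus: per-topic prevalences follow the published Reddit topic
#' proportions, hashtag/hyperlink rates follow the published platform
#' characteristics, and Twitter posts respect the 280-character limit.
#'
#' Two topic-assignment modes are available. By default
#' (`multi_topic_mixing = NULL`) each topic is drawn independently
#' Bernoulli(prevalence), so every configured prevalence is the exact
#' marginal probability. Supplying `multi_topic_mixing` (probabilities over
#' per-post topic counts 0..4, e.g. a truncated geometric) switches to
#' count mode: the topic count is drawn from that distribution and topics
#' are then drawn without replacement with prevalence-proportional weights.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param n_posts Named integer vector, base posts per platform.
#' @param topic_prevalence Named probabilities over the topic inventory.
#' @param multi_topic_mixing `NULL` (default) or numeric probabilities over
#'   topic counts `0:(length(multi_topic_mixing) - 1)`.
#' @param distress_rate Probability a post carries a planted distress marker.
#' @param fp_trap_rate Probability a post carries a false-positive trap
#'   phrase (inserted independently of gold labels).
#' @param duplicate_rate Fraction of extra same-user duplicate posts
#'   appended (per platform).
#' @param retweet_rate Fraction of extra retweet copies appended (Twitter).
#' @param offtopic_rate Fraction of extra off-topic posts appended (no IBD
#'   keyword, or an exclusion context such as an animal diagnosis).
#' @param hashtag_rate Probability a tweet gets hashtags.
#' @param hyperlink_rate Named per-platform probability of an embedded URL.
#' @param mode `"strict"` (disjoint vocabularies; exact-recovery oracle) or
#'   `"confusable"` (off-gold dictionary terms leak into posts at
#'   `confusable_rate`, exercising precision < 1 paths).
#' @param confusable_rate Leak probability in confusable mode.
#' @param vocabulary Vocabulary list; see `ibdtopics:::.default_vocabulary`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    n_posts = c(reddit = 500L, twitter = 500L),
    topic_prevalence = c(symptoms = 0.57, medication = 0.30, nutrition = 0.27,
                         procedures = 0.17, marijuana = 0.08, stigma = 0.04,
                         ostomy = 0.03, intimacy = 0.02),
    multi_topic_mixing = NULL,
    distress_rate = 0.8,
    fp_trap_rate = 0.1,
    duplicate_rate = 0.02,
    retweet_rate = 0.05,
    offtopic_rate = 0.02,
    hashtag_rate = 0.31,
    hyperlink_rate = c(reddit = 0.04, twitter = 0.25),
    mode = c("strict", "confusable"),
    confusable_rate = 0.1,
    vocabulary = .default_vocabulary()) {
  mode <- match.arg(mode)
  probs <- c(topic_prevalence, distress_rate, fp_trap_rate, duplicate_rate,
             retweet_rate, offtopic_rate, hashtag_rate, hyperlink_rate,
             confusable_rate, multi_topic_mixing)
  if (any(probs < 0 | probs > 1)) stop_data("all rates must lie in [0, 1]")
  if (!is.null(multi_topic_mixing)) {
    if (abs(sum(multi_topic_mixing) - 1) > 1e-8) {
      stop_data("multi_topic_mixing must sum to 1")
    }
    if (length(multi_topic_mixing) - 1L > length(topic_prevalence)) {
      stop_data("mixing support exceeds number of topics")
    }
  }
  if (is.null(names(topic_prevalence)) ||
      !all(names(topic_prevalence) %in% names(vocabulary$signal))) {
    stop_data("topic_prevalence names must match the vocabulary's signal topics")
  }
  ## strict mode requires disjoint signal vocabularies
  sig <- unlist(vocabulary$signal, use.names = FALSE)
  if (mode == "strict" && anyDuplicated(sig)) {
    stop_data("strict mode requires pairwise-disjoint signal vocabularies")
  }
  if (length(intersect(sig, vocabulary$filler))) {
    stop_data("signal terms must be disjoint from filler vocabulary")
  }
  structure(
    list(
      seed = as.integer(seed), n_posts = n_posts,
      topic_prevalence = topic_prevalence,
      multi_topic_mixing = multi_topic_mixing,
      distress_rate = distress_rate, fp_trap_rate = fp_trap_rate,
      duplicate_rate = duplicate_rate, retweet_rate = retweet_rate,
      offtopic_rate = offtopic_rate, hashtag_rate = hashtag_rate,
      hyperlink_rate = hyperlink_rate, mode = mode,
      confusable_rate = confusable_rate, vocabulary = vocabulary
    ),
    class = "generator_config"
  )
}

#' Truncated geometric mixing distribution
#'
#' Convenience constructor for count-mode generation: probabilities
#' proportional to `(1 - p)^k` on `k = 0, ..., kmax`.
#'
#' @param p Geometric decay parameter in (0, 1).
#' @param kmax Largest per-post topic count (default 4).
#' @return Numeric probability vector over `0:kmax`.
#' @export
truncated_geometric <- function(p, kmax = 4L) {
  if (p <= 0 || p >= 1) stop_data("p must lie in (0, 1)")
  w <- (1 - p)^(0:kmax)
  w / sum(w)
}

.draw_gold_topics <- function(config) {
  topics <- names(config$topic_prevalence)
  if (is.null(config$multi_topic_mixing)) {
    topics[stats::runif(length(topics)) < config$topic_prevalence]
  } else {
    kmax <- length(config$multi_topic_mixing) - 1L
    k <- sample_vec(0:kmax, 1L, prob = config$multi_topic_mixing)
    if (k == 0L) character() else {
      sample_vec(topics, k, prob = config$topic_prevalence)
    }
  }
}

## Assemble one post's text. Mandatory pieces: opener, one signal snippet per
## gold topic, a distress marker iff flagged, a trap phrase if drawn.
## Optional pieces (filler, hashtags, hyperlink) are appended only while a
## Twitter post stays within 280 characters.
.assemble_text <- function(platform, terms, distress, trap_topic,
                           leak_term, hashtag, hyperlink, config) {
  v <- config$vocabulary
  opener <- sample_vec(v$openers, 1L)
  marker <- if (distress) {
    sample_vec(c(v$distress_unigrams, v$distress_phrases), 1L)
  } else NULL
  trap <- if (!is.na(trap_topic)) v$trap[[trap_topic]] else NULL
  leak <- if (!is.na(leak_term)) leak_term else NULL

  pieces <- c(
    opener,
    if (length(terms)) paste("dealing with", terms, "lately"),
    if (!is.null(marker)) paste("feeling", marker, "about it"),
    trap, leak
  )
  text <- paste(pieces, collapse = ". ")
  limit <- if (platform == "twitter") 280L else Inf
  if (nchar(text) > limit) {
    ## compact form: drop the connective templates, keep the planted tokens
    text <- paste(c(opener, terms, marker, trap, leak), collapse = " ")
    if (nchar(text) > limit) {
      stop_data("required planted terms exceed the ", limit,
                "-character limit for ", platform)
    }
  }

  optional <- character()
  if (!is.na(hyperlink)) optional <- c(optional, hyperlink)
  if (hashtag) {
    optional <- c(optional,
                  paste(sample_vec(v$hashtags, sample_vec(1:3, 1L)), collapse = " "))
  }
  n_fill <- if (platform == "reddit") sample_vec(10:40, 1L) else sample_vec(0:6, 1L)
  if (n_fill > 0L) {
    optional <- c(optional,
                  paste(sample_vec(v$filler, n_fill, replace = TRUE), collapse = " "))
  }
  for (piece in optional) {
    cand <- paste(text, piece)
    if (nchar(cand) <= limit) text <- cand
  }
  list(text = text, opener = opener, marker = marker)
}

.generate_platform <- function(platform, n, config, id_offset, t0) {
  v <- config$vocabulary
  topics <- names(config$topic_prevalence)
  n_users <- max(1L, ceiling(n / 2))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    gold <- .draw_gold_topics(config)
    distress <- stats::runif(1) < config$distress_rate
    trap_topic <- if (stats::runif(1) < config$fp_trap_rate) {
      sample_vec(names(v$trap), 1L)
    } else NA_character_
    leak_term <- NA_character_
    if (config$mode == "confusable" && stats::runif(1) < config$confusable_rate) {
      off <- setdiff(topics, gold)
      if (length(off)) {
        leak_topic <- sample_vec(off, 1L)
        leak_term <- sample_vec(v$signal[[leak_topic]], 1L)
      }
    }
    hashtag <- platform == "twitter" && stats::runif(1) < config$hashtag_rate
    link_rate <- config$hyperlink_rate[[platform]] %||% 0
    hyperlink <- if (stats::runif(1) < link_rate) {
      sprintf("https://example.org/p%05d", sample_vec(1:99999, 1L))
    } else NA_character_

    term_by_topic <- vapply(gold, function(tp) sample_vec(v$signal[[tp]], 1L),
                            character(1))
    names(term_by_topic) <- gold
    asm <- .assemble_text(platform, term_by_topic, distress, trap_topic,
                          leak_term, hashtag, hyperlink, config)
    rows[[i]] <- list(
      meta = list(opener = asm$opener, terms = term_by_topic, marker = asm$marker),
      text = asm$text,
      post_id = sprintf("%s_%06d", substr(platform, 1, 2), id_offset + i),
      platform = platform,
      author = sprintf("user_%s_%05d", substr(platform, 1, 2),
                       sample_vec(seq_len(n_users), 1L)),
      timestamp = t0 + 60 * (id_offset + i),
      post_type = if (platform == "twitter") "tweet" else {
        if (stats::runif(1) < 0.05) "submission" else "comment"
      },
      subreddit = if (platform == "reddit") {
        sample_vec(
          c("CrohnsDisease", "AskReddit", "UlcerativeColitis", "IBD", "ibs",
            "AskDocs", "ostomy", sprintf("community_%03d", 1:40)),
          1L,
          prob = c(0.26, 0.13, 0.03, 0.03, 0.02, 0.01, 0.01, rep(0.51 / 40, 40))
        )
      } else NA_character_,
      is_retweet = if (platform == "twitter") FALSE else NA,
      gold_topics = gold,
      gold_distress = distress
    )
  }
  rows
}

.rows_to_posts <- function(rows) {
  data.frame(
    post_id = vapply(rows, `[[`, character(1), "post_id"),
    platform = vapply(rows, `[[`, character(1), "platform"),
    author = vapply(rows, `[[`, character(1), "author"),
    timestamp = as.POSIXct(vapply(rows, function(r) as.numeric(r$timestamp), numeric(1)),
                           origin = "1970-01-01", tz = "UTC"),
    text = vapply(rows, `[[`, character(1), "text"),
    post_type = vapply(rows, `[[`, character(1), "post_type"),
    subreddit = vapply(rows, `[[`, character(1), "subreddit"),
    is_retweet = vapply(rows, function(r) as.logical(r$is_retweet), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic labeled corpus
#'
#' Produces the configured number of base posts per platform, each carrying
#' gold topic and distress labels realized exactly in the text (only the
#' gold topics' signal terms appear; a distress marker appears iff the gold
#' distress flag is set; false-positive trap phrases are planted
#' independently of the gold labels). On top of the base posts it appends,
#' per the configured rates: same-user duplicate copies (later timestamp,
#' new id), retweet copies (Twitter), and off-topic posts (no IBD keyword or
#' an exclusion context, empty gold labels) — the material the cleaning
#' filters exist to remove. Deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @return A `corpus` with `gold_topics`/`gold_distress` set; provenance
#'   records seed and mode. Attribute `n_base` gives the per-platform base
#'   post counts (before injected duplicates/retweets/off-topic posts).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, {
    t0 <- as.POSIXct("2017-09-01 00:00:00", tz = "UTC")
    all_rows <- list()
    extra_rows <- list()
    id_offset <- 0L
    for (platform in names(config$n_posts)) {
      n <- config$n_posts[[platform]]
      rows <- .generate_platform(platform, n, config, id_offset, t0)
      id_offset <- id_offset + n

      ## same-user duplicates: exact text copies, later timestamp, new id
      n_dup <- round(config$duplicate_rate * n)
      if (n_dup > 0L && length(rows)) {
        src <- sample_vec(seq_along(rows), n_dup, replace = TRUE)
        for (j in seq_along(src)) {
          d <- rows[[src[j]]]
          d$post_id <- sprintf("%s_dup_%05d", substr(platform, 1, 2), j)
          d$timestamp <- d$timestamp + 86400
          extra_rows[[length(extra_rows) + 1L]] <- d
        }
      }
      ## retweets: flagged copies, plus an "rt @" prefixed variant whose text
      ## is rebuilt from the source post's planted pieces so its gold labels
      ## stay consistent within the 280-character limit
      if (platform == "twitter") {
        n_rt <- round(config$retweet_rate * n)
        if (n_rt > 0L && length(rows)) {
          src <- sample_vec(seq_along(rows), n_rt, replace = TRUE)
          for (j in seq_along(src)) {
            d <- rows[[src[j]]]
            d$post_id <- sprintf("tw_rt_%05d", j)
            d$author <- sprintf("user_tw_rt_%05d", j)
            d$timestamp <- d$timestamp + 3600
            if (j %% 2L == 0L) {
              d$is_retweet <- TRUE
            } else {
              ## flag missing in some archive dumps; prefix is the fallback cue
              meta <- rows[[src[j]]]$meta
              text <- paste0("RT @", sub("^user_", "", rows[[src[j]]]$author),
                             ": ", meta$opener)
              gold_rt <- character()
              for (tp in names(meta$terms)) {
                cand <- paste(text, meta$terms[[tp]])
                if (nchar(cand) <= 280L) {
                  text <- cand
                  gold_rt <- c(gold_rt, tp)
                }
              }
              distress_rt <- FALSE
              if (!is.null(meta$marker)) {
                cand <- paste(text, meta$marker)
                if (nchar(cand) <= 280L) {
                  text <- cand
                  distress_rt <- TRUE
                }
              }
              d$text <- text
              d$gold_topics <- gold_rt
              d$gold_distress <- distress_rt
            }
            extra_rows[[length(extra_rows) + 1L]] <- d
          }
        }
      }
      ## off-topic posts: removed by the relevance filter
      n_off <- round(config$offtopic_rate * n)
      if (n_off > 0L) {
        for (j in seq_len(n_off)) {
          animal <- j %% 2L == 0L
          extra_rows[[length(extra_rows) + 1L]] <- list(
            post_id = sprintf("%s_off_%05d", substr(platform, 1, 2), j),
            platform = platform,
            author = sprintf("user_%s_off_%05d", substr(platform, 1, 2), j),
            timestamp = t0 + 30 * j,
            text = if (animal) {
              "I just learned my dog has ibd and the vet visit was long"
            } else {
              "great earnings report in the business daily today"
            },
            post_type = if (platform == "twitter") "tweet" else "comment",
            subreddit = if (platform == "reddit") "news" else NA_character_,
            is_retweet = if (platform == "twitter") FALSE else NA,
            gold_topics = character(),
            gold_distress = FALSE
          )
        }
      }
      all_rows <- c(all_rows, rows)
    }
    all_rows <- c(all_rows, extra_rows)
    posts <- .rows_to_posts(all_rows)
    posts$gold_topics <- lapply(all_rows, `[[`, "gold_topics")
    posts$gold_distress <- vapply(all_rows, `[[`, logical(1), "gold_distress")
    out <- corpus(posts, provenance = sprintf(
      "synthetic corpus (seed %d, mode %s)", config$seed, config$mode
    ))
    attr(out, "n_base") <- config$n_posts
    attr(out, "config") <- config
    out
  })
}

#' Evaluate topic assignments against gold labels
#'
#' Standard per-topic precision/recall with confusion counts, plus pooled
#' micro-averages. Precision is `NA` for a topic with no predicted
#' positives (reported as such, not as 0 or 1).
#'
#' @param assignments A `topic_assignments` object.
#' @param x The gold-labeled `corpus` the assignments came from (same posts,
#'   same order).
#' @return List with `per_topic` (data frame topic/tp/fp/fn/tn/precision/
#'   recall) and `micro` (pooled precision/recall).
#' @export
gold_evaluation <- function(assignments, x) {
  stopifnot(inherits(x, "corpus"))
  if (all(vapply(x$posts$gold_topics, is.null, logical(1))) &&
      all(is.na(x$posts$gold_distress))) {
    stop_data("corpus carries no gold labels")
  }
  ids <- vapply(assignments, function(a) as.character(a$post_id), character(1))
  if (!identical(ids, x$posts$post_id)) {
    stop_data("assignments are not aligned with the corpus")
  }
  topics <- attr(assignments, "topic_names") %||% CANONICAL_TOPICS
  pred <- topic_matrix(assignments, topics = topics)
  gold <- matrix(FALSE, nrow(pred), ncol(pred), dimnames = dimnames(pred))
  for (i in seq_len(nrow(x$posts))) {
    gold[i, intersect(x$posts$gold_topics[[i]], topics)] <- TRUE
  }
  per <- do.call(rbind, lapply(topics, function(tp) {
    tp_n <- sum(pred[, tp] & gold[, tp])
    fp_n <- sum(pred[, tp] & !gold[, tp])
    fn_n <- sum(!pred[, tp] & gold[, tp])
    tn_n <- sum(!pred[, tp] & !gold[, tp])
    data.frame(
      topic = tp, tp = tp_n, fp = fp_n, fn = fn_n, tn = tn_n,
      precision = if (tp_n + fp_n > 0) tp_n / (tp_n + fp_n) else NA_real_,
      recall = if (tp_n + fn_n > 0) tp_n / (tp_n + fn_n) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(per) <- NULL
  tp_all <- sum(per$tp); fp_all <- sum(per$fp); fn_all <- sum(per$fn)
  list(
    per_topic = per,
    micro = list(
      precision = if (tp_all + fp_all > 0) tp_all / (tp_all + fp_all) else NA_real_,
      recall = if (tp_all + fn_all > 0) tp_all / (tp_all + fn_all) else NA_real_
    )
  )
}
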