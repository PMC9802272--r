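## Intercoder reliability and validation sampling ---------------------------

#' Construct a coding matrix
#'
#' Units x coders label matrix over a finite nominal category set. A
#' "computer" coder (classifier output) is an ordinary column, which is how
#' the human-vs-computer comparison is assembled. Missing entries are `NA`.
#'
#' @param labels Matrix (or data frame) of labels; rows = units, columns =
#'   coders. Values are coerced to character.
#' @param unit_ids Optional unit identifiers (default rownames or 1..n).
#' @param coders Optional coder names (default colnames or c1..ck).
#' @return An object of class `coding_matrix`.
#' @export
coding_matrix <- function(labels, unit_ids = NULL, coders = NULL) {
  m <- as.matrix(labels)
  storage.mode(m) <- "character"
  unit_ids <- unit_ids %||% rownames(m) %||% as.character(seq_len(nrow(m)))
  coders <- coders %||% colnames(m) %||% paste0("c", seq_len(ncol(m)))
  if (length(unit_ids) != nrow(m)) stop_data("unit_ids length != number of rows")
  if (length(coders) != ncol(m)) stop_data("coders length != number of columns")
  dimnames(m) <- list(unit_ids, coders)
  structure(list(labels = m, unit_ids = unit_ids, coders = coders),
            class = "coding_matrix")
}

#' Read / write a coding matrix as CSV
#'
#' First column `unit_id`, one column per coder; empty cells are missing.
#'
#' @param path CSV file path.
#' @return [read_coding_matrix()] returns a `coding_matrix`;
#'   [write_coding_matrix()] returns `path` invisibly.
#' @export
read_coding_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (names(df)[1L] != "unit_id") stop_data("first CSV column must be unit_id")
  m <- as.matrix(df[, -1L, drop = FALSE])
  m[m == ""] <- NA_character_
  coding_matrix(m, unit_ids = df$unit_id, coders = names(df)[-1L])
}

#' @rdname read_coding_matrix
#' @param x A `coding_matrix`.
#' @export
write_coding_matrix <- function(x, path) {
  stopifnot(inherits(x, "coding_matrix"))
  df <- data.frame(unit_id = x$unit_ids, x$labels, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Krippendorff's alpha (nominal)
#'
#' Chance-corrected intercoder reliability, alpha = 1 - D_o/D_e, computed
#' through the coincidence-matrix formulation: each unit with m >= 2
#' non-missing labels contributes every ordered pair of its values with
#' weight 1/(m - 1); observed disagreement sums the off-diagonal coincidence
#' mass and expected disagreement comes from the category marginals. Units
#' with fewer than two non-missing labels are excluded. Handles any number
#' of coders and missing data.
#'
#' When every pairable value falls in one category, expected disagreement is
#' zero and alpha is undefined: `NA` is returned with a warning rather than
#' overstating reliability on a degenerate sample.
#'
#' @param x A [coding_matrix()].
#' @return An object of class `reliability_result`: list with `alpha`,
#'   `n_units` (pairable units), `n_coders`, `n_pairable` (pairable values),
#'   `category_counts`, and the `coincidence` matrix.
#' @export
krippendorff_alpha <- function(x) {
  stopifnot(inherits(x, "coding_matrix"))
  m <- x$labels
  if (ncol(m) < 2L) stop_data("alpha needs at least 2 coders")
  cats <- sort(unique(as.vector(m[!is.na(m)])))
  if (!length(cats)) stop_data("no non-missing labels")

  o <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  n_units_used <- 0L
  for (u in seq_len(nrow(m))) {
    vals <- m[u, !is.na(m[u, ])]
    mu <- length(vals)
    if (mu < 2L) next
    n_units_used <- n_units_used + 1L
    w <- 1 / (mu - 1)
    for (i in seq_len(mu)) {
      for (j in seq_len(mu)) {
        if (i != j) o[vals[i], vals[j]] <- o[vals[i], vals[j]] + w
      }
    }
  }
  if (n_units_used == 0L) stop_data("no unit has two or more pairable values")

  nc <- rowSums(o)
  n <- sum(nc)
  d_o_num <- sum(o) - sum(diag(o))
  d_e_num <- n^2 - sum(nc^2)
  alpha <- if (d_e_num <= 0) {
    warning("expected disagreement is zero (single category used); ",
            "alpha is undefined", call. = FALSE)
    NA_real_
  } else {
    1 - (n - 1) * d_o_num / d_e_num
  }

  structure(
    list(
      alpha = alpha,
      n_units = n_units_used,
      n_coders = ncol(m),
      n_pairable = n,
      category_counts = nc,
      coincidence = o
    ),
    class = "reliability_result"
  )
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> alpha = %s over %d units, %d coders\n",
              ifelse(is.na(x$alpha), "undefined", sprintf("%.4f", x$alpha)),
              x$n_units, x$n_coders))
  invisible(x)
}

#' Percent agreement between two coders
#'
#' Fraction of units on which the two coders assign identical labels.
#' Defined only for exactly two coders with complete data; for anything else
#' use [krippendorff_alpha()].
#'
#' @param x A [coding_matrix()] with 2 coders, no missing labels.
#' @return Proportion in `[0, 1]`.
#' @export
percent_agreement <- function(x) {
  stopifnot(inherits(x, "coding_matrix"))
  if (ncol(x$labels) != 2L) {
    stop_data("percent_agreement requires exactly 2 coders; use krippendorff_alpha")
  }
  if (anyNA(x$labels)) {
    stop_data("percent_agreement requires complete data; use krippendorff_alpha")
  }
  mean(x$labels[, 1L] == x$labels[, 2L])
}

#' Adjudicate a two-coder matrix into a consensus labeling
#'
#' Concordant units keep their shared label; discordant units take the
#' supplied resolution. The result is usable as a single "human" coder in a
#' human-vs-computer coding matrix.
#'
#' @param x A [coding_matrix()] with exactly 2 coders and complete data.
#' @param resolutions Named character vector/list, unit id -> resolved label.
#'   Every discordant unit must appear.
#' @return Named character vector of consensus labels (names = unit ids).
#' @export
adjudicate <- function(x, resolutions = character()) {
  stopifnot(inherits(x, "coding_matrix"))
  if (ncol(x$labels) != 2L) stop_data("adjudicate expects exactly 2 coders")
  if (anyNA(x$labels)) stop_data("adjudicate expects complete data")
  resolutions <- unlist(resolutions)
  disc <- x$unit_ids[x$labels[, 1L] != x$labels[, 2L]]
  unresolved <- setdiff(disc, names(resolutions))
  if (length(unresolved)) {
    stop_data("unresolved discordant unit(s): ", paste(unresolved, collapse = ", "))
  }
  out <- x$labels[, 1L]
  out[disc] <- resolutions[disc]
  names(out) <- x$unit_ids
  out
}

#' Validation sampling plan
#'
#' Defaults mirror the study design: 60 classifier-positive and 60
#' classifier-negative posts per topic across the 8 canonical topics, i.e.
#' 8 x 120 = 960 stratum draws.
#'
#' @param per_topic_positive,per_topic_negative Draws per stratum.
#' @param topics Topic inventory.
#' @param seed Integer seed making the draw reproducible.
#' @return An object of class `validation_plan`.
#' @export
validation_plan <- function(per_topic_positive = 60L, per_topic_negative = 60L,
                            topics = canonical_topics(), seed = 1L) {
  if (per_topic_positive < 1L || per_topic_negative < 1L) {
    stop_data("per-stratum counts must be >= 1")
  }
  structure(
    list(
      per_topic_positive = as.integer(per_topic_positive),
      per_topic_negative = as.integer(per_topic_negative),
      topics = topics,
      seed = as.integer(seed)
    ),
    class = "validation_plan"
  )
}

#' Draw a stratified validation sample of classified posts
#'
#' For each topic, draws `per_topic_positive` posts classified as containing
#' the topic and `per_topic_negative` classified as not, without replacement
#' within each stratum, seeded and reproducible. Units drawn for several
#' strata appear once in the aggregated sample but are recorded in every
#' stratum ledger, matching the purposive-sample design in which a
#' "negative" draw for one topic can still carry other topics.
#'
#' @param assignments A `topic_assignments` object.
#' @param plan A [validation_plan()].
#' @return List with `unit_ids` (aggregated unique post ids), `strata`
#'   (data frame topic/stratum/post_id, exactly the requested counts) and
#'   `plan`.
#' @export
draw_validation_sample <- function(assignments, plan) {
  stopifnot(inherits(plan, "validation_plan"))
  tm <- topic_matrix(assignments, topics = plan$topics)
  ids <- rownames(tm)
  ## check all strata before drawing anything
  for (topic in plan$topics) {
    n_pos <- sum(tm[, topic])
    n_neg <- sum(!tm[, topic])
    if (n_pos < plan$per_topic_positive) {
      stop_data("stratum too small: topic '", topic, "', stratum 'positive' has ",
                n_pos, " posts, need ", plan$per_topic_positive)
    }
    if (n_neg < plan$per_topic_negative) {
      stop_data("stratum too small: topic '", topic, "', stratum 'negative' has ",
                n_neg, " posts, need ", plan$per_topic_negative)
    }
  }
  strata <- with_seed(plan$seed, {
    do.call(rbind, lapply(plan$topics, function(topic) {
      pos <- sample_vec(ids[tm[, topic]], plan$per_topic_positive)
      neg <- sample_vec(ids[!tm[, topic]], plan$per_topic_negative)
      data.frame(
        topic = topic,
        stratum = rep(c("positive", "negative"),
                      c(length(pos), length(neg))),
        post_id = c(pos, neg),
        stringsAsFactors = FALSE
      )
    }))
  })
  list(unit_ids = unique(strata$post_id), strata = strata, plan = plan)
}

#' Per-topic reliability summary
#'
#' Computes Krippendorff's alpha for each topic as a separate binary
#' present/absent matrix and summarizes by mean and range, the conventional
#' reporting style for multi-topic coding studies.
#'
#' @param matrices Named list of [coding_matrix()] objects, one per topic.
#' @return List with `per_topic` (named numeric vector of alphas), `mean`
#'   and `range` (over the topics where alpha is defined).
#' @export
topic_reliability_summary <- function(matrices) {
  alphas <- vapply(matrices, function(m) krippendorff_alpha(m)$alpha, numeric(1))
  ok <- !is.na(alphas)
  list(
    per_topic = alphas,
    mean = if (any(ok)) mean(alphas[ok]) else NA_real_,
    range = if (any(ok)) range(alphas[ok]) else c(NA_real_, NA_real_)
  )
}
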