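# Independent brute-force oracles, written before the implementations they
# check and kept free of package internals.

# Krippendorff's nominal alpha by direct pair enumeration: observed
# disagreement averages over every ordered pair of values within a unit
# (weight 1/(m_u - 1)); expected disagreement enumerates every ordered pair
# of pooled pairable values with an explicit double loop.
oracle_alpha <- function(labels) {
  labels <- as.matrix(labels)
  pooled <- character()
  d_o_sum <- 0
  for (u in seq_len(nrow(labels))) {
    vals <- labels[u, !is.na(labels[u, ])]
    m <- length(vals)
    if (m < 2) next
    pooled <- c(pooled, vals)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (i != j && vals[i] != vals[j]) d_o_sum <- d_o_sum + 1 / (m - 1)
      }
    }
  }
  n <- length(pooled)
  if (n == 0) stop("no pairable values")
  d_o <- d_o_sum / n
  d_e_sum <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && pooled[i] != pooled[j]) d_e_sum <- d_e_sum + 1
    }
  }
  d_e <- d_e_sum / (n * (n - 1))
  if (d_e == 0) return(NA_real_)
  1 - d_o / d_e
}

# Node strength by direct per-post counting: for each post with >= 2 topics,
# every topic in it gains (k - 1); never touches edge sums.
oracle_strength <- function(topic_sets, topics) {
  s <- stats::setNames(rep(0, length(topics)), topics)
  for (tp_set in topic_sets) {
    k <- length(tp_set)
    if (k >= 2) s[tp_set] <- s[tp_set] + (k - 1)
  }
  s
}

# Total edge weight by the combinatorial identity sum_p C(k_p, 2).
oracle_total_weight <- function(topic_sets) {
  sum(vapply(topic_sets, function(tp) choose(length(tp), 2), numeric(1)))
}

# Random small coding matrix for alpha comparisons (categories "a".."c",
# missingness included); some rows may end up unpairable on purpose.
random_coding_matrix <- function(n_units, n_coders, n_cats, miss_rate = 0.2) {
  cats <- letters[seq_len(n_cats)]
  m <- matrix(sample(cats, n_units * n_coders, replace = TRUE),
              nrow = n_units)
  m[matrix(runif(length(m)) < miss_rate, nrow = n_units)] <- NA
  m
}

# Random fake assignment collection over an arbitrary topic inventory.
random_assignments <- function(n_posts, topics, max_k = 4) {
  out <- lapply(seq_len(n_posts), function(i) {
    k <- sample(0:min(max_k, length(topics)), 1)
    structure(list(post_id = paste0("p", i),
                   topics = if (k) sample(topics, k) else character(),
                   match_spans = list(), fp_suppressed = list()),
              class = "topic_assignment")
  })
  structure(out, class = "topic_assignments",
            post_ids = paste0("p", seq_len(n_posts)),
            topic_names = topics)
}

published_counts <- function() {
  yaml::read_yaml(system.file("extdata", "published_summary_counts.yaml",
                              package = "ibdtopics"))
}
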