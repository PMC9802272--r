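## Topic co-occurrence network ----------------------------------------------

#' Build the topic co-occurrence network
#'
#' Undirected weighted graph over the topic inventory. Only posts carrying
#' two or more topics contribute; each such post adds 1 to the weight of
#' every unordered pair of its topics, so the total edge weight equals
#' `sum over posts of choose(k_p, 2)`. Node strength (weighted degree, the
#' sum of incident edge weights) is the centrality measure used to size
#' sociogram nodes; co-occurrence edges are symmetric, so "degree
#' centrality" here means strength, with a plain unweighted-degree variant
#' available from [rank_centrality()].
#'
#' @param assignments A `topic_assignments` object (or list of
#'   `topic_assignment`s).
#' @param topics Topic inventory; defaults to the assignment attribute or
#'   the canonical 8.
#' @return An object of class `topic_network`: list with `nodes`, `edges`
#'   (data frame topic_a/topic_b/weight, weight > 0 rows only), `strength`
#'   (named numeric), `n_multitopic_posts`, and the full symmetric `matrix`
#'   (zero diagonal).
#' @export
build_network <- function(assignments, topics = NULL) {
  topics <- topics %||% attr(assignments, "topic_names") %||% CANONICAL_TOPICS
  w <- matrix(0L, length(topics), length(topics), dimnames = list(topics, topics))
  n_multi <- 0L
  for (a in assignments) {
    tp <- intersect(a$topics, topics)
    k <- length(tp)
    if (k < 2L) next
    n_multi <- n_multi + 1L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        w[tp[i], tp[j]] <- w[tp[i], tp[j]] + 1L
        w[tp[j], tp[i]] <- w[tp[j], tp[i]] + 1L
      }
    }
  }
  ut <- upper.tri(w)
  idx <- which(ut & w > 0L, arr.ind = TRUE)
  edges <- data.frame(
    topic_a = topics[idx[, 1L]],
    topic_b = topics[idx[, 2L]],
    weight = w[idx],
    stringsAsFactors = FALSE
  )
  edges <- edges[order(-edges$weight, edges$topic_a, edges$topic_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(
      nodes = topics,
      edges = edges,
      strength = rowSums(w),
      n_multitopic_posts = n_multi,
      matrix = w
    ),
    class = "topic_network"
  )
}

#' @export
print.topic_network <- function(x, ...) {
  cat("<topic_network>", length(x$nodes), "nodes,", nrow(x$edges),
      "edges, total weight", sum(x$edges$weight),
      "from", x$n_multitopic_posts, "multi-topic posts\n")
  invisible(x)
}

#' Rank topics by co-occurrence centrality
#'
#' Descending by node strength (weighted degree); ties broken
#' lexicographically by topic name. `weighted = FALSE` ranks by unweighted
#' degree (number of distinct co-occurring topics) instead.
#'
#' @param network A [build_network()] result.
#' @param weighted Use weighted degree (default) or plain degree.
#' @return Data frame `topic`, `strength`, ordered.
#' @export
rank_centrality <- function(network, weighted = TRUE) {
  stopifnot(inherits(network, "topic_network"))
  s <- if (weighted) network$strength else rowSums(network$matrix > 0L)
  ord <- order(-s, names(s))
  data.frame(topic = names(s)[ord], strength = unname(s[ord]),
             stringsAsFactors = FALSE)
}

#' Convert a topic network to an igraph graph
#'
#' Nodes carry a `strength` attribute, edges a `weight` attribute; isolated
#' topics are kept as vertices.
#'
#' @param network A [build_network()] result.
#' @return An `igraph` object.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "topic_network"))
  g <- igraph::graph_from_data_frame(
    network$edges,
    directed = FALSE,
    vertices = data.frame(name = network$nodes,
                          strength = unname(network$strength[network$nodes]))
  )
  g
}

#' Export a sociogram file
#'
#' `graphml` and `dot` go through igraph (DOT node sizes follow strength via
#' the stored attribute); `edgelist_csv` writes columns `topic_a`,
#' `topic_b`, `weight` sorted descending by weight.
#'
#' @param network A [build_network()] result.
#' @param path Output file path.
#' @param format `"graphml"`, `"edgelist_csv"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_sociogram <- function(network, path, format = c("graphml", "edgelist_csv", "dot")) {
  format <- match.arg(format)
  stopifnot(inherits(network, "topic_network"))
  if (format == "edgelist_csv") {
    utils::write.csv(network$edges, path, row.names = FALSE)
  } else {
    igraph::write_graph(as_igraph(network), path,
                        format = if (format == "dot") "dot" else "graphml")
  }
  invisible(path)
}

#' Export the topic co-occurrence matrix as CSV
#'
#' 8 x 8 symmetric integer matrix with zero diagonal, the interchange shape
#' for co-occurrence frequency tables.
#'
#' @param network A [build_network()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
cooccurrence_matrix_csv <- function(network, path) {
  stopifnot(inherits(network, "topic_network"))
  utils::write.csv(network$matrix, path, row.names = TRUE)
  invisible(path)
}
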