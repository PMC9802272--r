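test_that("pair counting matches the hand-enumerated example", {
  asg <- random_assignments(0, c("A", "B", "C"))
  asg[[1]] <- structure(list(post_id = "1", topics = c("A", "B"),
                             match_spans = list(), fp_suppressed = list()),
                        class = "topic_assignment")
  asg[[2]] <- structure(list(post_id = "2", topics = c("A", "B"),
                             match_spans = list(), fp_suppressed = list()),
                        class = "topic_assignment")
  asg[[3]] <- structure(list(post_id = "3", topics = c("A", "C"),
                             match_spans = list(), fp_suppressed = list()),
                        class = "topic_assignment")
  net <- build_network(asg, topics = c("A", "B", "C"))
  expect_equal(net$matrix["A", "B"], 2L)
  expect_equal(net$matrix["A", "C"], 1L)
  expect_equal(unname(net$strength["A"]), 3)
  expect_equal(net$n_multitopic_posts, 3L)
  expect_equal(rank_centrality(net)$topic[1], "A")
})

test_that("single-topic posts contribute nothing; k topics add choose(k,2) pairs", {
  one <- random_assignments(0, c("A", "B", "C"))
  one[[1]] <- structure(list(post_id = "1", topics = "A",
                             match_spans = list(), fp_suppressed = list()),
                        class = "topic_assignment")
  net1 <- build_network(one, topics = c("A", "B", "C"))
  expect_equal(sum(net1$matrix), 0L)
  expect_equal(net1$n_multitopic_posts, 0L)

  three <- random_assignments(0, c("A", "B", "C"))
  three[[1]] <- structure(list(post_id = "1", topics = c("A", "B", "C"),
                               match_spans = list(), fp_suppressed = list()),
                          class = "topic_assignment")
  net3 <- build_network(three, topics = c("A", "B", "C"))
  expect_equal(sum(net3$edges$weight), 3L)
})

test_that("edge-weight conservation and strength consistency hold on random inputs", {
  set.seed(77)
  topics <- canonical_topics()
  for (i in 1:120) {
    asg <- random_assignments(sample(1:40, 1), topics)
    net <- build_network(asg)
    sets <- lapply(asg, function(a) a$topics)
    expect_equal(sum(net$edges$weight), oracle_total_weight(sets))
    expect_equal(net$strength, oracle_strength(sets, topics))
    ## strength from edge sums equals the stored strength
    for (tp in topics) {
      inc <- net$edges$weight[net$edges$topic_a == tp | net$edges$topic_b == tp]
      expect_equal(unname(net$strength[tp]), sum(inc))
    }
  }
})

test_that("removing single-topic posts leaves the network unchanged", {
  set.seed(78)
  asg <- random_assignments(60, canonical_topics())
  multi <- asg[vapply(asg, function(a) length(a$topics) >= 2, logical(1))]
  attr(multi, "topic_names") <- canonical_topics()
  class(multi) <- "topic_assignments"
  n1 <- build_network(asg)
  n2 <- build_network(multi, topics = canonical_topics())
  expect_identical(n1$matrix, n2$matrix)
  expect_equal(n1$n_multitopic_posts, n2$n_multitopic_posts)
})

test_that("centrality ranking breaks ties lexicographically and handles zeros", {
  asg <- random_assignments(0, c("b", "a", "c"))
  net <- build_network(asg, topics = c("b", "a", "c"))
  expect_identical(rank_centrality(net)$topic, c("a", "b", "c"))
  expect_true(all(rank_centrality(net)$strength == 0))
})

test_that("GraphML export round-trips weights and strengths", {
  set.seed(80)
  asg <- random_assignments(50, canonical_topics())
  net <- build_network(asg)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_sociogram(net, path, "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(sort(igraph::V(g)$name), sort(net$nodes))
  ew <- igraph::as_data_frame(g, what = "edges")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  got <- stats::setNames(ew$weight, key(ew$from, ew$to))
  want <- stats::setNames(net$edges$weight, key(net$edges$topic_a, net$edges$topic_b))
  expect_equal(got[names(want)], want)
  expect_equal(
    stats::setNames(igraph::V(g)$strength, igraph::V(g)$name)[net$nodes],
    net$strength
  )
})

test_that("edge-list CSV is weight-sorted; empty networks export all nodes", {
  set.seed(81)
  asg <- random_assignments(40, canonical_topics())
  net <- build_network(asg)
  path <- withr::local_tempfile(fileext = ".csv")
  export_sociogram(net, path, "edgelist_csv")
  df <- utils::read.csv(path)
  expect_identical(names(df), c("topic_a", "topic_b", "weight"))
  expect_true(!is.unsorted(rev(df$weight)))

  empty <- build_network(random_assignments(0, canonical_topics()))
  gpath <- withr::local_tempfile(fileext = ".graphml")
  export_sociogram(empty, gpath, "graphml")
  g <- igraph::read_graph(gpath, format = "graphml")
  expect_equal(igraph::vcount(g), 8)
  expect_equal(igraph::ecount(g), 0)

  dpath <- withr::local_tempfile(fileext = ".dot")
  export_sociogram(net, dpath, "dot")
  expect_true(file.size(dpath) > 0)
})
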