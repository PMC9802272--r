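lex <- tiny_lexicons()

test_that("relevance filter keeps keyword posts and drops exclusion contexts", {
  corp <- corpus(make_posts(
    list(id = "p1", text = "I just learned my dog has IBD"),
    list(id = "p2", text = "Living with Crohn's is hard"),
    list(id = "p3", text = "Great earnings report today"),
    list(id = "p4", text = "loving my #crohnsdisease community")
  ))
  res <- relevance_filter(corp, lex$relevance)
  expect_setequal(res$corpus$posts$post_id, c("p2", "p4"))
  expect_equal(res$report$removed_by_rule[["exclusion_context"]], 1L)
  expect_equal(res$report$removed_by_rule[["no_keyword"]], 1L)
  expect_equal(res$report$retained_count + sum(res$report$removed_by_rule),
               res$report$input_count)
})

test_that("relevance filter is idempotent", {
  corp <- generate_corpus(generator_config(seed = 11, n_posts = c(reddit = 60, twitter = 60)))
  once <- relevance_filter(corp, lex$relevance)$corpus
  twice <- relevance_filter(once, lex$relevance)$corpus
  expect_identical(twice$posts$post_id, once$posts$post_id)
})

test_that("retweet removal uses the flag, the rt @ prefix, and is platform-scoped", {
  corp <- corpus(make_posts(
    list(id = "t1", platform = "twitter", text = "my ibd flare", rt = TRUE),
    list(id = "t2", platform = "twitter", text = "RT @user: my ibd flare"),
    list(id = "t3", platform = "twitter", text = "original ibd tweet"),
    list(id = "r1", platform = "reddit", text = "I saw a retweet about ibd")
  ))
  res <- remove_retweets(corp)
  expect_setequal(res$corpus$posts$post_id, c("t3", "r1"))
  expect_equal(res$report$removed_by_rule[["retweet"]], 2L)
})

test_that("same-user dedup keeps the earliest copy and spares other authors", {
  corp <- corpus(make_posts(
    list(id = "a", author = "A", text = "ibd is rough", ts = "2018-01-02 00:00:00"),
    list(id = "b", author = "A", text = "IBD is rough!", ts = "2018-01-01 00:00:00"),
    list(id = "c", author = "B", text = "ibd is rough", ts = "2018-01-03 00:00:00"),
    list(id = "d", author = "A", text = "something else", ts = "2018-01-04 00:00:00")
  ))
  res <- dedup_same_user(corp)
  ## normalized texts of a and b are identical; the earlier (b) is kept
  expect_setequal(res$corpus$posts$post_id, c("b", "c", "d"))
  expect_equal(res$report$removed_by_rule[["same_user_duplicate"]], 1L)
})

test_that("dedup on a corpus without duplicates is the identity", {
  corp <- corpus(make_posts(
    list(id = "a", author = "A", text = "one ibd post"),
    list(id = "b", author = "B", text = "another ibd post")
  ))
  res <- dedup_same_user(corp)
  expect_identical(res$corpus$posts$post_id, corp$posts$post_id)
  expect_equal(res$report$removed_by_rule[["same_user_duplicate"]], 0L)
})

test_that("distress filter fires on unigrams and consecutive-token phrases", {
  corp <- corpus(make_posts(
    list(id = "p1", text = "I'm afraid my flare will return"),
    list(id = "p2", text = "Some days I feel alone in this"),
    list(id = "p3", text = "My colonoscopy is scheduled"),
    list(id = "p4", text = "alone I feel nothing")  # tokens not consecutive
  ))
  res <- distress_filter(corp, lex$distress)
  expect_setequal(res$corpus$posts$post_id, c("p1", "p2"))
  expect_true("afraid" %in% res$matches[["p1"]])
  expect_true("feel alone" %in% res$matches[["p2"]])
})

test_that("filter reports conserve counts on random synthetic corpora", {
  for (seed in c(3, 5, 9)) {
    corp <- generate_corpus(generator_config(seed = seed,
                                             n_posts = c(reddit = 40, twitter = 40)))
    for (res in list(relevance_filter(corp, lex$relevance),
                     remove_retweets(corp),
                     dedup_same_user(corp),
                     distress_filter(corp, lex$distress))) {
      expect_equal(res$report$retained_count + sum(res$report$removed_by_rule),
                   res$report$input_count)
    }
  }
})

test_that("retweet removal and dedup commute on synthetic corpora", {
  corp <- generate_corpus(generator_config(seed = 13, n_posts = c(reddit = 80, twitter = 80)))
  ab <- dedup_same_user(remove_retweets(corp)$corpus)$corpus
  ba <- remove_retweets(dedup_same_user(corp)$corpus)$corpus
  expect_setequal(ab$posts$post_id, ba$posts$post_id)
})

test_that("distress filter has recall 1 on planted-distress posts", {
  corp <- generate_corpus(generator_config(seed = 17, n_posts = c(reddit = 150, twitter = 150)))
  ## shipped lexicon covers the generator's full marker inventory
  res <- distress_filter(corp, read_cleaning_config()$distress)
  planted <- corp$posts$post_id[corp$posts$gold_distress]
  expect_true(all(planted %in% res$corpus$posts$post_id))
})
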