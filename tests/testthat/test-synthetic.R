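dict <- read_topic_dictionary()

test_that("the same seed produces byte-identical corpora", {
  cfg <- generator_config(seed = 101, n_posts = c(reddit = 60, twitter = 60))
  p1 <- withr::local_tempfile(fileext = ".jsonl")
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(generate_corpus(cfg), p1)
  write_corpus(generate_corpus(cfg), p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_false(identical(
    readLines(p1),
    {
      p3 <- withr::local_tempfile(fileext = ".jsonl")
      write_corpus(generate_corpus(generator_config(
        seed = 102, n_posts = c(reddit = 60, twitter = 60))), p3)
      readLines(p3)
    }
  ))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1234)
  before <- .Random.seed
  invisible(generate_corpus(generator_config(seed = 5, n_posts = c(reddit = 10, twitter = 10))))
  expect_identical(.Random.seed, before)
})

test_that("distress_rate 0 plants no distress markers anywhere", {
  corp <- generate_corpus(generator_config(seed = 55, distress_rate = 0,
                                           n_posts = c(reddit = 80, twitter = 80)))
  res <- distress_filter(corp, read_cleaning_config()$distress)
  expect_equal(n_posts(res$corpus), 0L)
})

test_that("tweets respect the 280-character limit without losing signal", {
  corp <- generate_corpus(generator_config(
    seed = 57, n_posts = c(twitter = 300),
    topic_prevalence = c(symptoms = 0.9, medication = 0.9, nutrition = 0.9,
                         procedures = 0.9, marijuana = 0.9, stigma = 0.9,
                         ostomy = 0.9, intimacy = 0.9)
  ))
  tw <- corp$posts[corp$posts$platform == "twitter", ]
  expect_true(all(nchar(tw$text) <= 280L))
  asg <- classify_corpus(corp, dict$lexicon, dict$fp)
  expect_equal(gold_evaluation(asg, corp)$micro$recall, 1)
})

test_that("recovered prevalence sits inside the exact binomial 99% interval", {
  n <- 1000L
  p <- 0.5
  corp <- generate_corpus(generator_config(
    seed = 59, n_posts = c(reddit = n),
    topic_prevalence = c(symptoms = p, medication = 0.2, nutrition = 0.2,
                         procedures = 0.1, marijuana = 0.1, stigma = 0.05,
                         ostomy = 0.05, intimacy = 0.02),
    duplicate_rate = 0, offtopic_rate = 0
  ))
  asg <- classify_corpus(corp, dict$lexicon, dict$fp)
  x <- sum(topic_matrix(asg)[, "symptoms"])
  expect_gte(x, stats::qbinom(0.005, n, p))
  expect_lte(x, stats::qbinom(0.995, n, p))
})

test_that("count-mode gold topic counts follow the configured mixing distribution", {
  mix <- truncated_geometric(0.5, kmax = 4)
  corp <- generate_corpus(generator_config(
    seed = 61, n_posts = c(reddit = 1000),
    multi_topic_mixing = mix,
    duplicate_rate = 0, offtopic_rate = 0
  ))
  k <- vapply(corp$posts$gold_topics, length, integer(1))
  obs <- tabulate(k + 1L, nbins = 5L)
  gof <- stats::chisq.test(obs, p = mix)
  expect_gt(gof$p.value, 0.01)
})

test_that("gold evaluation reports degenerate precision and recall honestly", {
  corp <- generate_corpus(generator_config(seed = 63, n_posts = c(reddit = 40)))
  inert <- topic_lexicon(
    stats::setNames(
      lapply(canonical_topics(), function(t) list(terms = "zzznomatch")),
      canonical_topics()
    )
  )
  asg <- classify_corpus(corp, inert, fp_lexicon())
  ev <- gold_evaluation(asg, corp)
  expect_true(all(is.na(ev$per_topic$precision)))
  has_pos <- ev$per_topic$tp + ev$per_topic$fn > 0
  expect_true(all(ev$per_topic$recall[has_pos] == 0))
})

test_that("corpora without gold labels are rejected by gold_evaluation", {
  corp <- corpus(make_posts(list(id = "a", text = "plain ibd post")))
  asg <- classify_corpus(corp, dict$lexicon, dict$fp)
  expect_error(gold_evaluation(asg, corp), "gold")
})

test_that("infeasible platform limits raise an error", {
  v <- .default_vocabulary_for_test()
  v$openers <- paste(rep("ulcerative colitis update", 20), collapse = " ")
  cfg <- generator_config(seed = 3, n_posts = c(twitter = 5),
                          topic_prevalence = c(symptoms = 1, medication = 1,
                                               nutrition = 1, procedures = 1,
                                               marijuana = 1, stigma = 1,
                                               ostomy = 1, intimacy = 1),
                          vocabulary = v)
  expect_error(generate_corpus(cfg), "280")
})
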