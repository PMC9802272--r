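test_that("perfect agreement over two categories gives alpha 1", {
  m <- coding_matrix(cbind(c("1", "0", "1", "0"), c("1", "0", "1", "0")))
  expect_equal(krippendorff_alpha(m)$alpha, 1)
})

test_that("the worked 2x4 example matches the brute-force oracle", {
  labels <- cbind(c("1", "0", "1", "0"), c("1", "0", "0", "0"))
  res <- krippendorff_alpha(coding_matrix(labels))
  expect_equal(res$alpha, oracle_alpha(labels), tolerance = 1e-12)
  expect_lt(res$alpha, 1)
})

test_that("systematic disagreement yields negative alpha approaching -1", {
  mk <- function(n) cbind(rep(c("1", "0"), n), rep(c("0", "1"), n))
  a10 <- krippendorff_alpha(coding_matrix(mk(10)))$alpha
  a50 <- krippendorff_alpha(coding_matrix(mk(50)))$alpha
  expect_lt(a10, 0)
  expect_lt(a50, a10)
  expect_equal(a50, oracle_alpha(mk(50)), tolerance = 1e-12)
})

test_that("alpha matches the oracle on random matrices with missing data", {
  set.seed(404)
  for (i in 1:80) {
    m <- random_coding_matrix(sample(2:12, 1), sample(2:3, 1), sample(2:3, 1))
    pairable <- sum(apply(m, 1, function(r) sum(!is.na(r)) >= 2))
    if (pairable == 0) next
    got <- tryCatch(suppressWarnings(krippendorff_alpha(coding_matrix(m))$alpha),
                    error = function(e) NULL)
    if (is.null(got)) next
    expect_equal(got, oracle_alpha(m), tolerance = 1e-12)
  }
})

test_that("alpha is invariant under unit and coder permutations", {
  set.seed(99)
  m <- random_coding_matrix(10, 3, 3)
  a0 <- suppressWarnings(krippendorff_alpha(coding_matrix(m))$alpha)
  a1 <- suppressWarnings(krippendorff_alpha(coding_matrix(m[sample(10), ]))$alpha)
  a2 <- suppressWarnings(krippendorff_alpha(coding_matrix(m[, c(2, 3, 1)]))$alpha)
  expect_equal(a1, a0, tolerance = 1e-12)
  expect_equal(a2, a0, tolerance = 1e-12)
})

test_that("single-category data leaves alpha undefined with a warning", {
  m <- coding_matrix(cbind(rep("1", 4), rep("1", 4)))
  expect_warning(res <- krippendorff_alpha(m), "undefined")
  expect_true(is.na(res$alpha))
})

test_that("percent agreement counts identical units and rejects misuse", {
  m <- coding_matrix(cbind(c("1", "0", "1", "0"), c("1", "0", "0", "0")))
  expect_equal(percent_agreement(m), 0.75)
  all_same <- coding_matrix(cbind(c("1", "0"), c("1", "0")))
  expect_equal(percent_agreement(all_same), 1)
  all_diff <- coding_matrix(cbind(c("1", "0"), c("0", "1")))
  expect_equal(percent_agreement(all_diff), 0)
  three <- coding_matrix(matrix("1", 2, 3))
  expect_error(percent_agreement(three), "alpha")
  miss <- coding_matrix(cbind(c("1", NA), c("1", "0")))
  expect_error(percent_agreement(miss), "alpha")
})

test_that("percent agreement is 1 exactly when observed disagreement is 0", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(sample(c("0", "1"), 12, replace = TRUE), ncol = 2)
    cm <- coding_matrix(m)
    res <- suppressWarnings(krippendorff_alpha(cm))
    d_o <- sum(res$coincidence) - sum(diag(res$coincidence))
    expect_equal(percent_agreement(cm) == 1, d_o == 0)
    if (!is.na(res$alpha)) expect_lte(res$alpha, 1 + 1e-12)
  }
})

test_that("adjudication resolves discordant units and flags unresolved ones", {
  m <- coding_matrix(cbind(c("1", "0", "1"), c("1", "0", "0")),
                     unit_ids = c("u1", "u2", "u3"))
  cons <- adjudicate(m, resolutions = c(u3 = "present"))
  expect_identical(unname(cons[c("u1", "u2")]), c("1", "0"))
  expect_identical(unname(cons["u3"]), "present")
  concordant <- coding_matrix(cbind(c("1", "0"), c("1", "0")),
                              unit_ids = c("a", "b"))
  expect_identical(unname(adjudicate(concordant)), c("1", "0"))
  expect_error(adjudicate(m), "u3")
})

test_that("coding matrices round-trip through CSV", {
  m <- coding_matrix(cbind(c("1", NA, "0"), c("1", "0", "0")),
                     unit_ids = c("u1", "u2", "u3"),
                     coders = c("coder_a", "coder_b"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_coding_matrix(m, path)
  back <- read_coding_matrix(path)
  expect_identical(back$labels, m$labels)
  expect_identical(back$coders, m$coders)
})

test_that("the validation sampler returns the exact stratum ledgers", {
  dict <- read_topic_dictionary()
  corp <- generate_corpus(generator_config(
    seed = 31, n_posts = c(reddit = 400, twitter = 400),
    topic_prevalence = c(symptoms = 0.5, medication = 0.45, nutrition = 0.45,
                         procedures = 0.4, marijuana = 0.4, stigma = 0.35,
                         ostomy = 0.35, intimacy = 0.3)
  ))
  asg <- classify_corpus(corp, dict$lexicon, dict$fp)
  plan <- validation_plan(per_topic_positive = 60, per_topic_negative = 60, seed = 7)
  s <- draw_validation_sample(asg, plan)
  expect_equal(nrow(s$strata), 8L * 120L)
  counts <- table(s$strata$topic, s$strata$stratum)
  expect_true(all(counts == 60L))
  ## aggregated units are unique even when drawn for several strata
  expect_true(anyDuplicated(s$unit_ids) == 0L)
  expect_lte(length(s$unit_ids), nrow(s$strata))
  ## within-stratum draws are without replacement
  expect_true(all(tapply(s$strata$post_id,
                         paste(s$strata$topic, s$strata$stratum),
                         anyDuplicated) == 0L))
  ## seeded reproducibility
  s2 <- draw_validation_sample(asg, plan)
  expect_identical(s2$strata, s$strata)
})

test_that("an undersized stratum errors naming topic and stratum", {
  dict <- read_topic_dictionary()
  corp <- generate_corpus(generator_config(
    seed = 33, n_posts = c(reddit = 300, twitter = 300),
    topic_prevalence = c(symptoms = 0.5, medication = 0.4, nutrition = 0.4,
                         procedures = 0.4, marijuana = 0.35, stigma = 0.35,
                         ostomy = 0.3, intimacy = 0.01)
  ))
  asg <- classify_corpus(corp, dict$lexicon, dict$fp)
  expect_error(draw_validation_sample(asg, validation_plan(seed = 1)),
               "intimacy.*positive")
})

test_that("human-vs-computer comparison reproduces the validation design", {
  dict <- read_topic_dictionary()
  corp <- generate_corpus(generator_config(seed = 37, n_posts = c(reddit = 150, twitter = 150)))
  asg <- classify_corpus(corp, dict$lexicon, dict$fp)
  computer <- ifelse(topic_matrix(asg)[, "symptoms"], "present", "absent")
  ## adjudicated humans recover the gold labels
  gold <- vapply(corp$posts$gold_topics, function(g) "symptoms" %in% g, logical(1))
  human <- ifelse(gold, "present", "absent")
  hvc <- coding_matrix(cbind(human = human, computer = computer),
                       unit_ids = corp$posts$post_id)
  expect_equal(krippendorff_alpha(hvc)$alpha, 1)
  expect_equal(percent_agreement(hvc), 1)
})

test_that("per-topic reliability summarizes by mean and range", {
  m1 <- coding_matrix(cbind(c("1", "0", "1", "0"), c("1", "0", "1", "0")))
  m2 <- coding_matrix(cbind(c("1", "0", "1", "0"), c("1", "0", "0", "0")))
  s <- topic_reliability_summary(list(a = m1, b = m2))
  expect_equal(unname(s$per_topic["a"]), 1)
  expect_equal(s$mean, mean(s$per_topic))
  expect_equal(s$range, range(s$per_topic))
})
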