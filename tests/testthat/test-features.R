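make_msg <- function(clauses, raw = 0L, eff = 0L) {
  epi_message("m", "pubA", "2020-01-01", clauses = clauses,
              raw_char_count = raw, effective_char_count = eff)
}

test_that("subject relevance is the mean of clipped noun/feature-word PMI", {
  stats <- hand_count_stats()
  # single noun perfectly co-occurring with the single feature word
  msg <- make_msg(list(epi_clause("a", "noun")))
  expect_equal(f1_subject_relevance(msg, "b", stats), log(2))

  # no nouns at all
  expect_equal(f1_subject_relevance(make_msg(list()), "b", stats), 0)

  # nouns never co-occurring with the feature words: all PMI clipped to 0
  stats2 <- corpus_stats(list(c("x", "y"), c("f1", "f2")))
  msg2 <- make_msg(list(epi_clause(c("x", "y"), "noun")))
  expect_equal(f1_subject_relevance(msg2, c("f1", "f2"), stats2), 0)

  expect_error(f1_subject_relevance(msg, character(), stats),
               class = "epiwatch_parameter_error")
})

test_that("vectorized F1 equals a brute-force double loop", {
  vocab <- c(letters[1:8], "fw1", "fw2", "fw3")
  docs <- random_docs(40, vocab, seed = 11)
  stats <- corpus_stats(docs)
  fwords <- c("fw1", "fw2", "fw3")
  for (seed in 1:4) {
    set.seed(seed)
    nouns <- sample(letters[1:8], sample(1:5, 1), replace = TRUE)
    msg <- make_msg(list(epi_clause(nouns, "noun")))
    acc <- 0
    for (nn in nouns) for (fw in fwords) {
      v <- pmi(nn, fw, stats, smoothing = 1e-9)
      if (is.finite(v) && v > 0) acc <- acc + v
    }
    expect_equal(f1_subject_relevance(msg, fwords, stats, smoothing = 1e-9),
                 acc / (length(nouns) * length(fwords)))
  }
})

test_that("text structure counts words, clauses and the length ratio", {
  msg <- make_msg(list(epi_clause(c("t1", "t2"), c("noun", "other")),
                       epi_clause(c("t3", "t4"), c("verb", "adverb"))),
                  raw = 100L, eff = 80L)
  ts <- text_structure_features(msg)
  expect_equal(ts$W, 3)
  expect_equal(ts$S, 2)
  expect_equal(ts$ratio, 0.8)

  empty <- text_structure_features(make_msg(list()))
  expect_equal(unlist(empty), c(W = 0, S = 0, ratio = 0))
})

test_that("emotional intensity is the positive share of polarized clauses", {
  cl <- function(pol) epi_clause("w", "other", pol)
  msg <- make_msg(list(cl("positive"), cl("positive"), cl("positive"),
                       cl("negative")))
  expect_equal(f5_emotional_intensity(msg), 0.75)

  expect_equal(f5_emotional_intensity(
    make_msg(list(cl("neutral"), cl("neutral")))), 0.5)
  expect_equal(f5_emotional_intensity(
    make_msg(rep(list(cl("negative")), 4))), 0)
})

test_that("publisher features pass through name, tier and history", {
  expect_equal(publisher_features(list(name_is_real = TRUE,
                                       platform_tier = 3L,
                                       history_count = 120L)),
               list(f6 = 1L, f7 = 3L, f8 = 120L))
  expect_equal(publisher_features(list(name_is_real = FALSE,
                                       platform_tier = 1L,
                                       history_count = 0L)),
               list(f6 = 0L, f7 = 1L, f8 = 0L))
})

test_that("the false-history update is the classified-false fraction", {
  pub <- list(publisher_id = "p", false_history_prob = 0)
  expect_equal(update_false_history(pub, character())$false_history_prob, 0)
  expect_equal(update_false_history(
    pub, c("false_info", "true_info", "false_info",
           "true_info"))$false_history_prob, 0.5)
  expect_equal(update_false_history(
    pub, rep("false_info", 4))$false_history_prob, 1.0)
})

test_that("theta elimination removes exactly the flagged publishers", {
  corpus <- three_message_corpus()
  corpus$publishers$false_history_prob <- c(0, 0.6)

  out <- eliminate_publishers(corpus, theta = 0.5)
  expect_length(out$messages, 2)  # pubB's message removed
  expect_false("pubB" %in% vapply(out$messages, `[[`, "", "publisher_id"))

  # unchanged when all publishers are at zero
  clean <- three_message_corpus()
  expect_length(eliminate_publishers(clean, 0.5)$messages, 3)

  # theta = 0 removes everything (all probabilities >= 0)
  expect_length(eliminate_publishers(corpus, 0)$messages, 0)

  expect_error(eliminate_publishers(corpus, 1.5),
               class = "epiwatch_parameter_error")
})

test_that("elimination is idempotent and monotone in theta", {
  corpus <- three_message_corpus()
  corpus$publishers$false_history_prob <- c(0.3, 0.7)
  once <- eliminate_publishers(corpus, 0.5)
  twice <- eliminate_publishers(once, 0.5)
  expect_equal(twice$messages, once$messages)

  thetas <- c(0.2, 0.5, 0.8)
  survivors <- lapply(thetas, function(th)
    vapply(eliminate_publishers(corpus, th)$messages, `[[`, "",
           "message_id"))
  expect_true(all(survivors[[1]] %in% survivors[[2]]))
  expect_true(all(survivors[[2]] %in% survivors[[3]]))
})

test_that("the feature vector has 8 classification + 1 regulatory entries", {
  corpus <- three_message_corpus()
  stats <- corpus_stats(corpus)
  pub <- as.list(corpus$publishers[1, ])
  v <- extract_features(corpus$messages[[1]], pub, "virus", stats)
  expect_length(v, 9)
  expect_named(v, c("f1_subject_relevance", "f2_feature_word_count",
                    "f3_clause_count", "f4_effective_length",
                    "f5_emotional_intensity", "f6_publisher_name",
                    "f7_publisher_level", "f8_history_amount",
                    "f9_false_history"))
  expect_length(grep("^f9", names(v), invert = TRUE, value = TRUE), 8)

  # deterministic
  expect_identical(v, extract_features(corpus$messages[[1]], pub, "virus",
                                       stats))
})

test_that("a fully neutral empty message maps to the trivial vector", {
  msg <- make_msg(list())
  pub <- list(name_is_real = FALSE, platform_tier = 1L, history_count = 0L,
              false_history_prob = 0)
  stats <- hand_count_stats()
  v <- extract_features(msg, pub, "b", stats)
  expect_equal(unname(v), c(0, 0, 0, 0, 0.5, 0, 1, 0, 0))
})

test_that("feature bounds hold on a generated corpus", {
  gen <- generate_corpus(generator_config(n_messages = 120, seed = 5))
  fm <- feature_matrix(gen$corpus, gen$feature_words)
  expect_true(all(fm$f4_effective_length >= 0 & fm$f4_effective_length <= 1))
  expect_true(all(fm$f5_emotional_intensity >= 0 &
                    fm$f5_emotional_intensity <= 1))
  expect_true(all(fm$f7_publisher_level %in% 1:3))
  expect_true(all(fm$f9_false_history >= 0 & fm$f9_false_history <= 1))
})
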