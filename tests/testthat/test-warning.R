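toy_gazetteer <- function(p = 34L) {
  data.frame(place = sprintf("place%02d", seq_len(p)),
             province = sprintf("prov%02d", seq_len(p)),
             stringsAsFactors = FALSE)
}

window_msg <- function(id, nouns, places = character(), pol = "neutral",
                       day = "2020-02-04") {
  epi_message(id, "pubA", day,
              clauses = list(epi_clause(nouns, "noun", pol)),
              raw_char_count = 10L, effective_char_count = 10L,
              places = places)
}

test_that("the quantity change rate follows (l2 - l1)/l1", {
  expect_equal(i1_change_rate(100, 150), 0.5)
  expect_equal(i1_change_rate(120, 120), 0)
  expect_equal(i1_change_rate(200, 100), -0.5)
  expect_true(is.na(i1_change_rate(0, 10)))
})

test_that("regional coverage counts distinct provinces over P", {
  gaz <- toy_gazetteer()
  msgs <- lapply(1:17, function(i)
    window_msg(paste0("m", i), "n1", places = sprintf("place%02d", i)))
  expect_equal(i2_region_coverage(msgs, gaz, 34), 0.5)

  expect_equal(i2_region_coverage(list(window_msg("m0", "n1")), gaz, 34), 0)

  all_p <- lapply(1:34, function(i)
    window_msg(paste0("a", i), "n1", places = sprintf("place%02d", i)))
  expect_equal(i2_region_coverage(all_p, gaz, 34), 1)

  # duplicate places count once
  dup <- list(window_msg("d1", "n1", places = c("place01", "place01")),
              window_msg("d2", "n1", places = "place01"))
  expect_equal(i2_region_coverage(dup, gaz, 34), 1 / 34)

  expect_warning(
    i2_region_coverage(list(window_msg("u", "n1", places = "atlantis")),
                       gaz, 34), "not in gazetteer")
  expect_error(i2_region_coverage(msgs, gaz[0, ], 34),
               class = "epiwatch_parameter_error")
})

test_that("emotional tendency is the plain mean of message intensities", {
  expect_equal(i3_emotional_tendency(c(0.6, 0.8)), 0.7)
  expect_equal(i3_emotional_tendency(rep(0.5, 5)), 0.5)
  expect_equal(i3_emotional_tendency(c(0.25, 0.5, 0.75)), 0.5)
  expect_true(is.na(i3_emotional_tendency(numeric())))
})

test_that("adaptive clustering separates disjoint vocabularies", {
  stats <- corpus_stats(list(c("a", "b"), c("a", "b"), c("x", "y"),
                             c("x", "y")))
  # one message alone is one cluster
  one <- cluster_subjects(list(c("a", "b")), stats)
  expect_equal(one$c, 1L)

  # disjoint vocabularies have zero cross-PMI: two clusters
  two <- cluster_subjects(list(c("a", "b"), c("x", "y")), stats)
  expect_equal(two$c, 2L)

  # duplicate messages always share a cluster
  dup <- cluster_subjects(list(c("a", "b"), c("a", "b"), c("x", "y")),
                          stats, tau = 0.9)
  expect_equal(dup$c, 2L)
  expect_equal(dup$assignments[1], dup$assignments[2])

  expect_error(cluster_subjects(list("a"), stats, tau = 2),
               class = "epiwatch_parameter_error")
})

test_that("subject concentration is exactly n/c", {
  expect_equal(i4_concentration(10, 5), 2)
  expect_equal(i4_concentration(7, 7), 1)
  expect_equal(i4_concentration(12, 3), 4)
  expect_error(i4_concentration(5, 0), class = "epiwatch_parameter_error")
})

test_that("new subjects are clusters unseen in the previous window", {
  docs <- list(c("a", "b"), c("a", "b"), c("x", "y"), c("x", "y"),
               c("p", "q"), c("p", "q"))
  stats <- corpus_stats(docs)
  prev <- cluster_subjects(list(c("a", "b"), c("x", "y")), stats)
  cur_same <- cluster_subjects(list(c("a", "b"), c("x", "y")), stats)
  expect_equal(i5_new_subjects(cur_same, prev, stats), 0L)

  # previous empty: every current cluster is new
  empty <- cluster_subjects(list(), stats)
  cur3 <- cluster_subjects(list(c("a", "b"), c("x", "y"), c("p", "q")),
                           stats)
  expect_equal(cur3$c, 3L)
  expect_equal(i5_new_subjects(cur3, empty, stats), 3L)
  expect_equal(i5_new_subjects(cur3, NULL, stats), 3L)

  # one cluster on a vocabulary absent from all previous clusters
  cur_new <- cluster_subjects(list(c("a", "b"), c("p", "q")), stats)
  expect_equal(i5_new_subjects(cur_new, prev, stats), 1L)
})

test_that("a single-window series flags I1 and counts clusters as new", {
  corpus <- epi_corpus(
    messages = list(
      window_msg("w1", c("a", "b")), window_msg("w2", c("a", "b")),
      window_msg("w3", c("x", "y"))),
    publishers = two_publishers())
  out <- compute_indicator_series(corpus, toy_gazetteer())
  expect_equal(nrow(out), 1)
  expect_true(is.na(out$i1_change_rate))
  expect_equal(out$i5_new_subjects, out$c_clusters)
  # five indicator columns
  expect_length(grep("^i[1-5]_", names(out)), 5)
  # Tc * c = n exactly
  expect_equal(out$i4_concentration * out$c_clusters, out$n_messages)
})

test_that("indicator records are invariant to message order in a window", {
  tl <- generate_timeline(generator_config(n_days = 3, seed = 4))
  base <- compute_indicator_series(tl$corpus, tl$gazetteer)
  perm <- tl$corpus
  set.seed(99)
  perm$messages <- perm$messages[sample(length(perm$messages))]
  expect_equal(compute_indicator_series(perm, tl$gazetteer), base)
})

test_that("coverage is monotone non-decreasing when messages are added", {
  gaz <- toy_gazetteer()
  msgs <- lapply(1:10, function(i)
    window_msg(paste0("m", i), "n1",
               places = sprintf("place%02d", sample(1:34, 1))))
  cov <- vapply(1:10, function(k)
    i2_region_coverage(msgs[1:k], gaz, 34), numeric(1))
  expect_true(all(diff(cov) >= 0))
})

test_that("Tc * c = n holds across a generated multi-day series", {
  tl <- generate_timeline(generator_config(n_days = 6, seed = 2))
  out <- compute_indicator_series(tl$corpus, tl$gazetteer)
  expect_equal(out$i4_concentration * out$c_clusters, as.numeric(out$n_messages))
  expect_true(all(out$i3_emotional_tendency > 0 &
                    out$i3_emotional_tendency < 1))
})
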