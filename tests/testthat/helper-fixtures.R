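# Deterministic fixtures built in code.

two_publishers <- function() {
  data.frame(
    publisher_id = c("pubA", "pubB"),
    name_is_real = c(TRUE, FALSE),
    platform_tier = c(3L, 1L),
    history_count = c(120L, 0L),
    false_history_prob = c(0, 0),
    stringsAsFactors = FALSE
  )
}

# 3 messages from 2 publishers, hand-written annotations
three_message_corpus <- function() {
  m1 <- epi_message(
    "m1", "pubA", "2020-02-04",
    clauses = list(
      epi_clause(c("virus", "spreads"), c("noun", "verb"), "negative"),
      epi_clause(c("mask", "helps"), c("noun", "verb"), "positive")
    ),
    raw_char_count = 100L, effective_char_count = 80L,
    places = c("wuhan", "beijing"), label = "true_info"
  )
  m2 <- epi_message(
    "m2", "pubA", "2020-02-05",
    clauses = list(
      epi_clause(c("vaccine", "works", "well"),
                 c("noun", "verb", "adverb"), "positive")
    ),
    raw_char_count = 60L, effective_char_count = 55L,
    places = "shanghai", label = "true_info"
  )
  m3 <- epi_message(
    "m3", "pubB", "2020-02-05",
    clauses = list(
      epi_clause(c("miracle", "cure"), c("adjective", "noun"), "positive"),
      epi_clause(c("buy", "now"), c("verb", "adverb"), "positive")
    ),
    raw_char_count = 40L, effective_char_count = 20L,
    places = character(), label = "false_info"
  )
  epi_corpus(messages = list(m1, m2, m3), publishers = two_publishers())
}

# stats where words a and b co-occur in 2 of 4 documents and each
# appears in 2: PMI(a, b) = log 2
hand_count_stats <- function() {
  corpus_stats(list(c("a", "b"), c("a", "b"), "c", "d"))
}

# linearly separable 8-point toy set
separable_toy <- function() {
  x <- cbind(c(1, 2, 3, 4, 10, 11, 12, 13), rep(0, 8))
  colnames(x) <- c("x1", "x2")
  list(x = x, y = c(0, 0, 0, 0, 1, 1, 1, 1))
}

# independent dense damped power-iteration oracle, run to convergence
dense_pagerank_oracle <- function(M, damping = 0.85, iters = 5000L) {
  A <- as.matrix(M)
  n <- nrow(A)
  dangling <- colSums(A) == 0
  if (any(dangling)) A[, dangling] <- 1 / n
  G <- damping * A + (1 - damping) / n
  s <- rep(1 / n, n)
  for (i in seq_len(iters)) s <- G %*% s
  as.numeric(s)
}

# brute-force document-frequency PMI oracle: recounts from the raw docs
brute_pmi <- function(docs, a, b, smoothing = 0) {
  n <- length(docs)
  in_a <- vapply(docs, function(d) a %in% d, logical(1))
  in_b <- vapply(docs, function(d) b %in% d, logical(1))
  pa <- sum(in_a) / n
  pb <- sum(in_b) / n
  pab <- sum(in_a & in_b) / n
  log((pab + smoothing) / ((pa + smoothing) * (pb + smoothing)))
}

random_docs <- function(n_docs, vocab, seed) {
  set.seed(seed)
  lapply(seq_len(n_docs), function(i)
    sample(vocab, sample(2:min(6, length(vocab)), 1)))
}

# route samples through a fitted tree, returning the leaf id per row;
# leaves are numbered in depth-first order
route_leaves <- function(node, x) {
  leaf_id <- integer(nrow(x))
  counter <- 0L
  walk <- function(nd, idx) {
    if (!is.null(nd$leaf)) {
      counter <<- counter + 1L
      leaf_id[idx] <<- counter
      return()
    }
    left <- x[idx, nd$feature] <= nd$threshold
    walk(nd$left, idx[left])
    walk(nd$right, idx[!left])
  }
  walk(node, seq_len(nrow(x)))
  leaf_id
}

leaf_values_dfs <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  c(leaf_values_dfs(node$left), leaf_values_dfs(node$right))
}
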