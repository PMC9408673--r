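# The nine-feature identification system. Eight classification features
# span four levels -- subject relevance (coarse granularity), text
# structure (fine granularity), emotional orientation, and publisher
# behaviour -- plus one regulatory feature tracking a publisher's
# history of released false information.

FEATURE_NAMES <- c("f1_subject_relevance", "f2_feature_word_count",
                   "f3_clause_count", "f4_effective_length",
                   "f5_emotional_intensity", "f6_publisher_name",
                   "f7_publisher_level", "f8_history_amount",
                   "f9_false_history")

#' Subject relevance of a message (F1)
#'
#' Relevance between the m nouns of a message and the k epidemic subject
#' feature words, computed as the mean over all m x k pairs of the
#' non-negative part of their PMI. Negative PMI encodes topical
#' irrelevance and is clipped to zero; a message without nouns scores 0.
#'
#' @param message a message record.
#' @param feature_words nonempty character vector of subject feature
#'   words.
#' @param stats [corpus_stats()] of the reference corpus.
#' @param smoothing additive PMI smoothing (see [pmi()]).
#' @return Non-negative relevance score.
#' @export
f1_subject_relevance <- function(message, feature_words, stats,
                                 smoothing = 0) {
  if (!length(feature_words)) {
    stop_epiwatch("`feature_words` must be nonempty",
                  "epiwatch_parameter_error")
  }
  nouns <- message_nouns(message)
  if (!length(nouns)) return(0)
  pm <- pmi_matrix(nouns, feature_words, stats, smoothing)
  pm[!is.finite(pm) | pm < 0] <- 0
  mean(pm)
}

#' Text structure features of a message (F2-F4)
#'
#' `W` counts tokens tagged noun, verb, adjective or adverb over all
#' clauses; `S` is the clause count; `ratio` is effective over raw
#' character count (0 when the message has no characters).
#'
#' @param message a message record.
#' @return Named list `W`, `S`, `ratio`.
#' @export
text_structure_features <- function(message) {
  W <- length(message_tokens(message,
                             pos = c("noun", "verb", "adjective", "adverb")))
  S <- length(message$clauses)
  ratio <- if (message$raw_char_count > 0)
    message$effective_char_count / message$raw_char_count else 0
  list(W = W, S = S, ratio = ratio)
}

#' Emotional intensity of a message (F5)
#'
#' The proportion P/(P+R) of positive evaluation clauses among the
#' polarized (positive or negative) clauses. Neutral clauses do not
#' count. A message with no polarized clause returns 0.5, the maximally
#' neutral value: both extremes (over-praise and over-belittlement)
#' signal falsity, so absence of polarity maps to the centre.
#'
#' @param message a message record.
#' @return Value in \[0, 1\].
#' @export
f5_emotional_intensity <- function(message) {
  pol <- vapply(message$clauses, `[[`, "", "polarity")
  P <- sum(pol == "positive")
  R <- sum(pol == "negative")
  if (P + R == 0L) 0.5 else P / (P + R)
}

#' Publisher behaviour features (F6-F8)
#'
#' F6 indicates a real-name account (1/0), F7 is the platform tier in
#' {1, 2, 3} (primary/intermediate/advanced), F8 the publisher's
#' historical message count.
#'
#' @param publisher one row of a corpus publisher table (or a list with
#'   the same fields).
#' @return Named list `f6`, `f7`, `f8`.
#' @export
publisher_features <- function(publisher) {
  list(f6 = as.integer(isTRUE(publisher$name_is_real) ||
                         identical(publisher$name_is_real, 1L)),
       f7 = as.integer(publisher$platform_tier),
       f8 = as.integer(publisher$history_count))
}

#' Update a publisher's false-history probability (F9)
#'
#' The regulatory feature starts at 0 and becomes the fraction of the
#' publisher's classified messages that the classifier labelled false.
#'
#' @param publisher a publisher record (list or one-row data frame).
#' @param classified character vector of classifier output labels
#'   (`"true_info"` / `"false_info"`) for this publisher's messages.
#' @return The publisher with `false_history_prob` updated.
#' @export
update_false_history <- function(publisher, classified) {
  n <- length(classified)
  publisher$false_history_prob <-
    if (n == 0L) 0 else sum(classified == "false_info") / n
  publisher
}

#' Eliminate publishers whose false-history probability reached a threshold
#'
#' Removes every message whose publisher's `false_history_prob` is at
#' least `theta` (default 0.5). The publisher table is kept intact so
#' the regulatory state survives; only messages are dropped. Idempotent,
#' and monotone in `theta`: a larger threshold removes a subset.
#'
#' @param corpus an [epi_corpus()].
#' @param theta elimination threshold in \[0, 1\].
#' @return The filtered corpus.
#' @export
eliminate_publishers <- function(corpus, theta = 0.5) {
  assert_prob(theta, "theta")
  bad <- corpus$publishers$publisher_id[
    corpus$publishers$false_history_prob >= theta]
  keep <- vapply(corpus$messages,
                 function(m) !(m$publisher_id %in% bad), logical(1))
  corpus$messages <- corpus$messages[keep]
  corpus
}

#' Extract the full feature vector of one message (F1-F9)
#'
#' @param message a message record.
#' @param publisher the matching publisher record.
#' @param feature_words subject feature words for F1.
#' @param stats [corpus_stats()] for PMI.
#' @param smoothing additive PMI smoothing.
#' @return Named numeric vector of length 9 (8 classification features
#'   plus the regulatory feature `f9_false_history`).
#' @export
extract_features <- function(message, publisher, feature_words, stats,
                             smoothing = 0) {
  ts <- text_structure_features(message)
  pb <- publisher_features(publisher)
  v <- c(f1_subject_relevance(message, feature_words, stats, smoothing),
         ts$W, ts$S, ts$ratio,
         f5_emotional_intensity(message),
         pb$f6, pb$f7, pb$f8,
         as.numeric(publisher$false_history_prob))
  names(v) <- FEATURE_NAMES
  v
}

#' Feature matrix of a whole corpus
#'
#' Applies [extract_features()] to every message and returns the result
#' as a data frame with one row per message, a `message_id` column, the
#' nine feature columns and a `label` column (NA where unlabeled).
#'
#' @param corpus an [epi_corpus()].
#' @param feature_words subject feature words for F1.
#' @param stats [corpus_stats()]; defaults to statistics of `corpus`
#'   itself.
#' @param smoothing additive PMI smoothing.
#' @return A data frame of features.
#' @export
feature_matrix <- function(corpus, feature_words, stats = NULL,
                           smoothing = 0) {
  if (is.null(stats)) stats <- corpus_stats(corpus)
  pub <- corpus$publishers
  rows <- lapply(corpus$messages, function(msg) {
    p <- pub[pub$publisher_id == msg$publisher_id, , drop = FALSE]
    extract_features(msg, as.list(p), feature_words, stats, smoothing)
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (!nrow(out)) {
    out <- as.data.frame(matrix(numeric(), 0, length(FEATURE_NAMES),
                                dimnames = list(NULL, FEATURE_NAMES)))
  }
  out$message_id <- vapply(corpus$messages, `[[`, "", "message_id")
  out$label <- vapply(corpus$messages,
                      function(m) m$label %||% NA_character_, "")
  out[, c("message_id", FEATURE_NAMES, "label")]
}
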