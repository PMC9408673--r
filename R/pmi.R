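# Document-level co-occurrence statistics and pointwise mutual
# information. Probabilities are estimated as document frequencies over
# the corpus: p(a) = df(a)/n, p(a,b) = df(a & b together)/n, and
# PMI(a,b) = log p(a,b) / (p(a) p(b)) with optional additive smoothing.

#' Document-level co-occurrence statistics
#'
#' Builds the frequency tables behind PMI from a corpus: the number of
#' documents, per-word document frequency, and the joint document
#' frequency of every co-occurring word pair (held as a sparse
#' word-by-word matrix; its diagonal is the document frequency).
#'
#' @param docs either an [epi_corpus()] (each message is one document,
#'   its token set deduplicated) or a list of character vectors.
#' @return An object of class `corpus_stats` with elements `doc_count`,
#'   `vocab`, `doc_freq` (named integer) and `cooc` (sparse symmetric
#'   count matrix).
#' @export
corpus_stats <- function(docs) {
  if (inherits(docs, "epi_corpus")) {
    docs <- lapply(docs$messages, message_tokens)
  }
  docs <- lapply(docs, function(d) unique(as.character(d)))
  docs <- Filter(length, docs)
  n <- length(docs)
  vocab <- sort(unique(unlist(docs, use.names = FALSE)))
  if (!length(vocab)) {
    return(structure(list(doc_count = n, vocab = character(),
                          doc_freq = integer(),
                          cooc = Matrix::sparseMatrix(i = integer(),
                                                      j = integer(),
                                                      x = numeric(),
                                                      dims = c(0, 0))),
                     class = "corpus_stats"))
  }
  ii <- unlist(lapply(seq_along(docs), function(k)
    rep.int(k, length(docs[[k]]))), use.names = FALSE)
  jj <- match(unlist(docs, use.names = FALSE), vocab)
  # documents x vocab binary incidence; crossprod gives pairwise joint
  # document frequencies with document frequencies on the diagonal
  inc <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(n, length(vocab)))
  cooc <- Matrix::crossprod(inc)
  dimnames(cooc) <- list(vocab, vocab)
  df <- as.integer(Matrix::diag(cooc))
  names(df) <- vocab
  structure(list(doc_count = n, vocab = vocab, doc_freq = df, cooc = cooc),
            class = "corpus_stats")
}

#' @exportS3Method base::print
print.corpus_stats <- function(x, ...) {
  cat(sprintf("<corpus_stats> %d documents, %d distinct words\n",
              x$doc_count, length(x$vocab)))
  invisible(x)
}

doc_freq_of <- function(stats, words) {
  f <- stats$doc_freq[words]
  f[is.na(f)] <- 0L
  unname(f)
}

joint_freq_of <- function(stats, words_a, words_b) {
  known_a <- words_a %in% stats$vocab
  known_b <- words_b %in% stats$vocab
  out <- matrix(0, length(words_a), length(words_b))
  if (any(known_a) && any(known_b)) {
    out[known_a, known_b] <-
      as.matrix(stats$cooc[words_a[known_a], words_b[known_b], drop = FALSE])
  }
  out
}

#' Pointwise mutual information of a word pair
#'
#' `log((p(a,b) + s) / ((p(a) + s) (p(b) + s)))` with natural log,
#' document-frequency probability estimates and additive smoothing `s`.
#' Symmetric in its word arguments; 0 when the pair occurs exactly as
#' often as independence predicts (with `smoothing = 0`).
#'
#' @param word_a,word_b words to compare.
#' @param stats a [corpus_stats()] object with `doc_count > 0`.
#' @param smoothing additive smoothing constant, >= 0. The default 0 is
#'   exact; use a tiny positive value (e.g. 1e-9) to keep never
#'   co-occurring pairs finite.
#' @return PMI value (may be `-Inf` for never co-occurring pairs at
#'   `smoothing = 0`).
#' @export
pmi <- function(word_a, word_b, stats, smoothing = 0) {
  if (stats$doc_count == 0L) {
    stop_epiwatch("corpus_stats has zero documents", "epiwatch_parameter_error")
  }
  assert_scalar_number(smoothing, "smoothing", lower = 0)
  drop(pmi_matrix(word_a, word_b, stats, smoothing))
}

#' Pairwise PMI matrix between two word sets
#'
#' Vectorized form of [pmi()]: element (i, j) is the PMI of
#' `words_a[i]` with `words_b[j]`.
#'
#' @inheritParams pmi
#' @param words_a,words_b character vectors.
#' @return A numeric matrix of dimension `length(words_a)` x
#'   `length(words_b)`.
#' @export
pmi_matrix <- function(words_a, words_b, stats, smoothing = 0) {
  if (stats$doc_count == 0L) {
    stop_epiwatch("corpus_stats has zero documents", "epiwatch_parameter_error")
  }
  n <- stats$doc_count
  pa <- doc_freq_of(stats, words_a) / n
  pb <- doc_freq_of(stats, words_b) / n
  pab <- joint_freq_of(stats, words_a, words_b) / n
  log((pab + smoothing) / (outer(pa + smoothing, pb + smoothing)))
}
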