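# Baseline annotation for raw text. The package treats clause
# segmentation, POS tags and clause polarity as INPUT data; this
# lexicon-lookup annotator is a deliberately naive fallback for plain
# text, not a contribution.

#' Count effective characters of a text
#'
#' "Invalid" characters default to URLs, whitespace and punctuation; the
#' set is configurable as a vector of regular expressions removed in
#' order. Counting is by Unicode code point.
#'
#' @param text a character string.
#' @param invalid_patterns character vector of regexes removed before
#'   counting.
#' @return Integer count of remaining code points.
#' @export
count_effective_chars <- function(text,
                                  invalid_patterns = c("https?://[^[:space:]]+",
                                                       "[[:space:]]",
                                                       "[[:punct:]]")) {
  for (p in invalid_patterns) text <- gsub(p, "", text, perl = TRUE)
  nchar(text, type = "chars")
}

#' Naive lexicon-based annotator for raw text
#'
#' Splits text into clauses at sentence/clause punctuation, tokenizes on
#' whitespace, tags tokens by lexicon lookup (unknown tokens are tagged
#' `other`) and assigns clause polarity as the sign of positive-minus-
#' negative sentiment-lexicon hits (ties are neutral). Intended as a
#' baseline only: real deployments should supply annotations produced by
#' a proper tagger.
#'
#' @param text raw message text.
#' @param pos_lexicon named character vector mapping token to POS tag.
#' @param sentiment_lexicon named numeric vector mapping token to +1
#'   (positive) or -1 (negative).
#' @return List of clause records as accepted by [epi_message()].
#' @export
annotate_text <- function(text, pos_lexicon = character(),
                          sentiment_lexicon = numeric()) {
  pieces <- strsplit(text, "[.!?;,。；，！？]+")[[1]]
  pieces <- trimws(pieces)
  pieces <- pieces[nzchar(pieces)]
  lapply(pieces, function(cl) {
    toks <- strsplit(cl, "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    pos <- unname(pos_lexicon[toks])
    pos[is.na(pos) | !pos %in% POS_TAGS] <- "other"
    sentiment <- sum(sentiment_lexicon[toks], na.rm = TRUE)
    polarity <- if (sentiment > 0) "positive"
                else if (sentiment < 0) "negative" else "neutral"
    list(tokens = Map(function(tk, pg) c(tk, pg), toks, pos,
                      USE.NAMES = FALSE),
         polarity = polarity)
  })
}
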