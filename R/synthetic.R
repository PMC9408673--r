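# Seeded synthetic corpora, link graphs and multi-day timelines with the
# statistical structure the feature system and the indicator system
# assume. Tokens are symbolic ("epi03", "off17", ...): the generator
# emulates distributional structure (topical co-occurrence, polarity
# ratios, publisher behaviour, topic drift), not natural language.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic-data generator
#'
#' Defaults define the reference study conditions used throughout the
#' test suite: 500 link-graph pages, 1000 messages from 50 publishers
#' with a 30% planted false fraction over 9 days. `effect_sizes`
#' controls how false messages differ from true ones on each feature
#' level: topical nouns (F1), clause and word counts (F2, F3), effective
#' length (F4), polarity extremity (F5) and publisher profile (F6-F8).
#'
#' @param n_pages pages of the synthetic link graph.
#' @param n_publishers number of publisher accounts.
#' @param n_messages number of messages.
#' @param false_fraction planted fraction of false messages in \[0, 1\].
#' @param n_days number of calendar days the corpus spans.
#' @param start_date first day of the corpus.
#' @param n_epidemic_vocab,n_offtopic_vocab sizes of the disjoint
#'   epidemic and off-topic noun vocabularies.
#' @param n_feature_words number of epidemic nouns that form the subject
#'   feature-word list.
#' @param n_provinces provinces of the synthetic gazetteer.
#' @param burst_days integer day indices whose message count is
#'   multiplied (timeline generator).
#' @param burst_multiplier count multiplier applied on `burst_days`.
#' @param messages_per_day base daily message count of the timeline
#'   generator.
#' @param max_new_subjects largest number of new subjects injectable on
#'   one timeline day.
#' @param sentiment_means per-day mean positive-clause probability for
#'   the timeline generator, recycled over days.
#' @param effect_sizes named list of per-feature shifts (see Details in
#'   the package vignette); any entry may be overridden.
#' @param seed integer seed; identical seeds reproduce identical output.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_pages = 500L, n_publishers = 50L,
                             n_messages = 1000L, false_fraction = 0.3,
                             n_days = 9L, start_date = "2020-02-04",
                             n_epidemic_vocab = 40L, n_offtopic_vocab = 40L,
                             n_feature_words = 10L, n_provinces = 34L,
                             burst_days = integer(), burst_multiplier = 2,
                             messages_per_day = 24L, max_new_subjects = 3L,
                             sentiment_means = 0.5,
                             effect_sizes = list(), seed = 0L) {
  assert_prob(false_fraction, "false_fraction")
  if (n_days < 1L) {
    stop_epiwatch("n_days must be >= 1", "epiwatch_parameter_error")
  }
  if (n_pages < 1L) {
    stop_epiwatch("n_pages must be >= 1", "epiwatch_parameter_error")
  }
  defaults <- list(
    p_epi_noun = c(true = 0.9, false = 0.15),
    clause_rate = c(true = 5, false = 2),
    eff_len_shape = list(true = c(9, 2), false = c(4, 4)),
    polarity_shape = list(true = c(6, 6), false = c(0.4, 0.4)),
    p_neutral_clause = c(true = 0.3, false = 0.1),
    p_good_publisher = c(true = 0.9, false = 0.15)
  )
  effect_sizes <- utils::modifyList(defaults, effect_sizes)
  structure(list(
    n_pages = as.integer(n_pages), n_publishers = as.integer(n_publishers),
    n_messages = as.integer(n_messages), false_fraction = false_fraction,
    n_days = as.integer(n_days), start_date = as.Date(start_date),
    n_epidemic_vocab = as.integer(n_epidemic_vocab),
    n_offtopic_vocab = as.integer(n_offtopic_vocab),
    n_feature_words = as.integer(n_feature_words),
    n_provinces = as.integer(n_provinces),
    burst_days = as.integer(burst_days),
    burst_multiplier = burst_multiplier,
    messages_per_day = as.integer(messages_per_day),
    max_new_subjects = as.integer(max_new_subjects),
    sentiment_means = sentiment_means,
    effect_sizes = effect_sizes, seed = as.integer(seed)
  ), class = "generator_config")
}

epidemic_vocab <- function(config)
  sprintf("epi%02d", seq_len(config$n_epidemic_vocab))
offtopic_vocab <- function(config)
  sprintf("off%02d", seq_len(config$n_offtopic_vocab))

#' Subject feature words of a generator configuration
#' @param config a [generator_config()].
#' @return Character vector of feature words (a slice of the epidemic
#'   vocabulary).
#' @export
default_feature_words <- function(config = generator_config()) {
  epidemic_vocab(config)[seq_len(config$n_feature_words)]
}

#' Synthetic place-name gazetteer
#'
#' Maps place mentions `place01..placeP` to provinces `prov01..provP`.
#'
#' @param config a [generator_config()].
#' @return Data frame with columns `place`, `province`.
#' @export
default_gazetteer <- function(config = generator_config()) {
  p <- config$n_provinces
  data.frame(place = sprintf("place%02d", seq_len(p)),
             province = sprintf("prov%02d", seq_len(p)),
             stringsAsFactors = FALSE)
}

synth_clauses <- function(is_false, es, q_positive, epi, off) {
  kind <- if (is_false) "false" else "true"
  n_clauses <- 1L + stats::rpois(1L, es$clause_rate[[kind]])
  lapply(seq_len(n_clauses), function(i) {
    n_nouns <- sample(1:3, 1L)
    from_epi <- stats::runif(n_nouns) < es$p_epi_noun[[kind]]
    nouns <- character(n_nouns)
    if (any(from_epi)) nouns[from_epi] <- sample(epi, sum(from_epi),
                                                 replace = TRUE)
    if (any(!from_epi)) nouns[!from_epi] <- sample(off, sum(!from_epi),
                                                   replace = TRUE)
    verbs <- sprintf("verb%02d", sample.int(20L, sample(1:2, 1L),
                                            replace = TRUE))
    mods <- sprintf("adj%02d", sample.int(15L, sample(0:2, 1L),
                                          replace = TRUE))
    filler <- sprintf("w%03d", sample.int(200L, sample(0:3, 1L),
                                          replace = TRUE))
    tokens <- c(
      Map(function(t) c(t, "noun"), nouns),
      Map(function(t) c(t, "verb"), verbs),
      Map(function(t) c(t, if (i %% 2L == 0L) "adverb" else "adjective"),
          mods),
      Map(function(t) c(t, "other"), filler))
    polarity <- if (stats::runif(1) < es$p_neutral_clause[[kind]]) "neutral"
                else if (stats::runif(1) < q_positive) "positive"
                else "negative"
    list(tokens = unname(tokens), polarity = polarity)
  })
}

#' Generate a seeded labeled synthetic corpus
#'
#' True messages draw their nouns mostly from the epidemic vocabulary
#' (which contains the subject feature words, so document-level
#' co-occurrence makes their PMI relevance high), carry more clauses and
#' words, a higher effective-length ratio, balanced clause polarity and
#' mostly real-name higher-tier publishers. False messages are shifted
#' on every level per `config$effect_sizes`: off-topic nouns, fewer
#' clauses, shorter effective length, polarity-extreme clauses,
#' pseudonymous low-tier publishers. Identical seeds reproduce
#' identical corpora.
#'
#' @param config a [generator_config()].
#' @return List with `corpus` (labeled [epi_corpus()]), `labels` (data
#'   frame `message_id`, `label`), `feature_words` and `gazetteer`.
#' @export
generate_corpus <- function(config = generator_config()) {
  es <- config$effect_sizes
  epi <- epidemic_vocab(config)
  off <- offtopic_vocab(config)
  gaz <- default_gazetteer(config)
  with_seed(config$seed, {
    n_good <- max(1L, round(0.6 * config$n_publishers))
    n_bad <- max(1L, config$n_publishers - n_good)
    publishers <- data.frame(
      publisher_id = sprintf("pub%03d", seq_len(n_good + n_bad)),
      name_is_real = c(stats::runif(n_good) < 0.9,
                       stats::runif(n_bad) < 0.2),
      platform_tier = c(sample(2:3, n_good, replace = TRUE),
                        sample(1:2, n_bad, replace = TRUE)),
      history_count = c(stats::rpois(n_good, 60), stats::rpois(n_bad, 5)),
      false_history_prob = 0,
      stringsAsFactors = FALSE)
    good_ids <- publishers$publisher_id[seq_len(n_good)]
    bad_ids <- publishers$publisher_id[n_good + seq_len(n_bad)]

    n <- config$n_messages
    is_false <- stats::runif(n) < config$false_fraction
    days <- sample.int(config$n_days, n, replace = TRUE)
    messages <- vector("list", n)
    for (i in seq_len(n)) {
      kind <- if (is_false[i]) "false" else "true"
      q_pos <- stats::rbeta(1, es$polarity_shape[[kind]][1],
                            es$polarity_shape[[kind]][2])
      clauses <- synth_clauses(is_false[i], es, q_pos, epi, off)
      n_tokens <- sum(vapply(clauses, function(cl) length(cl$tokens),
                             integer(1)))
      raw <- 20L + n_tokens * 5L + stats::rpois(1L, 10)
      ratio <- stats::rbeta(1, es$eff_len_shape[[kind]][1],
                            es$eff_len_shape[[kind]][2])
      from_good <- stats::runif(1) < es$p_good_publisher[[kind]]
      pid <- if (from_good) sample(good_ids, 1L) else sample(bad_ids, 1L)
      places <- sample(gaz$place, sample(0:3, 1L))
      messages[[i]] <- epi_message(
        message_id = sprintf("msg%05d", i), publisher_id = pid,
        timestamp = config$start_date + days[i] - 1L,
        clauses = clauses, raw_char_count = raw,
        effective_char_count = as.integer(round(ratio * raw)),
        places = places,
        label = if (is_false[i]) "false_info" else "true_info")
    }
    corpus <- epi_corpus(messages = messages, publishers = publishers)
    list(corpus = corpus,
         labels = data.frame(
           message_id = vapply(messages, `[[`, "", "message_id"),
           label = ifelse(is_false, "false_info", "true_info"),
           stringsAsFactors = FALSE),
         feature_words = default_feature_words(config),
         gazetteer = gaz)
  })
}

#' Generate a seeded synthetic link graph
#'
#' Pages are added in order; each links to a few earlier pages chosen
#' with probability proportional to current in-degree plus one
#' (preferential attachment), so early pages become hubs and the
#' reliability scores are non-uniform. No self-links are produced.
#'
#' @param config a [generator_config()].
#' @return List of [web_page()] records.
#' @export
generate_link_graph <- function(config = generator_config()) {
  n <- config$n_pages
  with_seed(config$seed + 1L, {
    indeg <- rep(0L, n)
    pages <- vector("list", n)
    pages[[1L]] <- web_page(1L, url = "https://example.org/page1")
    for (j in seq_len(n)[-1L]) {
      m <- min(j - 1L, sample(1:4, 1L))
      targets <- sample.int(j - 1L, m, prob = indeg[seq_len(j - 1L)] + 1)
      indeg[targets] <- indeg[targets] + 1L
      pages[[j]] <- web_page(j, url = sprintf("https://example.org/page%d", j),
                             out_links = targets)
    }
    pages
  })
}

#' Generate a multi-day timeline with planted topic drift
#'
#' Every day carries one persistent core epidemic subject plus a seeded
#' number (0..`max_new_subjects`) of brand-new subjects on disjoint
#' vocabularies, so new-subject counts and cluster counts are planted by
#' construction and subject concentration moves inversely to them. Days
#' listed in `config$burst_days` get `burst_multiplier` times the base
#' message count and a full complement of new subjects (a burst brings
#' new topics). Per-day mean polarity follows `config$sentiment_means`.
#'
#' @param config a [generator_config()].
#' @return List with `corpus` (all messages labeled `true_info`),
#'   `gazetteer`, and `schedule` (data frame `date`, `n_messages`,
#'   `n_new_subjects` of the planted truth).
#' @export
generate_timeline <- function(config = generator_config()) {
  gaz <- default_gazetteer(config)
  with_seed(config$seed + 2L, {
    publishers <- data.frame(
      publisher_id = sprintf("tlpub%02d", 1:5),
      name_is_real = TRUE, platform_tier = 3L,
      history_count = 100L, false_history_prob = 0,
      stringsAsFactors = FALSE)
    core_vocab <- sprintf("core%02d", 1:8)
    q_day <- rep_len(config$sentiment_means, config$n_days)
    n_new <- sample(0:config$max_new_subjects, config$n_days, replace = TRUE)
    if (config$n_days >= 1L) n_new[1L] <- 0L
    n_msgs <- rep(config$messages_per_day, config$n_days)
    for (b in config$burst_days) {
      if (b >= 1L && b <= config$n_days) {
        n_msgs[b] <- as.integer(round(n_msgs[b] * config$burst_multiplier))
        n_new[b] <- config$max_new_subjects
      }
    }
    messages <- list()
    mid <- 0L
    for (d in seq_len(config$n_days)) {
      vocabs <- c(list(core_vocab),
                  lapply(seq_len(n_new[d]), function(s)
                    sprintf("d%02ds%d_%02d", d, s, 1:8)))
      # each new subject claims a fixed share of the day's messages, the
      # persistent core subject takes the remainder
      per_new <- if (n_new[d] > 0L)
        max(2L, n_msgs[d] %/% (2L * (n_new[d] + 1L))) else 0L
      subject_of <- rep(1L, n_msgs[d])
      if (n_new[d] > 0L) {
        extra <- rep(seq_len(n_new[d]) + 1L, each = per_new)
        subject_of[seq_along(extra)] <- extra
      }
      for (i in seq_len(n_msgs[d])) {
        vocab <- vocabs[[subject_of[i]]]
        nouns <- sample(vocab, 5L)
        clauses <- lapply(seq_len(3L), function(k) {
          toks <- c(Map(function(t) c(t, "noun"),
                        nouns[((k - 1L) * 2L + 1L):min(k * 2L, 5L)]),
                    list(c(sprintf("verb%02d", sample.int(20L, 1L)), "verb")))
          polarity <- if (stats::runif(1) < 0.3) "neutral"
                      else if (stats::runif(1) < q_day[d]) "positive"
                      else "negative"
          list(tokens = unname(toks), polarity = polarity)
        })
        mid <- mid + 1L
        messages[[mid]] <- epi_message(
          message_id = sprintf("tl%05d", mid),
          publisher_id = sample(publishers$publisher_id, 1L),
          timestamp = config$start_date + d - 1L,
          clauses = clauses, raw_char_count = 120L,
          effective_char_count = 100L,
          places = sample(gaz$place, sample(1:3, 1L)),
          label = "true_info")
      }
    }
    list(corpus = epi_corpus(messages = messages, publishers = publishers),
         gazetteer = gaz,
         schedule = data.frame(
           date = config$start_date + seq_len(config$n_days) - 1L,
           n_messages = n_msgs, n_new_subjects = n_new))
  })
}
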