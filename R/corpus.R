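#' Corpus data model for epidemic messages
#'
#' A corpus bundles annotated epidemic messages with their publishers and,
#' optionally, a web-link graph. Messages arrive pre-annotated: clause
#' segmentation, part-of-speech tags and clause polarity are input data
#' (a naive lexicon-based fallback annotator is available via
#' [annotate_text()] for raw text). Publishers carry the behavioural
#' attributes used as classification features: whether the account name is
#' real, the platform tier (1 = primary, 2 = intermediate, 3 = advanced),
#' the historical message count, and a running probability of having
#' released false information (the regulatory state, 0 for unseen
#' publishers).
#'
#' @param messages list of message records, see [epi_message()].
#' @param publishers data frame with columns `publisher_id`,
#'   `name_is_real`, `platform_tier`, `history_count`,
#'   `false_history_prob`.
#' @param pages optional list of web pages, see [web_page()].
#' @return An object of class `epi_corpus`: a list with elements
#'   `messages`, `publishers` and `pages`.
#' @seealso [read_corpus()], [write_corpus()], [generate_corpus()]
#' @export
epi_corpus <- function(messages = list(), publishers = empty_publishers(),
                       pages = NULL) {
  corpus <- structure(
    list(messages = messages, publishers = publishers, pages = pages),
    class = "epi_corpus"
  )
  validate_corpus(corpus)
}

POS_TAGS <- c("noun", "verb", "adjective", "adverb", "other")
POLARITIES <- c("positive", "negative", "neutral")
LABELS <- c("true_info", "false_info")

empty_publishers <- function() {
  data.frame(
    publisher_id = character(), name_is_real = logical(),
    platform_tier = integer(), history_count = integer(),
    false_history_prob = numeric(), stringsAsFactors = FALSE
  )
}

#' Construct a single annotated message
#'
#' @param message_id unique string id.
#' @param publisher_id id of the publishing account.
#' @param timestamp a `Date` (or string coercible to one); the unit time
#'   of the warning stage is one calendar day.
#' @param clauses list of clauses; each clause is a list with `tokens`
#'   (a list of `c(token, pos)` pairs, pos one of noun/verb/adjective/
#'   adverb/other) and `polarity` (positive/negative/neutral).
#' @param raw_char_count total number of characters of the original text.
#' @param effective_char_count characters remaining after removing
#'   invalid characters (whitespace, punctuation, URLs by default).
#' @param places character vector of place-name mentions.
#' @param label optional ground-truth label, `"true_info"` or
#'   `"false_info"`.
#' @return A list with class-free message record structure.
#' @export
epi_message <- function(message_id, publisher_id, timestamp, clauses = list(),
                        raw_char_count = 0L, effective_char_count = 0L,
                        places = character(), label = NULL) {
  list(
    message_id = as.character(message_id),
    publisher_id = as.character(publisher_id),
    timestamp = as.Date(timestamp),
    clauses = clauses,
    raw_char_count = as.integer(raw_char_count),
    effective_char_count = as.integer(effective_char_count),
    places = as.character(places),
    label = label
  )
}

#' Construct a clause record
#'
#' @param tokens character vector of tokens.
#' @param pos character vector of part-of-speech tags, recycled to the
#'   length of `tokens`.
#' @param polarity one of `"positive"`, `"negative"`, `"neutral"`.
#' @return A clause record (list with `tokens` and `polarity`).
#' @export
epi_clause <- function(tokens, pos = "other", polarity = "neutral") {
  pos <- rep_len(pos, length(tokens))
  list(
    tokens = Map(function(tk, pg) c(tk, pg), as.character(tokens),
                 as.character(pos), USE.NAMES = FALSE),
    polarity = polarity
  )
}

#' Construct a web page record for the link graph
#'
#' Self-links and duplicate out-links are removed on construction: the
#' transfer matrix assumes simple links.
#'
#' @param page_id integer id, unique within a graph, >= 1.
#' @param url page URL.
#' @param out_links integer vector of page ids this page links to.
#' @param text optional page text.
#' @return A web page record (list).
#' @export
web_page <- function(page_id, url = "", out_links = integer(), text = "") {
  page_id <- as.integer(page_id)
  out_links <- unique(as.integer(out_links))
  out_links <- out_links[out_links != page_id]
  list(page_id = page_id, url = url, out_links = out_links, text = text)
}

validate_message <- function(msg, where = "") {
  need <- c("message_id", "publisher_id", "timestamp", "clauses",
            "raw_char_count", "effective_char_count", "places")
  missing <- setdiff(need, names(msg))
  if (length(missing)) {
    stop_epiwatch(sprintf("message%s missing field(s): %s", where,
                          paste(missing, collapse = ", ")),
                  "epiwatch_validation_error")
  }
  ts <- tryCatch(as.Date(msg$timestamp), error = function(e) NA)
  if (length(ts) != 1L || is.na(ts)) {
    stop_epiwatch(sprintf("message%s has unparseable timestamp", where),
                  "epiwatch_validation_error")
  }
  if (msg$effective_char_count > msg$raw_char_count) {
    stop_epiwatch(sprintf(
      "message%s: effective_char_count exceeds raw_char_count", where),
      "epiwatch_validation_error")
  }
  for (cl in msg$clauses) {
    if (!cl$polarity %in% POLARITIES) {
      stop_epiwatch(sprintf("message%s: invalid clause polarity '%s'",
                            where, cl$polarity),
                    "epiwatch_validation_error")
    }
    for (tk in cl$tokens) {
      if (length(tk) != 2L || !tk[[2L]] %in% POS_TAGS) {
        stop_epiwatch(sprintf("message%s: token must be (token, pos) with %s",
                              where, paste(POS_TAGS, collapse = "/")),
                      "epiwatch_validation_error")
      }
    }
  }
  if (!is.null(msg$label) && !msg$label %in% LABELS) {
    stop_epiwatch(sprintf("message%s: label must be one of %s", where,
                          paste(LABELS, collapse = ", ")),
                  "epiwatch_validation_error")
  }
  invisible(msg)
}

validate_corpus <- function(corpus) {
  pub <- corpus$publishers
  if (anyDuplicated(pub$publisher_id)) {
    stop_epiwatch("duplicate publisher_id in publisher table",
                  "epiwatch_validation_error")
  }
  if (nrow(pub) && !all(pub$platform_tier %in% 1:3)) {
    stop_epiwatch("platform_tier must be in {1, 2, 3}",
                  "epiwatch_validation_error")
  }
  if (nrow(pub) && (any(pub$false_history_prob < 0) ||
                    any(pub$false_history_prob > 1))) {
    stop_epiwatch("false_history_prob must lie in [0, 1]",
                  "epiwatch_validation_error")
  }
  if (nrow(pub) && any(pub$history_count < 0)) {
    stop_epiwatch("history_count must be >= 0", "epiwatch_validation_error")
  }
  ids <- vapply(corpus$messages, `[[`, "", "message_id")
  if (anyDuplicated(ids)) {
    stop_epiwatch("duplicate message_id in corpus",
                  "epiwatch_validation_error")
  }
  for (i in seq_along(corpus$messages)) {
    msg <- corpus$messages[[i]]
    validate_message(msg, sprintf(" %d", i))
    if (!msg$publisher_id %in% pub$publisher_id) {
      stop_epiwatch(sprintf(
        "message %d references unknown publisher_id '%s'", i,
        msg$publisher_id), "epiwatch_validation_error")
    }
  }
  if (!is.null(corpus$pages)) {
    pids <- vapply(corpus$pages, `[[`, integer(1), "page_id")
    if (anyDuplicated(pids)) {
      stop_epiwatch("duplicate page_id in link graph",
                    "epiwatch_validation_error")
    }
  }
  invisible(corpus)
}

#' @exportS3Method base::print
print.epi_corpus <- function(x, ...) {
  lab <- vapply(x$messages, function(m) m$label %||% NA_character_, "")
  cat(sprintf("<epi_corpus> %d messages, %d publishers%s\n",
              length(x$messages), nrow(x$publishers),
              if (is.null(x$pages)) ""
              else sprintf(", %d link-graph pages", length(x$pages))))
  if (length(x$messages)) {
    rng <- range(as.Date(vapply(x$messages, function(m)
      as.character(m$timestamp), "")))
    cat(sprintf("  dates %s .. %s\n", rng[1], rng[2]))
    if (any(!is.na(lab))) {
      cat(sprintf("  labels: %d true_info, %d false_info, %d unlabeled\n",
                  sum(lab == "true_info", na.rm = TRUE),
                  sum(lab == "false_info", na.rm = TRUE), sum(is.na(lab))))
    }
  }
  invisible(x)
}

# ---- JSON Lines serialization -------------------------------------------
# One record per line; messages and publishers share a file, discriminated
# by a "record" field. The link graph lives in its own file of page
# records. Schema documented in inst/extdata/corpus-schema.md.

message_to_list <- function(msg) {
  list(
    record = "message",
    message_id = msg$message_id,
    publisher_id = msg$publisher_id,
    timestamp = format(as.Date(msg$timestamp)),
    clauses = lapply(msg$clauses, function(cl) list(
      tokens = lapply(cl$tokens, function(tk) as.character(tk)),
      polarity = cl$polarity
    )),
    raw_char_count = msg$raw_char_count,
    effective_char_count = msg$effective_char_count,
    places = as.list(msg$places),
    label = msg$label
  )
}

list_to_message <- function(x) {
  epi_message(
    message_id = x$message_id, publisher_id = x$publisher_id,
    timestamp = x$timestamp,
    clauses = lapply(x$clauses, function(cl) list(
      tokens = lapply(cl$tokens, function(tk) unlist(tk, use.names = FALSE)),
      polarity = cl$polarity
    )),
    raw_char_count = x$raw_char_count,
    effective_char_count = x$effective_char_count,
    places = unlist(x$places, use.names = FALSE) %||% character(),
    label = x$label
  )
}

#' Read a corpus from a JSON Lines file
#'
#' Each line is one UTF-8 JSON record carrying a `record` discriminator:
#' `"publisher"` rows populate the publisher table, `"message"` rows the
#' message list. Unknown fields are ignored. The file is validated on
#' read: malformed lines raise a parse error naming the line number and a
#' message whose `publisher_id` does not resolve raises a validation
#' error.
#'
#' @param path path to the corpus JSON Lines file.
#' @param pages_path optional path to a link-graph JSON Lines file of
#'   page records (`page_id`, `url`, `out_links`, `text`).
#' @return A validated [epi_corpus()].
#' @export
read_corpus <- function(path, pages_path = NULL) {
  if (!file.exists(path)) {
    stop_epiwatch(sprintf("corpus file does not exist: %s", path),
                  "epiwatch_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  messages <- list()
  pub_rows <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$record)) {
      stop_epiwatch(sprintf("malformed corpus record at line %d of %s", i,
                            path), "epiwatch_parse_error")
    }
    if (identical(rec$record, "message")) {
      msg <- tryCatch(list_to_message(rec), error = function(e) {
        stop_epiwatch(sprintf("invalid message at line %d: %s", i,
                              conditionMessage(e)), "epiwatch_validation_error")
      })
      if (is.null(rec$timestamp)) {
        stop_epiwatch(sprintf("message at line %d missing timestamp", i),
                      "epiwatch_validation_error")
      }
      messages[[length(messages) + 1L]] <- msg
    } else if (identical(rec$record, "publisher")) {
      pub_rows[[length(pub_rows) + 1L]] <- data.frame(
        publisher_id = rec$publisher_id,
        name_is_real = isTRUE(rec$name_is_real),
        platform_tier = as.integer(rec$platform_tier),
        history_count = as.integer(rec$history_count),
        false_history_prob = as.numeric(rec$false_history_prob %||% 0),
        stringsAsFactors = FALSE
      )
    } else {
      stop_epiwatch(sprintf("unknown record type '%s' at line %d",
                            rec$record, i), "epiwatch_parse_error")
    }
  }
  publishers <- if (length(pub_rows)) do.call(rbind, pub_rows)
                else empty_publishers()
  pages <- if (!is.null(pages_path)) read_link_graph(pages_path) else NULL
  epi_corpus(messages = messages, publishers = publishers, pages = pages)
}

#' Write a corpus to a JSON Lines file
#'
#' Inverse of [read_corpus()]: publishers first, then messages, one JSON
#' record per line. Reading the written file reproduces the corpus
#' field-for-field.
#'
#' @param corpus an [epi_corpus()].
#' @param path output path.
#' @param pages_path optional output path for the link graph.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, pages_path = NULL) {
  validate_corpus(corpus)
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    stop_epiwatch(sprintf("cannot open '%s' for writing", path),
                  "epiwatch_io_error")
  })
  on.exit(close(con))
  pub <- corpus$publishers
  for (i in seq_len(nrow(pub))) {
    rec <- list(record = "publisher", publisher_id = pub$publisher_id[i],
                name_is_real = pub$name_is_real[i],
                platform_tier = pub$platform_tier[i],
                history_count = pub$history_count[i],
                false_history_prob = pub$false_history_prob[i])
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con, useBytes = TRUE)
  }
  for (msg in corpus$messages) {
    writeLines(jsonlite::toJSON(message_to_list(msg), auto_unbox = TRUE,
                                digits = NA, null = "null"), con,
               useBytes = TRUE)
  }
  if (!is.null(pages_path) && !is.null(corpus$pages)) {
    write_link_graph(corpus$pages, pages_path)
  }
  invisible(path)
}

#' Read a link graph from a JSON Lines file
#'
#' @param path path to a JSON Lines file of page records.
#' @return A list of [web_page()] records.
#' @export
read_link_graph <- function(path) {
  if (!file.exists(path)) {
    stop_epiwatch(sprintf("link graph file does not exist: %s", path),
                  "epiwatch_io_error")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$page_id)) {
      stop_epiwatch(sprintf("malformed page record at line %d of %s", i,
                            path), "epiwatch_parse_error")
    }
    web_page(rec$page_id, rec$url %||% "",
             rec$out_links %||% integer(), rec$text %||% "")
  })
}

#' Write a link graph to a JSON Lines file
#'
#' @param pages list of [web_page()] records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_link_graph <- function(pages, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (pg in pages) {
    rec <- list(page_id = pg$page_id, url = pg$url,
                out_links = as.list(pg$out_links), text = pg$text)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA),
               con, useBytes = TRUE)
  }
  invisible(path)
}

# ---- token access helpers ------------------------------------------------

#' Tokens of a message, optionally filtered by part of speech
#' @param msg a message record.
#' @param pos optional character vector of tags to keep.
#' @return character vector of tokens.
#' @export
message_tokens <- function(msg, pos = NULL) {
  out <- character()
  for (cl in msg$clauses) {
    for (tk in cl$tokens) {
      if (is.null(pos) || tk[[2L]] %in% pos) out <- c(out, tk[[1L]])
    }
  }
  out
}

#' Nouns of a message (the subject list used by PMI relevance)
#' @param msg a message record.
#' @return character vector of noun tokens.
#' @export
message_nouns <- function(msg) message_tokens(msg, pos = "noun")
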