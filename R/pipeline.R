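# End-to-end orchestration: reliable-source selection, corpus
# statistics, feature extraction, train/test split, classifier training
# and evaluation, publisher regulatory-state update, threshold
# elimination, and the downstream early-warning stage.

#' Configuration of the identification pipeline
#'
#' @param theta publisher-elimination threshold in \[0, 1\].
#' @param train_fraction fraction of labeled messages used for
#'   training, strictly inside (0, 1).
#' @param use_f9_in_classifier logical: include the regulatory feature
#'   F9 as a classifier input (default `FALSE`: F9 only drives
#'   elimination).
#' @param drop_features character vector of feature columns to ablate
#'   (e.g. `c("f1_subject_relevance", "f9_false_history")`).
#' @param smoothing additive PMI smoothing for feature extraction.
#' @param classify_threshold probability threshold of [classify()].
#' @param reliable_policy,reliable_multiplier,reliable_q selection
#'   policy forwarded to [select_reliable()].
#' @param damping,tol,max_iter forwarded to [score_pages()].
#' @param seed integer seed controlling the train/test split.
#' @param ... boosting hyper-parameters forwarded to [epiboost()]
#'   (`n_rounds`, `learning_rate`, `max_depth`, `lambda_reg`,
#'   `gamma_reg`, `min_child_hessian`, `base_score`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(theta = 0.5, train_fraction = 0.8,
                            use_f9_in_classifier = FALSE,
                            drop_features = character(),
                            smoothing = 0, classify_threshold = 0.5,
                            reliable_policy = "baseline",
                            reliable_multiplier = 1.0, reliable_q = 0.5,
                            damping = 0.85, tol = 1e-10, max_iter = 1000L,
                            seed = 0L, ...) {
  assert_prob(theta, "theta")
  assert_scalar_number(train_fraction, "train_fraction", lower = 0,
                       upper = 1, open_lower = TRUE, open_upper = TRUE)
  structure(list(theta = theta, train_fraction = train_fraction,
                 use_f9_in_classifier = use_f9_in_classifier,
                 drop_features = drop_features, smoothing = smoothing,
                 classify_threshold = classify_threshold,
                 reliable_policy = reliable_policy,
                 reliable_multiplier = reliable_multiplier,
                 reliable_q = reliable_q, damping = damping, tol = tol,
                 max_iter = max_iter, seed = as.integer(seed),
                 boost = list(...)), class = "pipeline_config")
}

classifier_feature_names <- function(config) {
  feats <- FEATURE_NAMES[1:8]
  if (isTRUE(config$use_f9_in_classifier)) feats <- FEATURE_NAMES
  setdiff(feats, config$drop_features)
}

stratified_split <- function(labels, train_fraction, seed) {
  with_seed(seed, {
    train <- logical(length(labels))
    for (lv in unique(labels)) {
      idx <- which(labels == lv)
      k <- max(1L, round(train_fraction * length(idx)))
      k <- min(k, length(idx) - 1L)  # keep at least one test sample
      train[sample(idx, k)] <- TRUE
    }
    train
  })
}

#' Run the false-information identification pipeline
#'
#' Executes the full identification flow on a labeled corpus: optional
#' reliable-source selection over a link graph, corpus co-occurrence
#' statistics, nine-feature extraction, a seeded label-stratified
#' train/test split, boosted-tree training, test-set evaluation,
#' classification of every message, the publisher false-history (F9)
#' update, and theta elimination of publishers whose classified-false
#' fraction reached the threshold. The surviving messages are the
#' "effective" corpus feeding the early-warning stage.
#'
#' @param corpus a labeled [epi_corpus()].
#' @param feature_words subject feature-word list for F1.
#' @param pages optional link graph (list of [web_page()]).
#' @param config a [pipeline_config()].
#' @param output_dir optional directory; when given, the filtered
#'   corpus (JSON Lines), model (JSON), feature matrix, metrics and a
#'   run manifest are written there.
#' @return A list of class `identification_report`: `model`,
#'   `accuracy`, `confusion` (2x2 table), `importance` (data frame with
#'   one row per feature F1..F9), `features` (feature matrix),
#'   `predicted` (per-message label), `publishers` (updated table),
#'   `filtered_corpus`, `n_effective`, `reliable_pages`, `config`,
#'   `timings`.
#' @export
run_identification <- function(corpus, feature_words,
                               pages = corpus$pages,
                               config = pipeline_config(),
                               output_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  labels <- vapply(corpus$messages, function(m) m$label %||% NA_character_,
                   "")
  if (!length(labels) || anyNA(labels)) {
    stop_epiwatch("run_identification needs a fully labeled corpus",
                  "epiwatch_config_error")
  }

  reliable <- NULL
  if (!is.null(pages) && length(pages)) {
    M <- build_transfer_matrix(pages)
    scores <- score_pages(M, damping = config$damping, tol = config$tol,
                          max_iter = config$max_iter)
    reliable <- select_reliable(scores, policy = config$reliable_policy,
                                multiplier = config$reliable_multiplier,
                                q = config$reliable_q)
  }

  stats <- corpus_stats(corpus)
  feats <- feature_matrix(corpus, feature_words, stats,
                          smoothing = config$smoothing)
  use <- classifier_feature_names(config)
  x <- as.matrix(feats[, use, drop = FALSE])
  y <- labels

  train <- stratified_split(y, config$train_fraction, config$seed)
  t_train0 <- proc.time()[["elapsed"]]
  model <- do.call(epiboost,
                   c(list(x = x[train, , drop = FALSE], y = y[train]),
                     config$boost))
  t_train1 <- proc.time()[["elapsed"]]
  test_pred <- predict(model, x[!train, , drop = FALSE], type = "class",
                       threshold = config$classify_threshold)
  accuracy <- mean(test_pred == y[!train])
  confusion <- table(truth = factor(y[!train], levels = LABELS),
                     predicted = factor(test_pred, levels = LABELS))

  predicted <- predict(model, x, type = "class",
                       threshold = config$classify_threshold)
  pub <- corpus$publishers
  msg_pub <- vapply(corpus$messages, `[[`, "", "publisher_id")
  for (i in seq_len(nrow(pub))) {
    upd <- update_false_history(as.list(pub[i, ]),
                                predicted[msg_pub == pub$publisher_id[i]])
    pub$false_history_prob[i] <- upd$false_history_prob
  }
  filtered <- corpus
  filtered$publishers <- pub
  # classification filter first, then theta elimination of publishers
  keep <- predicted == "true_info"
  filtered$messages <- filtered$messages[keep]
  filtered <- eliminate_publishers(filtered, theta = config$theta)

  importance <- data.frame(feature = FEATURE_NAMES,
                           gain = unname(model$importance[FEATURE_NAMES]),
                           used = FEATURE_NAMES %in% use,
                           stringsAsFactors = FALSE)
  importance$gain[is.na(importance$gain)] <- 0
  t1 <- proc.time()[["elapsed"]]

  report <- structure(list(
    model = model, accuracy = accuracy, confusion = confusion,
    importance = importance, features = feats, predicted = predicted,
    publishers = pub, filtered_corpus = filtered,
    n_effective = length(filtered$messages),
    reliable_pages = reliable, config = config,
    timings = c(total = t1 - t0, train = t_train1 - t_train0)
  ), class = "identification_report")

  if (!is.null(output_dir)) write_identification(report, output_dir)
  report
}

#' @exportS3Method base::print
print.identification_report <- function(x, ...) {
  cat(sprintf("<identification_report> test accuracy %.3f, %d effective message(s)\n",
              x$accuracy, x$n_effective))
  if (!is.null(x$reliable_pages)) {
    cat(sprintf("  reliable source pages: %d\n", length(x$reliable_pages)))
  }
  if (length(x$config$drop_features)) {
    cat(sprintf("  ablated features: %s\n",
                paste(x$config$drop_features, collapse = ", ")))
  }
  invisible(x)
}

write_identification <- function(report, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(report$filtered_corpus,
               file.path(output_dir, "effective_corpus.jsonl"))
  write_epiboost(report$model, file.path(output_dir, "model.json"))
  utils::write.csv(report$features,
                   file.path(output_dir, "features.csv"), row.names = FALSE)
  utils::write.csv(report$importance,
                   file.path(output_dir, "importance.csv"),
                   row.names = FALSE)
  metrics <- list(accuracy = report$accuracy,
                  confusion = as.list(as.data.frame(report$confusion)),
                  n_effective = report$n_effective,
                  n_reliable = if (is.null(report$reliable_pages)) NULL
                               else length(report$reliable_pages),
                  timings = as.list(report$timings))
  writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(output_dir, "metrics.json"))
  manifest <- list(
    package = "epiwatch",
    package_version = as.character(utils::packageVersion("epiwatch")),
    r_version = as.character(getRversion()),
    seed = report$config$seed,
    config = report$config[setdiff(names(report$config), "boost")],
    boost = report$config$boost,
    config_hash = config_hash(report$config))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE, force = TRUE),
             file.path(output_dir, "manifest.json"))
  invisible(output_dir)
}

config_hash <- function(config) {
  # order-stable digest of the flattened config, dependency-free
  flat <- unlist(config, use.names = TRUE)
  txt <- paste(names(flat), as.character(flat), sep = "=", collapse = ";")
  as.character(sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 977)) %%
                 .Machine$integer.max)
}

#' Run the early-warning stage on a filtered corpus
#'
#' @param corpus the effective [epi_corpus()] (output of
#'   [run_identification()]).
#' @param gazetteer place-to-province table.
#' @param stats optional [corpus_stats()]; defaults to the corpus's own.
#' @param config a [warning_config()].
#' @param output_path optional CSV path for the indicator series.
#' @return The indicator data frame of [compute_indicator_series()].
#' @export
run_warning <- function(corpus, gazetteer, stats = NULL,
                        config = warning_config(), output_path = NULL) {
  if (!length(corpus$messages)) {
    warning("empty filtered corpus: no indicators computed")
    out <- data.frame(date = as.Date(character()), n_messages = integer(),
                      i1_change_rate = numeric(),
                      i2_region_coverage = numeric(),
                      i3_emotional_tendency = numeric(),
                      i4_concentration = numeric(),
                      i5_new_subjects = integer(), c_clusters = integer())
  } else {
    out <- compute_indicator_series(corpus, gazetteer, stats, config)
    und <- sum(is.na(out$i1_change_rate))
    if (und > 0L) {
      message(sprintf("%d window(s) with undefined I1 (no preceding count)",
                      und))
    }
  }
  if (!is.null(output_path)) {
    utils::write.csv(out, output_path, row.names = FALSE)
  }
  out
}

#' Training-fraction sweep comparing the full and ablated models
#'
#' Re-runs identification at each training fraction for the full
#' feature set and for the model without the ablated features (default:
#' subject relevance F1 and the regulatory feature F9), recording test
#' accuracy. Optionally benchmarks established baseline classifiers
#' (logistic regression via `glm`) for context; baselines are library
#' calls, not part of the contribution.
#'
#' @param corpus a labeled [epi_corpus()].
#' @param feature_words subject feature words.
#' @param fractions training fractions to sweep.
#' @param drop_features features removed in the ablated model.
#' @param config base [pipeline_config()]; its `train_fraction` is
#'   overridden per sweep point.
#' @param include_baselines logical, add a logistic-regression baseline.
#' @return Long data frame with columns `train_fraction`, `model`,
#'   `accuracy`.
#' @export
run_ablation <- function(corpus, feature_words,
                         fractions = seq(0.1, 0.8, by = 0.1),
                         drop_features = c("f1_subject_relevance",
                                           "f9_false_history"),
                         config = pipeline_config(),
                         include_baselines = FALSE) {
  stats <- corpus_stats(corpus)
  feats <- feature_matrix(corpus, feature_words, stats,
                          smoothing = config$smoothing)
  y <- feats$label
  rows <- list()
  for (fr in fractions) {
    train <- stratified_split(y, fr, config$seed)
    for (variant in c("full", "ablated")) {
      cfg <- config
      cfg$drop_features <- if (variant == "ablated") drop_features
                           else character()
      use <- classifier_feature_names(cfg)
      x <- as.matrix(feats[, use, drop = FALSE])
      model <- do.call(epiboost, c(list(x = x[train, , drop = FALSE],
                                        y = y[train]), config$boost))
      pred <- predict(model, x[!train, , drop = FALSE], type = "class",
                      threshold = config$classify_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        train_fraction = fr, model = variant,
        accuracy = mean(pred == y[!train]), stringsAsFactors = FALSE)
    }
    if (include_baselines) {
      use <- classifier_feature_names(config)
      df <- feats[, use, drop = FALSE]
      df$.y <- as.integer(y == "false_info")
      fit <- stats::glm(.y ~ ., data = df[train, , drop = FALSE],
                        family = stats::binomial())
      p <- stats::predict(fit, newdata = df[!train, , drop = FALSE],
                          type = "response")
      rows[[length(rows) + 1L]] <- data.frame(
        train_fraction = fr, model = "logistic_baseline",
        accuracy = mean(classify(p, config$classify_threshold) ==
                          y[!train]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
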