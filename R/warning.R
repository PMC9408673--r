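# Public-opinion early-warning indicators over daily message windows.
# Two macro indicators -- quantity change rate and regional coverage --
# and three micro indicators -- emotional tendency, subject
# concentration and new-subject count -- are computed per calendar day
# from the filtered ("effective") epidemic messages.

#' Configuration of the early-warning stage
#'
#' @param tau similarity cut in \[0, 1\] for the adaptive subject
#'   clustering (clusters merge while linkage similarity >= `tau`).
#' @param tau_new relevance threshold below which a current-window
#'   cluster counts as a new subject; defaults to `tau`.
#' @param total_provinces number of provincial administrative regions P
#'   dividing the regional coverage; default 34.
#' @param smoothing additive PMI smoothing passed to [pmi_matrix()].
#' @return A list of class `warning_config`.
#' @export
warning_config <- function(tau = 0.5, tau_new = tau, total_provinces = 34L,
                           smoothing = 0) {
  assert_prob(tau, "tau")
  assert_prob(tau_new, "tau_new")
  assert_scalar_number(total_provinces, "total_provinces", lower = 1)
  structure(list(tau = tau, tau_new = tau_new,
                 total_provinces = as.integer(total_provinces),
                 smoothing = smoothing), class = "warning_config")
}

#' Quantity change rate of epidemic information (I1)
#'
#' `Qr = (l2 - l1) / l1` between two adjacent unit-time windows. With
#' `l1 = 0` the rate is undefined and `NA` is returned (flagged, never
#' an error).
#'
#' @param l1 message count of the earlier window.
#' @param l2 message count of the later window.
#' @return The change rate, or `NA` when `l1 = 0`.
#' @export
i1_change_rate <- function(l1, l2) {
  if (is.na(l1) || l1 == 0) return(NA_real_)
  (l2 - l1) / l1
}

#' Regional coverage rate of epidemic information (I2)
#'
#' Place mentions across the window's messages are mapped to provincial
#' administrative regions through a gazetteer; the coverage `Ac` is the
#' number of distinct provinces hit divided by the total number of
#' provinces P. Unmapped places are ignored with a warning.
#'
#' @param messages list of message records of one window.
#' @param gazetteer data frame with columns `place`, `province`.
#' @param total_provinces number of provinces P (> 0).
#' @return Coverage in \[0, 1\].
#' @export
i2_region_coverage <- function(messages, gazetteer, total_provinces = 34L) {
  if (is.null(gazetteer) || !nrow(gazetteer)) {
    stop_epiwatch("`gazetteer` must be a nonempty place->province table",
                  "epiwatch_parameter_error")
  }
  assert_scalar_number(total_provinces, "total_provinces", lower = 1)
  places <- unlist(lapply(messages, `[[`, "places"), use.names = FALSE)
  if (!length(places)) return(0)
  prov <- gazetteer$province[match(places, gazetteer$place)]
  if (anyNA(prov)) {
    warning(sprintf("%d place mention(s) not in gazetteer, ignored",
                    sum(is.na(prov))))
    prov <- prov[!is.na(prov)]
  }
  length(unique(prov)) / total_provinces
}

#' Emotional tendency of epidemic information (I3)
#'
#' The average emotional intensity (F5) over the n effective messages of
#' the window: `Et = (1/n) * sum_i P_i / (P_i + R_i)`, lying in (0, 1)
#' for intensities in (0, 1).
#'
#' @param intensities per-message emotional intensities.
#' @return The mean intensity, or `NA` for an empty window.
#' @export
i3_emotional_tendency <- function(intensities) {
  if (!length(intensities)) return(NA_real_)
  mean(intensities)
}

#' Subject matrix of a message window
#'
#' One row (noun list) per message: the subjects each message talks
#' about, in message order.
#'
#' @param messages list of message records.
#' @return List of character vectors (ragged rows).
#' @export
subject_matrix <- function(messages) lapply(messages, message_nouns)

# mean non-negative PMI between two noun lists
subject_relevance <- function(a, b, stats, smoothing = 0) {
  if (!length(a) || !length(b)) return(0)
  pm <- pmi_matrix(a, b, stats, smoothing)
  pm[!is.finite(pm) | pm < 0] <- 0
  mean(pm)
}

# self-normalized relevance in [0, 1]: r(A,B) / sqrt(r(A,A) r(B,B)).
# Invariant to the overall PMI scale, 1 for identical noun lists with
# positive self-relevance, 0 when either side has none.
normalized_relevance <- function(a, b, stats, smoothing = 0) {
  raa <- subject_relevance(a, a, stats, smoothing)
  rbb <- subject_relevance(b, b, stats, smoothing)
  if (raa <= 0 || rbb <= 0) return(0)
  min(1, subject_relevance(a, b, stats, smoothing) / sqrt(raa * rbb))
}

#' Adaptive clustering of a window's subjects
#'
#' Pairwise message relevance is the mean non-negative PMI between noun
#' lists, normalized by the geometric mean of the two self-relevances so
#' it is comparable across windows. Average-linkage agglomerative
#' clustering merges while the linkage similarity is at least `tau`; the
#' number of clusters c emerges from the data rather than being preset.
#'
#' @param subjects a [subject_matrix()] (list of noun vectors), n >= 1.
#' @param stats [corpus_stats()] for PMI.
#' @param tau similarity cut in \[0, 1\].
#' @param smoothing additive PMI smoothing.
#' @return A list of class `subject_clustering`: `assignments` (integer
#'   cluster id per message), `c` (cluster count), `representatives`
#'   (per-cluster combined noun multiset).
#' @export
cluster_subjects <- function(subjects, stats, tau = 0.5, smoothing = 0) {
  assert_prob(tau, "tau")
  n <- length(subjects)
  if (n == 0L) {
    return(structure(list(assignments = integer(), c = 0L,
                          representatives = list()),
                     class = "subject_clustering"))
  }
  if (n == 1L) {
    return(structure(list(assignments = 1L, c = 1L,
                          representatives = list(subjects[[1L]])),
                     class = "subject_clustering"))
  }
  sim <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      sim[i, j] <- sim[j, i] <-
        normalized_relevance(subjects[[i]], subjects[[j]], stats, smoothing)
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  assignments <- stats::cutree(hc, h = 1 - tau)
  reps <- lapply(seq_len(max(assignments)), function(k)
    unlist(subjects[assignments == k], use.names = FALSE))
  structure(list(assignments = unname(assignments),
                 c = max(assignments), representatives = reps),
            class = "subject_clustering")
}

#' @exportS3Method base::print
print.subject_clustering <- function(x, ...) {
  cat(sprintf("<subject_clustering> %d message(s) in %d cluster(s)\n",
              length(x$assignments), x$c))
  invisible(x)
}

#' Subject concentration of epidemic information (I4)
#'
#' `Tc = n / c`: messages per subject cluster. The fewer the clusters,
#' the more public attention concentrates on few subjects.
#'
#' @param n number of messages in the window.
#' @param c number of subject clusters (>= 1, <= n).
#' @return Concentration >= 1.
#' @export
i4_concentration <- function(n, c) {
  if (c < 1) {
    stop_epiwatch("cluster count c must be >= 1", "epiwatch_parameter_error")
  }
  n / c
}

#' New-subject count of epidemic information (I5)
#'
#' A current-window cluster is a new subject when its relevance (mean
#' non-negative PMI, self-normalized) to every previous-window cluster
#' falls below `tau_new`. All current clusters count as new when the
#' previous window had none.
#'
#' @param current current-window [cluster_subjects()] result.
#' @param previous previous-window clustering (may have `c = 0`).
#' @param stats [corpus_stats()] for PMI.
#' @param tau_new relevance threshold in \[0, 1\].
#' @param smoothing additive PMI smoothing.
#' @return Integer count of new subject clusters.
#' @export
i5_new_subjects <- function(current, previous, stats, tau_new = 0.5,
                            smoothing = 0) {
  assert_prob(tau_new, "tau_new")
  if (current$c == 0L) return(0L)
  if (is.null(previous) || previous$c == 0L) return(current$c)
  new_count <- 0L
  for (rep_cur in current$representatives) {
    rel <- vapply(previous$representatives, function(rep_prev)
      normalized_relevance(rep_cur, rep_prev, stats, smoothing), numeric(1))
    if (max(rel) < tau_new) new_count <- new_count + 1L
  }
  new_count
}

#' Compute the five-indicator early-warning series
#'
#' Splits a corpus into calendar-day windows spanning its date range and
#' computes one indicator record per day: I1 quantity change rate
#' (undefined on the first window), I2 regional coverage, I3 emotional
#' tendency, I4 subject concentration from adaptive PMI clustering, and
#' I5 new-subject count against the previous day's clusters. Results
#' are independent of message order within a window.
#'
#' @param corpus an [epi_corpus()] of effective (filtered) messages.
#' @param gazetteer data frame with columns `place`, `province`.
#' @param stats [corpus_stats()]; defaults to statistics of `corpus`.
#' @param config a [warning_config()].
#' @return A data frame with columns `date`, `n_messages`, `i1_change_rate`,
#'   `i2_region_coverage`, `i3_emotional_tendency`, `i4_concentration`,
#'   `i5_new_subjects` and `c_clusters`. Undefined indicators are `NA`.
#' @export
compute_indicator_series <- function(corpus, gazetteer, stats = NULL,
                                     config = warning_config()) {
  if (!length(corpus$messages)) {
    stop_epiwatch("corpus has no messages", "epiwatch_validation_error")
  }
  if (is.null(stats)) stats <- corpus_stats(corpus)
  dates <- as.Date(vapply(corpus$messages,
                          function(m) as.character(m$timestamp), ""))
  days <- seq(min(dates), max(dates), by = "day")
  prev_clust <- NULL
  prev_n <- NA_integer_
  rows <- vector("list", length(days))
  for (k in seq_along(days)) {
    msgs <- corpus$messages[dates == days[k]]
    n <- length(msgs)
    if (n > 0L) {
      clust <- cluster_subjects(subject_matrix(msgs), stats,
                                tau = config$tau,
                                smoothing = config$smoothing)
      i3 <- i3_emotional_tendency(
        vapply(msgs, f5_emotional_intensity, numeric(1)))
      i2 <- i2_region_coverage(msgs, gazetteer, config$total_provinces)
      i4 <- i4_concentration(n, clust$c)
      i5 <- i5_new_subjects(clust, prev_clust, stats,
                            tau_new = config$tau_new,
                            smoothing = config$smoothing)
      cc <- clust$c
    } else {
      clust <- NULL
      i2 <- 0; i3 <- NA_real_; i4 <- NA_real_; i5 <- NA_integer_
      cc <- 0L
    }
    rows[[k]] <- data.frame(
      date = days[k], n_messages = n,
      i1_change_rate = i1_change_rate(prev_n, n),
      i2_region_coverage = i2, i3_emotional_tendency = i3,
      i4_concentration = i4, i5_new_subjects = i5, c_clusters = cc)
    prev_clust <- clust
    prev_n <- n
  }
  do.call(rbind, rows)
}
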