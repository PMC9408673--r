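# Reliable-source identification by link analysis. A column-stochastic
# transfer matrix records the in/out links of a page set; a damped
# power iteration over it scores every page and a selection policy keeps
# the reliable ones.

#' Build the column-stochastic transfer matrix of a link graph
#'
#' Entry (i, j) is 1/outdegree(j) when page j links to page i and 0
#' otherwise, so every nonzero column holds equal entries summing to 1;
#' a page with ten out-links contributes ten entries of 1/10. Pages with
#' no out-links yield an all-zero column. Self-links and duplicate links
#' are removed on page construction; out-links pointing outside the page
#' set are dropped with a warning.
#'
#' @param pages list of [web_page()] records with unique ids.
#' @return A sparse `dgCMatrix` of dimension N x N with rows/columns in
#'   page order, dimnames set to the page ids.
#' @export
build_transfer_matrix <- function(pages) {
  ids <- vapply(pages, `[[`, integer(1), "page_id")
  if (anyDuplicated(ids)) {
    stop_epiwatch("duplicate page_id in link graph",
                  "epiwatch_validation_error")
  }
  n <- length(ids)
  idx <- seq_len(n)
  names(idx) <- as.character(ids)
  from <- integer(); to <- integer(); val <- numeric()
  dropped <- 0L
  for (j in seq_len(n)) {
    links <- setdiff(unique(pages[[j]]$out_links), ids[j])
    known <- links[as.character(links) %in% names(idx)]
    dropped <- dropped + (length(links) - length(known))
    if (length(known)) {
      from <- c(from, idx[as.character(known)])
      to <- c(to, rep.int(j, length(known)))
      val <- c(val, rep.int(1 / length(known), length(known)))
    }
  }
  if (dropped > 0L) {
    warning(sprintf("dropped %d out-link(s) to unknown pages", dropped))
  }
  Matrix::sparseMatrix(i = from, j = to, x = val, dims = c(n, n),
                       dimnames = list(as.character(ids), as.character(ids)))
}

#' Score pages by damped power iteration over the transfer matrix
#'
#' Computes the stationary distribution of the damped random surfer:
#' with probability `damping` follow a uniformly chosen out-link (mass on
#' pages without out-links is redistributed uniformly), otherwise
#' teleport to a uniform page. Iterates `s <- damping * (M s + z) +
#' (1 - damping)/N` until the L1 change drops below `tol` or `max_iter`
#' is reached. Scores are a probability vector at every iteration.
#'
#' @param M transfer matrix from [build_transfer_matrix()].
#' @param damping damping factor in (0, 1).
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap.
#' @return A list of class `reliability_scores`: `scores` (named numeric,
#'   sums to 1), `converged`, `iterations`.
#' @export
score_pages <- function(M, damping = 0.85, tol = 1e-10, max_iter = 1000L) {
  if (!is.numeric(damping) || length(damping) != 1L || is.na(damping) ||
      damping <= 0 || damping >= 1) {
    stop_epiwatch("`damping` must lie strictly inside (0, 1)",
                  "epiwatch_parameter_error")
  }
  assert_scalar_number(tol, "tol", lower = 0, open_lower = TRUE)
  n <- nrow(M)
  if (n == 0L) {
    return(structure(list(scores = numeric(), converged = TRUE,
                          iterations = 0L), class = "reliability_scores"))
  }
  dangling <- Matrix::colSums(M) == 0
  s <- rep(1 / n, n)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    dangle_mass <- sum(s[dangling])
    s_new <- damping * (as.numeric(M %*% s) + dangle_mass / n) +
      (1 - damping) / n
    delta <- sum(abs(s_new - s))
    s <- s_new
    if (delta < tol) { converged <- TRUE; break }
  }
  names(s) <- rownames(M)
  structure(list(scores = s, converged = converged, iterations = it),
            class = "reliability_scores")
}

#' @exportS3Method base::print
print.reliability_scores <- function(x, ...) {
  cat(sprintf("<reliability_scores> %d pages, %s after %d iteration(s)\n",
              length(x$scores),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  invisible(x)
}

#' Select reliable source pages from reliability scores
#'
#' The selection rule behind the published page counts is not fixed by
#' the scoring model, so two policies are offered. `"baseline"` keeps
#' pages scoring at least `multiplier` times the uniform baseline 1/N
#' (default multiplier 1); `"top_fraction"` keeps the `q` highest-scoring
#' pages.
#'
#' @param scores a `reliability_scores` object.
#' @param policy `"baseline"` or `"top_fraction"`.
#' @param multiplier baseline multiplier for the `"baseline"` policy.
#' @param q fraction in (0, 1] kept by the `"top_fraction"` policy.
#' @return Integer vector of selected page ids.
#' @export
select_reliable <- function(scores, policy = c("baseline", "top_fraction"),
                            multiplier = 1.0, q = 0.5) {
  policy <- match.arg(policy)
  s <- scores$scores
  if (!length(s)) return(integer())
  ids <- as.integer(names(s))
  if (policy == "baseline") {
    # small relative slack so an exactly-uniform score is never lost to
    # floating-point rounding of the threshold
    keep <- s >= multiplier / length(s) * (1 - 1e-9)
    ids[keep]
  } else {
    assert_scalar_number(q, "q", lower = 0, upper = 1, open_lower = TRUE)
    k <- max(1L, floor(q * length(s)))
    ids[order(s, decreasing = TRUE)[seq_len(k)]]
  }
}
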