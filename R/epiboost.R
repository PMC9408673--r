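# Second-order gradient-boosted decision trees, implemented from first
# principles. Each boosting round fits a regression tree to the
# per-sample gradients g and hessians h of the logistic loss at the
# current margin; the regularized objective per round is
#   sum_i l(y_i, yhat_i) + sum_t [ gamma * T_t + (lambda/2) * sum_j w_tj^2 ]
# and each leaf takes the closed-form optimal weight -G/(H + lambda).
# Split search is exact greedy over all features with midpoint
# thresholds; ties at a threshold route left.

#' Gradient and hessian of the logistic loss
#'
#' For the binary logistic loss at margin m with p = sigmoid(m):
#' g = p - y and h = p (1 - p). Both derivatives are taken with respect
#' to the margin of the previous boosting iteration.
#'
#' @param label 0/1 vector (1 = positive class).
#' @param margin numeric vector of current raw margins.
#' @return List with numeric vectors `g` and `h`.
#' @export
logistic_grad_hess <- function(label, margin) {
  p <- sigmoid(margin)
  list(g = p - label, h = p * (1 - p))
}

#' Closed-form optimal leaf weight
#'
#' Minimizing the per-leaf quadratic G w + (H + lambda) w^2 / 2 gives
#' w* = -G / (H + lambda).
#'
#' @param G sum of gradients routed to the leaf.
#' @param H sum of hessians routed to the leaf.
#' @param lambda_reg L2 regularization on leaf weights, with
#'   `H + lambda_reg > 0`.
#' @return The optimal weight.
#' @export
leaf_weight <- function(G, H, lambda_reg) {
  if (any(H + lambda_reg <= 0)) {
    stop_epiwatch("leaf_weight requires H + lambda_reg > 0",
                  "epiwatch_parameter_error")
  }
  -G / (H + lambda_reg)
}

#' Exact greedy split search
#'
#' Scans every feature and every midpoint between consecutive distinct
#' values; the structure-score gain of a candidate split is
#' `0.5 * (GL^2/(HL+lambda) + GR^2/(HR+lambda) - (GL+GR)^2/(HL+HR+lambda))
#' - gamma`. Returns `NULL` when no split has positive gain (or fewer
#' than two samples are given).
#'
#' @param x numeric feature matrix of the node's samples.
#' @param g,h gradient and hessian vectors.
#' @param lambda_reg L2 leaf regularization.
#' @param gamma_reg per-leaf complexity penalty subtracted from the gain.
#' @param min_child_hessian minimum hessian sum required on each side.
#' @return `NULL`, or a list `feature`, `threshold`, `gain`,
#'   `left_index` (logical vector, TRUE routes left).
#' @export
best_split <- function(x, g, h, lambda_reg = 1, gamma_reg = 0,
                       min_child_hessian = 0) {
  n <- nrow(x)
  if (is.null(n) || n < 2L) return(NULL)
  G <- sum(g); H <- sum(h)
  parent_score <- G^2 / (H + lambda_reg)
  best <- NULL
  for (j in seq_len(ncol(x))) {
    ord <- order(x[, j])
    xs <- x[ord, j]
    cuts <- which(diff(xs) > 0)
    if (!length(cuts)) next
    GL <- cumsum(g[ord])[cuts]
    HL <- cumsum(h[ord])[cuts]
    ok <- HL >= min_child_hessian & (H - HL) >= min_child_hessian
    if (!any(ok)) next
    gain <- 0.5 * (GL^2 / (HL + lambda_reg) +
                   (G - GL)^2 / (H - HL + lambda_reg) -
                   parent_score) - gamma_reg
    gain[!ok] <- -Inf
    k <- which.max(gain)
    if (gain[k] > 0 && (is.null(best) || gain[k] > best$gain)) {
      thr <- (xs[cuts[k]] + xs[cuts[k] + 1L]) / 2
      best <- list(feature = j, threshold = thr, gain = gain[k],
                   left_index = x[, j] <= thr)
    }
  }
  best
}

fit_tree <- function(x, g, h, depth, lambda_reg, gamma_reg,
                     min_child_hessian, gain_acc) {
  if (depth > 0L) {
    sp <- best_split(x, g, h, lambda_reg, gamma_reg, min_child_hessian)
    if (!is.null(sp)) {
      gain_acc[sp$feature] <- gain_acc[sp$feature] + sp$gain
      li <- sp$left_index
      left <- fit_tree(x[li, , drop = FALSE], g[li], h[li], depth - 1L,
                       lambda_reg, gamma_reg, min_child_hessian, gain_acc)
      right <- fit_tree(x[!li, , drop = FALSE], g[!li], h[!li], depth - 1L,
                        lambda_reg, gamma_reg, min_child_hessian,
                        left$gain_acc)
      return(list(node = list(feature = sp$feature,
                              threshold = sp$threshold,
                              left = left$node, right = right$node),
                  gain_acc = right$gain_acc))
    }
  }
  list(node = list(leaf = leaf_weight(sum(g), sum(h), lambda_reg)),
       gain_acc = gain_acc)
}

predict_tree <- function(node, x) {
  out <- numeric(nrow(x))
  route <- function(nd, idx) {
    if (!length(idx)) return()
    if (!is.null(nd$leaf)) {
      out[idx] <<- nd$leaf
    } else {
      left <- x[idx, nd$feature] <= nd$threshold
      route(nd$left, idx[left])
      route(nd$right, idx[!left])
    }
  }
  route(node, seq_len(nrow(x)))
  out
}

tree_leaves <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  c(tree_leaves(node$left), tree_leaves(node$right))
}

model_penalty <- function(trees, lambda_reg, gamma_reg) {
  sum(vapply(trees, function(tr) {
    w <- tree_leaves(tr)
    gamma_reg * length(w) + 0.5 * lambda_reg * sum(w^2)
  }, numeric(1)))
}

#' Fit a boosted-tree false-information classifier
#'
#' Trains an additive model of regression trees by second-order gradient
#' boosting on the binary logistic loss: round t fits a tree to the
#' gradients and hessians of the loss at the margin of round t - 1, each
#' leaf takes the closed-form weight -G/(H + lambda) scaled by the
#' learning rate, and splits maximize the regularized structure-score
#' gain. The regularized objective (training log-loss plus
#' `gamma_reg * #leaves + lambda_reg/2 * sum of squared leaf weights`)
#' is tracked per round.
#'
#' @param x numeric feature matrix (or data frame of numeric columns),
#'   one row per sample; or a formula (see
#'   \code{\link{epiboost.formula}}).
#' @param y labels: a 0/1 vector, logical, or factor/character with
#'   values `true_info`/`false_info` (`false_info` is the positive
#'   class). Both classes must be present.
#' @param n_rounds number of boosting rounds (trees).
#' @param learning_rate shrinkage eta in (0, 1] applied to leaf weights.
#' @param max_depth maximum tree depth (1 = a single split).
#' @param lambda_reg L2 regularization lambda on leaf weights.
#' @param gamma_reg per-leaf penalty gamma pruning low-gain splits.
#' @param min_child_hessian minimum hessian sum per child.
#' @param base_score initial probability; default is the empirical
#'   positive rate. The model margin starts at `logit(base_score)`.
#' @param ... unused.
#' @return An object of class `epiboost`: list with `trees`,
#'   `base_margin`, `config`, `importance` (total split gain per
#'   feature), `objective` (per-round regularized objective,
#'   element 1 = before any tree), `feature_names`, `n_samples`.
#' @examples
#' x <- matrix(c(1:8, rep(0, 8)), ncol = 2)
#' y <- rep(c(0, 1), each = 4)
#' fit <- epiboost(x, y, n_rounds = 5, max_depth = 1)
#' predict(fit, x)
#' @export
epiboost <- function(x, ...) UseMethod("epiboost")

#' @rdname epiboost
#' @export
epiboost.default <- function(x, y, n_rounds = 50L, learning_rate = 0.3,
                             max_depth = 3L, lambda_reg = 1,
                             gamma_reg = 0, min_child_hessian = 0,
                             base_score = NULL, ...) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- encode_labels(y)
  if (length(y) != nrow(x)) {
    stop_epiwatch("length(y) must equal nrow(x)", "epiwatch_parameter_error")
  }
  if (nrow(x) < 2L || length(unique(y)) < 2L) {
    stop_epiwatch("training needs >= 2 samples with both classes present",
                  "epiwatch_training_error")
  }
  assert_scalar_number(learning_rate, "learning_rate", lower = 0, upper = 1,
                       open_lower = TRUE)
  assert_scalar_number(lambda_reg, "lambda_reg", lower = 0)
  assert_scalar_number(gamma_reg, "gamma_reg", lower = 0)
  assert_scalar_number(min_child_hessian, "min_child_hessian", lower = 0)
  if (max_depth < 1L) {
    stop_epiwatch("max_depth must be >= 1", "epiwatch_parameter_error")
  }
  if (is.null(base_score)) base_score <- mean(y)
  assert_scalar_number(base_score, "base_score", lower = 0, upper = 1,
                       open_lower = TRUE, open_upper = TRUE)
  base_margin <- logit(base_score)
  feature_names <- colnames(x) %||% paste0("x", seq_len(ncol(x)))

  margin <- rep(base_margin, nrow(x))
  trees <- vector("list", n_rounds)
  gain_acc <- numeric(ncol(x))
  objective <- numeric(n_rounds + 1L)
  objective[1L] <- logloss(y, margin)
  for (t in seq_len(n_rounds)) {
    gh <- logistic_grad_hess(y, margin)
    fitted <- fit_tree(x, gh$g, gh$h, depth = max_depth,
                       lambda_reg = lambda_reg, gamma_reg = gamma_reg,
                       min_child_hessian = min_child_hessian,
                       gain_acc = gain_acc)
    gain_acc <- fitted$gain_acc
    tree <- shrink_tree(fitted$node, learning_rate)
    trees[[t]] <- tree
    margin <- margin + predict_tree(tree, x)
    objective[t + 1L] <- logloss(y, margin) +
      model_penalty(trees[seq_len(t)], lambda_reg, gamma_reg)
  }
  names(gain_acc) <- feature_names
  structure(list(
    trees = trees, base_margin = base_margin,
    config = list(n_rounds = as.integer(n_rounds),
                  learning_rate = learning_rate,
                  max_depth = as.integer(max_depth),
                  lambda_reg = lambda_reg, gamma_reg = gamma_reg,
                  min_child_hessian = min_child_hessian,
                  base_score = base_score),
    importance = gain_acc, objective = objective,
    feature_names = feature_names, n_samples = nrow(x)
  ), class = "epiboost")
}

#' @rdname epiboost
#' @param formula model formula, e.g. `label ~ .`; the response is the
#'   class label.
#' @param data data frame holding the features and response.
#' @export
epiboost.formula <- function(x, data, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  xm <- as.matrix(mf[, -1L, drop = FALSE])
  fit <- epiboost.default(xm, y, ...)
  fit$formula <- x
  fit
}

encode_labels <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), LABELS)
    if (length(bad)) {
      stop_epiwatch(sprintf("unknown label(s): %s", paste(bad, collapse = ", ")),
                    "epiwatch_parameter_error")
    }
    return(as.integer(y == "false_info"))
  }
  if (is.logical(y)) return(as.integer(y))
  if (!all(y %in% c(0, 1))) {
    stop_epiwatch("numeric labels must be 0/1", "epiwatch_parameter_error")
  }
  as.integer(y)
}

logloss <- function(y, margin) {
  # stable sum of log(1 + exp(-z)) with z the margin toward the true class
  z <- margin * (2 * y - 1)
  sum(pmax(-z, 0) + log1p(exp(-abs(z))))
}

shrink_tree <- function(node, eta) {
  if (!is.null(node$leaf)) return(list(leaf = eta * node$leaf))
  list(feature = node$feature, threshold = node$threshold,
       left = shrink_tree(node$left, eta), right = shrink_tree(node$right, eta))
}

#' Predict from a fitted boosted-tree classifier
#'
#' @param object an [epiboost()] fit.
#' @param newdata numeric matrix or data frame with the training feature
#'   columns.
#' @param type `"prob"` (probability of the positive class,
#'   `false_info`), `"margin"` (raw additive score) or `"class"`
#'   (labels at `threshold`).
#' @param threshold classification threshold in (0, 1), a probability at
#'   or above it classifies as `false_info`.
#' @param ... unused.
#' @return Numeric vector, or character labels for `type = "class"`.
#' @export
predict.epiboost <- function(object, newdata, type = c("prob", "margin",
                                                       "class"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    have <- intersect(object$feature_names, colnames(newdata))
    if (length(have) == length(object$feature_names)) {
      newdata <- newdata[, object$feature_names, drop = FALSE]
    }
  }
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != length(object$feature_names)) {
    stop_epiwatch(sprintf("newdata has %d feature column(s), model expects %d",
                          ncol(x), length(object$feature_names)),
                  "epiwatch_parameter_error")
  }
  margin <- rep(object$base_margin, nrow(x))
  for (tr in object$trees) margin <- margin + predict_tree(tr, x)
  switch(type,
         margin = margin,
         prob = sigmoid(margin),
         class = classify(sigmoid(margin), threshold))
}

#' Map falsity probabilities to labels
#'
#' @param probabilities probabilities of falsity in \[0, 1\].
#' @param threshold decision threshold, strictly inside (0, 1); a
#'   probability equal to the threshold classifies as false.
#' @return Character vector of `"true_info"` / `"false_info"`.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold >= 1) {
    stop_epiwatch("`threshold` must lie strictly inside (0, 1)",
                  "epiwatch_parameter_error")
  }
  ifelse(probabilities >= threshold, "false_info", "true_info")
}

#' @exportS3Method base::print
print.epiboost <- function(x, ...) {
  cat(sprintf("<epiboost> %d tree(s), depth <= %d, eta = %g, lambda = %g, gamma = %g\n",
              length(x$trees), x$config$max_depth, x$config$learning_rate,
              x$config$lambda_reg, x$config$gamma_reg))
  cat(sprintf("  trained on %d samples, %d features; final objective %.6g\n",
              x$n_samples, length(x$feature_names),
              x$objective[length(x$objective)]))
  invisible(x)
}

#' @exportS3Method base::summary
summary.epiboost <- function(object, ...) {
  imp <- sort(object$importance, decreasing = TRUE)
  structure(list(fit = object, importance = imp), class = "summary.epiboost")
}

#' @exportS3Method base::print
print.summary.epiboost <- function(x, ...) {
  print(x$fit)
  cat("Feature importance (total split gain):\n")
  imp <- data.frame(feature = names(x$importance),
                    gain = unname(x$importance))
  print(imp, row.names = FALSE)
  invisible(x)
}

#' @export
plot.epiboost <- function(x, ...) {
  imp <- sort(x$importance, decreasing = FALSE)
  graphics::barplot(imp, horiz = TRUE, las = 1,
                    xlab = "total split gain",
                    main = "Feature importance", ...)
  invisible(x)
}

#' Serialize a fitted classifier to a versioned JSON document
#' @param model an [epiboost()] fit.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epiboost <- function(model, path) {
  doc <- list(format = "epiboost", version = 1L,
              base_margin = model$base_margin, config = model$config,
              feature_names = model$feature_names,
              importance = as.list(model$importance),
              objective = model$objective, n_samples = model$n_samples,
              trees = model$trees)
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                              null = "null"), path, useBytes = TRUE)
  invisible(path)
}

#' Read a serialized classifier back
#' @param path path written by [write_epiboost()].
#' @return An [epiboost()] object.
#' @export
read_epiboost <- function(path) {
  doc <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = FALSE)
  if (!identical(doc$format, "epiboost")) {
    stop_epiwatch("not an epiboost model file", "epiwatch_parse_error")
  }
  fix_tree <- function(nd) {
    if (!is.null(nd$leaf)) return(list(leaf = as.numeric(nd$leaf)))
    list(feature = as.integer(nd$feature),
         threshold = as.numeric(nd$threshold),
         left = fix_tree(nd$left), right = fix_tree(nd$right))
  }
  structure(list(
    trees = lapply(doc$trees, fix_tree),
    base_margin = as.numeric(doc$base_margin),
    config = doc$config,
    importance = stats::setNames(as.numeric(unlist(doc$importance)),
                                 names(doc$importance)),
    objective = as.numeric(unlist(doc$objective)),
    feature_names = unlist(doc$feature_names),
    n_samples = as.integer(doc$n_samples)
  ), class = "epiboost")
}
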