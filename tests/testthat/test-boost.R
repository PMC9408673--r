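test_that("logistic gradient and hessian match the hand derivatives", {
  gh <- logistic_grad_hess(1, 0)
  expect_equal(gh$g, -0.5)
  expect_equal(gh$h, 0.25)
  gh0 <- logistic_grad_hess(0, 0)
  expect_equal(gh0$g, 0.5)
  expect_equal(gh0$h, 0.25)

  set.seed(1)
  m <- rnorm(100, sd = 4)
  h <- logistic_grad_hess(rbinom(100, 1, 0.5), m)$h
  expect_true(all(h > 0 & h <= 0.25))
})

test_that("leaf weights minimize the per-leaf quadratic", {
  expect_equal(leaf_weight(2, 3, 1), -0.5)
  expect_equal(leaf_weight(0, 5, 1), 0)
  expect_lt(abs(leaf_weight(2, 3, 1e9)), 1e-8)  # shrinkage limit
  expect_error(leaf_weight(1, -2, 1), class = "epiwatch_parameter_error")
})

test_that("best_split separates two samples with opposite gradients", {
  x <- matrix(c(0, 1), ncol = 1)
  sp <- best_split(x, g = c(-0.5, 0.5), h = c(0.25, 0.25))
  expect_equal(sp$feature, 1)
  expect_equal(sp$threshold, 0.5)
  expect_equal(sp$left_index, c(TRUE, FALSE))
})

test_that("best_split returns none under heavy pruning or constant features", {
  x <- matrix(c(0, 1), ncol = 1)
  expect_null(best_split(x, c(-0.5, 0.5), c(0.25, 0.25), gamma_reg = 100))
  expect_null(best_split(matrix(c(1, 1, 1), ncol = 1),
                         c(-1, 0, 1), rep(0.25, 3)))
  expect_null(best_split(matrix(1, 1, 1), 1, 1))
})

test_that("best_split agrees with exhaustive enumeration of candidates", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 12
    x <- matrix(rnorm(n * 3), n, 3)
    g <- rnorm(n); h <- runif(n, 0.05, 0.25)
    lambda <- 1; gamma <- 0.01
    # brute force: every feature, every midpoint
    best_gain <- -Inf
    for (j in 1:3) {
      xs <- sort(unique(x[, j]))
      for (k in seq_len(length(xs) - 1)) {
        thr <- (xs[k] + xs[k + 1]) / 2
        L <- x[, j] <= thr
        gain <- 0.5 * (sum(g[L])^2 / (sum(h[L]) + lambda) +
                       sum(g[!L])^2 / (sum(h[!L]) + lambda) -
                       sum(g)^2 / (sum(h) + lambda)) - gamma
        best_gain <- max(best_gain, gain)
      }
    }
    sp <- best_split(x, g, h, lambda_reg = lambda, gamma_reg = gamma)
    if (best_gain <= 0) {
      expect_null(sp)
    } else {
      expect_equal(sp$gain, best_gain, tolerance = 1e-12)
    }
  }
})

test_that("a separable toy set is fit to training accuracy 1", {
  toy <- separable_toy()
  fit <- epiboost(toy$x, toy$y, n_rounds = 10, max_depth = 2)
  pred <- predict(fit, toy$x, type = "class")
  expect_equal(mean((pred == "false_info") == (toy$y == 1)), 1)
  # probabilities sit on the correct side of 0.5
  p <- predict(fit, toy$x, type = "prob")
  expect_true(all((p >= 0.5) == (toy$y == 1)))
})

test_that("zero rounds predict the base rate everywhere", {
  toy <- separable_toy()
  fit <- epiboost(toy$x, toy$y, n_rounds = 0)
  expect_equal(predict(fit, toy$x, type = "prob"), rep(0.5, 8))
  fit2 <- epiboost(toy$x, c(0, 0, 0, 0, 0, 0, 1, 1), n_rounds = 0)
  expect_equal(predict(fit2, toy$x, type = "prob"), rep(0.25, 8))
})

test_that("the regularized objective never increases across rounds", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- 30
    x <- matrix(rnorm(n * 4), n, 4)
    y <- as.integer(x[, 1] + rnorm(n, 0, 0.5) > 0)
    if (length(unique(y)) < 2) next
    fit <- epiboost(x, y, n_rounds = 25)
    expect_true(all(diff(fit$objective) <= 1e-9))
  }
})

test_that("fitted leaf weights satisfy -G/(H+lambda) recomputed post-hoc", {
  set.seed(7)
  n <- 40
  x <- matrix(rnorm(n * 3), n, 3)
  y <- as.integer(x[, 1] - x[, 2] > 0)
  eta <- 0.3; lambda <- 1
  fit <- epiboost(x, y, n_rounds = 8, learning_rate = eta,
                  lambda_reg = lambda, base_score = 0.5)
  margin <- rep(fit$base_margin, n)
  for (tr in fit$trees) {
    gh <- logistic_grad_hess(y, margin)
    ids <- route_leaves(tr, x)
    stored <- leaf_values_dfs(tr)
    for (leaf in unique(ids)) {
      G <- sum(gh$g[ids == leaf]); H <- sum(gh$h[ids == leaf])
      expect_equal(stored[leaf], eta * leaf_weight(G, H, lambda),
                   tolerance = 1e-10)
    }
    margin <- margin + epiwatch:::predict_tree(tr, x)
  }
})

test_that("margins match the reference gradient-boosting implementation", {
  for (seed in c(3, 17)) {
    set.seed(seed)
    n <- 50
    x <- matrix(rnorm(n * 5), n, 5)
    y <- as.integer(x[, 1] + 0.5 * x[, 2] + rnorm(n, 0, 0.4) > 0)
    fit <- epiboost(x, y, n_rounds = 12, learning_rate = 0.3, max_depth = 3,
                    lambda_reg = 1, gamma_reg = 0, base_score = 0.5)
    bst <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", eta = 0.3, max_depth = 3,
                    lambda = 1, gamma = 0, min_child_weight = 0,
                    tree_method = "exact", base_score = 0.5, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = y), nrounds = 12, verbose = 0)
    ours <- predict(fit, x, type = "margin")
    ref <- predict(bst, xgboost::xgb.DMatrix(x), outputmargin = TRUE)
    expect_lt(max(abs(ours - ref)), 1e-6)
  }
})

test_that("training rejects degenerate inputs", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(epiboost(x, rep(1, 5)), class = "epiwatch_training_error")
  expect_error(epiboost(x, c(0, 1, 0)), class = "epiwatch_parameter_error")
  expect_error(epiboost(x, c(0, 1, 2, 0, 1)),
               class = "epiwatch_parameter_error")
})

test_that("prediction validates dimensions and classify applies the tie rule", {
  toy <- separable_toy()
  fit <- epiboost(toy$x, toy$y, n_rounds = 3)
  expect_error(predict(fit, toy$x[, 1, drop = FALSE]),
               class = "epiwatch_parameter_error")

  expect_equal(classify(c(0.5, 0.49, 0.51)),
               c("false_info", "true_info", "false_info"))
  expect_error(classify(0.5, threshold = 1),
               class = "epiwatch_parameter_error")
  expect_error(classify(0.5, threshold = 0),
               class = "epiwatch_parameter_error")
})

test_that("the formula interface and importance accounting line up", {
  gen <- generate_corpus(generator_config(n_messages = 150, seed = 8))
  fm <- feature_matrix(gen$corpus, gen$feature_words)
  fit <- epiboost(label ~ f1_subject_relevance + f2_feature_word_count +
                    f4_effective_length + f5_emotional_intensity,
                  data = fm, n_rounds = 10)
  expect_s3_class(fit, "epiboost")
  expect_length(fit$importance, 4)
  expect_true(all(fit$importance >= 0))
  expect_gt(sum(fit$importance), 0)
})

test_that("models survive JSON round-trips with identical predictions", {
  toy <- separable_toy()
  fit <- epiboost(toy$x, toy$y, n_rounds = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_epiboost(fit, path)
  back <- read_epiboost(path)
  expect_equal(predict(back, toy$x, type = "margin"),
               predict(fit, toy$x, type = "margin"), tolerance = 1e-12)
  expect_equal(back$importance, fit$importance)
})
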