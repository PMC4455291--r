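make_separable <- function(n_per = 20, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * 3, 0), n_per, 3),
             matrix(rnorm(n_per * 3, 4), n_per, 3))
  list(X = X, y = rep(1:2, each = n_per))
}

test_that("a separable two-class problem is fit perfectly", {
  d <- make_separable()
  fit <- fit_plsda(d$X, d$y, n_components = 1)
  expect_equal(classify(fit, d$X), d$y)
  expect_equal(confusion(d$y, classify(fit, d$X), 2)$ccr, 1.0)
  # one-dimensional predictor, threshold-separable
  x1 <- matrix(c(1:5, 11:15), ncol = 1)
  y1 <- rep(1:2, each = 5)
  fit1 <- fit_plsda(x1, y1, n_components = 1)
  expect_equal(classify(fit1, x1), y1)
})

test_that("full-component PLS predictions equal multivariate least squares", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40; p <- 6
    X <- matrix(rnorm(n * p), n, p)
    y <- sample(1:3, n, replace = TRUE)
    fit <- fit_plsda(X, y, n_components = p)
    pred <- predict(fit, X)
    # independent least-squares oracle on the one-hot coding
    Y <- diag(3)[y, ]
    ols <- cbind(1, X) %*% qr.coef(qr(cbind(1, X)), Y)
    expect_lt(max(abs(pred - ols)), 1e-8)
  }
})

test_that("duplicated predictor columns do not change full-rank predictions", {
  set.seed(7)
  X <- matrix(rnorm(60 * 4), 60, 4)
  y <- sample(1:3, 60, replace = TRUE)
  Xdup <- cbind(X, X[, 2], X[, 4])
  # at the rank of the predictors both fits are the least-squares projection
  f1 <- fit_plsda(X, y, n_components = 4)
  f2 <- fit_plsda(Xdup, y, n_components = 4)
  expect_lt(max(abs(predict(f1, X) - predict(f2, Xdup))), 1e-8)
})

test_that("successive X-scores are mutually orthogonal", {
  set.seed(11)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- sample(1:4, 50, replace = TRUE)
  fit <- fit_plsda(X, y, n_components = 5)
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("classification is invariant to adding a constant to scores", {
  # direct argmax check on a hand-built model
  fake <- structure(list(x_mean = rep(0, 2), x_sd = rep(1, 2), scale = FALSE,
                         y_mean = c(0, 0, 0),
                         coefficients = rbind(c(1, 0, 0), c(0, 1, 0)),
                         class_labels = 1:3, n_components = 1L),
                    class = "plsda")
  expect_equal(classify(fake, rbind(c(0.9, 0.1))), 1L)
  expect_equal(classify(fake, rbind(c(0.5, 0.5))), 1L)  # tie -> lowest index
  expect_equal(classify(fake, rbind(c(0.1, 0.8))), 2L)
  shifted <- structure(modifyList(unclass(fake),
                                  list(y_mean = c(5, 5, 5))), class = "plsda")
  X <- matrix(rnorm(20), 10, 2)
  expect_equal(classify(fake, X), classify(shifted, X))
})

test_that("fit validates its inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(fit_plsda(X, rep(1, 10), 1), "two classes")
  expect_error(fit_plsda(X, rep(1:2, 5), 15), "n_components")
  expect_error(fit_plsda(matrix(1, 10, 2), rep(1:2, 5), 1), "constant")
  expect_error(fit_plsda(cbind(rnorm(10), 1), rep(1:2, 5), 1,
                         scale = TRUE), "zero-variance")
  fit <- fit_plsda(X, rep(1:2, 5), 1)
  expect_error(predict(fit, matrix(0.5, 3, 5)), "predictor count")
})

test_that("confusion reports match a counting oracle", {
  rep1 <- confusion(c(1, 1, 2, 2), c(1, 2, 2, 2), 2)
  expect_equal(unclass(rep1$confusion), matrix(c(1, 0, 1, 2), 2, 2),
               ignore_attr = TRUE)
  expect_equal(rep1$ccr, 0.75)
  expect_equal(rep1$per_class_error, c(0.5, 0), ignore_attr = TRUE)

  perfect <- confusion(1:5, 1:5, 5)
  expect_equal(perfect$ccr, 1)
  expect_equal(perfect$per_class_error, rep(0, 5), ignore_attr = TRUE)

  set.seed(90)
  for (rep in 1:10) {
    S <- sample(2:6, 1); n <- 200
    truth <- sample(1:S, n, replace = TRUE)
    pred <- sample(1:S, n, replace = TRUE)
    cr <- confusion(truth, pred, S)
    # brute-force counting
    cnt <- matrix(0L, S, S)
    for (t in seq_len(n)) cnt[truth[t], pred[t]] <- cnt[truth[t], pred[t]] + 1L
    expect_equal(unclass(cr$confusion), cnt, ignore_attr = TRUE)
    expect_equal(rowSums(cr$confusion), as.vector(table(factor(truth, 1:S))),
                 ignore_attr = TRUE)
    expect_equal(cr$ccr, sum(diag(cnt)) / n)
  }
  expect_error(confusion(integer(0), integer(0), 2), "empty")
  expect_error(confusion(c(1, 3), c(1, 1), 2), "1..S")
})

test_that("component selection follows the one-standard-error rule", {
  expect_equal(select_ncomp(matrix(rnorm(40), 20, 2), rep(1:2, 10),
                            max_components = 1), 1L)
  # pure noise: smallest model wins
  set.seed(17)
  X <- matrix(rnorm(100 * 6), 100, 6)
  y <- sample(1:3, 100, replace = TRUE)
  expect_equal(select_ncomp(X, y, max_components = 5, seed = 2), 1L)
  # strongly separable: selected model classifies nearly perfectly
  d <- make_separable(n_per = 30, seed = 3)
  a <- select_ncomp(d$X, d$y, max_components = 3, seed = 2)
  fit <- fit_plsda(d$X, d$y, a)
  expect_gte(mean(classify(fit, d$X) == d$y), 0.95)
  expect_warning(select_ncomp(d$X[c(1:3, 31:60), ], d$y[c(1:3, 31:60)],
                              max_components = 2, n_folds = 5), "folds")
})

test_that("fitted components agree with an established PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(23)
  X <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(NULL, paste0("x", 1:8)))
  y <- sample(1:3, 60, replace = TRUE)
  Y <- diag(3)[y, ]
  fit <- fit_plsda(X, y, n_components = 3)
  ref <- mixOmics::pls(X, Y, ncomp = 3, scale = FALSE, mode = "regression")
  pred_ref <- predict(ref, X)$predict[, , 3]
  expect_lt(max(abs(predict(fit, X) - pred_ref)), 1e-6)
})
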