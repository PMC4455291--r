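#' Partial Least Squares Discriminant Analysis
#'
#' PLS-DA regresses a one-hot indicator coding of the class labels on the
#' predictors by PLS2 (NIPALS) and assigns each sample to the class with the
#' largest predicted indicator score (ties broken towards the lowest class
#' index). Columns are mean-centred; variance scaling is off by default since
#' all sensor channels share one normalised response scale.
#'
#' @param X numeric matrix, samples x predictors
#' @param labels integer class labels in `1..S`; at least two classes present
#' @param n_components number of latent components `A`, with
#'   `A <= min(n_samples - 1, n_predictors)`
#' @param scale logical: autoscale columns to unit variance
#' @param class_labels optional integer vector of all class ids (defaults to
#'   `1:max(labels)`); classes absent from `labels` still get a coefficient
#'   column of zeros
#' @return an object of class `plsda` with centering vectors, weights,
#'   loadings, scores, regression `coefficients` (predictors x classes) and
#'   `class_labels`
#' @export
fit_plsda <- function(X, labels, n_components = 2L, scale = FALSE,
                      class_labels = NULL) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  labels <- as.integer(labels)
  n <- nrow(X); p <- ncol(X)
  if (length(labels) != n) stop("'labels' length must equal nrow(X)")
  if (length(unique(labels)) < 2L)
    stop("need at least two classes to fit PLS-DA")
  if (is.null(class_labels)) class_labels <- seq_len(max(labels))
  S <- length(class_labels)
  A <- as.integer(n_components)
  if (A < 1L || A > min(n - 1L, p))
    stop("'n_components' must satisfy 1 <= A <= min(n_samples - 1, n_predictors)")
  x_mean <- colMeans(X)
  Xc <- sweep(X, 2, x_mean)
  x_sd <- rep(1, p)
  if (scale) {
    x_sd <- apply(Xc, 2, stats::sd)
    if (any(x_sd == 0))
      stop("zero-variance predictor column(s): ",
           paste(which(x_sd == 0), collapse = ", "))
    Xc <- sweep(Xc, 2, x_sd, `/`)
  } else if (all(apply(Xc, 2, function(z) all(z == 0)))) {
    stop("all predictor columns are constant")
  }
  Y <- matrix(0, n, S)
  Y[cbind(seq_len(n), match(labels, class_labels))] <- 1
  y_mean <- colMeans(Y)
  Yc <- sweep(Y, 2, y_mean)

  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- matrix(0, S, A)
  Tm <- matrix(0, n, A)
  Xr <- Xc; Yr <- Yc
  for (a in seq_len(A)) {
    u <- Yr[, which.max(colSums(Yr^2))]
    w <- rep(0, p)
    for (it in seq_len(500L)) {
      w_new <- crossprod(Xr, u)[, 1]
      nw <- sqrt(sum(w_new^2))
      if (nw < 1e-14) break
      w_new <- w_new / nw
      tt <- Xr %*% w_new
      q <- crossprod(Yr, tt)[, 1] / sum(tt^2)
      u_new <- (Yr %*% q) / sum(q^2)
      done <- sum((w_new - w)^2) < 1e-24
      w <- w_new; u <- u_new
      if (done) break
    }
    tt <- Xr %*% w
    tt2 <- sum(tt^2)
    if (tt2 < 1e-14)
      stop("deflated predictors degenerate at component ", a,
           "; reduce 'n_components'")
    pl <- crossprod(Xr, tt)[, 1] / tt2
    q <- crossprod(Yr, tt)[, 1] / tt2
    Xr <- Xr - tt %*% t(pl)
    Yr <- Yr - tt %*% t(q)
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tm[, a] <- tt
  }
  # B maps centred (scaled) X to centred Y: B = W (P'W)^-1 Q'
  B <- W %*% solve(crossprod(P, W), t(Q))
  structure(list(n_components = A, x_mean = x_mean, x_sd = x_sd,
                 scale = scale, y_mean = y_mean,
                 x_weights = W, x_loadings = P, y_loadings = Q,
                 scores = Tm, coefficients = B,
                 class_labels = as.integer(class_labels)),
            class = "plsda")
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA model: %d components, %d predictors, %d classes\n",
              x$n_components, nrow(x$coefficients), length(x$class_labels)))
  invisible(x)
}

#' Predict continuous class scores
#'
#' @param object a `plsda` model
#' @param X samples x predictors matrix matching the training predictors
#' @param ... unused
#' @return samples x classes matrix of predicted indicator scores
#' @export
predict.plsda <- function(object, X, ...) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(object$coefficients))
    stop("predictor count does not match the fitted model")
  Xc <- sweep(sweep(X, 2, object$x_mean), 2, object$x_sd, `/`)
  sweep(Xc %*% object$coefficients, 2, object$y_mean, `+`)
}

#' Assign class labels by the argmax rule
#'
#' @param model a `plsda` model
#' @param X samples x predictors matrix
#' @return integer vector of class labels; exact ties go to the lowest class
#'   index
#' @export
classify <- function(model, X) {
  sc <- predict(model, X)
  model$class_labels[apply(sc, 1, which.max)]
}

#' Confusion matrix and correct-classification rate
#'
#' @param true_labels,predicted_labels equal-length integer vectors in `1..S`
#' @param S number of classes
#' @return object of class `class_report`: `confusion` (S x S counts, rows =
#'   true), `ccr` = trace/total, and `per_class_error[s] = 1 -
#'   confusion[s, s] / rowsum[s]`
#' @export
confusion <- function(true_labels, predicted_labels, S) {
  true_labels <- as.integer(true_labels)
  predicted_labels <- as.integer(predicted_labels)
  if (length(true_labels) == 0L) stop("empty label vectors")
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  S <- as.integer(S)
  if (any(c(true_labels, predicted_labels) < 1L) ||
      any(c(true_labels, predicted_labels) > S))
    stop("labels must lie in 1..S")
  cm <- table(factor(true_labels, levels = seq_len(S)),
              factor(predicted_labels, levels = seq_len(S)))
  cm <- unclass(matrix(as.integer(cm), S, S,
                       dimnames = list(true = seq_len(S), pred = seq_len(S))))
  rs <- rowSums(cm)
  per_class_error <- ifelse(rs > 0, 1 - diag(cm) / rs, NA_real_)
  structure(list(confusion = cm,
                 ccr = sum(diag(cm)) / sum(cm),
                 per_class_error = per_class_error,
                 n = length(true_labels)),
            class = "class_report")
}

#' @export
print.class_report <- function(x, ...) {
  cat(sprintf("correct classification rate: %.1f%% (n = %d)\n",
              100 * x$ccr, x$n))
  cat("per-class error (%):",
      paste(sprintf("%.1f", 100 * x$per_class_error), collapse = ", "), "\n")
  print(x$confusion)
  invisible(x)
}

#' Choose the number of PLS components by cross-validation
#'
#' Stratified k-fold cross-validation of the correct-classification rate for
#' `A = 1..max_components`; returns the smallest A whose mean CV CCR is within
#' one standard error of the best (one-SE rule). If some class has fewer
#' members than folds, the fold count is reduced with a warning.
#'
#' @param X,labels training data as for [fit_plsda()]
#' @param max_components largest candidate A
#' @param n_folds number of folds (>= 2)
#' @param seed seed for the fold assignment
#' @param scale passed to [fit_plsda()]
#' @return the selected integer number of components
#' @export
select_ncomp <- function(X, labels, max_components = NULL, n_folds = 5L,
                         seed = 1L, scale = FALSE) {
  X <- as.matrix(X); labels <- as.integer(labels)
  S <- max(labels)
  if (is.null(max_components)) max_components <- S
  max_components <- min(max_components, ncol(X), nrow(X) - 1L)
  if (max_components < 1L) stop("no admissible component count")
  if (n_folds < 2L) stop("'n_folds' must be >= 2")
  min_class <- min(table(labels))
  if (min_class < n_folds) {
    n_folds <- max(2L, as.integer(min_class))
    warning("class smaller than fold count; reducing to ", n_folds, " folds")
  }
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (s in unique(labels)) {
    idx <- which(labels == s)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  ccr <- matrix(NA_real_, n_folds, max_components)
  for (k in seq_len(n_folds)) {
    tr <- fold != k; te <- !tr
    if (length(unique(labels[tr])) < 2L) next
    a_max <- min(max_components, sum(tr) - 1L)
    for (a in seq_len(a_max)) {
      fit <- fit_plsda(X[tr, , drop = FALSE], labels[tr], a, scale = scale,
                       class_labels = seq_len(S))
      pred <- classify(fit, X[te, , drop = FALSE])
      ccr[k, a] <- mean(pred == labels[te])
    }
  }
  mu <- colMeans(ccr, na.rm = TRUE)
  se <- apply(ccr, 2, function(z) stats::sd(z, na.rm = TRUE) /
                sqrt(sum(!is.na(z))))
  best <- which.max(mu)
  within <- which(mu >= mu[best] - se[best])
  as.integer(min(within))
}
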