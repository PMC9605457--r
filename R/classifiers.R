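# Minimal deterministic implementations of the baseline classifiers.
# LDA uses MASS and logistic regression uses stats::glm; the remaining six
# (GNB, KNN, linear SVM, MLP, CART, bagged-forest) are compact in-package
# versions because no heavier ML packages are assumed at run time. All fits
# consume the ambient RNG stream, so a single seed set by the caller makes
# the whole cross-validation reproducible.
#
# Contract: fit_<model>(x, y) -> model object; predict_score(model, x) ->
# continuous score per row, monotone in P(y = 1); decisions are score > 0.5
# for probability-type scores and > 0 for margins.

predict_score <- function(model, x) UseMethod("predict_score")

score_cut <- function(model) if (inherits(model, "pv_svm")) 0 else 0.5

## ---- logistic regression (L2-penalized, IRLS) ------------------------------
# a small ridge penalty (not on the intercept) keeps the fit identified when
# folds have fewer rows than features and the classes are separable — the
# behaviour of the standard library implementations this baseline mirrors

fit_lr <- function(x, y, lambda = 1, iters = 50L) {
  xa <- cbind(1, x)
  p <- ncol(xa)
  pen <- diag(c(0, rep(lambda, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(iters)) {
    eta <- as.numeric(xa %*% beta)
    mu <- stats::plogis(eta)
    wgt <- pmax(mu * (1 - mu), 1e-6)
    H <- t(xa) %*% (xa * wgt) + pen
    g <- t(xa) %*% (y - mu) - pen %*% beta
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
    if (max(abs(step)) < 1e-8) break
  }
  structure(list(coef = beta), class = "pv_lr")
}
predict_score.pv_lr <- function(model, x) {
  as.numeric(stats::plogis(cbind(1, x) %*% model$coef))
}

## ---- linear discriminant analysis ----------------------------------------

fit_lda <- function(x, y) {
  # collinearity warnings are routine with 40 features on small folds
  fit <- suppressWarnings(MASS::lda(x, grouping = factor(y, levels = c(0, 1))))
  structure(list(fit = fit), class = "pv_lda")
}
predict_score.pv_lda <- function(model, x) {
  unname(stats::predict(model$fit, x)$posterior[, "1"])
}

## ---- Gaussian naive Bayes --------------------------------------------------

fit_gnb <- function(x, y) {
  stats_by <- function(cls) {
    xi <- x[y == cls, , drop = FALSE]
    list(mu = colMeans(xi), var = pmax(apply(xi, 2, stats::var), 1e-9))
  }
  structure(list(c0 = stats_by(0L), c1 = stats_by(1L),
                 logprior = log(c(mean(y == 0L), mean(y == 1L)))),
            class = "pv_gnb")
}
predict_score.pv_gnb <- function(model, x) {
  loglik <- function(p, prior) {
    rowSums(sweep(sweep(x, 2, p$mu)^2, 2, -2 * p$var, "/")) -
      sum(0.5 * log(2 * pi * p$var)) + prior
  }
  l0 <- loglik(model$c0, model$logprior[1])
  l1 <- loglik(model$c1, model$logprior[2])
  1 / (1 + exp(l0 - l1))
}

## ---- k-nearest neighbours --------------------------------------------------

fit_knn <- function(x, y, k = 5L) {
  structure(list(x = x, y = y, k = min(k, nrow(x))), class = "pv_knn")
}
predict_score.pv_knn <- function(model, x) {
  apply(x, 1, function(row) {
    d <- sqrt(colSums((t(model$x) - row)^2))
    mean(model$y[order(d)[seq_len(model$k)]])
  })
}

## ---- linear SVM (Pegasos subgradient) --------------------------------------

# averaged Pegasos on the bias-augmented design (the intercept column takes
# the same light regularization as the weights)
fit_svm <- function(x, y, lambda = 0.01, epochs = 100L) {
  yy <- ifelse(y == 1L, 1, -1)
  xa <- cbind(x, 1)
  n <- nrow(xa); p <- ncol(xa)
  w <- numeric(p)
  w_avg <- numeric(p)
  t <- 0; n_avg <- 0
  for (e in seq_len(epochs)) {
    for (i in sample.int(n)) {
      t <- t + 1
      eta <- 1 / (lambda * (t + 10))
      w <- (1 - eta * lambda) * w
      if (yy[i] * sum(w * xa[i, ]) < 1) w <- w + eta * yy[i] * xa[i, ]
      if (e > epochs / 2) {
        n_avg <- n_avg + 1
        w_avg <- w_avg + (w - w_avg) / n_avg
      }
    }
  }
  structure(list(w = w_avg), class = "pv_svm")
}
predict_score.pv_svm <- function(model, x) {
  as.numeric(cbind(x, 1) %*% model$w)
}

## ---- single-hidden-layer perceptron ----------------------------------------

fit_mlp <- function(x, y, hidden = 8L, lr = 0.5, iters = 300L, decay = 1e-3) {
  n <- nrow(x); p <- ncol(x)
  W1 <- matrix(stats::rnorm(p * hidden, 0, 0.3), p, hidden)
  b1 <- numeric(hidden)
  W2 <- stats::rnorm(hidden, 0, 0.3)
  b2 <- 0
  for (it in seq_len(iters)) {
    H <- stats::plogis(sweep(x %*% W1, 2, b1, "+"))
    p1 <- stats::plogis(as.numeric(H %*% W2) + b2)
    err <- p1 - y                                   # dL/dz2, cross-entropy
    gW2 <- as.numeric(t(H) %*% err) / n + decay * W2
    gb2 <- mean(err)
    dH <- outer(err, W2) * H * (1 - H)
    gW1 <- t(x) %*% dH / n + decay * W1
    gb1 <- colMeans(dH)
    W2 <- W2 - lr * gW2; b2 <- b2 - lr * gb2
    W1 <- W1 - lr * gW1; b1 <- b1 - lr * gb1
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2), class = "pv_mlp")
}
predict_score.pv_mlp <- function(model, x) {
  H <- stats::plogis(sweep(x %*% model$W1, 2, model$b1, "+"))
  stats::plogis(as.numeric(H %*% model$W2) + model$b2)
}

## ---- CART decision tree (gini) ----------------------------------------------

grow_tree <- function(x, y, depth, min_n, features) {
  node <- list(prob = mean(y))
  if (depth == 0L || length(y) < min_n || node$prob %in% c(0, 1)) return(node)
  best <- list(gini = Inf)
  for (j in features) {
    v <- x[, j]
    cuts <- sort(unique(v))
    if (length(cuts) < 2L) next
    cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (cut in cuts) {
      left <- v <= cut
      nl <- sum(left); nr <- length(y) - nl
      if (nl == 0L || nr == 0L) next
      pl <- mean(y[left]); pr <- mean(y[!left])
      g <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / length(y)
      if (g < best$gini - 1e-12) best <- list(gini = g, j = j, cut = cut)
    }
  }
  if (!is.finite(best$gini)) return(node)
  left <- x[, best$j] <= best$cut
  node$j <- best$j
  node$cut <- best$cut
  node$left <- grow_tree(x[left, , drop = FALSE], y[left], depth - 1L, min_n, features)
  node$right <- grow_tree(x[!left, , drop = FALSE], y[!left], depth - 1L, min_n, features)
  node
}

tree_prob <- function(node, row) {
  while (!is.null(node$j)) {
    node <- if (row[node$j] <= node$cut) node$left else node$right
  }
  node$prob
}

fit_dt <- function(x, y, depth = 4L, min_n = 5L) {
  structure(list(tree = grow_tree(x, y, depth, min_n, seq_len(ncol(x)))),
            class = "pv_dt")
}
predict_score.pv_dt <- function(model, x) {
  apply(x, 1, function(row) tree_prob(model$tree, row))
}

## ---- random forest: bagged trees on random feature subspaces ----------------

fit_rf <- function(x, y, n_trees = 50L, depth = 4L, min_n = 5L) {
  p <- ncol(x)
  mtry <- max(1L, floor(sqrt(p)))
  trees <- lapply(seq_len(n_trees), function(b) {
    rows <- sample.int(nrow(x), replace = TRUE)
    feats <- sample.int(p, mtry)
    grow_tree(x[rows, , drop = FALSE], y[rows], depth, min_n, feats)
  })
  structure(list(trees = trees), class = "pv_rf")
}
predict_score.pv_rf <- function(model, x) {
  probs <- vapply(model$trees,
                  function(tr) apply(x, 1, function(row) tree_prob(tr, row)),
                  numeric(nrow(x)))
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  rowMeans(probs)
}

PV_MODELS <- list(svm = fit_svm, mlp = fit_mlp, gnb = fit_gnb, dt = fit_dt,
                  rf = fit_rf, lr = fit_lr, lda = fit_lda, knn = fit_knn)
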