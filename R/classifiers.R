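# The five model families of the classification harness.
#
# No SVM/tree/forest/kNN package is assumed: the linear SVM is solved
# by dual coordinate descent on the L1-loss SVC dual (the LIBLINEAR
# algorithm), trees are CART with Gini impurity, the forest is bagged
# CART with per-split feature subsampling, kNN is exact Euclidean
# search.  Logistic regression uses stats::glm.  Every fit is
# deterministic given its seed.
#
# Common contract: X is a numeric matrix (documents x features), y a
# 0/1 integer vector (1 = positive class); `predict(model, X)` returns
# a continuous score increasing with the positive class (margin for the
# SVM, probability for logistic/tree/forest, vote fraction for kNN).

# ---- feature standardization (fit on training data only) -------------

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

# ---- linear SVM ------------------------------------------------------

# Dual coordinate descent for the L1-loss linear SVC
#   min_w 0.5 ||w||^2 + C sum_i max(0, 1 - y_i w.x_i)
# with the bias handled as an augmented (regularized) constant feature,
# as in LIBLINEAR.  Deterministic given `seed` (seeded coordinate
# permutations).
svm_dcd <- function(X, y, C = 1, max_epochs = 1000L, tol = 1e-4,
                    seed = 0L) {
  n <- nrow(X)
  Xa <- cbind(X, bias = 1)
  d <- ncol(Xa)
  Qii <- rowSums(Xa^2)
  alpha <- numeric(n)
  w <- numeric(d)
  with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      pg_max <- -Inf; pg_min <- Inf
      for (i in sample.int(n)) {
        xi <- Xa[i, ]
        G <- y[i] * sum(w * xi) - 1
        if (alpha[i] <= 0) {
          PG <- min(G, 0)
        } else if (alpha[i] >= C) {
          PG <- max(G, 0)
        } else PG <- G
        pg_max <- max(pg_max, PG); pg_min <- min(pg_min, PG)
        if (abs(PG) > 1e-12) {
          a_new <- min(max(alpha[i] - G / Qii[i], 0), C)
          w <- w + (a_new - alpha[i]) * y[i] * xi
          alpha[i] <- a_new
        }
      }
      if (pg_max - pg_min < tol) break
    }
  })
  list(w = w[-d], b = w[d], alpha = alpha, epochs = epoch)
}

fit_svm <- function(X, y01, C = 1, seed = 0L) {
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  fit <- svm_dcd(Xs, ifelse(y01 == 1L, 1, -1), C = C, seed = seed)
  structure(list(w = stats::setNames(fit$w, colnames(X)), b = fit$b,
                 C = C, scaler = scaler, kernel = "linear"),
            class = "ng_svm")
}

#' @export
predict.ng_svm <- function(object, newdata, ...) {
  Xs <- apply_scaler(object$scaler, as.matrix(newdata))
  drop(Xs %*% object$w) + object$b
}

# ---- logistic regression ---------------------------------------------

fit_logistic <- function(X, y01) {
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, Xs), y01, family = stats::binomial()))
  structure(list(coef = fit$coefficients, scaler = scaler),
            class = "ng_logistic")
}

#' @export
predict.ng_logistic <- function(object, newdata, ...) {
  Xs <- apply_scaler(object$scaler, as.matrix(newdata))
  stats::plogis(drop(cbind(1, Xs) %*% object$coef))
}

# ---- k-nearest neighbours --------------------------------------------

fit_knn <- function(X, y01, k = 5L) {
  scaler <- fit_scaler(X)
  structure(list(X = apply_scaler(scaler, X), y = y01,
                 k = min(k, nrow(X)), scaler = scaler),
            class = "ng_knn")
}

#' @export
predict.ng_knn <- function(object, newdata, ...) {
  Xs <- apply_scaler(object$scaler, as.matrix(newdata))
  tX <- t(object$X)
  vapply(seq_len(nrow(Xs)), function(i) {
    d2 <- colSums((tX - Xs[i, ])^2)
    nn <- order(d2)[seq_len(object$k)]   # stable order() breaks ties
    mean(object$y[nn])
  }, numeric(1))
}

# ---- CART decision tree ----------------------------------------------

# Best Gini split of one node; returns NULL when no admissible split.
cart_best_split <- function(X, y, idx, feats, min_leaf) {
  n <- length(idx)
  best <- NULL
  for (j in feats) {
    x <- X[idx, j]
    o <- order(x, method = "radix")
    xs <- x[o]; ys <- y[idx][o]
    cum1 <- cumsum(ys)
    tot1 <- cum1[n]
    i <- seq_len(n - 1L)
    valid <- xs[i] < xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
    if (!any(valid)) next
    nl <- i; nr <- n - i
    pl <- cum1[i] / nl; pr <- (tot1 - cum1[i]) / nr
    imp <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / n
    imp[!valid] <- Inf
    k <- which.min(imp)
    if (is.null(best) || imp[k] < best$impurity) {
      best <- list(feature = j, threshold = (xs[k] + xs[k + 1L]) / 2,
                   impurity = imp[k])
    }
  }
  best
}

cart_grow <- function(X, y, idx, depth, max_depth, min_split, min_leaf,
                      mtry) {
  n <- length(idx)
  p <- mean(y[idx])
  if (depth >= max_depth || n < min_split || p == 0 || p == 1) {
    return(list(leaf = TRUE, prob = p, n = n))
  }
  feats <- if (mtry < ncol(X)) sample.int(ncol(X), mtry)
           else seq_len(ncol(X))
  sp <- cart_best_split(X, y, idx, feats, min_leaf)
  if (is.null(sp)) return(list(leaf = TRUE, prob = p, n = n))
  go_left <- X[idx, sp$feature] <= sp$threshold
  left <- idx[go_left]
  right <- idx[!go_left]
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       n = n,
       left = cart_grow(X, y, left, depth + 1L, max_depth, min_split,
                        min_leaf, mtry),
       right = cart_grow(X, y, right, depth + 1L, max_depth, min_split,
                         min_leaf, mtry))
}

fit_cart <- function(X, y01, max_depth = 12L, min_split = 10L,
                     min_leaf = 5L, mtry = ncol(X), seed = 0L) {
  tree <- with_seed(seed,
    cart_grow(X, y01, seq_len(nrow(X)), 0L, max_depth, min_split,
              min_leaf, mtry))
  structure(list(tree = tree, p = ncol(X)), class = "ng_cart")
}

cart_predict_node <- function(node, X, idx, out) {
  if (node$leaf) { out[idx] <- node$prob; return(out) }
  go_left <- X[idx, node$feature] <= node$threshold
  out <- cart_predict_node(node$left, X, idx[go_left], out)
  cart_predict_node(node$right, X, idx[!go_left], out)
}

#' @export
predict.ng_cart <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  cart_predict_node(object$tree, X, seq_len(nrow(X)), numeric(nrow(X)))
}

# ---- random forest (bagged CART, per-split feature subsampling) ------

fit_forest <- function(X, y01, n_trees = 100L, mtry = NULL,
                       max_depth = 12L, min_split = 5L, min_leaf = 3L,
                       seed = 0L) {
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  n <- nrow(X)
  trees <- with_seed(seed, lapply(seq_len(n_trees), function(t) {
    boot <- sample.int(n, n, replace = TRUE)
    cart_grow(X[boot, , drop = FALSE], y01[boot],
              seq_len(n), 0L, max_depth, min_split, min_leaf, mtry)
  }))
  structure(list(trees = trees, p = ncol(X)), class = "ng_forest")
}

#' @export
predict.ng_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  idx <- seq_len(nrow(X))
  probs <- vapply(object$trees, function(tr) {
    cart_predict_node(tr, X, idx, numeric(nrow(X)))
  }, numeric(nrow(X)))
  rowMeans(matrix(probs, nrow = nrow(X)))
}

# ---- ROC AUC ---------------------------------------------------------

#' Area under the ROC curve of a continuous score
#'
#' Rank-based (Mann-Whitney) AUC with midrank tie handling; invariant
#' under strictly monotone transforms of the score.
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels 0/1 (or logical) true labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
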