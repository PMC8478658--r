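# Small, dependency-free classifiers used by the cross-validation and
# importance machinery: multiclass AdaBoost (SAMME) over decision stumps,
# a one-vs-rest linear SVM trained by deterministic subgradient descent,
# and a CART-based random forest with out-of-bag permutation importance.
# Sample sizes here are tens-to-hundreds, so plain R is fast enough.

# ---- decision stump -------------------------------------------------------

# Weighted multiclass decision stump: best (feature, threshold) split,
# each side predicting its weight-majority class.
fit_stump <- function(x, y, w) {
  n <- nrow(x); p <- ncol(x)
  classes <- levels(y)
  best <- list(err = Inf)
  for (j in seq_len(p)) {
    xj <- x[, j]
    ord <- order(xj)
    xs <- xj[ord]
    cuts <- unique(xs[-n] + diff(xs) / 2)
    if (!length(cuts)) next
    if (length(cuts) > 32) cuts <- stats::quantile(cuts, probs = seq(0.02, 0.98, length.out = 32), names = FALSE)
    for (cut in cuts) {
      left <- xj <= cut
      wl <- vapply(classes, function(cl) sum(w[left & y == cl]), numeric(1))
      wr <- vapply(classes, function(cl) sum(w[!left & y == cl]), numeric(1))
      pred_l <- classes[which.max(wl)]
      pred_r <- classes[which.max(wr)]
      err <- sum(wl[classes != pred_l]) + sum(wr[classes != pred_r])
      if (err < best$err - 1e-12) {
        best <- list(err = err, feature = j, cut = cut,
                     left = pred_l, right = pred_r)
      }
    }
  }
  best
}

predict_stump <- function(stump, x) {
  ifelse(x[, stump$feature] <= stump$cut, stump$left, stump$right)
}

# ---- AdaBoost (SAMME) -----------------------------------------------------

fit_adaboost <- function(x, y, n_rounds = 40L) {
  x <- as.matrix(x); y <- factor(y)
  k <- nlevels(y)
  n <- nrow(x)
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0)
  for (t in seq_len(n_rounds)) {
    st <- fit_stump(x, y, w)
    if (!is.finite(st$err)) break
    pred <- predict_stump(st, x)
    err <- max(sum(w[pred != as.character(y)]), 1e-10)
    if (err >= 1 - 1 / k) break  # worse than chance: stop
    alpha <- log((1 - err) / err) + log(k - 1)
    w <- w * exp(alpha * (pred != as.character(y)))
    w <- w / sum(w)
    stumps[[length(stumps) + 1L]] <- st
    alphas <- c(alphas, alpha)
    if (err < 1e-9) break  # perfect stump
  }
  structure(list(stumps = stumps, alphas = alphas, classes = levels(y)),
            class = "aml_adaboost")
}

#' @export
predict.aml_adaboost <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  votes <- matrix(0, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (i in seq_along(object$stumps)) {
    pred <- predict_stump(object$stumps[[i]], newdata)
    votes[cbind(seq_len(nrow(newdata)), match(pred, object$classes))] <-
      votes[cbind(seq_len(nrow(newdata)), match(pred, object$classes))] +
      object$alphas[i]
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

# ---- linear SVM (one-vs-rest, deterministic subgradient descent) ---------

fit_linear_svm <- function(x, y, lambda = 0.01, n_iter = 300L) {
  x <- as.matrix(x); y <- factor(y)
  mu <- colMeans(x); sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(x, mu, sdv)
  classes <- levels(y)
  models <- lapply(classes, function(cl) {
    yy <- ifelse(y == cl, 1, -1)
    w <- rep(0, ncol(xs)); b <- 0
    for (t in seq_len(n_iter)) {
      margin <- yy * (xs %*% w + b)
      viol <- margin < 1
      gw <- lambda * w - colMeans(xs[viol, , drop = FALSE] * yy[viol]) *
        mean(viol)
      gw[!is.finite(gw)] <- lambda * w[!is.finite(gw)]
      gb <- -mean(yy * viol)
      eta <- 1 / (lambda * (t + 10))
      w <- w - eta * gw
      b <- b - eta * gb
    }
    list(w = w, b = b)
  })
  structure(list(models = models, classes = classes, mu = mu, sdv = sdv),
            class = "aml_svm")
}

#' @export
predict.aml_svm <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$mu, object$sdv)
  scores <- vapply(object$models, function(m) as.numeric(xs %*% m$w + m$b),
                   numeric(nrow(xs)))
  scores <- matrix(scores, nrow = nrow(xs))
  factor(object$classes[max.col(scores, ties.method = "first")],
         levels = object$classes)
}

fit_classifier <- function(kind, x, y, ...) {
  switch(kind,
         adaboost = fit_adaboost(x, y, ...),
         svm = fit_linear_svm(x, y, ...),
         rf = fit_random_forest(x, y, ...),
         stop2("unknown classifier '%s'", kind))
}

# ---- CART tree ------------------------------------------------------------

# Gini-impurity CART tree on a numeric matrix; nodes stored in a flat list.
fit_cart <- function(x, y, mtry, min_node = 3L, max_depth = 10L,
                     rng = NULL) {
  classes <- levels(y)
  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }
  gini <- function(counts) {
    n <- sum(counts)
    if (n == 0) return(0)
    1 - sum((counts / n)^2)
  }
  build <- function(idx, depth) {
    yy <- y[idx]
    counts <- tabulate(yy, nbins = length(classes))
    pred <- classes[which.max(counts)]
    if (length(idx) < min_node || depth >= max_depth ||
        max(counts) == length(idx)) {
      return(new_node(list(leaf = TRUE, pred = pred)))
    }
    feats <- sample.int(ncol(x), min(mtry, ncol(x)))
    best <- list(gain = 1e-12)
    parent_gini <- gini(counts)
    for (j in feats) {
      xj <- x[idx, j]
      ord <- order(xj)
      xs <- xj[ord]; ys <- as.integer(yy[ord])
      if (xs[1] == xs[length(xs)]) next
      left_counts <- numeric(length(classes))
      total_counts <- tabulate(ys, nbins = length(classes))
      for (i in seq_len(length(idx) - 1L)) {
        left_counts[ys[i]] <- left_counts[ys[i]] + 1
        if (xs[i] == xs[i + 1]) next
        nl <- i; nr <- length(idx) - i
        g <- parent_gini -
          (nl * gini(left_counts) +
             nr * gini(total_counts - left_counts)) / length(idx)
        if (g > best$gain) {
          best <- list(gain = g, feature = j,
                       cut = (xs[i] + xs[i + 1]) / 2)
        }
      }
    }
    if (is.null(best$feature)) {
      return(new_node(list(leaf = TRUE, pred = pred)))
    }
    left_idx <- idx[x[idx, best$feature] <= best$cut]
    right_idx <- idx[x[idx, best$feature] > best$cut]
    node_id <- new_node(list(leaf = FALSE, feature = best$feature,
                             cut = best$cut, left = NA, right = NA,
                             pred = pred))
    l <- build(left_idx, depth + 1L)
    r <- build(right_idx, depth + 1L)
    nodes[[node_id]]$left <<- l
    nodes[[node_id]]$right <<- r
    node_id
  }
  root <- build(seq_len(nrow(x)), 0L)
  list(nodes = nodes, root = root, classes = classes)
}

predict_cart <- function(tree, x) {
  n <- nrow(x)
  out <- character(n)
  for (i in seq_len(n)) {
    nid <- tree$root
    repeat {
      node <- tree$nodes[[nid]]
      if (node$leaf) { out[i] <- node$pred; break }
      nid <- if (x[i, node$feature] <= node$cut) node$left else node$right
    }
  }
  out
}

# ---- random forest --------------------------------------------------------

fit_random_forest <- function(x, y, n_trees = 200L, mtry = NULL,
                              seed = 1L) {
  x <- as.matrix(x); y <- factor(y)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  n <- nrow(x)
  trees <- vector("list", n_trees)
  oob <- vector("list", n_trees)
  with_seed(derive_seed(seed, "rf"), {
    for (t in seq_len(n_trees)) {
      boot_idx <- sample.int(n, n, replace = TRUE)
      trees[[t]] <- fit_cart(x[boot_idx, , drop = FALSE], y[boot_idx], mtry)
      oob[[t]] <- setdiff(seq_len(n), boot_idx)
    }
  })
  structure(list(trees = trees, oob = oob, classes = levels(y),
                 x = x, y = y, seed = seed),
            class = "aml_rf")
}

#' @export
predict.aml_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  votes <- matrix(0L, nrow(newdata), length(object$classes),
                  dimnames = list(NULL, object$classes))
  for (tree in object$trees) {
    pred <- predict_cart(tree, newdata)
    idx <- cbind(seq_len(nrow(newdata)), match(pred, object$classes))
    votes[idx] <- votes[idx] + 1L
  }
  factor(object$classes[max.col(votes, ties.method = "first")],
         levels = object$classes)
}

# Out-of-bag accuracy of a fitted forest.
rf_oob_accuracy <- function(forest) {
  n <- nrow(forest$x)
  votes <- matrix(0L, n, length(forest$classes))
  for (t in seq_along(forest$trees)) {
    idx <- forest$oob[[t]]
    if (!length(idx)) next
    pred <- predict_cart(forest$trees[[t]], forest$x[idx, , drop = FALSE])
    at <- cbind(idx, match(pred, forest$classes))
    votes[at] <- votes[at] + 1L
  }
  covered <- rowSums(votes) > 0
  pred <- forest$classes[max.col(votes[covered, , drop = FALSE],
                                 ties.method = "first")]
  mean(pred == as.character(forest$y)[covered])
}

# Mean-decrease-accuracy importance: per tree, OOB accuracy drop when each
# feature's OOB values are permuted; averaged over trees.
rf_importance <- function(forest) {
  p <- ncol(forest$x)
  drops <- matrix(0, length(forest$trees), p)
  with_seed(derive_seed(forest$seed, "rfimp"), {
    for (t in seq_along(forest$trees)) {
      idx <- forest$oob[[t]]
      if (length(idx) < 2) next
      xo <- forest$x[idx, , drop = FALSE]
      yo <- as.character(forest$y)[idx]
      base_acc <- mean(predict_cart(forest$trees[[t]], xo) == yo)
      for (j in seq_len(p)) {
        xp <- xo
        xp[, j] <- xp[sample.int(nrow(xp)), j]
        drops[t, j] <- base_acc -
          mean(predict_cart(forest$trees[[t]], xp) == yo)
      }
    }
  })
  imp <- colMeans(drops)
  names(imp) <- colnames(forest$x)
  imp
}

# ---- generic stratified CV accuracy --------------------------------------

# Mean/sd of stratified k-fold accuracy for a classifier kind on (x, y).
cv_accuracy <- function(x, y, kind, k_folds = 5L, seed = 1L, ...) {
  x <- as.matrix(x); y <- factor(y)
  folds <- stratified_folds(y, k_folds, seed)
  accs <- vapply(seq_len(k_folds), function(f) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[te])) < 1 || length(unique(y[tr])) < 2)
      return(NA_real_)
    fit <- fit_classifier(kind, x[tr, , drop = FALSE], droplevels(y[tr]), ...)
    pred <- predict(fit, x[te, , drop = FALSE])
    mean(as.character(pred) == as.character(y[te]))
  }, numeric(1))
  accs <- accs[!is.na(accs)]
  list(mean = mean(accs), sd = stats::sd(accs), folds = accs)
}
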