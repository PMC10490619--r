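# Four classifier families behind one fit/predict interface. Labels are a
# factor with levels c("focused", "distracted"); "distracted" is the
# positive class throughout. Scores are oriented so larger = more likely
# positive: signed decision value (SVM), fraction of positive neighbours
# (KNN), posterior probability (LDA), vote fraction (RF).

classifier_families <- function() c("svm_rbf", "knn", "lda", "rf")

as_label_factor <- function(y) {
  factor(as.character(y), levels = c("focused", "distracted"))
}

rbf_kernel <- function(a, b, gamma) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

fit_svm_rbf <- function(x, y, C = 32, gamma = 0.5) {
  yy <- ifelse(y == "distracted", 1, -1)
  n <- nrow(x)
  K <- rbf_kernel(x, x, gamma)
  D <- (yy %o% yy) * K
  diag(D) <- diag(D) + 1e-8 * mean(diag(D))
  A <- cbind(yy, diag(n), -diag(n))
  b0 <- c(0, numeric(n), rep(-C, n))
  sol <- quadprog::solve.QP(Dmat = D, dvec = rep(1, n), Amat = A,
                            bvec = b0, meq = 1)
  alpha <- pmin(pmax(sol$solution, 0), C)
  sv <- alpha > 1e-6 * C
  coef <- alpha * yy
  margin <- alpha > 1e-6 * C & alpha < C * (1 - 1e-6)
  if (!any(margin)) margin <- sv
  b <- mean(yy[margin] - K[margin, sv, drop = FALSE] %*% coef[sv])
  list(kind = "svm_rbf", x = x[sv, , drop = FALSE], coef = coef[sv],
       b = b, gamma = gamma)
}

predict_svm_rbf <- function(fit, newx) {
  s <- as.numeric(rbf_kernel(newx, fit$x, fit$gamma) %*% fit$coef + fit$b)
  list(label = ifelse(s >= 0, "distracted", "focused"), score = s)
}

fit_knn <- function(x, y, k = 2) {
  list(kind = "knn", x = x, y = y, k = k)
}

predict_knn <- function(fit, newx) {
  k <- min(fit$k, nrow(fit$x))
  d2 <- outer(rowSums(newx^2), rowSums(fit$x^2), "+") -
    2 * tcrossprod(newx, fit$x)
  pos <- fit$y == "distracted"
  lab <- character(nrow(newx))
  sc <- numeric(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    ord <- order(d2[i, ])
    nb <- ord[seq_len(k)]
    frac <- mean(pos[nb])
    sc[i] <- frac
    lab[i] <- if (frac > 0.5) "distracted"
      else if (frac < 0.5) "focused"
      else as.character(fit$y[nb[1]])  # even-k tie: nearest neighbour decides
  }
  list(label = lab, score = sc)
}

fit_lda <- function(x, y) {
  list(kind = "lda", fit = MASS::lda(x, grouping = y))
}

predict_lda <- function(fit, newx) {
  pr <- stats::predict(fit$fit, newx)
  list(label = as.character(pr$class),
       score = pr$posterior[, "distracted"])
}

# --- native random forest: bagged CART with Gini splits ---------------------

gini_best_split <- function(xcol, ypos) {
  o <- order(xcol)
  xs <- xcol[o]; ys <- ypos[o]
  n <- length(ys)
  cum_pos <- cumsum(ys)
  tot_pos <- cum_pos[n]
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L]
  if (!any(valid)) return(NULL)
  nl <- i; nr <- n - i
  pl <- cum_pos[i] / nl
  pr <- (tot_pos - cum_pos[i]) / nr
  imp <- nl * pl * (1 - pl) + nr * pr * (1 - pr)
  imp[!valid] <- Inf
  j <- which.min(imp)
  list(threshold = (xs[j] + xs[j + 1L]) / 2, impurity = imp[j] / n)
}

grow_tree <- function(x, ypos, mtry, max_depth, min_n = 2L, depth = 0L) {
  n <- length(ypos)
  p_hat <- mean(ypos)
  if (n < min_n || p_hat == 0 || p_hat == 1 || depth >= max_depth)
    return(list(leaf = TRUE, prob = p_hat))
  feats <- sample.int(ncol(x), mtry)
  best <- NULL
  for (f in feats) {
    sp <- gini_best_split(x[, f], ypos)
    if (!is.null(sp) &&
        (is.null(best) || sp$impurity < best$impurity)) {
      best <- sp
      best$feature <- f
    }
  }
  parent_imp <- p_hat * (1 - p_hat)
  if (is.null(best) || best$impurity >= parent_imp - 1e-12)
    return(list(leaf = TRUE, prob = p_hat))
  left <- x[, best$feature] <= best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       left = grow_tree(x[left, , drop = FALSE], ypos[left], mtry,
                        max_depth, min_n, depth + 1L),
       right = grow_tree(x[!left, , drop = FALSE], ypos[!left], mtry,
                         max_depth, min_n, depth + 1L))
}

predict_tree <- function(tree, newx) {
  out <- numeric(nrow(newx))
  rec <- function(node, idx) {
    if (!length(idx)) return()
    if (node$leaf) {
      out[idx] <<- node$prob
      return()
    }
    left <- newx[idx, node$feature] <= node$threshold
    rec(node$left, idx[left])
    rec(node$right, idx[!left])
  }
  rec(tree, seq_len(nrow(newx)))
  out
}

fit_rf <- function(x, y, trees = 500, max_depth = Inf, seed = 1) {
  ypos <- y == "distracted"
  mtry <- max(1L, floor(sqrt(ncol(x))))
  set.seed(seed)
  forest <- lapply(seq_len(trees), function(t) {
    idx <- sample.int(nrow(x), replace = TRUE)
    grow_tree(x[idx, , drop = FALSE], ypos[idx], mtry, max_depth)
  })
  list(kind = "rf", forest = forest)
}

predict_rf <- function(fit, newx) {
  votes <- vapply(fit$forest, function(tr) predict_tree(tr, newx) >= 0.5,
                  logical(nrow(newx)))
  if (is.null(dim(votes))) votes <- matrix(votes, nrow = nrow(newx))
  frac <- rowMeans(votes)
  list(label = ifelse(frac >= 0.5, "distracted", "focused"), score = frac)
}

#' Fit a classifier of one of the four supported families
#'
#' @param x numeric feature matrix (rows = sessions).
#' @param y labels coercible to the `focused`/`distracted` factor.
#' @param family one of `"svm_rbf"`, `"knn"`, `"lda"`, `"rf"`.
#' @param hp named list of hyperparameters: `C`, `gamma` (SVM); `k` (KNN);
#'   `trees`, `max_depth` (RF).
#' @param seed seed for the stochastic RF fit.
#' @return A fitted model for [predict_classifier()].
#' @export
fit_classifier <- function(x, y, family = "svm_rbf", hp = list(), seed = 1) {
  family <- match.arg(family, classifier_families())
  x <- as.matrix(x)
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2)
    stopf("training data contain a single class",
          class = "distractr_fold_error")
  switch(family,
    svm_rbf = fit_svm_rbf(x, y, C = hp$C %||% 32, gamma = hp$gamma %||% 0.5),
    knn = fit_knn(x, y, k = hp$k %||% 2),
    lda = fit_lda(x, y),
    rf = fit_rf(x, y, trees = hp$trees %||% 500,
                max_depth = hp$max_depth %||% Inf, seed = seed))
}

#' Predict labels and decision scores
#'
#' @param fit result of [fit_classifier()].
#' @param newx numeric feature matrix.
#' @return List with `label` (character) and `score` (numeric, larger =
#'   more distracted).
#' @export
predict_classifier <- function(fit, newx) {
  newx <- as.matrix(newx)
  switch(fit$kind,
    svm_rbf = predict_svm_rbf(fit, newx),
    knn = predict_knn(fit, newx),
    lda = predict_lda(fit, newx),
    rf = predict_rf(fit, newx))
}
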