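#' Assemble the subjects x features classification matrix
#'
#' Inner-joins per-session HRV and EDA feature tables on
#' `(subject_id, condition)`, enforcing exactly two sessions (one per
#' condition) per subject. Columns keep the canonical order: the 14 HRV
#' features then the 7 electrodermal features. Missing `Latency` values
#' (sessions without any SCR) are imputed with the response-window length —
#' "no response within the window".
#'
#' @param hrv data frame: `subject_id`, `condition`, 14 HRV columns.
#' @param eda data frame: `subject_id`, `condition`, 7 EDA columns.
#' @param window_length imputation value for missing Latency (s).
#' @return A `feature_matrix`: data frame with `subject_id`, `condition`
#'   and 21 feature columns, sorted by subject then condition.
#' @export
build_feature_matrix <- function(hrv, eda, window_length = 300) {
  key <- c("subject_id", "condition")
  stopifnot(all(key %in% names(hrv)), all(key %in% names(eda)))
  m <- merge(hrv[, c(key, hrv_feature_names())],
             eda[, c(key, gsr_feature_names())], by = key)
  counts <- table(m$subject_id)
  bad <- names(counts)[counts != 2L]
  miss <- union(setdiff(hrv$subject_id, m$subject_id),
                setdiff(eda$subject_id, m$subject_id))
  bad <- union(bad, miss)
  if (length(bad))
    stopf("subjects without exactly 2 matched sessions: %s",
          paste(sort(bad), collapse = ", "),
          class = "distractr_structural_error")
  if (anyNA(m$Latency)) {
    m$Latency[is.na(m$Latency)] <- window_length
    message(sprintf("imputed %s missing Latency value(s) with %g s",
                    "nSCR = 0", window_length))
  }
  m <- m[order(m$subject_id, m$condition != "focused"), ]
  rownames(m) <- NULL
  class(m) <- c("feature_matrix", "data.frame")
  m
}

feature_cols <- function(m) setdiff(names(m), c("subject_id", "condition"))

#' Z-score normalization fitted on training rows only
#'
#' Standardizes with training-fold means and SDs (no leakage into the
#' held-out rows); constant training columns are dropped with a warning.
#'
#' @param train,test numeric matrices / data frames with the same columns.
#' @return List with normalized `train`, `test`, and `dropped` column names.
#' @export
zscore_normalize <- function(train, test) {
  train <- as.matrix(train)
  test <- as.matrix(test)
  mu <- colMeans(train)
  sdv <- apply(train, 2, sd)
  keep <- sdv > 0
  if (any(!keep))
    warnf("dropping constant training feature(s): %s",
          paste(colnames(train)[!keep], collapse = ", "))
  tr <- sweep(sweep(train[, keep, drop = FALSE], 2, mu[keep]), 2,
              sdv[keep], "/")
  te <- sweep(sweep(test[, keep, drop = FALSE], 2, mu[keep]), 2,
              sdv[keep], "/")
  list(train = tr, test = te, dropped = colnames(train)[!keep])
}

#' Rank features by absolute paired statistic
#'
#' Runs the normality-gated paired comparison ([compare_conditions()]) per
#' feature and sorts by descending |statistic| (t or z depending on the
#' branch taken), ties broken by original column order. Degenerate
#' features rank last with a warning.
#'
#' @param matrix a [build_feature_matrix()] result.
#' @param alpha normality-gate level.
#' @return Data frame `feature`, `statistic`, `abs_statistic`, `test`, in
#'   rank order.
#' @export
rank_features <- function(matrix, alpha = 0.05) {
  feats <- feature_cols(matrix)
  foc <- matrix[matrix$condition == "focused", ]
  dis <- matrix[matrix$condition == "distracted", ]
  foc <- foc[order(foc$subject_id), ]
  dis <- dis[order(dis$subject_id), ]
  rows <- lapply(seq_along(feats), function(i) {
    f <- feats[i]
    res <- tryCatch(compare_conditions(foc[[f]], dis[[f]], alpha = alpha),
                    error = function(e) NULL)
    if (is.null(res)) {
      warnf("feature %s is degenerate; ranked last", f)
      return(data.frame(feature = f, statistic = NA_real_,
                        abs_statistic = -Inf, test = "degenerate",
                        order = i))
    }
    data.frame(feature = f, statistic = res$statistic,
               abs_statistic = abs(res$statistic), test = res$test_name,
               order = i)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$abs_statistic, out$order), ]
  out$order <- NULL
  rownames(out) <- NULL
  out
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: both of that subject's sessions are held out,
#' z-score normalization is fitted on the training fold only, the
#' classifier is fitted and the held-out sessions predicted. With
#' `rank_per_fold`, feature ranking is recomputed inside each training
#' fold and the top `n_features` kept (leakage-safe mode); otherwise the
#' supplied feature set is used as is.
#'
#' @param matrix a [build_feature_matrix()] result (>= 3 subjects).
#' @param family classifier family.
#' @param hp hyperparameter list (see [fit_classifier()]).
#' @param features feature subset to use; default all.
#' @param rank_per_fold recompute the ranking within each training fold.
#' @param n_features subset size kept in `rank_per_fold` mode.
#' @param seed seed forwarded to stochastic fits.
#' @return A `cv_result`: `predictions` data frame (`subject_id`,
#'   `condition`, `truth`, `pred`, `score`, `fold`), `accuracy`, and
#'   `train_subjects` (per-fold training subject ids, for leakage audits).
#' @export
loso_cv <- function(matrix, family = "svm_rbf", hp = list(),
                    features = NULL, rank_per_fold = FALSE,
                    n_features = NULL, seed = 1) {
  subjects <- unique(matrix$subject_id)
  if (length(subjects) < 3)
    stopf("LOSO needs at least 3 subjects",
          class = "distractr_invalid_argument")
  if (is.null(features)) features <- feature_cols(matrix)
  preds <- vector("list", length(subjects))
  train_log <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    tr <- matrix[matrix$subject_id != s, ]
    te <- matrix[matrix$subject_id == s, ]
    fset <- features
    if (rank_per_fold) {
      rk <- suppressWarnings(rank_features(tr))
      fset <- head(rk$feature, n_features %||% length(features))
    }
    if (nlevels(droplevels(as_label_factor(tr$condition))) < 2)
      stopf("fold %s has a single-class training set", s,
            class = "distractr_fold_error")
    nz <- suppressWarnings(zscore_normalize(tr[, fset, drop = FALSE],
                                            te[, fset, drop = FALSE]))
    fit <- fit_classifier(nz$train, tr$condition, family, hp,
                          seed = session_seed(seed, i))
    pr <- predict_classifier(fit, nz$test)
    preds[[i]] <- data.frame(subject_id = te$subject_id,
                             condition = te$condition,
                             truth = te$condition, pred = pr$label,
                             score = pr$score, fold = i)
    train_log[[i]] <- unique(tr$subject_id)
  }
  predictions <- do.call(rbind, preds)
  structure(list(predictions = predictions,
                 accuracy = mean(predictions$pred == predictions$truth),
                 train_subjects = setNames(train_log, subjects),
                 family = family, hp = hp, features = features),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds, accuracy %.4f\n", x$family,
              length(x$train_subjects), x$accuracy))
  invisible(x)
}

#' Default hyperparameter grids
#'
#' SVM: C over 2^(-5..15) crossed with gamma over 2^(-15..3); KNN: k in
#' 1..15; LDA: a single (empty) point; RF: depth in {unlimited, 3, 5, 10}.
#'
#' @param family classifier family.
#' @param trees RF ensemble size.
#' @return List of hyperparameter lists in documented grid order.
#' @export
default_grid <- function(family, trees = 500) {
  family <- match.arg(family, classifier_families())
  switch(family,
    svm_rbf = {
      g <- expand.grid(C = 2^(-5:15), gamma = 2^(-15:3))
      lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
    },
    knn = lapply(1:15, function(k) list(k = k)),
    lda = list(list()),
    rf = lapply(list(Inf, 3, 5, 10),
                function(d) list(trees = trees, max_depth = d)))
}

#' Grid search over hyperparameters by LOSO accuracy
#'
#' @inheritParams loso_cv
#' @param grid list of hyperparameter lists; ties resolve to the first
#'   maximising point in grid order.
#' @return List with `hp` (selected point), `accuracy`, and the per-point
#'   `trace` data frame.
#' @export
grid_search <- function(matrix, family = "svm_rbf",
                        grid = default_grid(family), features = NULL,
                        seed = 1) {
  if (!length(grid))
    stopf("empty hyperparameter grid", class = "distractr_invalid_argument")
  accs <- vapply(grid, function(hp)
    loso_cv(matrix, family, hp, features = features, seed = seed)$accuracy,
    numeric(1))
  best <- which.max(accs)  # first maximum in grid order
  list(hp = grid[[best]], accuracy = accs[best],
       trace = data.frame(point = seq_along(grid), accuracy = accs))
}

#' t-ranked backward feature elimination under LOSO evaluation
#'
#' Ranks features once on the full matrix by |paired statistic| (the
#' literal protocol; see `rank_per_fold` in [loso_cv()] for the
#' leakage-safe variant), then evaluates nested suffixes of the ranking:
#' the full set first, dropping the lowest-ranked remaining feature at
#' each step down to one, re-running grid search + LOSO each time.
#'
#' @inheritParams grid_search
#' @return An `elimination_trace`: `ranking` (from [rank_features()]),
#'   `trace` data frame (`n_features`, `features`, `accuracy`, `hp`),
#'   `best_features`, `best_accuracy`, `best_hp`.
#' @export
backward_elimination <- function(matrix, family = "svm_rbf",
                                 grid = default_grid(family), seed = 1) {
  ranking <- rank_features(matrix)
  if (nrow(ranking) < 2)
    stopf("backward elimination needs at least 2 features",
          class = "distractr_invalid_argument")
  sizes <- rev(seq_len(nrow(ranking)))
  rows <- vector("list", length(sizes))
  hps <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    fset <- head(ranking$feature, sizes[i])
    gs <- grid_search(matrix, family, grid, features = fset, seed = seed)
    rows[[i]] <- data.frame(n_features = sizes[i],
                            features = paste(fset, collapse = ","),
                            accuracy = gs$accuracy)
    hps[[i]] <- gs$hp
  }
  trace <- do.call(rbind, rows)
  best <- which.max(trace$accuracy)
  structure(list(ranking = ranking, trace = trace,
                 best_features = strsplit(trace$features[best], ",")[[1]],
                 best_accuracy = trace$accuracy[best],
                 best_hp = hps[[best]], family = family),
            class = "elimination_trace")
}

#' @export
print.elimination_trace <- function(x, ...) {
  cat(sprintf("<elimination_trace> %s: best accuracy %.4f with %d features\n",
              x$family, x$best_accuracy, length(x$best_features)))
  invisible(x)
}

#' Evaluate cross-validated predictions
#'
#' Confusion counts with distracted = positive, the derived accuracy,
#' sensitivity, specificity, precision and F1, and the ROC curve / AUC
#' from a decision-score sweep (trapezoidal area).
#'
#' @param cv a `cv_result` from [loso_cv()], or a data frame with `truth`,
#'   `pred` and optionally `score` columns.
#' @return An `evaluation_report`: `TP`, `FN`, `TN`, `FP`, `accuracy`,
#'   `sensitivity`, `specificity`, `precision`, `F1`, `AUC`, `roc_points`.
#' @export
evaluate <- function(cv) {
  df <- if (inherits(cv, "cv_result")) cv$predictions else cv
  truth_pos <- df$truth == "distracted"
  pred_pos <- df$pred == "distracted"
  tp <- sum(truth_pos & pred_pos)
  fn <- sum(truth_pos & !pred_pos)
  tn <- sum(!truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  auc <- NA_real_
  roc <- NULL
  if (!is.null(df$score) && !anyNA(df$score)) {
    ord <- order(df$score, decreasing = TRUE)
    sc <- df$score[ord]
    pos <- truth_pos[ord]
    # group tied scores so the curve is threshold-consistent
    grp <- cumsum(c(TRUE, diff(sc) != 0))
    tps <- cumsum(pos)
    fps <- cumsum(!pos)
    last <- tapply(seq_along(grp), grp, max)
    tpr <- c(0, tps[last] / max(sum(pos), 1))
    fpr <- c(0, fps[last] / max(sum(!pos), 1))
    auc <- trapz(fpr, tpr)
    roc <- data.frame(FPR = fpr, TPR = tpr)
  } else if (is.null(df$score) || anyNA(df$score)) {
    warnf("decision scores missing; AUC omitted")
  }
  structure(list(TP = tp, FN = fn, TN = tn, FP = fp,
                 accuracy = (tp + tn) / (tp + tn + fp + fn),
                 sensitivity = sens, specificity = spec,
                 precision = prec, F1 = f1, AUC = auc, roc_points = roc),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> acc %.4f sens %.4f spec %.4f ",
                     "F1 %.4f AUC %s\n  TP %d FN %d TN %d FP %d\n"),
              x$accuracy, x$sensitivity, x$specificity, x$F1,
              ifelse(is.na(x$AUC), "NA", sprintf("%.4f", x$AUC)),
              x$TP, x$FN, x$TN, x$FP))
  invisible(x)
}
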