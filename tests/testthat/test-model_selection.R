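make_cohort_tables <- function(n = 4, seed = 1) {
  co <- generate_cohort(n, seed = seed, duration = 120, include_ecg = FALSE)
  f <- cohort_features(co, from_truth = TRUE)
  f
}

test_that("feature matrix assembles with canonical shape and order", {
  f <- make_cohort_tables(4)
  m <- build_feature_matrix(f$hrv, f$eda, window_length = 120)
  expect_equal(nrow(m), 8)
  expect_identical(setdiff(names(m), c("subject_id", "condition")),
                   c("mRR", "SDRR", "RMSSD", "pNN50", "VLF", "LF", "HF",
                     "TP", "LF_HF", "nLF", "nHF", "SD_ratio", "ApEn",
                     "SampEn", "SCR", "nSCR", "ISCR", "Latency", "AmpSum",
                     "PhasicMax", "Tonic"))
  expect_false(anyNA(m[, -(1:2)]))
  # a subject missing its EDA rows must be named in the error
  bad <- f$eda[f$eda$subject_id != "S02", ]
  expect_error(build_feature_matrix(f$hrv, bad),
               "S02", class = "distractr_structural_error")
})

test_that("z-score normalization uses train statistics only", {
  train <- matrix(c(3, 5, 7, 5, 5, 5), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  test <- matrix(c(9, 1), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(nz <- zscore_normalize(train, test), "constant")
  expect_identical(nz$dropped, "b")
  expect_equal(unname(nz$test[1, "a"]), (9 - 5) / 2)
  nz2 <- zscore_normalize(train[, 1, drop = FALSE], train[, 1, drop = FALSE])
  expect_lt(max(abs(colMeans(nz2$train))), 1e-12)
  expect_lt(abs(sd(nz2$train[, 1]) - 1), 1e-12)
})

test_that("feature ranking puts a planted effect first and is stable", {
  hits <- vapply(1:40, function(s) {
    m <- synthetic_matrix(20, 2, informative = 1, effect = 1.5, seed = s)
    rank_features(m)$feature[1] == "F1"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # two identical columns: tie broken by column order, deterministically
  m <- synthetic_matrix(10, 2, seed = 5)
  m$F2 <- m$F1
  r1 <- rank_features(m); r2 <- rank_features(m)
  expect_identical(r1$feature, r2$feature)
  expect_identical(r1$feature[1], "F1")
  expect_equal(nrow(r1), 2)
})

test_that("LOSO structure: one fold per subject, no self-training", {
  m <- synthetic_matrix(8, 3, informative = 2, seed = 2)
  cv <- loso_cv(m, "knn", list(k = 3))
  expect_equal(length(cv$train_subjects), 8)
  expect_equal(nrow(cv$predictions), 16)
  expect_equal(as.vector(table(cv$predictions$subject_id)), rep(2L, 8))
  for (s in names(cv$train_subjects))
    expect_false(s %in% cv$train_subjects[[s]])
  expect_error(loso_cv(synthetic_matrix(2, 2), "knn"),
               class = "distractr_invalid_argument")
})

test_that("perfectly separable clusters give 100% for all four families", {
  m <- separable_matrix(8, 4)
  for (fam in c("svm_rbf", "knn", "lda", "rf")) {
    hp <- switch(fam, svm_rbf = list(C = 32, gamma = 0.5),
                 knn = list(k = 2), rf = list(trees = 50), list())
    cv <- loso_cv(m, fam, hp, seed = 3)
    expect_equal(cv$accuracy, 1.0, info = fam)
  }
})

test_that("label permutation drives accuracy to chance", {
  accs <- vapply(1:10, function(s) {
    m <- synthetic_matrix(15, 4, informative = 0, seed = 100 + s)
    loso_cv(m, "knn", list(k = 3))$accuracy
  }, numeric(1))
  ci <- 1.96 * sqrt(0.25 / 30)
  expect_lt(abs(mean(accs) - 0.5), ci)
})

test_that("grid search honours order, ties and the paper-scale optima", {
  m <- synthetic_matrix(8, 3, informative = 2, seed = 4)
  one <- grid_search(m, "knn", list(list(k = 4)))
  expect_identical(one$hp, list(k = 4))
  expect_error(grid_search(m, "knn", list()),
               class = "distractr_invalid_argument")
  # default grids must contain the protocol's selected optima
  svm_grid <- default_grid("svm_rbf")
  expect_true(any(vapply(svm_grid, function(g)
    g$C == 32 && g$gamma == 0.5, logical(1))))
  ks <- vapply(default_grid("knn"), `[[`, numeric(1), "k")
  expect_true(all(c(1, 2) %in% ks))
})

test_that("backward elimination traces nested suffixes and finds signal", {
  m <- synthetic_matrix(12, 10, informative = 3, effect = 2, seed = 6)
  el <- backward_elimination(m, "knn", list(list(k = 1), list(k = 3)))
  expect_equal(nrow(el$trace), 10)
  expect_identical(sort(el$trace$n_features), 1:10)
  expect_gte(el$best_accuracy, el$trace$accuracy[el$trace$n_features == 10])
  expect_gte(el$best_accuracy, max(el$trace$accuracy) - 1e-12)
  # nested suffixes of the ranking
  rank_order <- el$ranking$feature
  for (i in seq_len(nrow(el$trace))) {
    fs <- strsplit(el$trace$features[i], ",")[[1]]
    expect_identical(fs, head(rank_order, length(fs)))
  }
})

test_that("elimination drops noise features in the median seed", {
  n_noise_kept <- vapply(1:5, function(s) {
    m <- synthetic_matrix(12, 10, informative = 3, effect = 2.5,
                          seed = 50 + s)
    el <- backward_elimination(m, "knn", list(list(k = 3)))
    sum(el$best_features %in% paste0("F", 4:10))
  }, numeric(1))
  expect_lte(median(n_noise_kept), 3.5)  # at least half of 7 noise cols gone
})

test_that("evaluation metrics reproduce the confusion arithmetic", {
  df <- data.frame(
    truth = c(rep("distracted", 30), rep("focused", 30)),
    pred = c(rep("distracted", 29), "focused",
             rep("focused", 24), rep("distracted", 6)))
  df$score <- NULL
  expect_warning(ev <- evaluate(df), "scores")
  expect_equal(c(ev$TP, ev$FN, ev$TN, ev$FP), c(29, 1, 24, 6))
  expect_equal(ev$sensitivity, 29 / 30)
  expect_equal(ev$specificity, 24 / 30)
  expect_equal(ev$accuracy, 53 / 60)
  expect_equal(ev$F1, 2 * (29 / 35) * (29 / 30) / (29 / 35 + 29 / 30))
  expect_true(is.na(ev$AUC))
})

test_that("AUC is 1 for perfect ranking and ~0.5 under permutation", {
  df <- data.frame(truth = rep(c("distracted", "focused"), each = 20),
                   pred = rep(c("distracted", "focused"), each = 20),
                   score = c(runif(20, 0.6, 1), runif(20, 0, 0.4)))
  expect_equal(evaluate(df)$AUC, 1.0)
  set.seed(9)
  aucs <- replicate(50, {
    df$score <- runif(40)
    evaluate(df)$AUC
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("fold with single-class training data raises a fold error", {
  m <- synthetic_matrix(4, 2, seed = 1)
  m$condition[m$condition == "distracted"] <- "focused"
  m$condition[1] <- "distracted"
  expect_error(suppressWarnings(loso_cv(m, "knn", list(k = 1))),
               class = "distractr_fold_error")
})
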