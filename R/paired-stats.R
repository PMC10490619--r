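#' Shapiro-Wilk normality test
#'
#' W statistic and p-value via Royston's approximation (backed by
#' `stats::shapiro.test`). Intended for the small paired samples of this
#' pipeline (the gate is specified for n below 50).
#'
#' @param values numeric vector, 3 <= n <= 5000, non-degenerate.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3)
    stopf("Shapiro-Wilk needs at least 3 values",
          class = "distractr_insufficient_data")
  if (sd(values) == 0)
    stopf("Shapiro-Wilk undefined for identical values",
          class = "distractr_degenerate_input")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

new_paired_result <- function(test_name, statistic, p, sw_p, d1, d2, n,
                              outliers = 0L) {
  structure(list(test_name = test_name, statistic = statistic, p = p,
                 sw_p = sw_p, descriptive_1 = d1, descriptive_2 = d2,
                 n = n, outliers = outliers),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<%s> n = %d, statistic = %.3f, p = %.4g (SW p = %s)\n",
              x$test_name, x$n, x$statistic, x$p,
              if (is.na(x$sw_p)) "NA" else format(x$sw_p, digits = 3)))
  cat("  condition 1:", x$descriptive_1, "\n  condition 2:", x$descriptive_2, "\n")
  invisible(x)
}

mean_sd_desc <- function(v) sprintf("%.2f +/- %.2f", mean(v), sd(v))
median_iqr_desc <- function(v) {
  q <- quantile(v, c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  sprintf("%.2f (%.2f, %.2f)", q[1], q[2], q[3])
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d)/sqrt(n))` on the differences `y - x`, df = n - 1,
#' two-sided p.
#'
#' @param x,y paired condition values (condition 1, condition 2).
#' @param sw_p optional Shapiro-Wilk p on the differences, recorded in the
#'   result.
#' @return A `paired_test_result`.
#' @export
paired_t <- function(x, y, sw_p = NA_real_) {
  stopifnot(length(x) == length(y))
  d <- y - x
  n <- length(d)
  if (n < 2)
    stopf("need at least 2 pairs", class = "distractr_insufficient_data")
  if (sd(d) == 0)
    stopf("zero-variance differences", class = "distractr_degenerate_input")
  t <- mean(d) / (sd(d) / sqrt(n))
  p <- 2 * pt(-abs(t), df = n - 1)
  new_paired_result("paired_t", t, p, sw_p,
                    mean_sd_desc(x), mean_sd_desc(y), n)
}

# Exact null distribution of W+ over sign assignments, by convolution on
# doubled (hence integer) average ranks. Returns P(W+ <= w) and P(W+ >= w).
wilcoxon_exact_tails <- function(ranks2, w2) {
  maxs <- sum(ranks2)
  dist <- numeric(maxs + 1L)  # counts over achievable doubled sums
  dist[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), dist[seq_len(maxs + 1L - r)])
    dist <- dist + shifted
  }
  total <- sum(dist)
  sums <- 0:maxs
  c(lower = sum(dist[sums <= w2 + 1e-9]) / total,
    upper = sum(dist[sums >= w2 - 1e-9]) / total)
}

#' Wilcoxon signed-rank test
#'
#' Signed ranks with average-rank ties; zero differences dropped. The
#' two-sided p-value is exact (sign-assignment enumeration via rank
#' convolution) for n <= 25 non-zero differences, and uses the normal
#' approximation with continuity and tie correction above. The normal
#' z statistic is always reported (it is the ranking statistic used by
#' the feature-elimination stage).
#'
#' @inheritParams paired_t
#' @return A `paired_test_result` with `statistic` = z.
#' @export
wilcoxon_signed_rank <- function(x, y, sw_p = NA_real_) {
  stopifnot(length(x) == length(y))
  d <- (y - x)[y != x]
  n <- length(d)
  if (sum(y != x) == 0)
    stopf("all differences are zero", class = "distractr_degenerate_input")
  if (n < 5)
    stopf("need at least 5 non-zero differences",
          class = "distractr_insufficient_data")
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(rk)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- 0.5 * sign(w_pos - mu)
  z <- if (sigma2 > 0) (w_pos - mu - cc) / sqrt(sigma2) else 0
  if (n <= 25) {
    tails <- wilcoxon_exact_tails(as.integer(round(2 * rk)),
                                  round(2 * w_pos))
    p <- min(1, 2 * min(tails))
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  new_paired_result("wilcoxon", z, p, sw_p,
                    median_iqr_desc(x), median_iqr_desc(y), length(x))
}

#' Compare two related conditions with the normality-gated procedure
#'
#' The decision procedure applied to every feature: compute the paired
#' differences, screen for outliers (beyond 1.5 IQR of the quartiles of
#' the differences), run Shapiro-Wilk on the differences, then use the
#' paired t-test when `sw_p >= alpha` and no outlier is present, and the
#' Wilcoxon signed-rank test otherwise. Descriptives mirror the branch:
#' mean +/- SD for the t branch, median (P25, P75) for Wilcoxon
#' (type-7 quantiles).
#'
#' @param x,y paired condition values (condition 1 = focused,
#'   condition 2 = distracted).
#' @param alpha normality-gate level, default 0.05.
#' @return A `paired_test_result`; `outliers` records the screen count.
#' @export
compare_conditions <- function(x, y, alpha = 0.05) {
  stopifnot(length(x) == length(y))
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  d <- y - x
  if (sd(d) == 0)
    stopf("zero-variance differences", class = "distractr_degenerate_input")
  q <- quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  n_out <- sum(d < q[1] - 1.5 * iqr | d > q[2] + 1.5 * iqr)
  sw_p <- shapiro_wilk(d)$p
  res <- if (sw_p >= alpha && n_out == 0L) {
    paired_t(x, y, sw_p = sw_p)
  } else {
    wilcoxon_signed_rank(x, y, sw_p = sw_p)
  }
  res$outliers <- n_out
  res
}

#' Condition-comparison summary table over a feature matrix
#'
#' Applies [compare_conditions()] to every feature column of a paired
#' feature table and returns a summary in the style of a
#' descriptives/test-statistic table (one row per feature).
#'
#' @param features data frame with columns `subject_id`, `condition`
#'   (`"focused"`/`"distracted"`) and one column per feature.
#' @param alpha normality-gate level.
#' @param holm apply a Holm correction across features (off by default,
#'   matching per-feature reporting).
#' @return Data frame with columns `feature`, `cond1`, `cond2`, `sw_p`,
#'   `test`, `statistic`, `p` (and `p_holm` when requested).
#' @export
stats_table <- function(features, alpha = 0.05, holm = FALSE) {
  stopifnot(all(c("subject_id", "condition") %in% names(features)))
  feats <- setdiff(names(features), c("subject_id", "condition"))
  foc <- features[features$condition == "focused", ]
  dis <- features[features$condition == "distracted", ]
  foc <- foc[order(foc$subject_id), ]
  dis <- dis[order(dis$subject_id), ]
  stopifnot(identical(foc$subject_id, dis$subject_id))
  rows <- lapply(feats, function(f) {
    res <- tryCatch(compare_conditions(foc[[f]], dis[[f]], alpha = alpha),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(feature = f, cond1 = NA, cond2 = NA, sw_p = NA,
                        test = "degenerate", statistic = NA, p = NA))
    data.frame(feature = f, cond1 = res$descriptive_1,
               cond2 = res$descriptive_2, sw_p = res$sw_p,
               test = res$test_name, statistic = res$statistic, p = res$p)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}
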