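# Independent oracles used across the suite. These deliberately use naive
# direct computation (loops, exhaustive enumeration) so they share no code
# path with the package implementations they check.

# Naive template-counting approximate entropy: explicit loop over
# templates, Chebyshev distance, self-match included.
apen_naive <- function(x, m, r) {
  N <- length(x)
  phi <- function(k) {
    n <- N - k + 1L
    counts <- integer(n)
    for (i in seq_len(n)) {
      ti <- x[i:(i + k - 1L)]
      cnt <- 0L
      for (j in seq_len(n)) {
        if (max(abs(ti - x[j:(j + k - 1L)])) <= r) cnt <- cnt + 1L
      }
      counts[i] <- cnt
    }
    mean(log(counts / n))
  }
  phi(m) - phi(m + 1L)
}

# Naive sample entropy with the package's documented convention:
# B over all N-m+1 length-m templates, A over the N-m length-(m+1)
# templates, self-matches excluded; fully-regular degenerate case -> 0.
sampen_naive <- function(x, m, r) {
  N <- length(x)
  count_pairs <- function(k) {
    n <- N - k + 1L
    cnt <- 0L
    for (i in seq_len(n - 1L)) {
      ti <- x[i:(i + k - 1L)]
      for (j in (i + 1L):n) {
        if (max(abs(ti - x[j:(j + k - 1L)])) <= r) cnt <- cnt + 1L
      }
    }
    cnt
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  if (B == choose(N - m + 1L, 2) && A == choose(N - m, 2)) return(0)
  if (A == 0 || B == 0) return(NaN)
  -log(A / B)
}

# Exhaustive sign-pattern enumeration oracle for the Wilcoxon signed-rank
# two-sided p (n <= ~14). Ties get average ranks, zeros are dropped.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(rk[signs])
  }, numeric(1))
  p_lo <- mean(ws <= w_obs + 1e-9)
  p_hi <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_lo, p_hi))
}

# An rr_series with prescribed intervals (ms), first peak at t = 0.
rr_from_intervals <- function(intervals) {
  rr_series(c(0, cumsum(intervals) / 1000))
}

# Noiseless GSR trace with planted Bateman SCRs on a flat baseline.
planted_gsr <- function(onsets, amps, duration = 300, fs = 10,
                        baseline = 1.0, tau1 = 3.75, tau2 = 1.0) {
  tt <- seq(0, duration, by = 1 / fs)
  x <- rep(baseline, length(tt))
  tpk <- log(tau1 / tau2) * tau1 * tau2 / (tau1 - tau2)
  pk <- exp(-tpk / tau1) - exp(-tpk / tau2)
  for (i in seq_along(onsets)) {
    idx <- tt >= onsets[i]
    rel <- tt[idx] - onsets[i]
    x[idx] <- x[idx] + amps[i] * (exp(-rel / tau1) - exp(-rel / tau2)) / pk
  }
  gsr_recording(x, fs = fs, window_length = duration)
}

# Synthetic paired feature matrix: `informative` features carry a paired
# condition shift of size `effect` (in SD units), the rest are pure noise.
synthetic_matrix <- function(n_subjects, n_features, informative = 0,
                             effect = 1.5, seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_subjects))
  rows <- lapply(seq_len(n_subjects), function(i) {
    base <- rnorm(n_features)
    foc <- base + rnorm(n_features, 0, 1)
    dis <- base + rnorm(n_features, 0, 1)
    if (informative > 0)
      dis[seq_len(informative)] <- dis[seq_len(informative)] + effect
    rbind(data.frame(subject_id = ids[i], condition = "focused",
                     t(setNames(foc, paste0("F", seq_len(n_features))))),
          data.frame(subject_id = ids[i], condition = "distracted",
                     t(setNames(dis, paste0("F", seq_len(n_features))))))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  class(m) <- c("feature_matrix", "data.frame")
  m
}

# Perfectly separated two-cluster matrix: cluster gap >> spread.
separable_matrix <- function(n_subjects = 8, n_features = 4, seed = 1) {
  set.seed(seed)
  ids <- sprintf("P%02d", seq_len(n_subjects))
  rows <- lapply(seq_len(n_subjects), function(i) {
    rbind(data.frame(subject_id = ids[i], condition = "focused",
                     t(setNames(rnorm(n_features, 0, 0.1),
                                paste0("F", seq_len(n_features))))),
          data.frame(subject_id = ids[i], condition = "distracted",
                     t(setNames(rnorm(n_features, 10, 0.1),
                                paste0("F", seq_len(n_features))))))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  class(m) <- c("feature_matrix", "data.frame")
  m
}
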