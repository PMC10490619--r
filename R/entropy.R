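# Pairwise Chebyshev distances between all length-m templates of x,
# computed dimension-wise with pmax on full N x N matrices.
cheb_template_dist <- function(x, m) {
  n <- length(x) - m + 1L
  d <- abs(outer(x[seq_len(n)], x[seq_len(n)], "-"))
  if (m > 1L) for (j in seq_len(m - 1L)) {
    idx <- seq_len(n) + j
    d <- pmax(d, abs(outer(x[idx], x[idx], "-")))
  }
  d
}

#' Approximate entropy (ApEn)
#'
#' `ApEn = Phi_m - Phi_{m+1}` with
#' `Phi_k = mean_i log(C_i^k)`, where `C_i^k` is the fraction of length-k
#' templates (self-match included) within Chebyshev distance `r` of
#' template i.
#'
#' @param series numeric vector, length >= m + 2.
#' @param m embedding dimension, >= 1 (default 2).
#' @param r tolerance, > 0; default `0.2 * sd(series)`.
#' @return ApEn in nats.
#' @export
approximate_entropy <- function(series, m = 2, r = 0.2 * sd(series)) {
  series <- as.numeric(series)
  if (length(series) < m + 2)
    stopf("series too short for m = %d", m,
          class = "distractr_insufficient_data")
  if (!is.finite(r) || r <= 0)
    stopf("tolerance `r` must be positive",
          class = "distractr_invalid_argument")
  phi <- function(k) {
    d <- cheb_template_dist(series, k)
    counts <- rowSums(d <= r)
    mean(log(counts / (length(series) - k + 1L)))
  }
  phi(m) - phi(m + 1L)
}

#' Sample entropy (SampEn)
#'
#' `SampEn = -log(A/B)` with self-matches excluded: `B` counts template
#' pairs `i < j` of length m within Chebyshev distance `r` (over all
#' `N - m + 1` length-m templates) and `A` the same for length m + 1
#' (over the `N - m` such templates). A perfectly regular series in which
#' every template pair matches at both lengths returns 0; if `A` or `B`
#' is zero the result is `NaN` with a warning.
#'
#' @inheritParams approximate_entropy
#' @return SampEn in nats.
#' @export
sample_entropy <- function(series, m = 2, r = 0.2 * sd(series)) {
  series <- as.numeric(series)
  if (length(series) < m + 2)
    stopf("series too short for m = %d", m,
          class = "distractr_insufficient_data")
  if (!is.finite(r) || r <= 0)
    stopf("tolerance `r` must be positive",
          class = "distractr_invalid_argument")
  count_pairs <- function(k) {
    d <- cheb_template_dist(series, k)
    (sum(d <= r) - nrow(d)) / 2
  }
  B <- count_pairs(m)
  A <- count_pairs(m + 1L)
  nB <- length(series) - m + 1L
  nA <- length(series) - m
  if (B == choose(nB, 2) && A == choose(nA, 2)) return(0)
  if (A == 0 || B == 0) {
    warnf("sample entropy undefined (A = %g, B = %g); returning NaN", A, B)
    return(NaN)
  }
  -log(A / B)
}
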