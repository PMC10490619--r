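#' Zero-phase band-pass filter
#'
#' Frequency-domain (FFT) zero-phase band-pass with raised-cosine
#' transition edges; the mean is removed first and the signal is
#' mirror-padded to suppress edge transients. Output length equals
#' input length.
#'
#' @param ecg an [ecg_recording()].
#' @param low,high band edges (Hz), `0 < low < high < fs/2`.
#' @param trans transition half-width (Hz); default `min(low/2, 1)`.
#' @return A filtered [ecg_recording()].
#' @export
bandpass_filter <- function(ecg, low = 5, high = 15, trans = NULL) {
  stopifnot(inherits(ecg, "ecg_recording"))
  fs <- ecg$fs
  if (!(low > 0 && low < high && high < fs / 2))
    stopf("invalid band: need 0 < low < high < fs/2",
          class = "distractr_invalid_argument")
  if (is.null(trans)) trans <- min(low / 2, 1)
  x <- ecg$samples - mean(ecg$samples)
  n <- length(x)
  pad <- min(n, 2048L)
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[n - seq_len(pad) + 1L]))
  m <- nextn(length(xp), 2)
  xp <- c(xp, numeric(m - length(xp)))
  f <- c(seq(0, m %/% 2), seq(-(m - m %/% 2 - 1L), -1L)) * fs / m
  af <- abs(f)
  H <- numeric(m)
  H[af >= low & af <= high] <- 1
  lo_ramp <- af > low - trans & af < low
  H[lo_ramp] <- 0.5 * (1 + cos(pi * (low - af[lo_ramp]) / trans))
  hi_ramp <- af > high & af < high + trans
  H[hi_ramp] <- 0.5 * (1 + cos(pi * (af[hi_ramp] - high) / trans))
  y <- Re(fft(fft(xp) * H, inverse = TRUE)) / m
  ecg_recording(y[pad + seq_len(n)], fs, ecg$start_time)
}

#' Detect R peaks with the Pan-Tompkins algorithm
#'
#' Classic chain: 5-15 Hz band-pass, five-point derivative, squaring,
#' 150 ms moving-window integration, then adaptive dual-threshold peak
#' acceptance with a 200 ms refractory period and search-back at half
#' threshold when more than 1.66x the running RR average elapses without
#' a beat. Peak instants are refined to the band-passed waveform maximum.
#'
#' @param ecg an [ecg_recording()] of at least 5 s.
#' @param refine_window half-width (s) of the R-refinement window.
#' @return Strictly increasing R-peak times (s); empty for silent input.
#' @export
detect_r_peaks <- function(ecg, refine_window = 0.1) {
  stopifnot(inherits(ecg, "ecg_recording"))
  fs <- ecg$fs
  n <- length(ecg$samples)
  if (n < 5 * fs)
    stopf("Pan-Tompkins needs at least 5 s of signal",
          class = "distractr_insufficient_data")
  if (max(abs(ecg$samples - mean(ecg$samples))) < 1e-12) return(numeric(0))

  bp <- bandpass_filter(ecg, 5, min(15, fs / 2 - 1))$samples
  # symmetric (zero-phase) five-point derivative
  d <- c(0, 0, bp[seq_len(n - 4L)] * -1 + bp[seq_len(n - 4L) + 1L] * -2 +
           bp[seq_len(n - 4L) + 3L] * 2 + bp[seq_len(n - 4L) + 4L], 0, 0) / 8
  sq <- d^2
  w <- max(3L, round(0.15 * fs))
  if (w %% 2L == 0L) w <- w + 1L
  cs <- cumsum(c(0, sq))
  half_w <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - half_w, 1L)
  hi <- pmin(seq_len(n) + half_w, n)
  mwi <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)

  # candidate peaks: local maxima of the integrated signal
  cand <- which(diff(sign(diff(mwi))) < 0) + 1L
  cand <- cand[mwi[cand] > 1e-12 * max(mwi)]
  if (!length(cand)) return(numeric(0))

  refr <- 0.2 * fs
  spki <- max(mwi[seq_len(min(n, round(2 * fs)))]) * 0.5
  npki <- mean(mwi[seq_len(min(n, round(2 * fs)))]) * 0.5
  thr <- function() npki + 0.25 * (spki - npki)
  peaks <- integer(0)
  noise_cand <- integer(0)
  rr_avg <- NA_real_
  last <- -Inf
  for (i in cand) {
    if (i - last < refr) next
    if (mwi[i] >= thr()) {
      # search-back first: did we miss a beat in a long gap?
      if (!is.na(rr_avg) && is.finite(last) && (i - last) > 1.66 * rr_avg &&
          length(noise_cand)) {
        gap <- noise_cand[noise_cand > last + refr & noise_cand < i - refr]
        if (length(gap)) {
          bk <- gap[which.max(mwi[gap])]
          if (mwi[bk] >= 0.5 * thr()) {
            peaks <- c(peaks, bk)
            spki <- 0.25 * mwi[bk] + 0.75 * spki
          }
        }
      }
      peaks <- c(peaks, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
      if (length(peaks) >= 2L) {
        rrs <- diff(tail(peaks, 9L))
        rr_avg <- mean(rrs)
      }
      last <- i
      noise_cand <- integer(0)
    } else {
      npki <- 0.125 * mwi[i] + 0.875 * npki
      noise_cand <- c(noise_cand, i)
    }
  }
  if (!length(peaks)) return(numeric(0))
  peaks <- sort(unique(peaks))

  # refine to the band-passed R maximum around each integrated-signal peak
  hw <- round(refine_window * fs)
  ref <- vapply(peaks, function(i) {
    a <- max(1L, i - hw); b <- min(n, i + hw)
    as.integer(a + which.max(bp[a:b]) - 1L)
  }, integer(1))
  ref <- sort(unique(ref))
  ref <- ref[c(TRUE, diff(ref) > refr)]
  ecg$start_time + (ref - 1L) / fs
}

#' Build an artifact-corrected RR series from R-peak times
#'
#' Intervals deviating more than `correction_threshold` from the local
#' median (centred 11-beat window) are flagged as artifacts and replaced
#' by cubic-spline interpolation through the unflagged intervals.
#'
#' @param peak_times strictly increasing R instants (s); at least 3.
#' @param correction_threshold relative deviation triggering correction;
#'   default 0.3.
#' @return An [rr_series()] with corrected intervals and artifact flags.
#' @export
build_rr_series <- function(peak_times, correction_threshold = 0.3) {
  if (length(peak_times) < 3)
    stopf("need at least 3 R peaks", class = "distractr_insufficient_data")
  rr <- rr_series(peak_times)
  x <- rr$intervals
  n <- length(x)
  loc <- vapply(seq_len(n), function(i) {
    a <- max(1L, i - 5L); b <- min(n, i + 5L)
    median(x[a:b])
  }, numeric(1))
  flags <- abs(x - loc) / loc > correction_threshold
  if (any(flags) && sum(!flags) >= 4L) {
    good <- which(!flags)
    x[flags] <- spline(good, x[good], xout = which(flags), method = "fmm")$y
  }
  rr$intervals <- x
  rr$artifact_flags <- flags
  rr
}

#' Time-domain HRV features
#'
#' @param rr an [rr_series()] with at least 2 intervals.
#' @return Named list: `mRR` (ms, mean), `SDRR` (ms, sample SD), `RMSSD`
#'   (ms, root mean squared successive difference), `pNN50` (% of
#'   successive differences exceeding 50 ms).
#' @export
time_domain_features <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  if (length(x) < 2)
    stopf("need at least 2 intervals", class = "distractr_insufficient_data")
  d <- diff(x)
  list(mRR = mean(x), SDRR = sd(x), RMSSD = sqrt(mean(d^2)),
       pNN50 = 100 * mean(abs(d) > 50))
}

#' Lomb-Scargle power spectral density of an RR tachogram
#'
#' Standard Lomb-Scargle periodogram of the (interval time, interval)
#' tachogram on a uniform grid over 0-`fmax` Hz, normalized so the spectrum
#' integrates (trapezoid rule) to the sample variance of the intervals:
#' band integrals are then in ms^2 and a pure oscillation of amplitude A
#' contributes A^2/2 to its band.
#'
#' @param rr an [rr_series()] with at least 16 intervals.
#' @param grid_step frequency grid step (Hz), default 0.002.
#' @param fmax upper frequency bound (Hz), default 0.4.
#' @param detrend `"none"` (default) or `"linear"` detrending of the
#'   tachogram before analysis.
#' @return An object of class `psd_estimate` with `frequencies` (Hz,
#'   0..fmax) and `power` (ms^2/Hz).
#' @export
lomb_scargle_psd <- function(rr, grid_step = 0.002, fmax = 0.4,
                             detrend = c("none", "linear")) {
  detrend <- match.arg(detrend)
  stopifnot(inherits(rr, "rr_series"))
  if (length(rr$intervals) < 16)
    stopf("need at least 16 intervals for spectral analysis",
          class = "distractr_insufficient_data")
  check_scalar(grid_step, "grid_step", lower = 1e-6)
  t <- rr$peak_times[-1]
  x <- rr$intervals
  if (detrend == "linear") {
    fit <- stats::lm.fit(cbind(1, t), x)
    x <- fit$residuals
  } else {
    x <- x - mean(x)
  }
  v <- sum(x^2) / (length(x) - 1L)
  freqs <- seq(grid_step, fmax, by = grid_step)
  w <- 2 * pi * freqs
  # vectorized over the frequency grid
  P <- vapply(w, function(wi) {
    tau <- atan2(sum(sin(2 * wi * t)), sum(cos(2 * wi * t))) / (2 * wi)
    ct <- cos(wi * (t - tau)); st <- sin(wi * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2))
  }, numeric(1))
  freqs <- c(0, freqs)
  P <- c(0, P)
  tot <- trapz(freqs, P)
  scale <- if (tot > 0) v / tot else 0
  structure(list(frequencies = freqs, power = P * scale),
            class = "psd_estimate")
}

band_power <- function(psd, lo, hi) {
  f <- psd$frequencies; p <- psd$power
  keep <- f >= lo & f <= hi
  fk <- f[keep]; pk <- p[keep]
  if (!length(fk) || fk[1] > lo) {  # interpolate the left edge
    if (lo >= f[1] && lo <= f[length(f)]) {
      pl <- approx(f, p, xout = lo)$y
      fk <- c(lo, fk); pk <- c(pl, pk)
    }
  }
  if (fk[length(fk)] < hi && hi <= f[length(f)]) {
    ph <- approx(f, p, xout = hi)$y
    fk <- c(fk, hi); pk <- c(pk, ph)
  }
  trapz(fk, pk)
}

#' Frequency-domain HRV features from a PSD estimate
#'
#' Trapezoidal band integrals over the standard bands: VLF 0-0.04 Hz,
#' LF 0.04-0.15 Hz, HF 0.15-0.4 Hz; TP is their sum (total 0-0.4 Hz
#' power). Normalized powers use `nLF = 100*LF/(LF+HF)` and
#' `nHF = 100 - nLF`, so `nLF + nHF = 100` by construction.
#'
#' @param psd a `psd_estimate` whose grid covers 0-0.4 Hz.
#' @return Named list `VLF`, `LF`, `HF`, `TP` (ms^2), `LF_HF`, `nLF`,
#'   `nHF`. `LF_HF` is `Inf` (with a warning) when HF = 0.
#' @export
frequency_domain_features <- function(psd) {
  f <- psd$frequencies
  if (f[1] > 1e-12 || f[length(f)] < 0.4 - 1e-9)
    stopf("PSD grid must cover 0-0.4 Hz",
          class = "distractr_invalid_argument")
  vlf <- band_power(psd, 0, 0.04)
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15, 0.4)
  tp <- vlf + lf + hf
  if (hf == 0) {
    warnf("HF power is zero; LF/HF reported as Inf")
    lf_hf <- Inf
    nlf <- if (lf > 0) 100 else NA_real_
  } else {
    lf_hf <- lf / hf
    nlf <- 100 * lf / (lf + hf)
  }
  list(VLF = vlf, LF = lf, HF = hf, TP = tp, LF_HF = lf_hf,
       nLF = nlf, nHF = 100 - nlf)
}

#' Poincare-plot descriptors
#'
#' `SD1 = RMSSD/sqrt(2)` (short-term, uncentred convention so the RMSSD
#' identity holds exactly) and `SD2 = sqrt(2*SDRR^2 - SD1^2)` (long-term).
#' The ratio is reported as SD1/SD2, with SD2/SD1 also returned.
#'
#' @param rr an [rr_series()] with at least 3 intervals.
#' @return Named list `SD1`, `SD2` (ms), `SD_ratio` (SD1/SD2),
#'   `SD2_SD1` (SD2/SD1).
#' @export
poincare_features <- function(rr) {
  x <- if (inherits(rr, "rr_series")) rr$intervals else as.numeric(rr)
  if (length(x) < 3)
    stopf("need at least 3 intervals", class = "distractr_insufficient_data")
  rmssd <- sqrt(mean(diff(x)^2))
  sd1 <- rmssd / sqrt(2)
  sd2sq <- 2 * var(x) - sd1^2
  sd2 <- sqrt(max(sd2sq, 0))
  if (sd2 <= 1e-8 * mean(x))  # constant series up to round-off
    stopf("SD2 is zero; Poincare ratio undefined",
          class = "distractr_degenerate_input")
  list(SD1 = sd1, SD2 = sd2, SD_ratio = sd1 / sd2, SD2_SD1 = sd2 / sd1)
}
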