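make_tone_ecg <- function(freq, fs = 250, dur = 10) {
  t <- seq(0, dur, by = 1 / fs)
  ecg_recording(sin(2 * pi * freq * t), fs)
}

test_that("band-pass filter attenuates out-of-band tones, keeps in-band", {
  fs <- 250
  dc <- ecg_recording(rep(3, 10 * fs), fs)
  out <- bandpass_filter(dc, 5, 15)
  expect_lt(max(abs(out$samples)), 1e-6 * 3)

  mid <- function(x) x[round(length(x) * 0.3):round(length(x) * 0.7)]
  tone10 <- bandpass_filter(make_tone_ecg(10), 5, 15)
  amp10 <- max(abs(mid(tone10$samples)))
  expect_lt(abs(amp10 - 1), 0.05)

  tone50 <- bandpass_filter(make_tone_ecg(50), 5, 15)
  amp50 <- max(abs(mid(tone50$samples)))
  expect_lt(20 * log10(amp50), -20)

  expect_error(bandpass_filter(dc, 15, 5),
               class = "distractr_invalid_argument")
})

test_that("Pan-Tompkins recovers noiseless planted beats within a sample", {
  rr <- rr_from_intervals(rep(1000, 59))  # 60 bpm, 60 s
  syn <- synthesize_ecg(rr, fs = 250, snr_db = Inf, seed = 1,
                        wander_amp = 0, powerline_amp = 0)
  pk <- detect_r_peaks(syn$ecg)
  expect_true(abs(length(pk) - 60) <= 1)
  err <- vapply(pk, function(t) min(abs(syn$r_times - t)), numeric(1))
  expect_lt(max(err), 1 / 250 + 1e-9)
})

test_that("silent or flat input yields an empty peak list", {
  z <- ecg_recording(numeric(250 * 6), 250)
  expect_identical(detect_r_peaks(z), numeric(0))
  expect_error(detect_r_peaks(ecg_recording(rnorm(500), 250)),
               class = "distractr_insufficient_data")
})

test_that("RR construction flags and repairs a dropped beat", {
  clean <- build_rr_series(seq(0, 40, by = 0.8))
  expect_equal(sum(clean$artifact_flags), 0)
  expect_equal(clean$intervals, rep(800, 50))

  pk <- seq(0, 40, by = 0.8)
  pk <- pk[-20]  # one dropped beat -> one 1600 ms gap
  fixed <- build_rr_series(pk)
  expect_equal(sum(fixed$artifact_flags), 1)
  expect_lt(abs(fixed$intervals[which(fixed$artifact_flags)] - 800), 10)
  expect_error(build_rr_series(c(0, 0.8)),
               class = "distractr_insufficient_data")
})

test_that("time-domain features match hand arithmetic", {
  rr <- rr_from_intervals(c(800, 810, 790, 850, 795))
  td <- time_domain_features(rr)
  # explicit sums: mean = 4045/5; SDRR^2 = 2320/4; RMSSD^2 = 7125/4
  expect_equal(td$mRR, 4045 / 5)
  expect_equal(td$SDRR, sqrt(2320 / 4))
  expect_equal(td$RMSSD, sqrt(7125 / 4))
  expect_equal(td$pNN50, 50)

  cst <- time_domain_features(rr_from_intervals(rep(800, 10)))
  expect_equal(cst$SDRR, 0)
  expect_equal(cst$RMSSD, 0)
  expect_equal(cst$pNN50, 0)
})

test_that("Lomb-Scargle recovers a planted 0.10 Hz tone in the LF band", {
  prof <- subject_profile(base_sdrr = 0, lf_amp = 20, hf_amp = 0)
  rr <- generate_rr(prof, "focused", 300, seed = 1)
  psd <- lomb_scargle_psd(rr)
  f_peak <- psd$frequencies[which.max(psd$power)]
  expect_lt(abs(f_peak - 0.10), 0.002 + 1e-12)
  fd <- frequency_domain_features(psd)
  expect_gt(fd$nLF, 95)
  expect_lt(abs(fd$LF - (fd$TP - fd$VLF)), 0.01 * fd$TP)
  expect_error(lomb_scargle_psd(rr_from_intervals(rep(800, 10))),
               class = "distractr_insufficient_data")
})

test_that("near-uniform sampling matches the classical periodogram peak", {
  n <- 512
  x <- 1000 + 5 * sin(2 * pi * 0.1 * seq_len(n))  # ~1 Hz sampling
  rr <- rr_from_intervals(x)
  psd <- lomb_scargle_psd(rr, grid_step = 0.002)
  f_lomb <- psd$frequencies[which.max(psd$power)]
  pg <- stats::spec.pgram(ts(x, frequency = 1), plot = FALSE, taper = 0,
                          detrend = TRUE)
  f_pg <- pg$freq[which.max(pg$spec)]
  expect_lt(abs(f_lomb - f_pg), 0.002 + max(diff(pg$freq)))
})

test_that("white-noise tachogram spreads power across bands by bandwidth", {
  # flat spectrum: each band's share approximates its width / 0.4
  fracs <- sapply(1:9, function(s) {
    prof <- subject_profile(base_sdrr = 20, lf_amp = 0, hf_amp = 0)
    rr <- generate_rr(prof, "focused", 300, seed = s)
    fd <- frequency_domain_features(lomb_scargle_psd(rr))
    c(fd$VLF, fd$LF, fd$HF) / fd$TP
  })
  med <- apply(fracs, 1, median)
  expect_lt(abs(med[1] - 0.04 / 0.4), 0.10)
  expect_lt(abs(med[2] - 0.11 / 0.4), 0.12)
  expect_lt(abs(med[3] - 0.25 / 0.4), 0.12)
})

test_that("band powers are additive and normalized powers complementary", {
  set.seed(5)
  for (i in 1:5) {
    f <- seq(0, 0.4, by = 0.002)
    psd <- structure(list(frequencies = f, power = rexp(length(f))),
                     class = "psd_estimate")
    fd <- frequency_domain_features(psd)
    expect_lt(abs(fd$VLF + fd$LF + fd$HF - fd$TP), 1e-9 * fd$TP)
    expect_identical(fd$nLF + fd$nHF, 100)
    expect_lt(abs(fd$LF_HF - fd$nLF / fd$nHF), 1e-9 * max(fd$LF_HF, 1))
  }
  # LF = 2 HF arithmetic case: rectangular bands
  f <- seq(0, 0.4, by = 0.002)
  p <- numeric(length(f))
  p[f >= 0.04 & f <= 0.15] <- 2 / 0.11
  p[f > 0.15 & f <= 0.4] <- 1 / 0.25
  fd <- frequency_domain_features(
    structure(list(frequencies = f, power = p), class = "psd_estimate"))
  expect_lt(abs(fd$LF_HF - 2), 0.1)
  expect_lt(abs(fd$nLF - 200 / 3), 2)
})

test_that("Poincare geometry follows the enforced RMSSD convention", {
  set.seed(8)
  for (i in 1:5) {
    rr <- rr_from_intervals(800 + rnorm(60, 0, 20))
    pc <- poincare_features(rr)
    td <- time_domain_features(rr)
    expect_lt(abs(pc$SD1 - td$RMSSD / sqrt(2)), 1e-9)
    expect_equal(pc$SD_ratio * pc$SD2_SD1, 1)
  }
  # alternating series: short-term variability dominates
  alt <- rr_from_intervals(rep(c(800, 900), 30))
  pc <- poincare_features(alt)
  expect_gt(pc$SD1, pc$SD2)
  expect_error(poincare_features(rr_from_intervals(rep(800, 10))),
               class = "distractr_degenerate_input")
})

test_that("extract_hrv equals the truth-channel features on clean input", {
  prof <- subject_profile(base_sdrr = 5)
  rr <- generate_rr(prof, "focused", 120, seed = 3)
  syn <- synthesize_ecg(rr, fs = 250, snr_db = Inf, seed = 1,
                        wander_amp = 0, powerline_amp = 0)
  v_ecg <- extract_hrv(syn$ecg)
  v_truth <- hrv_from_rr(build_rr_series(syn$r_times))
  expect_length(v_ecg, 14)
  expect_named(v_ecg, c("mRR", "SDRR", "RMSSD", "pNN50", "VLF", "LF", "HF",
                        "TP", "LF_HF", "nLF", "nHF", "SD_ratio", "ApEn",
                        "SampEn"))
  for (f in names(v_ecg))
    expect_lt(abs(v_ecg[[f]] - v_truth[[f]]),
              1e-3 * max(abs(v_truth[[f]]), 1e-6))
  expect_identical(v_ecg, extract_hrv(syn$ecg))  # deterministic
})

test_that("time reversal leaves the symmetric features unchanged", {
  rr <- generate_rr(subject_profile(), "focused", 120, seed = 6)
  rev_rr <- rr_from_intervals(rev(rr$intervals))
  a <- time_domain_features(rr); b <- time_domain_features(rev_rr)
  for (f in c("mRR", "SDRR", "RMSSD", "pNN50"))
    expect_equal(a[[f]], b[[f]])
  r <- 0.2 * sd(rr$intervals)
  expect_equal(sample_entropy(rr$intervals, 2, r),
               sample_entropy(rev(rr$intervals), 2, r))
})
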