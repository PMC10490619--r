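test_that("degenerate constant tachogram is exact", {
  prof <- subject_profile(base_mrr = 800, base_sdrr = 0, lf_amp = 0,
                          hf_amp = 0)
  rr <- generate_rr(prof, "focused", duration = 80, seed = 1)
  expect_length(rr$intervals, 100)
  expect_equal(rr$intervals, rep(800, 100))
})

test_that("generated mean RR matches the profile (law of large numbers)", {
  prof <- subject_profile()
  rr <- generate_rr(prof, "focused", duration = 300, seed = 1)
  sem <- sd(rr$intervals) / sqrt(length(rr$intervals))
  expect_lt(abs(mean(rr$intervals) - prof$base_mrr), 3 * sem + 1)
})

test_that("lf_scale injects LF power monotonically (noiseless generator)", {
  prof <- subject_profile(base_sdrr = 0)
  lf <- vapply(c(0.5, 1, 1.5, 2, 3), function(s) {
    eff <- condition_effects(lf_scale = s, tp_scale = 1, d_mrr = 0,
                             d_sdrr = 0)
    rr <- generate_rr(prof, "distracted", 300, seed = 9, effects = eff)
    frequency_domain_features(lomb_scargle_psd(rr))$LF
  }, numeric(1))
  expect_true(all(diff(lf) > 0))
})

test_that("generate_rr rejects bad durations and is deterministic", {
  prof <- subject_profile()
  expect_error(generate_rr(prof, "focused", duration = -5),
               class = "distractr_invalid_argument")
  expect_error(generate_rr(prof, "focused", duration = 30),
               class = "distractr_invalid_argument")
  a <- generate_rr(prof, "distracted", 120, seed = 42)
  b <- generate_rr(prof, "distracted", 120, seed = 42)
  expect_identical(a, b)
})

test_that("synthesized ECG places templates exactly", {
  # 60 s at 80 bpm constant -> exactly 80 beats, truth count conserved
  rr <- rr_from_intervals(rep(750, 80))
  syn <- synthesize_ecg(rr, fs = 250, snr_db = Inf, seed = 1,
                        wander_amp = 0, powerline_amp = 0)
  expect_length(syn$r_times, 81)  # planted peaks = intervals + 1
  expect_equal(length(syn$r_times) - 1, length(rr$intervals))
  # noiseless: the waveform argmax in each beat window is the planted R
  for (t in syn$r_times[seq(1, 81, by = 8)]) {
    tt <- rec_time(syn$ecg)
    win <- which(abs(tt - t) <= 0.2)
    i_max <- win[which.max(syn$ecg$samples[win])]
    expect_lt(abs(tt[i_max] - t), 1 / 250 + 1e-12)
  }
  expect_error(synthesize_ecg(rr, fs = 50),
               class = "distractr_invalid_argument")
})

test_that("GSR generator honours degenerate and deterministic contracts", {
  prof <- subject_profile(scr_rate = 0, base_tonic = 1.0)
  g <- generate_gsr(prof, "focused", 120, seed = 1, noise_sd = 0)
  # tonic drift is part of the model; with rate 0 there are no events
  expect_length(g$truth$onsets, 0)
  prof_flat <- subject_profile(scr_rate = 0, base_tonic = 1.0)
  g2 <- generate_gsr(prof_flat, "focused", 120, seed = 5, noise_sd = 0)
  expect_true(all(abs(g2$gsr$samples - 1.0) < 0.15))
  a <- generate_gsr(subject_profile(), "distracted", 120, seed = 3)
  b <- generate_gsr(subject_profile(), "distracted", 120, seed = 3)
  expect_identical(a, b)
  expect_error(generate_gsr(subject_profile(scr_rate = -1), "focused"),
               class = "distractr_invalid_argument")
})

test_that("behavioural generator enforces counts and configured effects", {
  prof <- subject_profile()
  beh <- generate_behavior(prof, "focused", n_stimuli = 150,
                           target_rate = 0.2, seed = 1)
  expect_equal(nrow(beh$stimuli), 150)
  expect_equal(sum(beh$stimuli$is_target), 30)
  perf <- generate_behavior(subject_profile(acc_p = 1), "focused",
                            seed = 2, fa_p = 0)
  expect_equal(perf$accuracy, 1)
  # Monte-Carlo check of the reaction-time effect
  f <- generate_behavior(prof, "focused", n_stimuli = 1000, seed = 11)
  d <- generate_behavior(prof, "distracted", n_stimuli = 1000, seed = 11)
  expect_gt(d$mean_rt, f$mean_rt)
  expect_true(d$rating %in% 1:2)
  expect_true(f$rating %in% 4:5)
  expect_error(generate_behavior(prof, "focused", n_stimuli = 0),
               class = "distractr_invalid_argument")
})

test_that("cohort has two sessions per subject and reproducible profiles", {
  co <- generate_cohort(30, seed = 4, duration = 60, include_ecg = FALSE)
  expect_length(co$sessions, 60)
  conds <- vapply(co$sessions, `[[`, "", "condition")
  expect_equal(sum(conds == "focused"), 30)
  expect_equal(sum(conds == "distracted"), 30)
  co2 <- generate_cohort(2, seed = 9, duration = 60, include_ecg = FALSE)
  co3 <- generate_cohort(2, seed = 9, duration = 60, include_ecg = FALSE)
  expect_identical(co2$profiles, co3$profiles)
  expect_identical(co2$sessions[[1]]$rr, co3$sessions[[1]]$rr)
  expect_error(generate_cohort(1), class = "distractr_invalid_argument")
})

test_that("truth-channel conservation holds across a cohort", {
  co <- generate_cohort(3, seed = 2, duration = 60, include_ecg = TRUE)
  for (s in co$sessions) {
    expect_equal(length(s$r_times), length(s$rr$intervals) + 1)
    expect_equal(length(s$gsr_truth$onsets), length(s$gsr_truth$amplitudes))
    expect_true(all(diff(s$gsr_truth$onsets) > 0))
    expect_true(all(s$gsr_truth$amplitudes > 0))
  }
})
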