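#' Subject profile for the synthetic cohort generator
#'
#' Per-subject baseline physiology. Defaults are centred on the focused
#' (non-fatigued) condition of a young male manual-labour cohort: mean RR
#' near 884 ms, a 0.10 Hz (Mayer-wave / blood-pressure) RR oscillation, a
#' 0.25 Hz respiratory oscillation, a tonic skin conductance level near
#' 1.2 uS and roughly a dozen spontaneous SCRs per minute during a vigilance
#' task.
#'
#' @param subject_id character id.
#' @param base_mrr mean RR baseline (ms), > 0.
#' @param base_sdrr SD of the white (beat-to-beat) RR noise (ms), >= 0.
#'   Note this is the broadband component only; measured SDRR also includes
#'   the two oscillations.
#' @param lf_amp amplitude of the 0.10 Hz RR oscillation (ms).
#' @param hf_amp amplitude of the 0.25 Hz RR oscillation (ms).
#' @param base_tonic tonic skin conductance level (microsiemens).
#' @param scr_rate spontaneous SCR rate (events/min), >= 0.
#' @param scr_amp_meanlog,scr_amp_sdlog lognormal parameters of SCR
#'   amplitudes (uS).
#' @param rt_mu reaction-time location (log-ms).
#' @param rt_sigma reaction-time scale (log-ms).
#' @param acc_p probability of a correct response to a target stimulus.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id = "S01",
                            base_mrr = 884, base_sdrr = 8,
                            lf_amp = 15, hf_amp = 20,
                            base_tonic = 1.2, scr_rate = 13,
                            scr_amp_meanlog = log(0.04), scr_amp_sdlog = 0.7,
                            rt_mu = log(450), rt_sigma = 0.2,
                            acc_p = 0.95) {
  check_scalar(base_mrr, "base_mrr", lower = .Machine$double.eps)
  check_scalar(base_sdrr, "base_sdrr", lower = 0)
  check_scalar(scr_rate, "scr_rate", lower = 0)
  check_scalar(acc_p, "acc_p", lower = 0, upper = 1)
  structure(list(subject_id = subject_id, base_mrr = base_mrr,
                 base_sdrr = base_sdrr, lf_amp = lf_amp, hf_amp = hf_amp,
                 base_tonic = base_tonic, scr_rate = scr_rate,
                 scr_amp_meanlog = scr_amp_meanlog,
                 scr_amp_sdlog = scr_amp_sdlog,
                 rt_mu = rt_mu, rt_sigma = rt_sigma, acc_p = acc_p),
            class = "subject_profile")
}

#' Condition effects applied under the distracted (fatigued) state
#'
#' Additive/multiplicative shifts injected into a session when
#' `condition = "distracted"`. Every sign is configurable; the defaults
#' follow the directions reported for fatigue-induced distraction:
#' higher mean RR, SDRR, LF and total RR power; longer first-SCR latency;
#' slower and less accurate continuous-performance-test behaviour; low
#' (1-2) versus high (4-5) concentration self-ratings.
#'
#' @param d_mrr additive mean-RR shift (ms).
#' @param d_sdrr additive shift of the broadband RR noise SD (ms).
#' @param lf_scale multiplier on the 0.10 Hz oscillation amplitude
#'   (LF power scales with its square).
#' @param tp_scale multiplier on total RR power (applied as `sqrt(tp_scale)`
#'   to every variability component).
#' @param d_latency additive first-SCR latency shift (s).
#' @param d_rt multiplicative reaction-time scale factor.
#' @param d_acc decrement of target-hit probability.
#' @param d_tonic additive tonic-level shift (uS).
#' @param d_scr_rate additive SCR-rate shift (events/min).
#' @param scr_amp_scale multiplier on SCR amplitudes.
#' @param likert_focused,likert_distracted admissible 5-point concentration
#'   ratings per condition.
#' @return An object of class `condition_effects`.
#' @export
condition_effects <- function(d_mrr = 10, d_sdrr = 2,
                              lf_scale = 1.6, tp_scale = 1.15,
                              d_latency = 2.5, d_rt = 1.15, d_acc = 0.12,
                              d_tonic = -0.05, d_scr_rate = -3,
                              scr_amp_scale = 1.0,
                              likert_focused = 4:5,
                              likert_distracted = 1:2) {
  vals <- c(d_mrr, d_sdrr, lf_scale, tp_scale, d_latency, d_rt, d_acc,
            d_tonic, d_scr_rate, scr_amp_scale)
  if (any(!is.finite(vals)))
    stopf("condition effect shifts must be finite",
          class = "distractr_invalid_argument")
  structure(list(d_mrr = d_mrr, d_sdrr = d_sdrr, lf_scale = lf_scale,
                 tp_scale = tp_scale, d_latency = d_latency, d_rt = d_rt,
                 d_acc = d_acc, d_tonic = d_tonic, d_scr_rate = d_scr_rate,
                 scr_amp_scale = scr_amp_scale,
                 likert_focused = likert_focused,
                 likert_distracted = likert_distracted),
            class = "condition_effects")
}

#' Null condition effects (no distracted shift on any channel)
#' @return A `condition_effects` object with all shifts at their neutral value.
#' @export
zero_effects <- function() {
  condition_effects(d_mrr = 0, d_sdrr = 0, lf_scale = 1, tp_scale = 1,
                    d_latency = 0, d_rt = 1, d_acc = 0, d_tonic = 0,
                    d_scr_rate = 0, scr_amp_scale = 1,
                    likert_focused = 1:5, likert_distracted = 1:5)
}

check_condition <- function(condition) {
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% c("focused", "distracted"))
    stopf("`condition` must be \"focused\" or \"distracted\"",
          class = "distractr_invalid_argument")
  condition
}

#' Generate a synthetic RR tachogram
#'
#' Sinusoid-plus-noise inter-beat model: the n-th interval is
#' `mrr + a_LF * sin(2*pi*0.10*t_n) + a_HF * sin(2*pi*0.25*t_n + phi) + e_n`
#' with `e_n ~ N(0, sdrr^2)` and `t_n` the cumulative beat time. Under the
#' distracted condition the mean shifts by `d_mrr`, the noise SD by `d_sdrr`,
#' the LF amplitude is multiplied by `lf_scale`, and all variability
#' components by `sqrt(tp_scale)`.
#'
#' @param profile a [subject_profile()].
#' @param condition `"focused"` or `"distracted"`.
#' @param duration recording length (s), >= 60.
#' @param seed integer seed; identical inputs give identical output.
#' @param effects a [condition_effects()].
#' @return An [rr_series()] whose first peak is at time 0.
#' @export
generate_rr <- function(profile, condition = "focused", duration = 300,
                        seed = 1, effects = condition_effects()) {
  check_condition(condition)
  if (!is.numeric(duration) || length(duration) != 1L || duration <= 0)
    stopf("`duration` must be positive", class = "distractr_invalid_argument")
  if (duration < 60)
    stopf("`duration` must be at least 60 s",
          class = "distractr_invalid_argument")
  dis <- condition == "distracted"
  mrr <- profile$base_mrr + if (dis) effects$d_mrr else 0
  tp <- if (dis) sqrt(effects$tp_scale) else 1
  sdrr <- (profile$base_sdrr + if (dis) effects$d_sdrr else 0) * tp
  a_lf <- profile$lf_amp * (if (dis) effects$lf_scale else 1) * tp
  a_hf <- profile$hf_amp * tp

  set.seed(seed)
  phi <- runif(1, 0, 2 * pi)
  n_max <- ceiling(duration * 1000 / max(mrr - 6 * sdrr - a_lf - a_hf, 300)) + 2L
  noise <- rnorm(n_max, 0, sdrr)
  times <- numeric(n_max + 1L)
  k <- 0L
  t_cur <- 0
  repeat {
    rr <- mrr + a_lf * sin(2 * pi * 0.10 * t_cur) +
      a_hf * sin(2 * pi * 0.25 * t_cur + phi) + noise[k + 1L]
    rr <- max(rr, 300)  # physiological floor
    if (t_cur + rr / 1000 > duration + 1e-9) break
    k <- k + 1L
    t_cur <- t_cur + rr / 1000
    times[k + 1L] <- t_cur
    if (k >= n_max) break
  }
  rr_series(times[seq_len(k + 1L)])
}

qrs_template <- function(fs) {
  # analytic QRS-like complex: tall Gaussian R wave flanked by symmetric
  # negative Q/S lobes; ~100 ms support, peak exactly at the centre sample
  half <- round(0.05 * fs)
  t <- (-half:half) / fs
  1.0 * exp(-0.5 * (t / 0.012)^2) -
    0.15 * exp(-0.5 * ((t + 0.028) / 0.011)^2) -
    0.15 * exp(-0.5 * ((t - 0.028) / 0.011)^2)
}

#' Synthesize an ECG waveform from an RR series
#'
#' Places a fixed QRS-like template (Gaussian R wave with symmetric negative
#' flanking lobes, ~100 ms support) at each R instant snapped to the sample
#' grid, then adds baseline wander (a 0.3 Hz sinusoid), a 50 Hz powerline
#' sinusoid, and white noise scaled to the requested SNR relative to the
#' clean beat train.
#'
#' @param rr an [rr_series()].
#' @param fs sampling rate (Hz), >= 100.
#' @param snr_db white-noise SNR in dB; `Inf` for noiseless.
#' @param seed integer seed.
#' @param wander_amp baseline-wander amplitude (mV); 0 disables.
#' @param powerline_amp 50 Hz amplitude (mV); 0 disables.
#' @return A list with `ecg` (an [ecg_recording()]) and `r_times`, the
#'   ground-truth R instants after grid snapping (s).
#' @export
synthesize_ecg <- function(rr, fs = 250, snr_db = 20, seed = 1,
                           wander_amp = 0.1, powerline_amp = 0.02) {
  stopifnot(inherits(rr, "rr_series"))
  if (!is.numeric(fs) || fs < 100)
    stopf("`fs` must be at least 100 Hz to resolve the QRS template",
          class = "distractr_invalid_argument")
  tmpl <- qrs_template(fs)
  half <- (length(tmpl) - 1L) %/% 2L
  pad0 <- half + round(0.2 * fs)  # keep the first beat clear of the edge
  r_idx <- round(rr$peak_times * fs) + pad0 + 1L
  n <- max(r_idx) + half + round(0.2 * fs)
  x <- numeric(n)
  off <- -half:half
  for (i in r_idx) x[i + off] <- x[i + off] + tmpl
  p_signal <- mean(x^2)

  set.seed(seed)
  tt <- (seq_len(n) - 1L) / fs
  if (wander_amp > 0)
    x <- x + wander_amp * sin(2 * pi * 0.3 * tt + runif(1, 0, 2 * pi))
  if (powerline_amp > 0)
    x <- x + powerline_amp * sin(2 * pi * 50 * tt + runif(1, 0, 2 * pi))
  if (is.finite(snr_db))
    x <- x + rnorm(n, 0, sqrt(p_signal / 10^(snr_db / 10)))
  start <- -pad0 / fs
  list(ecg = ecg_recording(x, fs, start_time = start),
       r_times = (r_idx - 1L) / fs + start)
}

bateman_raw <- function(t, tau1, tau2) exp(-t / tau1) - exp(-t / tau2)

#' Generate a synthetic skin-conductance recording
#'
#' Signal = slow tonic drift around the subject's baseline level + a train of
#' SCRs (Bateman-kernel impulses at Poisson onsets with lognormal amplitudes)
#' + white measurement noise. Under the distracted condition the tonic level
#' shifts by `d_tonic`, the SCR rate by `d_scr_rate`, amplitudes scale by
#' `scr_amp_scale`, and the first-event latency grows by `d_latency`.
#'
#' @param profile a [subject_profile()].
#' @param condition `"focused"` or `"distracted"`.
#' @param duration recording length (s).
#' @param fs sampling rate (Hz); wearable default 10.
#' @param seed integer seed.
#' @param effects a [condition_effects()].
#' @param noise_sd white measurement noise SD (uS); default 0.002,
#'   a realistic wearable-GSR quantization/noise floor.
#' @param tau1,tau2 Bateman decay/rise constants (s) used to shape events.
#' @return A list with `gsr` (a [gsr_recording()]) and `truth` (class
#'   `gsr_ground_truth`: `onsets` (s), `amplitudes` (uS), `condition`).
#' @export
generate_gsr <- function(profile, condition = "focused", duration = 300,
                         fs = 10, seed = 1, effects = condition_effects(),
                         noise_sd = 0.002, tau1 = 3.75, tau2 = 1.0) {
  check_condition(condition)
  check_scalar(duration, "duration", lower = 1)
  dis <- condition == "distracted"
  rate <- max(profile$scr_rate + if (dis) effects$d_scr_rate else 0, 0)
  tonic0 <- max(profile$base_tonic + if (dis) effects$d_tonic else 0, 0.05)
  amp_scale <- if (dis) effects$scr_amp_scale else 1

  set.seed(seed)
  n <- round(duration * fs) + 1L
  tt <- (seq_len(n) - 1L) / fs
  tonic <- tonic0 + 0.08 * tonic0 * sin(2 * pi * 0.002 * tt + runif(1, 0, 2 * pi)) +
    0.04 * tonic0 * sin(2 * pi * 0.005 * tt + runif(1, 0, 2 * pi))

  n_ev <- rpois(1, rate * duration / 60)
  onsets <- sort(runif(n_ev, 0.5, duration - 10))
  if (n_ev > 0 && dis) {
    onsets[1] <- onsets[1] + effects$d_latency
    onsets <- sort(onsets)
    onsets <- onsets[onsets < duration - 5]
  }
  onsets <- unique(onsets)
  amps <- rlnorm(length(onsets), profile$scr_amp_meanlog,
                 profile$scr_amp_sdlog) * amp_scale

  x <- tonic
  if (length(onsets)) {
    tpk <- log(tau1 / tau2) * tau1 * tau2 / (tau1 - tau2)
    peak <- bateman_raw(tpk, tau1, tau2)
    for (j in seq_along(onsets)) {
      rel <- tt - onsets[j]
      idx <- rel >= 0
      x[idx] <- x[idx] + amps[j] * bateman_raw(rel[idx], tau1, tau2) / peak
    }
  }
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  truth <- structure(list(onsets = onsets, amplitudes = amps,
                          condition = condition),
                     class = "gsr_ground_truth")
  list(gsr = gsr_recording(x, fs = fs, window_start = 0,
                           window_length = duration),
       truth = truth)
}

#' Generate behavioural (continuous performance test) responses
#'
#' Emulates a 5-min hazard-identification vigilance task: `n_stimuli`
#' stimuli of which `target_rate` contain a target; hits on targets are
#' Bernoulli with the subject's `acc_p` (minus `d_acc` when distracted),
#' reaction times are lognormal (location scaled by `d_rt` when distracted),
#' and a post-task 5-point concentration rating is drawn from the
#' condition's admissible set.
#'
#' @param profile a [subject_profile()].
#' @param condition `"focused"` or `"distracted"`.
#' @param n_stimuli number of stimuli (> 0); task default 150.
#' @param target_rate fraction of target stimuli in (0, 1); default 0.2.
#' @param seed integer seed.
#' @param effects a [condition_effects()].
#' @param fa_p false-alarm probability on non-targets.
#' @return A list of class `behavioral_record`: per-stimulus data frame
#'   (`is_target`, `responded`, `correct`, `rt_ms`), plus summary fields
#'   `mean_rt`, `accuracy`, `rating`.
#' @export
generate_behavior <- function(profile, condition = "focused",
                              n_stimuli = 150, target_rate = 0.2, seed = 1,
                              effects = condition_effects(), fa_p = 0.02) {
  check_condition(condition)
  if (!is.numeric(n_stimuli) || n_stimuli <= 0)
    stopf("`n_stimuli` must be positive", class = "distractr_invalid_argument")
  if (target_rate <= 0 || target_rate >= 1)
    stopf("`target_rate` must be in (0, 1)",
          class = "distractr_invalid_argument")
  dis <- condition == "distracted"
  p_hit <- min(max(profile$acc_p - if (dis) effects$d_acc else 0, 0), 1)
  mu <- profile$rt_mu + if (dis) log(effects$d_rt) else 0

  set.seed(seed)
  n_targets <- round(n_stimuli * target_rate)
  is_target <- rep(FALSE, n_stimuli)
  is_target[sample.int(n_stimuli, n_targets)] <- TRUE
  responded <- logical(n_stimuli)
  responded[is_target] <- runif(n_targets) < p_hit
  responded[!is_target] <- runif(n_stimuli - n_targets) <
    (fa_p * if (dis) 2 else 1)
  correct <- responded == is_target
  rt <- rep(NA_real_, n_stimuli)
  rt[responded] <- rlnorm(sum(responded), mu, profile$rt_sigma)
  likert <- if (dis) effects$likert_distracted else effects$likert_focused
  rating <- likert[sample.int(length(likert), 1)]
  structure(list(stimuli = data.frame(is_target = is_target,
                                      responded = responded,
                                      correct = correct, rt_ms = rt),
                 mean_rt = mean(rt, na.rm = TRUE),
                 accuracy = mean(correct), rating = rating,
                 condition = condition),
            class = "behavioral_record")
}

draw_profiles <- function(n_subjects) {
  rtnorm <- function(n, mu, sd, lo) pmax(rnorm(n, mu, sd), lo)
  data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subjects)),
    base_mrr = rnorm(n_subjects, 884, 25),
    base_sdrr = rtnorm(n_subjects, 8, 2, 3),
    lf_amp = rtnorm(n_subjects, 15, 4, 3),
    hf_amp = rtnorm(n_subjects, 20, 5, 3),
    base_tonic = rtnorm(n_subjects, 1.2, 0.4, 0.2),
    scr_rate = rtnorm(n_subjects, 13, 5, 2),
    scr_amp_meanlog = rnorm(n_subjects, log(0.04), 0.3),
    scr_amp_sdlog = rep(0.7, n_subjects),
    rt_mu = rnorm(n_subjects, log(450), 0.15),
    rt_sigma = rep(0.2, n_subjects),
    acc_p = pmin(pmax(rnorm(n_subjects, 0.95, 0.04), 0.7), 0.999),
    stringsAsFactors = FALSE)
}

#' Generate a paired-condition synthetic cohort
#'
#' Draws `n_subjects` subject profiles from documented hyperdistributions
#' (see the methods vignette) and produces one focused and one distracted
#' session per subject — RR tachogram, optional ECG waveform, GSR trace,
#' behavioural record, and the ground-truth channel. Session seeds are
#' derived from the cohort seed with [session_seed()].
#'
#' @param n_subjects number of subjects, >= 2 (study scale: 30).
#' @param effects a [condition_effects()].
#' @param seed integer cohort seed.
#' @param duration session length (s), default 300 (5-min task).
#' @param fs_ecg ECG sampling rate (Hz).
#' @param fs_gsr GSR sampling rate (Hz).
#' @param snr_db ECG white-noise SNR (dB).
#' @param include_ecg generate the raw ECG waveform per session (the stated
#'   study design); `FALSE` keeps only the ground-truth RR channel, for
#'   cheap structural tests.
#' @return An object of class `synthetic_cohort`: `profiles` data frame,
#'   `sessions` list (each with `subject_id`, `condition`, `rr`, `ecg`,
#'   `r_times`, `gsr`, `gsr_truth`, `behavior`), `effects`, `seed`.
#' @export
generate_cohort <- function(n_subjects = 30, effects = condition_effects(),
                            seed = 1, duration = 300, fs_ecg = 250,
                            fs_gsr = 10, snr_db = 20, include_ecg = TRUE) {
  if (!is.numeric(n_subjects) || n_subjects < 2)
    stopf("`n_subjects` must be at least 2",
          class = "distractr_invalid_argument")
  set.seed(session_seed(seed, 0))
  profiles <- draw_profiles(n_subjects)
  sessions <- vector("list", 2L * n_subjects)
  counter <- 0L
  for (i in seq_len(n_subjects)) {
    prof <- do.call(subject_profile, as.list(profiles[i, ]))
    for (cond in c("focused", "distracted")) {
      counter <- counter + 1L
      s_rr <- session_seed(seed, counter * 4L + 1L)
      s_ecg <- session_seed(seed, counter * 4L + 2L)
      s_gsr <- session_seed(seed, counter * 4L + 3L)
      s_beh <- session_seed(seed, counter * 4L + 4L)
      rr <- generate_rr(prof, cond, duration, seed = s_rr, effects = effects)
      ecg <- r_times <- NULL
      if (include_ecg) {
        syn <- synthesize_ecg(rr, fs = fs_ecg, snr_db = snr_db, seed = s_ecg)
        ecg <- syn$ecg
        r_times <- syn$r_times
      }
      g <- generate_gsr(prof, cond, duration, fs = fs_gsr, seed = s_gsr,
                        effects = effects)
      beh <- generate_behavior(prof, cond, seed = s_beh, effects = effects)
      sessions[[counter]] <- list(subject_id = prof$subject_id,
                                  condition = cond, rr = rr, ecg = ecg,
                                  r_times = r_times, gsr = g$gsr,
                                  gsr_truth = g$truth, behavior = beh)
    }
  }
  structure(list(profiles = profiles, sessions = sessions, effects = effects,
                 seed = seed, duration = duration),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects x 2 conditions (%d sessions), seed %d\n",
              nrow(x$profiles), length(x$sessions), x$seed))
  invisible(x)
}
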