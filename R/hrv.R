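#' Canonical names of the 14 HRV features
#' @return Character vector in canonical (time, frequency, nonlinear) order.
#' @export
hrv_feature_names <- function() {
  c("mRR", "SDRR", "RMSSD", "pNN50", "VLF", "LF", "HF", "TP",
    "LF_HF", "nLF", "nHF", "SD_ratio", "ApEn", "SampEn")
}

#' Compute the 14 HRV features from an RR series
#'
#' Time-domain (mRR, SDRR, RMSSD, pNN50), Lomb-Scargle frequency-domain
#' (VLF, LF, HF, TP, LF/HF, nLF, nHF), and nonlinear (SD1/SD2 ratio,
#' approximate and sample entropy) features of one recording.
#'
#' @param rr an [rr_series()].
#' @param grid_step spectral grid step (Hz).
#' @param detrend spectral detrending, `"none"` or `"linear"`.
#' @param m,r_factor entropy embedding dimension and tolerance factor;
#'   the tolerance `r = r_factor * sd(intervals)` is frozen per series
#'   before both entropies.
#' @return Named numeric vector of the 14 features.
#' @export
hrv_from_rr <- function(rr, grid_step = 0.002, detrend = "none",
                        m = 2, r_factor = 0.2) {
  td <- time_domain_features(rr)
  fd <- frequency_domain_features(
    lomb_scargle_psd(rr, grid_step = grid_step, detrend = detrend))
  pc <- poincare_features(rr)
  r <- r_factor * sd(rr$intervals)
  out <- c(mRR = td$mRR, SDRR = td$SDRR, RMSSD = td$RMSSD, pNN50 = td$pNN50,
           VLF = fd$VLF, LF = fd$LF, HF = fd$HF, TP = fd$TP,
           LF_HF = fd$LF_HF, nLF = fd$nLF, nHF = fd$nHF,
           SD_ratio = pc$SD_ratio,
           ApEn = approximate_entropy(rr$intervals, m = m, r = r),
           SampEn = sample_entropy(rr$intervals, m = m, r = r))
  out[hrv_feature_names()]
}

#' Extract the 14 HRV features from a raw ECG recording
#'
#' Full chain: band-pass filtering, Pan-Tompkins R detection, RR
#' construction with artifact correction, then [hrv_from_rr()]. Stage
#' failures are re-raised with the failing stage named.
#'
#' @param ecg an [ecg_recording()] of at least 60 s.
#' @param correction_threshold artifact-correction threshold for
#'   [build_rr_series()].
#' @param ... passed to [hrv_from_rr()].
#' @return Named numeric vector of the 14 features.
#' @export
extract_hrv <- function(ecg, correction_threshold = 0.3, ...) {
  stopifnot(inherits(ecg, "ecg_recording"))
  if (length(ecg$samples) < 60 * ecg$fs)
    stopf("HRV extraction needs at least 60 s of ECG",
          class = "distractr_insufficient_data")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("[%s] %s", name, conditionMessage(e),
            class = "distractr_stage_error"))
  }
  peaks <- stage("detect_r_peaks", detect_r_peaks(ecg))
  rr <- stage("build_rr_series",
              build_rr_series(peaks, correction_threshold))
  stage("hrv_from_rr", hrv_from_rr(rr, ...))
}
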