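# Session interchange format: `time_s,value` CSV plus a JSON sidecar
# (<file>.json) holding subject_id, condition, fs, units, signal kind.

#' Write a signal session to CSV with a JSON sidecar
#'
#' @param rec an [ecg_recording()] or [gsr_recording()].
#' @param path CSV destination; the sidecar goes to `<path>.json`.
#' @param subject_id,condition session key, stored in the sidecar.
#' @return `path`, invisibly.
#' @export
write_session <- function(rec, path, subject_id, condition) {
  kind <- if (inherits(rec, "ecg_recording")) "ecg" else "gsr"
  df <- data.frame(time_s = rec_time(rec), value = rec$samples)
  write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = subject_id, condition = condition,
               fs = rec$fs, units = if (kind == "ecg") "mV" else "uS",
               kind = kind, start_time = rec$start_time)
  if (kind == "gsr") {
    meta$window_start <- rec$window_start
    meta$window_length <- rec$window_length
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a signal session written by [write_session()]
#'
#' CSV dialect: comma-separated, header `time_s,value`, '.' decimal; the
#' sampling rate and units come from the JSON sidecar. EDF input is not
#' supported in this build (no EDF reader in the supported stack).
#'
#' @param path CSV path.
#' @param format `"csv"` (the only supported format).
#' @return The recording (class per the sidecar `kind`), with the sidecar
#'   metadata attached as attribute `meta`.
#' @export
load_signal <- function(path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "edf")
    stopf("EDF input is not supported in this build; convert to CSV",
          class = "distractr_format_error")
  if (!file.exists(path))
    stopf("file not found: %s", path, class = "distractr_format_error")
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stopf("missing JSON sidecar (fs metadata): %s", sidecar,
          class = "distractr_format_error")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$fs))
    stopf("sidecar lacks `fs`", class = "distractr_format_error")
  df <- read.csv(path)
  if (!all(c("time_s", "value") %in% names(df)))
    stopf("CSV must have header `time_s,value`",
          class = "distractr_format_error")
  if (any(diff(df$time_s) <= 0))
    stopf("non-monotonic timestamps in %s", path,
          class = "distractr_data_error")
  rec <- if (identical(meta$kind, "ecg")) {
    ecg_recording(df$value, meta$fs, meta$start_time %||% df$time_s[1])
  } else {
    gsr_recording(df$value, meta$fs,
                  start_time = meta$start_time %||% df$time_s[1],
                  window_start = meta$window_start %||% 0,
                  window_length = meta$window_length %||% 300)
  }
  attr(rec, "meta") <- meta
  rec
}

#' Write a synthetic cohort to disk
#'
#' One ECG and one GSR CSV (+ JSON sidecars) per session, a cohort
#' manifest CSV, and the ground truth (planted R peaks and SCR events) as
#' JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$sessions, function(s) {
    stem <- sprintf("%s_%s", s$subject_id, s$condition)
    ecg_path <- NA_character_
    if (!is.null(s$ecg)) {
      ecg_path <- file.path(dir, paste0(stem, "_ecg.csv"))
      write_session(s$ecg, ecg_path, s$subject_id, s$condition)
    }
    gsr_path <- file.path(dir, paste0(stem, "_gsr.csv"))
    write_session(s$gsr, gsr_path, s$subject_id, s$condition)
    truth <- list(subject_id = s$subject_id, condition = s$condition,
                  r_peak_times = if (!is.null(s$r_times)) s$r_times else
                    s$rr$peak_times,
                  scr_onsets = s$gsr_truth$onsets,
                  scr_amplitudes = s$gsr_truth$amplitudes,
                  behavior = list(mean_rt = s$behavior$mean_rt,
                                  accuracy = s$behavior$accuracy,
                                  rating = s$behavior$rating))
    jsonlite::write_json(truth, file.path(dir, paste0(stem, "_truth.json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(subject_id = s$subject_id, condition = s$condition,
               ecg = basename(ecg_path), gsr = basename(gsr_path),
               truth = paste0(stem, "_truth.json"))
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "cohort_manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Per-session feature extraction over a whole cohort
#'
#' Runs the HRV and EDA extraction chains on every session and collects
#' the behavioural summaries.
#'
#' @param cohort a [generate_cohort()] result.
#' @param from_truth use the planted (ground-truth) RR series instead of
#'   running R-peak detection on the waveform; also the fallback when the
#'   cohort was generated without ECG waveforms.
#' @param scr_threshold SCR amplitude threshold (uS).
#' @return List of data frames: `hrv` (14 features), `eda` (7 features),
#'   `behavior` (mean RT ms, accuracy, rating), each keyed by
#'   `(subject_id, condition)`.
#' @export
cohort_features <- function(cohort, from_truth = FALSE,
                            scr_threshold = 0.01) {
  hrv <- list(); eda <- list(); beh <- list()
  for (i in seq_along(cohort$sessions)) {
    s <- cohort$sessions[[i]]
    v <- if (from_truth || is.null(s$ecg)) {
      hrv_from_rr(s$rr)
    } else {
      extract_hrv(s$ecg)
    }
    hrv[[i]] <- data.frame(subject_id = s$subject_id,
                           condition = s$condition, t(v))
    e <- extract_eda(s$gsr, threshold = scr_threshold)
    eda[[i]] <- data.frame(subject_id = s$subject_id,
                           condition = s$condition, t(e))
    beh[[i]] <- data.frame(subject_id = s$subject_id,
                           condition = s$condition,
                           mean_rt = s$behavior$mean_rt,
                           accuracy = s$behavior$accuracy,
                           rating = s$behavior$rating)
  }
  fix <- function(l) {
    d <- do.call(rbind, l)
    names(d) <- sub("^t\\.", "", names(d))
    d
  }
  list(hrv = fix(hrv), eda = fix(eda), behavior = fix(beh))
}
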