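#' Build a validated pipeline run configuration
#'
#' Collects every tunable of the simulate-extract-stats-train chain in one
#' structure. All defaults are the documented package defaults; everything
#' here can also be supplied from a YAML file via [load_run_config()].
#'
#' @param seed integer master seed.
#' @param n_subjects cohort size (study scale: 30).
#' @param effects a [condition_effects()].
#' @param duration session length (s).
#' @param fs_ecg,fs_gsr sampling rates (Hz).
#' @param snr_db ECG noise level (dB).
#' @param scr_threshold SCR amplitude threshold (uS).
#' @param entropy_m,entropy_r embedding dimension and tolerance factor.
#' @param alpha statistics gate level, in (0, 1).
#' @param families classifier families to evaluate.
#' @param feature_sets any of `"hrv"`, `"gsr"`, `"combined"`.
#' @param grids named list of hyperparameter grids per family; defaults to
#'   compact grids (knn k in 1..5; svm C in {1, 32, 128} x gamma in
#'   {1/16, 0.5}; lda; rf 100 trees) sized for interactive runs — pass
#'   [default_grid()] results for the full protocol grids.
#' @param elimination run t-ranked backward elimination per family
#'   (substantially slower); off by default.
#' @param from_truth extract HRV from the planted RR series instead of the
#'   synthesized waveform.
#' @param out_dir output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n_subjects = 30,
                       effects = condition_effects(), duration = 300,
                       fs_ecg = 250, fs_gsr = 10, snr_db = 20,
                       scr_threshold = 0.01, entropy_m = 2,
                       entropy_r = 0.2, alpha = 0.05,
                       families = c("knn", "svm_rbf"),
                       feature_sets = c("hrv", "gsr", "combined"),
                       grids = NULL, elimination = FALSE,
                       from_truth = FALSE, out_dir = tempfile("distractr_run")) {
  check_scalar(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  check_scalar(n_subjects, "n_subjects", lower = 2)
  families <- match.arg(families, classifier_families(), several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, c("hrv", "gsr", "combined"),
                            several.ok = TRUE)
  if (is.null(grids)) {
    grids <- list(
      knn = lapply(1:5, function(k) list(k = k)),
      svm_rbf = {
        g <- expand.grid(C = c(1, 32, 128), gamma = c(2^-4, 0.5))
        lapply(seq_len(nrow(g)), function(i) as.list(g[i, ]))
      },
      lda = list(list()),
      rf = list(list(trees = 100, max_depth = Inf),
                list(trees = 100, max_depth = 5)))
  }
  structure(list(seed = seed, n_subjects = n_subjects, effects = effects,
                 duration = duration, fs_ecg = fs_ecg, fs_gsr = fs_gsr,
                 snr_db = snr_db, scr_threshold = scr_threshold,
                 entropy_m = entropy_m, entropy_r = entropy_r,
                 alpha = alpha, families = families,
                 feature_sets = feature_sets, grids = grids,
                 elimination = elimination, from_truth = from_truth,
                 out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Flat keys mirror the [run_config()] arguments; an `effects` section
#' maps to [condition_effects()] fields.
#'
#' @param path YAML file.
#' @param ... overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
load_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$effects)) y$effects <- do.call(condition_effects, y$effects)
  do.call(run_config, modifyList(y, list(...)))
}

set_features <- function(set) {
  switch(set, hrv = hrv_feature_names(), gsr = gsr_feature_names(),
         combined = c(hrv_feature_names(), gsr_feature_names()))
}

#' Run the full pipeline: simulate, extract, test, classify
#'
#' Stages: (1) generate the paired-condition cohort and write the session
#' files; (2) extract the 14 HRV + 7 EDA features per session into a
#' feature CSV; (3) produce the gated paired-statistics table over the 21
#' physiological features and the behavioural measures; (4) for each
#' configured feature set x classifier family, grid-search + LOSO-evaluate
#' (optionally with backward elimination) and write evaluation reports.
#' A manifest with config hash, per-file checksums and timestamps is
#' written last; a stage failure aborts with the stage named.
#'
#' @param config a [run_config()].
#' @return The manifest (list), invisibly; on disk under
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage [%s] failed: %s", name, conditionMessage(e),
            class = "distractr_stage_error"))
  }
  message("stage simulate: ", config$n_subjects, " subjects")
  cohort <- stage("simulate",
    generate_cohort(config$n_subjects, config$effects, config$seed,
                    duration = config$duration, fs_ecg = config$fs_ecg,
                    fs_gsr = config$fs_gsr, snr_db = config$snr_db,
                    include_ecg = !config$from_truth))
  sess_dir <- file.path(config$out_dir, "sessions")
  stage("simulate", write_cohort(cohort, sess_dir))

  message("stage extract: 21 features per session")
  feats <- stage("extract",
    cohort_features(cohort, from_truth = config$from_truth,
                    scr_threshold = config$scr_threshold))
  matrix <- stage("extract", build_feature_matrix(feats$hrv, feats$eda,
                                                  config$duration))
  feat_path <- file.path(config$out_dir, "features.csv")
  write.csv(matrix, feat_path, row.names = FALSE)

  message("stage stats: gated paired comparisons")
  phys <- stage("stats", stats_table(as.data.frame(matrix),
                                     alpha = config$alpha))
  beh <- stage("stats", stats_table(feats$behavior, alpha = config$alpha))
  stats_path <- file.path(config$out_dir, "stats.csv")
  write.csv(rbind(phys, beh), stats_path, row.names = FALSE)

  reports <- list()
  for (fset in config$feature_sets) {
    cols <- set_features(fset)
    sub <- matrix[, c("subject_id", "condition", cols)]
    class(sub) <- class(matrix)
    for (fam in config$families) {
      tag <- paste(fset, fam, sep = "_")
      message("stage train-eval: ", tag)
      grid <- config$grids[[fam]] %||% default_grid(fam)
      rep <- stage(paste0("train-eval/", tag), {
        if (config$elimination) {
          el <- backward_elimination(sub, fam, grid, seed = config$seed)
          write.csv(el$trace,
                    file.path(config$out_dir,
                              paste0("elimination_", tag, ".csv")),
                    row.names = FALSE)
          cv <- loso_cv(sub, fam, el$best_hp, features = el$best_features,
                        seed = config$seed)
        } else {
          gs <- grid_search(sub, fam, grid, seed = config$seed)
          cv <- loso_cv(sub, fam, gs$hp, seed = config$seed)
        }
        ev <- evaluate(cv)
        out <- file.path(config$out_dir, paste0("report_", tag, ".json"))
        jsonlite::write_json(
          list(feature_set = fset, family = fam, hp = cv$hp,
               TP = ev$TP, FN = ev$FN, TN = ev$TN, FP = ev$FP,
               accuracy = ev$accuracy, sensitivity = ev$sensitivity,
               specificity = ev$specificity, precision = ev$precision,
               F1 = ev$F1, AUC = ev$AUC),
          out, auto_unbox = TRUE, digits = NA)
        if (!is.null(ev$roc_points))
          write.csv(ev$roc_points,
                    file.path(config$out_dir, paste0("roc_", tag, ".csv")),
                    row.names = FALSE)
        ev
      })
      reports[[tag]] <- rep
    }
  }

  cfg_path <- file.path(config$out_dir, "config.yaml")
  cfg <- config
  cfg$effects <- unclass(cfg$effects)
  cfg$grids <- NULL
  yaml::write_yaml(unclass(cfg), cfg_path)
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(config$out_dir, "manifest.json"))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    created = format(t0), finished = format(Sys.time()),
    r_version = R.version.string,
    package_version = as.character(utils::packageVersion("distractr")),
    n_sessions = length(cohort$sessions),
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(manifest = manifest, reports = reports,
                 stats = rbind(phys, beh), features = matrix))
}
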