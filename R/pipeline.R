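# End-to-end orchestration: synthesize or ingest recordings, preprocess,
# balance, split, normalize, featurize, train, evaluate, generate.

#' Run configuration
#'
#' Bundles every tunable of an end-to-end run. A run's echoed config (written
#' to the output directory) reproduces the run bit-for-bit: every stochastic
#' stage derives its seed from the global seed via [derive_seed()].
#'
#' @param synthetic A [synthetic_spec()], or `NULL` when `input_paths` given.
#' @param input_paths Character vector of recording files (EDF or
#'   matrix+sidecar), used when `synthetic` is `NULL`.
#' @param mains Mains frequency for the notch filter.
#' @param feature A [feature_config()].
#' @param feature_subset Descriptor subset, see [assemble_features()].
#' @param cvae A [cvae_config()].
#' @param split_frac Training fraction of the stratified split.
#' @param label_policy Evaluation label policy, see [cvae_posterior_mean()].
#' @param out_dir Output directory for run artifacts.
#' @param seed Global run seed.
#' @return Object of class `run_config`.
#' @export
run_config <- function(synthetic = synthetic_spec(), input_paths = NULL,
                       mains = 50, feature = feature_config(),
                       feature_subset = c("stft", "hurst", "dfa", "kolmen",
                                          "cd", "lle"),
                       cvae = cvae_config(), split_frac = 0.8,
                       label_policy = "marginal",
                       out_dir = tempfile("eegcvae_run_"), seed = 1L) {
  structure(as.list(environment()), class = "run_config")
}

config_echo <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  yaml::as.yaml(strip(cfg))
}

#' Execute the full pipeline
#'
#' Stages: (1) synthesize or read recordings; (2) montage restriction,
#' zero-phase filtering, resampling to 125 Hz, epoching; (3) amplitude QC;
#' (4) class balancing with inverse-frequency weights; (5) stratified 80/20
#' split; (6) per-recording normalization fitted on the training split; (7)
#' feature extraction; (8) CVAE training; (9) evaluation on the held-out
#' split (metrics, Wilson CI). Artifacts (feature tables, checkpoint,
#' metrics, manifest with per-stage counts, config echo) are written to
#' `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @return List with `features_train`, `features_test`, `fit`, `metrics`,
#'   `manifest`, `class_weights`, `out_dir` (invisibly also on disk).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed)
  log_path <- file.path(cfg$out_dir, "run.log")
  logf <- function(fmt, ...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
    cat(msg, "\n", file = log_path, append = TRUE)
  }
  writeLines(config_echo(cfg), file.path(cfg$out_dir, "config.yaml"))

  recs <- if (!is.null(cfg$synthetic)) {
    logf("synthesizing cohort")
    gen_two_class_recordings(cfg$synthetic)
  } else {
    logf("reading %d recordings", length(cfg$input_paths))
    lapply(cfg$input_paths, read_recording)
  }
  manifest$n_recordings <- length(recs)

  logf("preprocessing")
  windows <- unlist(lapply(recs, preprocess_recording, mains = cfg$mains),
                    recursive = FALSE)
  manifest$windows_segmented <- length(windows)

  qc <- amplitude_qc(windows)
  manifest$windows_qc_dropped <- length(qc$dropped)
  manifest$windows_qc_kept <- length(qc$kept)

  bal <- balance_and_weight(qc$kept, seed = derive_seed(cfg$seed, "balance"))
  manifest$windows_balanced <- length(bal$windows)
  manifest$class_weights <- as.list(bal$class_weights)

  meta <- window_meta(bal$windows)
  split <- stratified_split(meta$label, meta$subject_id, frac = cfg$split_frac,
                            seed = derive_seed(cfg$seed, "split"))
  manifest$windows_train <- length(split$train)
  manifest$windows_test <- length(split$test)

  stats <- fit_norm_stats(bal$windows[split$train])
  normed <- apply_norm(bal$windows, stats)
  write_norm_config(stats, bal$class_weights,
                    file.path(cfg$out_dir, "norm_stats.txt"))

  logf("featurizing %d windows", length(normed))
  feats <- featurize_windows(normed, cfg$feature, cfg$feature_subset)
  ftr <- feats[split$train, , drop = FALSE]
  fte <- feats[split$test, , drop = FALSE]
  utils::write.csv(ftr, file.path(cfg$out_dir, "features_train.csv"),
                   row.names = FALSE)
  utils::write.csv(fte, file.path(cfg$out_dir, "features_test.csv"),
                   row.names = FALSE)

  fc <- feature_columns(feats)
  cvae_cfg <- cfg$cvae
  cvae_cfg$d_feat <- length(fc)
  cvae_cfg$seed <- derive_seed(cfg$seed, "cvae")
  logf("training CVAE (%d features, %d epochs)", length(fc), cvae_cfg$epochs)
  fit <- cvae_train(as.matrix(ftr[, fc]), ftr$label, cvae_cfg,
                    class_weights = unname(bal$class_weights),
                    x_val = as.matrix(fte[, fc]), y_val = fte$label,
                    label_policy = cfg$label_policy)
  cvae_save(fit, file.path(cfg$out_dir, "checkpoint.rds"))
  utils::write.csv(fit$trace, file.path(cfg$out_dir, "training_trace.csv"),
                   row.names = FALSE)

  pred <- cvae_predict(fit, as.matrix(fte[, fc]), y_true = fte$label,
                       label_policy = cfg$label_policy)
  metrics <- compute_metrics(fte$label, pred)
  ci <- wilson_ci(metrics$accuracy, metrics$n)
  manifest$test_accuracy <- metrics$accuracy
  manifest$wilson_ci <- as.list(ci)
  write_metrics_report(metrics, ci, file.path(cfg$out_dir, "metrics.txt"))
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  logf("done: accuracy %.4f", metrics$accuracy)

  invisible(list(features_train = ftr, features_test = fte, fit = fit,
                 metrics = metrics, manifest = manifest,
                 class_weights = bal$class_weights, out_dir = cfg$out_dir))
}

# Structured-text metrics report (key/value lines + confusion block).
write_metrics_report <- function(metrics, ci, path) {
  lines <- c(sprintf("accuracy %.6f", metrics$accuracy),
             sprintf("precision %.6f", metrics$precision),
             sprintf("recall %.6f", metrics$recall),
             sprintf("macro_f1 %.6f", metrics$macro_f1),
             sprintf("n %d", metrics$n),
             sprintf("wilson_lower %.6f", ci["lower"]),
             sprintf("wilson_upper %.6f", ci["upper"]),
             "confusion:",
             apply(metrics$confusion, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
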