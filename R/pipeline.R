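#' Pipeline configuration
#'
#' One document driving the whole pipeline: either a synthetic cohort spec
#' or an input directory of recordings, plus preprocessing, feature,
#' statistics and classification settings. Serializable to/from YAML or
#' JSON; unknown keys are rejected.
#'
#' @param cohort A [cohort_spec()] (synthetic input), or `NULL` when
#'   `input_dir` is given.
#' @param input_dir Directory with `manifest.csv` + EDF files (real or
#'   previously simulated input); ignored when `cohort` is given.
#' @param line_freq Notch frequency, Hz.
#' @param band Band-pass corners `c(low, high)`, Hz.
#' @param artifact_regression Run reference-channel artifact regression.
#' @param epoch_len Epoch length, s.
#' @param aggregation `"per-epoch"` or `"per-task-mean"` for the feature
#'   table handed to classification (statistics always additionally use the
#'   per-task-mean table).
#' @param pairing A [channel_pairing()].
#' @param select_threshold Feature-importance selection threshold.
#' @param split A [split_spec()].
#' @param models Classifier families to run.
#' @param run_stats,run_classification Stage toggles.
#' @param seed Master seed (propagated to the cohort spec and the split
#'   when they do not set their own).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), input_dir = NULL,
                            line_freq = 60, band = c(0.5, 44),
                            artifact_regression = TRUE, epoch_len = 10,
                            aggregation = "per-epoch",
                            pairing = channel_pairing(),
                            select_threshold = 0.95,
                            split = split_spec(),
                            models = model_families(),
                            run_stats = TRUE, run_classification = TRUE,
                            seed = 1L) {
  structure(
    list(cohort = cohort, input_dir = input_dir, line_freq = line_freq,
         band = band, artifact_regression = artifact_regression,
         epoch_len = epoch_len, aggregation = aggregation, pairing = pairing,
         select_threshold = select_threshold, split = split, models = models,
         run_stats = run_stats, run_classification = run_classification,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_to_list <- function(config) {
  list(
    cohort = if (is.null(config$cohort)) NULL else list(
      n_stroke = config$cohort$n_stroke,
      n_control = config$cohort$n_control,
      stroke_profiles = lapply(config$cohort$profiles$stroke, as.list),
      control_profiles = lapply(config$cohort$profiles$control, as.list),
      asymmetry_factor = config$cohort$asymmetry_factor,
      blink_rate = config$cohort$blink_rate,
      emg_burst_rate = config$cohort$emg_burst_rate,
      task_sequence = as.list(config$cohort$task_sequence),
      sampling_rate = config$cohort$sampling_rate,
      seed = config$cohort$seed
    ),
    input_dir = config$input_dir,
    line_freq = config$line_freq,
    band = config$band,
    artifact_regression = config$artifact_regression,
    epoch_len = config$epoch_len,
    aggregation = config$aggregation,
    pairing = lapply(config$pairing$pairs, identity),
    select_threshold = config$select_threshold,
    split = unclass(config$split),
    models = config$models,
    run_stats = config$run_stats,
    run_classification = config$run_classification,
    seed = config$seed
  )
}

#' Serialize / deserialize a pipeline config as YAML
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the [pipeline_config()]. Unknown keys in the document are rejected.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- c("cohort", "input_dir", "line_freq", "band",
             "artifact_regression", "epoch_len", "aggregation", "pairing",
             "select_threshold", "split", "models", "run_stats",
             "run_classification", "seed")
  unknown <- setdiff(names(doc), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cohort <- NULL
  if (!is.null(doc$cohort)) {
    ck <- doc$cohort
    mk_prof <- function(lst) {
      lapply(lst, function(p) do.call(band_profile, p))
    }
    cohort <- cohort_spec(
      n_stroke = ck$n_stroke, n_control = ck$n_control,
      stroke_profiles = mk_prof(ck$stroke_profiles),
      control_profiles = mk_prof(ck$control_profiles),
      asymmetry_factor = ck$asymmetry_factor,
      blink_rate = ck$blink_rate, emg_burst_rate = ck$emg_burst_rate,
      task_sequence = as.data.frame(ck$task_sequence,
                                    stringsAsFactors = FALSE),
      sampling_rate = ck$sampling_rate, seed = ck$seed
    )
  }
  sp <- doc$split %||% list()
  pipeline_config(
    cohort = cohort, input_dir = doc$input_dir,
    line_freq = doc$line_freq %||% 60,
    band = unlist(doc$band %||% c(0.5, 44)),
    artifact_regression = doc$artifact_regression %||% TRUE,
    epoch_len = doc$epoch_len %||% 10,
    aggregation = doc$aggregation %||% "per-epoch",
    pairing = channel_pairing(doc$pairing %||%
                                list(c("C1", "C2"), c("T7", "T8"))),
    select_threshold = doc$select_threshold %||% 0.95,
    split = split_spec(sp$train_fraction %||% 0.7,
                       sp$stratified %||% TRUE,
                       sp$group_aware %||% TRUE,
                       sp$seed %||% (doc$seed %||% 1L)),
    models = unlist(doc$models %||% model_families()),
    run_stats = doc$run_stats %||% TRUE,
    run_classification = doc$run_classification %||% TRUE,
    seed = doc$seed %||% 1L
  )
}

#' Preprocess one recording
#'
#' The standard cleaning chain: notch, band-pass, optional
#' reference-channel artifact regression, 10-s epoching.
#'
#' @param recording An [eeg_recording()].
#' @param config A [pipeline_config()] (only its preprocessing fields are
#'   used).
#' @return List of [eeg_epoch()].
#' @export
preprocess_recording <- function(recording, config = pipeline_config()) {
  rec <- notch_filter(recording, config$line_freq)
  rec <- bandpass_filter(rec, config$band[1], config$band[2])
  if (config$artifact_regression) rec <- remove_artifacts(rec)
  epoch_recording(rec, config$epoch_len)
}

#' Run the full analysis pipeline
#'
#' Simulate-or-read the cohort, preprocess every subject, extract per-epoch
#' features, assemble feature tables, and (as configured) run the group
#' statistics and the classification experiment. All stage outputs are
#' written under `out_dir` as CSV plus a machine-readable JSON run manifest
#' (config hash, seed, package version); a rerun with the same config and
#' seed regenerates byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisible list with elements `features` (per-epoch
#'   `feature_table`), `task_means`, `comparisons`, `ranking`, `results`
#'   (classification metric rows), and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("qeeg_run_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  recordings <- if (!is.null(config$cohort)) {
    generate_cohort(config$cohort)
  } else if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    stop("config must provide a cohort spec or an input_dir")
  }

  epoch_rows <- lapply(recordings, function(rec) {
    epochs <- tryCatch(preprocess_recording(rec, config),
                       error = function(e) {
                         stop("preprocessing failed for subject ",
                              rec$subject_id, ": ", conditionMessage(e))
                       })
    extract_features(epochs, config$pairing)
  })
  feature_df <- do.call(rbind, epoch_rows)
  per_epoch <- build_feature_table(feature_df, "per-epoch")
  task_means <- build_feature_table(feature_df, "per-task-mean")
  utils::write.csv(per_epoch, file.path(out_dir, "features_per_epoch.csv"),
                   row.names = FALSE)
  utils::write.csv(task_means, file.path(out_dir, "features_task_means.csv"),
                   row.names = FALSE)

  comparisons <- NULL; ranking <- NULL
  if (isTRUE(config$run_stats)) {
    screened <- screen_features(task_means)
    comparisons <- compare_groups(screened)
    ranking <- rank_features(screen_features(per_epoch))
    utils::write.csv(comparisons, file.path(out_dir, "group_comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(ranking, file.path(out_dir, "feature_importance.csv"),
                     row.names = FALSE)
  }

  results <- NULL
  if (isTRUE(config$run_classification)) {
    table <- if (config$aggregation == "per-epoch") per_epoch else task_means
    results <- run_experiment(table, models = config$models,
                              spec = config$split,
                              select_threshold = config$select_threshold)
    utils::write.csv(results, file.path(out_dir, "classification_results.csv"),
                     row.names = FALSE)
    roc <- attr(results, "roc")
    roc_df <- do.call(rbind, lapply(names(roc), function(k) {
      cbind(data.frame(dataset_model = k, stringsAsFactors = FALSE), roc[[k]])
    }))
    utils::write.csv(roc_df, file.path(out_dir, "roc_points.csv"),
                     row.names = FALSE)
  }

  config_path <- file.path(out_dir, "config.yaml")
  write_config(config, config_path)
  manifest <- list(
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(config_path)),
    seed = config$seed,
    n_subjects = length(recordings),
    datasets = c(sort(unique(per_epoch$task)), "all"),
    package_version = as.character(utils::packageVersion("qeegstroke"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(features = per_epoch, task_means = task_means,
                 comparisons = comparisons, ranking = ranking,
                 results = results, manifest = manifest, out_dir = out_dir))
}
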