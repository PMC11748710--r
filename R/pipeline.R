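#' Pipeline configuration
#'
#' One structured object carrying every tunable of the end-to-end pipeline;
#' round-trips losslessly through YAML so runs are reproducible from the
#' config file alone.
#'
#' @param range_lo,range_hi,interval histogram settings, see [hist_config()].
#' @param lambda ridge penalty.
#' @param standardize z-score features before ridge fitting.
#' @param shap_mode,shap_permutations,shap_seed Shapley settings.
#' @param shap_floor,redundancy_threshold selection-rule settings.
#' @param split_fraction,split_seed train/test split.
#' @param n_per_class,sim_seed synthetic-dataset settings.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(range_lo = 5, range_hi = 150, interval = 5,
                            lambda = 1, standardize = TRUE,
                            shap_mode = "sampled", shap_permutations = 200,
                            shap_seed = 1, shap_floor = 0.015,
                            redundancy_threshold = 0.95,
                            split_fraction = 0.7, split_seed = 1,
                            n_per_class = 50, sim_seed = 1) {
  structure(list(range_lo = range_lo, range_hi = range_hi,
                 interval = interval, lambda = lambda,
                 standardize = standardize, shap_mode = shap_mode,
                 shap_permutations = shap_permutations,
                 shap_seed = shap_seed, shap_floor = shap_floor,
                 redundancy_threshold = redundancy_threshold,
                 split_fraction = split_fraction, split_seed = split_seed,
                 n_per_class = n_per_class, sim_seed = sim_seed),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return \code{write_pipeline_config} invisibly returns \code{path};
#'   \code{read_pipeline_config} returns the config.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

config_hist <- function(config)
  hist_config(config$range_lo, config$range_hi, config$interval)

#' Simulate a synthetic dataset to disk
#'
#' Writes per-sample image/mask PNG pairs plus a manifest CSV
#' (sample_id, label, seed, image, mask).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
oct_simulate <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- sim_config(n_per_class = config$n_per_class, seed = config$sim_seed)
  ds <- generate_dataset(sim)
  manifest <- data.frame(
    sample_id = vapply(ds$images, `[[`, "", "sample_id"),
    label = as.character(ds$labels),
    seed = sim$seed + seq_along(ds$images))
  manifest$image <- paste0(manifest$sample_id, ".png")
  manifest$mask <- paste0(manifest$sample_id, "_mask.png")
  for (k in seq_along(ds$images))
    write_nucleus_image(ds$images[[k]],
                        file.path(out_dir, manifest$image[k]),
                        file.path(out_dir, manifest$mask[k]))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Extract a feature table from images on disk
#'
#' Reads the manifest written by [oct_simulate()] (or an equivalent CSV with
#' columns sample_id, label, image, mask), extracts the 27 features per
#' sample, and writes \code{features.csv}. Unreadable samples are skipped
#' with a recorded per-sample error; the run continues.
#'
#' @param in_dir directory containing \code{manifest.csv} and the images.
#' @param config a [pipeline_config()].
#' @param out_csv output CSV path (default \code{features.csv} in
#'   \code{in_dir}).
#' @return Invisibly, the feature table; attribute \code{errors} lists
#'   skipped samples.
#' @export
oct_extract <- function(in_dir, config = pipeline_config(),
                        out_csv = file.path(in_dir, "features.csv")) {
  manifest <- utils::read.csv(file.path(in_dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  hc <- config_hist(config)
  rows <- list(); errors <- character(0)
  for (k in seq_len(nrow(manifest))) {
    rec <- manifest[k, ]
    row <- tryCatch({
      im <- read_nucleus_image(file.path(in_dir, rec$image),
                               file.path(in_dir, rec$mask),
                               sample_id = rec$sample_id, label = rec$label)
      extract_features(im, hc)
    }, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", rec$sample_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(row)) rows[[rec$sample_id]] <- row
  }
  if (length(errors) > 0)
    warning("skipped ", length(errors), " sample(s): ",
            paste(errors, collapse = "; "))
  out <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  out <- cbind(sample_id = names(rows), out, stringsAsFactors = FALSE)
  out$label <- manifest$label[match(out$sample_id, manifest$sample_id)]
  rownames(out) <- NULL
  write_feature_csv(out, out_csv)
  invisible(structure(out, errors = errors))
}

#' Importance analysis and feature selection on a feature table
#'
#' Runs the Shapley/correlation importance report and the selection rule;
#' writes \code{importance.csv}, \code{importance_pcc_matrix.csv} and
#' \code{selected.json} when \code{out_dir} is given.
#'
#' @param table feature table (data.frame or CSV path).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return List with \code{report} and \code{selected}.
#' @export
oct_analyze <- function(table, config = pipeline_config(), out_dir = NULL) {
  if (is.character(table)) table <- read_feature_csv(table)
  report <- importance_report(
    table, mode = config$shap_mode,
    n_permutations = config$shap_permutations, seed = config$shap_seed,
    split_fraction = config$split_fraction, split_seed = config$split_seed,
    lambda = config$lambda)
  rule <- selection_rule(config$shap_floor, config$redundancy_threshold)
  selected <- select_features(report, rule)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_importance_csv(report, file.path(out_dir, "importance.csv"))
    write_selection_json(selected, rule, file.path(out_dir, "selected.json"))
  }
  list(report = report, selected = selected)
}

participant_split <- function(table, fraction, seed) {
  if ("participant" %in% names(table)) {
    ids <- unique(table$participant)
    set.seed(seed)
    train_ids <- sample(ids, max(1, round(fraction * length(ids))))
    table$participant %in% train_ids
  } else {
    split_train_test(table$label, fraction, seed)
  }
}

#' Train the ridge ensemble and evaluate on a held-out split
#'
#' Splits at the participant level when a \code{participant} column exists
#' (so eyes/images of one person never straddle the split), otherwise by
#' stratified rows; fits EMRR on the selected features and reports the five
#' evaluation metrics. Writes \code{model.json}, \code{metrics.csv} and
#' \code{metrics_confusion.csv} when \code{out_dir} is given.
#'
#' @param table feature table (data.frame or CSV path).
#' @param selected feature names to train on (default: all).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return List with \code{model}, \code{confusion}, \code{metrics},
#'   \code{train} (the split indicator).
#' @export
oct_train_eval <- function(table, selected = NULL,
                           config = pipeline_config(), out_dir = NULL) {
  if (is.character(table)) table <- read_feature_csv(table)
  train <- participant_split(table, config$split_fraction, config$split_seed)
  if (!all(severity_levels() %in% table$label[train]))
    stop("class absent from training split")
  model <- fit_emrr(table[train, , drop = FALSE], features = selected,
                    lambda = config$lambda, standardize = config$standardize)
  pred <- predict(model, table[!train, , drop = FALSE])
  cm <- confusion(table$label[!train], pred)
  metrics <- compute_metrics(cm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_emrr_json(model, file.path(out_dir, "model.json"))
    write_metrics_csv(metrics, file.path(out_dir, "metrics.csv"), cm)
  }
  list(model = model, confusion = cm, metrics = metrics, train = train)
}

#' Histogram-setting ablation
#'
#' Re-extracts features and re-runs train/eval for every combination of
#' intensity range (0--255 vs 5--150) and bin width (10 vs 5) on the same
#' images and the same split, yielding one metrics row per setting.
#'
#' @param images list of labeled [nucleus_image()] objects.
#' @param config a [pipeline_config()].
#' @param out_csv optional output CSV path.
#' @return Data.frame with one row per setting: range, interval, the five
#'   macro metrics and overall accuracy.
#' @export
oct_ablate <- function(images, config = pipeline_config(), out_csv = NULL) {
  settings <- expand.grid(lo = c(0, 5), interval = c(10, 5))
  settings$hi <- ifelse(settings$lo == 0, 255, 150)
  rows <- lapply(seq_len(nrow(settings)), function(k) {
    s <- settings[k, ]
    tab <- extract_feature_table(images, hist_config(s$lo, s$hi, s$interval))
    res <- oct_train_eval(tab, config = config)
    macro <- res$metrics$per_class["macro", ]
    data.frame(range = sprintf("%d-%d", s$lo, s$hi), interval = s$interval,
               ACC = macro$ACC, PRE = macro$PRE, SEN = macro$SEN,
               SPE = macro$SPE, F1 = macro$F1,
               overall_accuracy = res$metrics$overall_accuracy)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}
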