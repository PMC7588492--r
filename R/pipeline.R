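#' Configuration of an end-to-end experiment
#'
#' Bundles everything a full run needs: the synthetic-cohort
#' configuration, the train/test split (85/15, matched pairs kept
#' together), the hyperparameter candidates, ensemble size, the target
#' sensitivity for threshold calibration, the comparator for the
#' head-to-head harness, and the seeds. Defaults are desk-scale: 300
#' admissions and a 3-member ensemble run in minutes on one CPU; the
#' reference design uses a 10-member ensemble.
#'
#' @param cohort an [cohort_config()].
#' @param train_fraction fraction of matched pairs assigned to training.
#' @param candidates list of [rnn_hyperparams()].
#' @param n_members ensemble size.
#' @param target_sensitivity sensitivity floor for threshold calibration.
#' @param comparator list: `type` `"degraded"` (ensemble predictions
#'   shrunk toward 0.5 plus noise -- a stand-in second predictor for the
#'   comparison harness) or `"creatinine_only"` (a reduced model trained
#'   on the creatinine channel alone); `shrink`, `noise_sd` for the
#'   degraded type.
#' @param imbalanced_incidence optional AKI incidence (e.g. 0.1) for an
#'   additional imbalanced evaluation of the test set; `NULL` skips it.
#' @param seed master seed; every stage derives its own stream from it.
#' @param out_dir optional directory; when given, the manifest and all
#'   report tables are written there.
#' @return object of class `aki_experiment_config`.
#' @export
experiment_config <- function(cohort = cohort_config(),
                              train_fraction = 0.85,
                              candidates = list(
                                rnn_hyperparams("gru", hidden = 16),
                                rnn_hyperparams("rnn", hidden = 16)),
                              n_members = 3,
                              target_sensitivity = 0.85,
                              comparator = list(type = "degraded",
                                                shrink = 0.45,
                                                noise_sd = 0.15),
                              imbalanced_incidence = NULL,
                              seed = 1,
                              out_dir = NULL) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(cohort = cohort, train_fraction = train_fraction,
                 candidates = candidates, n_members = n_members,
                 target_sensitivity = target_sensitivity,
                 comparator = comparator,
                 imbalanced_incidence = imbalanced_incidence,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "aki_experiment_config")
}

comparator_predictions <- function(config, point_preds, grids, seed) {
  type <- config$comparator$type
  if (type == "degraded") {
    with_seed(seed, {
      r <- 0.5 + config$comparator$shrink * (point_preds$risk - 0.5) +
        stats::rnorm(nrow(point_preds), 0, config$comparator$noise_sd)
    })
    clamp(r, 0.001, 0.999)
  } else if (type == "creatinine_only") {
    abort("creatinine_only comparator is produced inside run_experiment")
  } else {
    abort(sprintf("unknown comparator type '%s'", type))
  }
}

# Restrict grids to the creatinine channel (reduced single-feature model).
reduce_grids <- function(grids, channels = "creatinine") {
  purrr::map(grids, function(g) {
    g$values <- g$values[, c("time_h", channels), drop = FALSE]
    g$mask <- g$mask[, c("time_h", channels), drop = FALSE]
    g
  })
}

#' Guard against fitting leakage
#'
#' Errors unless the object's recorded fit-provenance hash matches the
#' given admission ids -- the audit used by [run_experiment()] to refuse
#' preprocessing components fitted on anything but the training split.
#'
#' @param object a fitted `aki_scaler` or `aki_text_model`.
#' @param ids the admission ids (scaler) or training texts (text model)
#'   the object must have been fitted on.
#' @export
assert_fit_provenance <- function(object, ids) {
  h <- attr(object, "fitted_on") %||% object$fitted_on
  if (!identical(h, rlang::hash(sort(ids)))) {
    abort("fit provenance mismatch: component was not fitted on the training split")
  }
  invisible(TRUE)
}

#' Run the complete experiment
#'
#' Executes the whole design on synthetic data: generate -> label and
#' exclude -> match controls to cases on observation length -> 85/15
#' pair-preserving split -> preprocess (text model and scaler fitted on
#' the training split only) -> five-fold cross-validated hyperparameter
#' selection -> uniform ensemble -> sensitivity-targeted threshold ->
#' full-series test evaluation with clustered CIs -> quasi-random
#' prediction points -> head-to-head comparison against the configured
#' comparator (DeLong, paired t on the score S, calibration) ->
#' time-to-event stratified report. All randomness derives from the
#' config seed; rerunning the same config reproduces every table.
#'
#' @param config an [experiment_config()].
#' @return object of class `aki_experiment`: list with the cohort,
#'   labels, windows, matched pairs, split, fitted components,
#'   `full_series_report` (threshold-dependent and threshold-free metrics
#'   with ICC-adjusted CIs), `point_comparison`, `tte_report`, and the
#'   run `manifest`. Reports are also written to `config$out_dir` if set.
#' @export
run_experiment <- function(config) {
  cohort <- generate_cohort(config$cohort)
  labels <- label_cohort(cohort)
  counts <- list(generated = nrow(labels),
                 excluded = sum(labels$excluded))
  ok <- labels[!labels$excluded, ]
  windows <- build_observation_windows(cohort, labels)
  wl <- dplyr::left_join(ok, windows, by = "admission_id")

  cases <- wl[wl$label == 1, c("admission_id", "length_h")]
  controls <- wl[wl$label == 0, c("admission_id", "length_h")]
  if (nrow(cases) > nrow(controls)) {
    warn(sprintf("dropping %d unmatched cases (more cases than controls)",
                 nrow(cases) - nrow(controls)))
    cases <- utils::head(dplyr::arrange(cases, .data$admission_id),
                         nrow(controls))
  }
  pairs <- match_cases_controls(cases, controls)
  counts$cases <- nrow(cases); counts$controls_pool <- nrow(controls)

  pair_ids <- pairs$pair_id
  n_train <- round(config$train_fraction * length(pair_ids))
  train_pairs <- with_seed(child_seed(config$seed, "split"),
                           sample(pair_ids, n_train))
  split_of <- ifelse(pairs$pair_id %in% train_pairs, "train", "test")
  train_ids <- c(pairs$case_id[split_of == "train"],
                 pairs$control_id[split_of == "train"])
  test_ids <- c(pairs$case_id[split_of == "test"],
                pairs$control_id[split_of == "test"])
  counts$train <- length(train_ids); counts$test <- length(test_ids)

  # preprocessing components: training split only
  tx_train <- cohort$surgery_text[
    cohort$surgery_text$admission_id %in% train_ids, ]
  text_model <- suppressWarnings(
    fit_surgery_text_model(tx_train$text, tx_train$category,
                           on_rare = "drop"))
  trained <- build_feature_grids(cohort, windows, labels, text_model,
                                 ids = train_ids)
  scaler <- trained$scaler
  assert_fit_provenance(scaler, train_ids)
  test_grids <- build_feature_grids(cohort, windows, labels, text_model,
                                    scaler = scaler, ids = test_ids)$grids

  cv <- cross_validate(trained$grids, labels, config$candidates,
                       pairs = pairs, seed = child_seed(config$seed, "cv"))
  ensemble <- train_ensemble(trained$grids, cv$best_hp,
                             base_seed = child_seed(config$seed, "ens"),
                             n_members = config$n_members)
  thr <- calibrate_threshold(cv$oof, target = config$target_sensitivity)

  test_pred <- predict_risk_cohort(ensemble, test_grids, labels)
  full_report <- evaluate_predictions(test_pred, threshold = thr$threshold)

  # head-to-head harness at one quasi-random point per test admission
  test_windows <- windows[windows$admission_id %in% test_ids, ]
  pts <- sample_prediction_points(test_windows,
                                  seed = child_seed(config$seed, "points"))
  tp_split <- split(test_pred, test_pred$admission_id)
  point_pred <- purrr::map_dfr(seq_len(nrow(pts)), function(i) {
    d <- tp_split[[pts$admission_id[i]]]
    dplyr::mutate(d[pts$step[i] + 1L, ], point_h = pts$point_h[i])
  })
  comp_risk <- if (config$comparator$type == "creatinine_only") {
    red_train <- reduce_grids(trained$grids)
    red_test <- reduce_grids(test_grids)
    red_fit <- train_ensemble(red_train, cv$best_hp,
                              base_seed = child_seed(config$seed, "red"),
                              n_members = config$n_members)
    red_pred <- predict_risk_cohort(red_fit, red_test)
    dplyr::inner_join(red_pred,
                      point_pred[, c("admission_id", "time_h")],
                      by = c("admission_id", "time_h"))$risk
  } else {
    comparator_predictions(config, point_pred, test_grids,
                           child_seed(config$seed, "comp"))
  }
  point_data <- point_pred %>%
    dplyr::mutate(risk_comparator = comp_risk) %>%
    dplyr::left_join(test_windows[, c("admission_id", "end_h", "length_h")],
                     by = "admission_id") %>%
    dplyr::rename(window_end_h = "end_h", window_length_h = "length_h")

  comparison <- compare_predictors(point_data, risk, risk_comparator)
  point_metrics <- dplyr::bind_rows(
    dplyr::mutate(compute_metrics(point_data, risk = risk, threshold = 0.5),
                  predictor = "model"),
    dplyr::mutate(compute_metrics(point_data, risk = risk_comparator,
                                  threshold = 0.5),
                  predictor = "comparator"))
  calib <- dplyr::bind_rows(
    dplyr::mutate(hosmer_lemeshow(point_data, risk = risk),
                  predictor = "model"),
    dplyr::mutate(hosmer_lemeshow(point_data, risk = risk_comparator),
                  predictor = "comparator"))
  tte <- dplyr::bind_rows(
    dplyr::mutate(stratify_by_time_to_event(point_data), predictor = "model"),
    dplyr::mutate(stratify_by_time_to_event(
      dplyr::mutate(point_data, risk = .data$risk_comparator)),
      predictor = "comparator"))

  imbalanced <- NULL
  if (!is.null(config$imbalanced_incidence)) {
    inc <- config$imbalanced_incidence
    te <- ok[ok$admission_id %in% test_ids, ]
    ctrl_ids <- te$admission_id[te$label == 0]
    n_cases_keep <- max(1, round(length(ctrl_ids) * inc / (1 - inc)))
    case_ids <- with_seed(child_seed(config$seed, "imb"),
                          sample(te$admission_id[te$label == 1],
                                 min(n_cases_keep, sum(te$label == 1))))
    sub <- test_pred[test_pred$admission_id %in% c(ctrl_ids, case_ids), ]
    imbalanced <- evaluate_predictions(sub, threshold = thr$threshold)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("akirisk")),
    r_version = R.version.string,
    seed = config$seed,
    cohort_seed = config$cohort$seed,
    counts = counts,
    selected_hp = format(cv$best_hp),
    threshold = thr$threshold,
    train_ids_hash = rlang::hash(sort(train_ids)),
    scaler_fitted_on = attr(scaler, "fitted_on"),
    text_model_fitted_on = text_model$fitted_on,
    excluded = labels[labels$excluded,
                      c("admission_id", "exclusion_reason")]
  )

  out <- structure(list(
    config = config, cohort = cohort, labels = labels, windows = windows,
    pairs = pairs, split = tibble::tibble(
      admission_id = c(train_ids, test_ids),
      split = rep(c("train", "test"), c(length(train_ids), length(test_ids)))),
    text_model = text_model, scaler = scaler, cv = cv, ensemble = ensemble,
    threshold = thr, test_predictions = test_pred,
    full_series_report = full_report,
    imbalanced_report = imbalanced,
    prediction_points = point_data,
    point_comparison = list(tests = comparison, metrics = point_metrics,
                            calibration = calib),
    tte_report = tte,
    manifest = manifest
  ), class = "aki_experiment")

  if (!is.null(config$out_dir)) write_experiment(out, config$out_dir)
  out
}

#' @export
print.aki_experiment <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    paste0("<aki_experiment> %d admissions (%d excluded), %d train / %d",
           " test\n  model %s, threshold %.3f\n  test AUC %.3f, mean",
           " MSE_pat %.3f\n"),
    m$counts$generated, m$counts$excluded, m$counts$train, m$counts$test,
    m$selected_hp, m$threshold,
    x$full_series_report$estimate[x$full_series_report$metric == "auc"],
    attr(x$full_series_report, "mse_pat")))
  invisible(x)
}

#' Write every report of an experiment to disk
#'
#' Plain-text outputs only: the run manifest as JSON, the three report
#' tables and the per-point predictions as CSV.
#'
#' @param experiment an `aki_experiment`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(experiment$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(drop_list_cols(experiment$full_series_report),
                   file.path(dir, "full_series_report.csv"),
                   row.names = FALSE)
  utils::write.csv(drop_list_cols(experiment$point_comparison$metrics),
                   file.path(dir, "point_metrics.csv"), row.names = FALSE)
  utils::write.csv(drop_list_cols(experiment$tte_report),
                   file.path(dir, "time_to_event_report.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$prediction_points,
                   file.path(dir, "prediction_points.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(delong = experiment$point_comparison$tests$delong,
         score_test = experiment$point_comparison$tests$score_test,
         calibration = drop_list_cols(experiment$point_comparison$calibration)),
    file.path(dir, "comparison.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

drop_list_cols <- function(df) {
  df[, !purrr::map_lgl(df, is.list), drop = FALSE]
}
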