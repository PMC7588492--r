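#' Hyperparameters of the recurrent risk model
#'
#' The learning rate is fixed at 0.001 (Adam); it is a constant of the
#' training procedure, not a tunable. Tunable axes are the recurrent cell
#' type, the hidden width and the number of epochs; the shipped default
#' candidate set is a desk-scale configuration choice, not a claim about
#' any particular production search space.
#'
#' @param cell `"gru"` or `"rnn"` (tanh cell).
#' @param hidden hidden-state width.
#' @param epochs maximum training epochs.
#' @param val_fraction fraction of training admissions held out inside
#'   each fit for early stopping (0 disables).
#' @param patience epochs without validation improvement before stopping.
#' @return object of class `aki_hyperparams`.
#' @export
rnn_hyperparams <- function(cell = c("gru", "rnn"), hidden = 16,
                            epochs = 20, val_fraction = 0.15, patience = 4) {
  cell <- match.arg(cell)
  stopifnot(hidden > 0, epochs > 0)
  structure(list(cell = cell, hidden = as.integer(hidden),
                 epochs = as.integer(epochs), learning_rate = 0.001,
                 val_fraction = val_fraction, patience = as.integer(patience)),
            class = "aki_hyperparams")
}

#' @export
format.aki_hyperparams <- function(x, ...) {
  sprintf("%s(h=%d, epochs=%d, lr=%g)", x$cell, x$hidden, x$epochs,
          x$learning_rate)
}

#' @export
print.aki_hyperparams <- function(x, ...) {
  cat("<aki_hyperparams>", format(x), "\n"); invisible(x)
}

# Feature matrix (T x F) of a grid, fixed column order.
grid_matrix <- function(grid) {
  as.matrix(grid$values[, setdiff(names(grid$values), "time_h"), drop = FALSE])
}

# Glorot-style initial weights drawn from the R RNG (seed upstream). The
# readout layer (last hidden+1 entries) starts at zero so an untrained
# model predicts exactly 0.5 everywhere: without signal in the labels,
# training has nothing to move it away from the constant predictor.
init_weights <- function(n_features, hp) {
  n <- cpp_rnn_n_weights(n_features, hp$hidden, hp$cell)
  w <- stats::rnorm(n, 0, 1 / sqrt(hp$hidden + n_features))
  w[(n - hp$hidden):n] <- 0
  w
}

#' Fit one recurrent risk model
#'
#' Trains a single-member model on per-admission feature grids with the
#' Adam optimizer at the fixed learning rate 0.001, minimising the mean
#' per-step binary cross-entropy against the constant per-patient target
#' (every step of an AKI case is a positive example). Training is causal:
#' the recurrence runs forward only, so the prediction at step i depends
#' only on inputs up to i. A slice of the training admissions is held out
#' for early stopping. The seed controls the weight initialisation, the
#' validation slice and the per-epoch presentation order.
#'
#' @param grids named list of scaled `aki_grid`s with `label` fields.
#' @param hp an [rnn_hyperparams()] object.
#' @param seed integer.
#' @return object of class `aki_rnn`: weights, hyperparameters, loss
#'   history, feature roster.
#' @export
fit_rnn <- function(grids, hp, seed = 1) {
  stopifnot(length(grids) > 0)
  X <- purrr::map(grids, grid_matrix)
  y <- purrr::map_dbl(grids, function(g) g$label)
  if (anyNA(y)) abort("all training grids need labels")
  feats <- colnames(X[[1]])
  n <- length(X)
  fit <- with_seed(seed, {
    w0 <- init_weights(length(feats), hp)
    n_val <- if (hp$val_fraction > 0) max(2L, round(hp$val_fraction * n)) else 0L
    val_idx <- if (n_val > 0 && n - n_val >= 2) sample(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)
    ord <- t(vapply(seq_len(hp$epochs),
                    function(e) sample(tr_idx),
                    integer(length(tr_idx))))
    cpp_rnn_train(unname(X), y, hp$cell, hp$hidden, w0, ord,
                  hp$learning_rate, as.integer(val_idx), hp$patience, 5.0)
  })
  structure(list(weights = fit$weights, hp = hp, features = feats,
                 train_loss = fit$train_loss, val_loss = fit$val_loss,
                 best_epoch = fit$best_epoch, seed = seed),
            class = "aki_rnn")
}

#' Train a uniform ensemble of recurrent risk models
#'
#' Fits `n_members` models with identical hyperparameters but different
#' initialisation seeds (`base_seed`, `base_seed + 1`, ...) and hence
#' different weight draws, validation slices and data orders. The
#' ensemble prediction is the unweighted mean of the member
#' probabilities, which stabilises the seed-to-seed variability of any
#' single member.
#'
#' @param grids named list of scaled training grids.
#' @param hp an [rnn_hyperparams()].
#' @param base_seed first member seed.
#' @param n_members ensemble size (10 in the reference design;
#'   smaller for desk-scale runs).
#' @return object of class `aki_ensemble`.
#' @export
train_ensemble <- function(grids, hp, base_seed = 1, n_members = 10) {
  stopifnot(n_members >= 1)
  members <- purrr::map(seq_len(n_members) - 1L,
                        function(k) fit_rnn(grids, hp, seed = base_seed + k))
  structure(list(members = members, hp = hp, base_seed = base_seed),
            class = "aki_ensemble")
}

#' Per-step risk predictions for one admission
#'
#' Runs every ensemble member over the feature grid and averages the
#' per-step probabilities with equal weights. Output is aligned to the
#' grid timestamps; step i uses only inputs at steps `<= i`.
#'
#' @param object an `aki_ensemble` or single `aki_rnn`.
#' @param grid a scaled `aki_grid` preprocessed with the
#'   training-fitted scaler and text model.
#' @return tibble `admission_id`, `time_h`, `risk`.
#' @export
predict_risk <- function(object, grid) {
  feats <- setdiff(names(grid$values), "time_h")
  members <- if (inherits(object, "aki_ensemble")) object$members else
    list(object)
  if (!identical(feats, members[[1]]$features)) {
    abort("feature roster of the grid does not match the trained model")
  }
  X <- grid_matrix(grid)
  p <- purrr::map(members, function(mem) {
    as.numeric(cpp_rnn_predict(X, mem$weights, mem$hp$cell, mem$hp$hidden))
  })
  tibble::tibble(
    admission_id = grid$admission_id %||% NA_character_,
    time_h = grid$values$time_h,
    risk = Reduce(`+`, p) / length(p)
  )
}

#' Per-step risk predictions for many admissions
#'
#' @param object ensemble or single model.
#' @param grids named list of scaled grids.
#' @param labels optional label tibble to join a `label` column.
#' @return long tibble `admission_id`, `time_h`, `risk` (and `label`).
#' @export
predict_risk_cohort <- function(object, grids, labels = NULL) {
  out <- purrr::map_dfr(grids, function(g) predict_risk(object, g))
  if (!is.null(labels)) {
    out <- dplyr::left_join(
      out, dplyr::select(labels, "admission_id", "label"),
      by = "admission_id")
  }
  out
}

# Stratified, pair-preserving fold assignment at admission level.
make_folds <- function(labels, pair_of, n_folds, seed) {
  # group admissions by pair (controls share their case's pair id)
  grp <- tibble::tibble(
    admission_id = labels$admission_id,
    label = labels$label,
    pair = pair_of[labels$admission_id]
  )
  pairs <- grp %>%
    dplyr::group_by(.data$pair) %>%
    dplyr::summarise(ids = list(.data$admission_id),
                     has_case = max(.data$label), .groups = "drop")
  # shuffle, then deal case-bearing and case-free groups round-robin
  # separately so every fold keeps balanced class proportions
  with_seed(seed, {
    pairs <- pairs[sample(nrow(pairs)), ]
  })
  pairs <- dplyr::arrange(pairs, dplyr::desc(.data$has_case))
  pairs$fold <- rep_len(seq_len(n_folds), nrow(pairs))
  fold_of <- stats::setNames(
    rep(pairs$fold, lengths(pairs$ids)), unlist(pairs$ids))
  fold_of[labels$admission_id]
}

#' Five-fold cross-validated hyperparameter selection
#'
#' Splits training admissions into folds at the admission level --
#' stratified by label and keeping each matched case-control pair in the
#' same fold -- trains every candidate on each 4/5, predicts the held-out
#' fold, and pools all out-of-fold per-step predictions into one AUC per
#' candidate. The candidate with the highest pooled out-of-fold AUC wins
#' (ties: first in the list); its out-of-fold predictions are returned for
#' threshold calibration.
#'
#' @param grids named list of scaled training grids (with labels).
#' @param labels label tibble covering these admissions.
#' @param candidates list of [rnn_hyperparams()] objects.
#' @param pairs optional matched-cohort tibble (keeps pairs together).
#' @param n_folds number of folds (default 5).
#' @param seed integer; drives fold assignment and member training.
#' @return list: `best_hp`, `oof` (tibble of out-of-fold predictions of
#'   the best candidate), `cv_auc` (per-candidate tibble), `folds`.
#' @export
cross_validate <- function(grids, labels, candidates, pairs = NULL,
                           n_folds = 5, seed = 1) {
  if (length(candidates) == 0) abort("no hyperparameter candidates supplied")
  labels <- labels[labels$admission_id %in% names(grids), ]
  pair_of <- if (!is.null(pairs)) {
    p <- c(stats::setNames(pairs$pair_id, pairs$case_id),
           stats::setNames(pairs$pair_id, pairs$control_id))
    out <- p[labels$admission_id]
    # unmatched admissions become their own group
    out[is.na(out)] <- paste0("solo_", which(is.na(out)))
    stats::setNames(as.character(out), labels$admission_id)
  } else {
    stats::setNames(labels$admission_id, labels$admission_id)
  }
  fold <- make_folds(labels, pair_of, n_folds, child_seed(seed, "folds"))
  results <- purrr::imap(candidates, function(hp, ci) {
    oof <- purrr::map_dfr(seq_len(n_folds), function(f) {
      tr_ids <- labels$admission_id[fold != f]
      te_ids <- labels$admission_id[fold == f]
      # the training seed is shared across candidates (per fold) so that
      # identical candidates score identically and ties break by order
      fit <- fit_rnn(grids[tr_ids], hp, seed = child_seed(seed, c("cv", f)))
      predict_risk_cohort(fit, grids[te_ids], labels)
    })
    list(hp = hp, oof = oof, auc = auc_rank(oof$risk, oof$label))
  })
  aucs <- purrr::map_dbl(results, "auc")
  best <- which.max(aucs)  # first index on ties
  list(
    best_hp = results[[best]]$hp,
    oof = results[[best]]$oof,
    cv_auc = tibble::tibble(
      candidate = purrr::map_chr(candidates, format),
      auc = aucs),
    folds = fold
  )
}

#' Calibrate the decision threshold to a target sensitivity
#'
#' Finds the largest threshold t such that the pooled per-step sensitivity
#' of the out-of-fold calibration predictions (`risk >= t` positive) is at
#' least the target -- i.e. the k-th largest positive-class prediction
#' with `k = ceiling(target * n_pos)`. Choosing the largest such t gives
#' the best specificity compatible with the sensitivity floor. Thresholds
#' at the upper boundary are shifted just below 1 by `eps` so they remain
#' usable cut-points.
#'
#' @param oof tibble of pooled out-of-fold predictions (`risk`, `label`).
#' @param target target sensitivity (default 0.85).
#' @param eps boundary resolution (default `1e-6`).
#' @return object of class `aki_threshold`: list with `threshold`,
#'   `target`, `achieved_sensitivity`, `provenance` hash.
#' @export
calibrate_threshold <- function(oof, target = 0.85, eps = 1e-6) {
  stopifnot(target > 0, target <= 1)
  pos <- oof$risk[oof$label == 1]
  if (length(pos) == 0 || max(pos) <= 0) {
    abort("target sensitivity unreachable: no usable positive predictions")
  }
  k <- ceiling(target * length(pos))
  t <- sort(pos, decreasing = TRUE)[k]
  t <- min(max(t, eps), 1 - eps)
  structure(list(threshold = t, target = target,
                 achieved_sensitivity = mean(pos >= t),
                 provenance = rlang::hash(oof)),
            class = "aki_threshold")
}

#' @export
print.aki_threshold <- function(x, ...) {
  cat(sprintf(
    "<aki_threshold> %.4f (target sensitivity %.2f, achieved %.3f)\n",
    x$threshold, x$target, x$achieved_sensitivity))
  invisible(x)
}
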