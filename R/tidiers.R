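#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a metrics report into a plain tibble
#'
#' @param x an `aki_metrics_report`.
#' @param ... unused.
#' @return tibble of metric, estimate, SE and CI columns.
#' @export
tidy.aki_metrics_report <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' @rdname tidy.aki_metrics_report
#' @export
glance.aki_metrics_report <- function(x, ...) {
  tibble::tibble(
    mse_pat = attr(x, "mse_pat"),
    threshold = attr(x, "threshold"),
    icc = x$icc[1],
    de = x$de[x$metric == "auc"],
    n = x$n[1], k = x$k[1],
    n_eff = x$n_eff[x$metric == "auc"]
  )
}

#' Tidy the head-to-head comparison
#'
#' @param x an `aki_comparison`.
#' @param ... unused.
#' @return tibble with one row per test (DeLong, paired t on S).
#' @export
tidy.aki_comparison <- function(x, ...) {
  tibble::tibble(
    test = c("delong_auc", "paired_t_score"),
    estimate_a = c(x$delong$auc_a, x$score_test$mean_s_a),
    estimate_b = c(x$delong$auc_b, x$score_test$mean_s_b),
    statistic = c(x$delong$z, x$score_test$t),
    p_value = c(x$delong$p_value, x$score_test$p_value)
  )
}

#' Tidy / summarise a trained ensemble
#'
#' `tidy()` returns one row per member (seed, epochs used, final losses);
#' `glance()` one row for the whole ensemble.
#'
#' @param x an `aki_ensemble`.
#' @param ... unused.
#' @export
tidy.aki_ensemble <- function(x, ...) {
  purrr::imap_dfr(x$members, function(mem, i) {
    tibble::tibble(
      member = i, seed = mem$seed, best_epoch = mem$best_epoch,
      final_train_loss = utils::tail(mem$train_loss, 1),
      best_val_loss = if (length(mem$val_loss)) min(mem$val_loss) else NA_real_
    )
  })
}

#' @rdname tidy.aki_ensemble
#' @export
glance.aki_ensemble <- function(x, ...) {
  tibble::tibble(
    n_members = length(x$members),
    cell = x$hp$cell, hidden = x$hp$hidden,
    learning_rate = x$hp$learning_rate,
    n_weights = length(x$members[[1]]$weights)
  )
}

#' Tidy a fitted scaler
#'
#' @param x an `aki_scaler`.
#' @param ... unused.
#' @export
tidy.aki_scaler <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- class(tibble::tibble())
  out
}

#' Tidy the surgery-text model coefficients
#'
#' @param x an `aki_text_model`.
#' @param ... unused.
#' @return tibble `type`, `term`, `estimate` (intercept term is
#'   `"(Intercept)"`).
#' @export
tidy.aki_text_model <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, ty) {
    co <- as.matrix(stats::coef(f, s = x$lambda))
    tibble::tibble(type = ty, term = rownames(co), estimate = co[, 1])
  })
}
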