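#' Predictive-quality score S and its double-log transform
#'
#' For a probability prediction `r` of an event, the score is `S = r` when
#' the event occurred and `S = 1 - r` when it did not, i.e. the probability
#' mass the predictor put on the truth. Because S is typically very
#' non-normal, the transform `X = -log(-log(S))` is also returned; it is
#' approximately normal for well-behaved predictors and is the scale on
#' which paired comparisons and power calculations are done. S is clipped
#' to `[eps, 1 - eps]` before the transform, which diverges at 0 and 1.
#'
#' @param data data frame with one row per prediction unit.
#' @param risk,label column names (unquoted) of the predicted probability
#'   and the binary outcome.
#' @param eps clipping constant for the transform (default `1e-6`).
#' @return the input with columns `S` and `X_t` appended.
#' @export
#' @examples
#' score_predictions(data.frame(risk = c(0.8, 0.8), label = c(1, 0)))
score_predictions <- function(data, risk = risk, label = label, eps = 1e-6) {
  r <- dplyr::pull(data, {{ risk }})
  y <- dplyr::pull(data, {{ label }})
  assert_prob(r, "risk")
  stopifnot(all(y %in% c(0, 1)))
  S <- ifelse(y == 1, r, 1 - r)
  Sc <- clamp(S, eps, 1 - eps)
  dplyr::mutate(dplyr::as_tibble(data), S = S, X_t = -log(-log(Sc)))
}

#' Mean per-patient Brier score
#'
#' Each patient's Brier score is the mean squared difference between their
#' per-step risk predictions and their (constant) binary outcome,
#' `MSE_pat = (1/ts) * sum_i (y_i - y_true)^2`; the cohort value is the
#' unweighted mean over patients. Normalising inside each patient first
#' makes the metric independent of how long each patient was observed: a
#' patient with a 7-day stay counts exactly as much as one discharged after
#' a day. A predictor that always outputs 0.5 scores 0.25.
#'
#' @param data long data frame of per-step predictions.
#' @param id,risk,label unquoted column names: patient identifier,
#'   predicted probability per step, binary outcome.
#' @return one-row tibble with `estimate` (the mean of per-patient scores),
#'   `n_patients`, and `per_patient` (list column of per-patient scores).
#' @export
mean_mse_pat <- function(data, id = admission_id, risk = risk, label = label) {
  if (nrow(data) == 0) abort("no prediction series supplied")
  per <- data %>%
    dplyr::group_by({{ id }}) %>%
    dplyr::summarise(
      mse_pat = mean(({{ risk }} - {{ label }})^2),
      n_steps = dplyr::n(),
      .groups = "drop"
    )
  tibble::tibble(
    estimate = mean(per$mse_pat),
    n_patients = nrow(per),
    per_patient = list(per)
  )
}

# Rank-statistic AUC (equivalent to the Mann-Whitney U scaled to [0,1],
# ties counted 1/2). Kept internal; compute_metrics exposes it.
auc_rank <- function(risk, label) {
  pos <- risk[label == 1]
  neg <- risk[label == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Precision-recall AUC by step integration over the sorted score sweep.
pr_auc_step <- function(risk, label) {
  n_pos <- sum(label == 1)
  if (n_pos == 0 || n_pos == length(label)) return(NA_real_)
  ord <- order(risk, decreasing = TRUE)
  y <- label[ord]
  s <- risk[ord]
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  # evaluate at the last index of each tied score block
  keep <- c(s[-1] != s[-length(s)], TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  recall <- tp / n_pos
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Threshold-dependent and threshold-free classification metrics
#'
#' Computes the full metric roster for a set of probability predictions:
#' AUC (rank statistic), PR_AUC (precision-recall step integration), Brier
#' score, and -- at the supplied decision threshold, with `risk >=
#' threshold` declared positive -- accuracy, sensitivity, specificity, F1,
#' false-positive rate, NPV and PPV.
#'
#' @param data data frame of prediction units (per step or per patient).
#' @param risk,label unquoted column names.
#' @param threshold decision cut-point in `(0, 1)`.
#' @return tibble with columns `metric` and `estimate`. Ranking metrics are
#'   `NA` (with a warning) if only one class is present.
#' @export
compute_metrics <- function(data, risk = risk, label = label, threshold = 0.5) {
  r <- dplyr::pull(data, {{ risk }})
  y <- dplyr::pull(data, {{ label }})
  assert_prob(r, "risk")
  stopifnot(all(y %in% c(0, 1)), threshold > 0, threshold < 1)
  if (length(unique(y)) < 2) {
    warn("only one outcome class present; ranking metrics are undefined (NA)")
  }
  pred <- as.integer(r >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(
    metric = c("auc", "pr_auc", "brier", "accuracy", "sensitivity",
               "specificity", "f1", "fpr", "npv", "ppv"),
    estimate = c(
      auc_rank(r, y),
      pr_auc_step(r, y),
      mean((r - y)^2),
      (tp + tn) / length(y),
      safe_div(tp, tp + fn),
      safe_div(tn, tn + fp),
      safe_div(2 * tp, 2 * tp + fp + fn),
      safe_div(fp, fp + tn),
      safe_div(tn, tn + fn),
      safe_div(tp, tp + fp)
    )
  )
}

#' Intracluster correlation coefficient (one-way ANOVA estimator)
#'
#' Repeated per-step quantities from one patient are correlated; the ICC
#' measures how strongly. Uses the one-way random-effects ANOVA estimator
#' `(MSB - MSW) / (MSB + (m0 - 1) MSW)` with the standard unbalanced-design
#' average cluster size `m0 = (N - sum(m_i^2)/N) / (k - 1)`, clipped to
#' `[0, 1]`.
#'
#' @param data data frame of per-step values.
#' @param value,id unquoted column names of the measured quantity and the
#'   patient (cluster) identifier.
#' @return scalar ICC in `[0, 1]`.
#' @export
estimate_icc <- function(data, value = value, id = admission_id) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ id }}))
  k <- nlevels(g)
  if (k < 2) abort("ICC needs at least two clusters")
  n <- length(v)
  m_i <- as.numeric(table(g))
  grand <- mean(v)
  mu_i <- tapply(v, g, mean)
  ssb <- sum(m_i * (mu_i - grand)^2)
  ssw <- sum((v - mu_i[g])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  m0 <- (n - sum(m_i^2) / n) / (k - 1)
  if (msw == 0 && msb == 0) return(0)
  if (msw == 0) return(1)
  clamp((msb - msw) / (msb + (m0 - 1) * msw), 0, 1)
}

#' Design-effect-adjusted confidence interval for a proportion-type metric
#'
#' Per-step predictions cluster within patients, so the nominal sample size
#' `n = sum(m_i)` overstates the information available. The design effect
#' `DE = (mbar * k) / sum(m_i / (1 + (m_i - 1) * ICC))` inflates the
#' variance; the effective sample size is `n_eff = n / DE`, the standard
#' error `sqrt(X (1 - X) / n_eff)`, and the 95% CI `X +/- 1.96 * SE`
#' (clipped to `[0, 1]`). With ICC = 0 or all clusters of size one, DE = 1
#' and the adjustment vanishes; with ICC = 1 each patient collapses to a
#' single effective observation (`n_eff = k`).
#'
#' @param x metric point estimate in `[0, 1]`.
#' @param m integer vector of cluster sizes (time steps per patient).
#' @param icc intracluster correlation in `[0, 1]`.
#' @param conf_z normal quantile for the interval (1.96 for 95%).
#' @return one-row tibble: `estimate`, `se`, `conf_low`, `conf_high`, `n`,
#'   `k`, `de`, `n_eff`, `icc`.
#' @export
#' @examples
#' clustered_ci(0.85, m = rep(1, 350), icc = 0.9) # DE = 1, n_eff = 350
clustered_ci <- function(x, m, icc, conf_z = 1.96) {
  if (!is.finite(x) || x < 0 || x > 1) abort("metric `x` must lie in [0, 1]")
  stopifnot(all(m >= 1), icc >= 0, icc <= 1)
  k <- length(m)
  n <- sum(m)
  de <- (mean(m) * k) / sum(m / (1 + (m - 1) * icc))
  n_eff <- n / de
  se <- sqrt(x * (1 - x) / n_eff)
  tibble::tibble(
    estimate = x, se = se,
    conf_low = max(0, x - conf_z * se),
    conf_high = min(1, x + conf_z * se),
    n = n, k = k, de = de, n_eff = n_eff, icc = icc
  )
}

#' Full metrics report with ICC-adjusted confidence intervals
#'
#' Computes every metric in [compute_metrics()] on pooled per-step
#' predictions and attaches a design-effect-adjusted CI to each. One ICC --
#' estimated from the per-step correctness indicator (prediction at the
#' threshold vs label) -- is reused for all metrics of the report; the
#' squared error per step is available as an alternative ICC variable.
#' The same CI construction is applied to the ranking metrics (AUC,
#' PR_AUC), mirroring the convention of treating every metric as a
#' proportion; this is recorded in the report metadata.
#'
#' @param data long per-step predictions (`admission_id`, `risk`, `label`).
#' @param threshold decision threshold.
#' @param icc_variable `"correctness"` (default) or `"squared_error"`.
#' @return object of class `aki_metrics_report`: a tibble of metrics with
#'   CI columns, plus `mse_pat` and ICC/DE metadata as attributes.
#' @export
evaluate_predictions <- function(data, threshold = 0.5,
                                 icc_variable = c("correctness", "squared_error")) {
  icc_variable <- match.arg(icc_variable)
  stopifnot(all(c("admission_id", "risk", "label") %in% names(data)))
  v <- if (icc_variable == "correctness") {
    as.numeric((data$risk >= threshold) == (data$label == 1))
  } else {
    (data$risk - data$label)^2
  }
  icc <- estimate_icc(dplyr::mutate(data, .icc_var = v), value = .data$.icc_var)
  m <- as.numeric(table(data$admission_id))
  mets <- compute_metrics(data, threshold = threshold)
  ci <- purrr::map(mets$estimate, function(x) {
    if (is.na(x)) {
      tibble::tibble(se = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
                     n = sum(m), k = length(m), de = NA_real_,
                     n_eff = NA_real_, icc = icc)
    } else {
      dplyr::select(clustered_ci(x, m, icc), -"estimate")
    }
  })
  out <- dplyr::bind_cols(mets, dplyr::bind_rows(ci))
  msep <- mean_mse_pat(data)
  attr(out, "mse_pat") <- msep$estimate
  attr(out, "threshold") <- threshold
  attr(out, "icc_variable") <- icc_variable
  attr(out, "note") <- paste(
    "CIs use X +/- 1.96*sqrt(X(1-X)/n_eff) for every metric,",
    "including AUC/PR_AUC, which are not binomial proportions."
  )
  class(out) <- c("aki_metrics_report", class(out))
  out
}

#' @export
print.aki_metrics_report <- function(x, ...) {
  cat(sprintf(
    "<aki_metrics_report>  threshold = %.3g, ICC = %.3f (on %s), mean MSE_pat = %.3f\n",
    attr(x, "threshold"), x$icc[1], attr(x, "icc_variable"), attr(x, "mse_pat")))
  NextMethod()
}

#' Hosmer-Lemeshow calibration test
#'
#' Groups predictions into `g` equal-frequency bins by predicted risk and
#' compares observed to expected event counts:
#' `chi2 = sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))`, with `df = g - 2`
#' degrees of freedom and an upper-tail chi-square p value. Bins with
#' identical quantile boundaries (heavily tied predictions) are merged; the
#' test errors below 3 usable bins.
#'
#' The degrees of freedom depend on where the probabilities came from:
#' `g - 2` is the classical reference for predictions of a logistic model
#' fitted on the same data (and is the convention this package reports by
#' default); for externally supplied probabilities never fitted to these
#' labels -- a validation sample, or a simulation with known true risks --
#' the statistic is approximately chi-square with `g` degrees of freedom,
#' and `reference = "validation"` must be used for the p value to be
#' uniform under perfect calibration.
#'
#' @param data data frame of prediction units.
#' @param risk,label unquoted column names.
#' @param g number of bins (default 10 deciles, hence df = 8).
#' @param reference `"development"` (df = g - 2, default) or
#'   `"validation"` (df = g).
#' @return one-row tibble `statistic`, `df`, `p_value`, `g_used`, with the
#'   per-bin table in the `bins` list column.
#' @export
hosmer_lemeshow <- function(data, risk = risk, label = label, g = 10,
                            reference = c("development", "validation")) {
  reference <- match.arg(reference)
  r <- dplyr::pull(data, {{ risk }})
  y <- dplyr::pull(data, {{ label }})
  assert_prob(r, "risk")
  breaks <- unique(stats::quantile(r, probs = seq(0, 1, length.out = g + 1)))
  if (length(breaks) - 1 < 3) abort("fewer than 3 usable calibration bins")
  bin <- cut(r, breaks = breaks, include.lowest = TRUE)
  tab <- tibble::tibble(bin = bin, r = r, y = y) %>%
    dplyr::group_by(bin) %>%
    dplyr::summarise(n = dplyr::n(), observed = sum(.data$y),
                     expected = sum(.data$r), mean_risk = mean(.data$r),
                     obs_rate = mean(.data$y), .groups = "drop")
  denom <- tab$expected * (1 - tab$expected / tab$n)
  ok <- denom > 0
  stat <- sum((tab$observed[ok] - tab$expected[ok])^2 / denom[ok])
  df <- if (reference == "development") nrow(tab) - 2 else nrow(tab)
  tibble::tibble(
    statistic = stat, df = df,
    p_value = stats::pchisq(stat, df, lower.tail = FALSE),
    g_used = nrow(tab), bins = list(tab)
  )
}

#' Compare two predictors on the same units
#'
#' Runs the two standard head-to-head comparisons for paired probability
#' predictions of one outcome: DeLong's test for the difference of the two
#' correlated ROC AUCs, and a paired t-test on the predictive-quality score
#' S (see [score_predictions()]). Both predictors must be evaluated on
#' exactly the same units in the same order.
#'
#' @param data data frame with one row per unit.
#' @param risk_a,risk_b,label unquoted column names of the two predictors'
#'   probabilities and the shared outcome.
#' @return object of class `aki_comparison`: list with `delong`
#'   (Z, p, the two AUCs, var of the AUC difference) and `score_test`
#'   (mean S per predictor, t, df, p).
#' @export
compare_predictors <- function(data, risk_a, risk_b, label = label) {
  ra <- as.numeric(dplyr::pull(data, {{ risk_a }}))
  rb <- as.numeric(dplyr::pull(data, {{ risk_b }}))
  y <- as.numeric(dplyr::pull(data, {{ label }}))
  assert_prob(ra, "risk_a"); assert_prob(rb, "risk_b")
  if (length(ra) != length(rb) || length(ra) != length(y)) {
    abort("predictors must be evaluated on identical units")
  }
  roc_a <- pROC::roc(y, ra, quiet = TRUE, direction = "<", levels = c(0, 1))
  roc_b <- pROC::roc(y, rb, quiet = TRUE, direction = "<", levels = c(0, 1))
  identical_preds <- isTRUE(all.equal(ra, rb))
  if (identical_preds) {
    delong <- tibble::tibble(auc_a = as.numeric(pROC::auc(roc_a)),
                             auc_b = as.numeric(pROC::auc(roc_b)),
                             z = 0, p_value = 1, var_diff = 0)
  } else {
    dl <- pROC::roc.test(roc_a, roc_b, method = "delong", paired = TRUE)
    z <- as.numeric(dl$statistic)
    d <- as.numeric(pROC::auc(roc_a)) - as.numeric(pROC::auc(roc_b))
    delong <- tibble::tibble(
      auc_a = as.numeric(pROC::auc(roc_a)),
      auc_b = as.numeric(pROC::auc(roc_b)),
      z = z, p_value = as.numeric(dl$p.value),
      var_diff = if (z == 0) NA_real_ else (d / z)^2
    )
  }
  Sa <- ifelse(y == 1, ra, 1 - ra)
  Sb <- ifelse(y == 1, rb, 1 - rb)
  if (isTRUE(all.equal(Sa, Sb))) {
    st <- tibble::tibble(mean_s_a = mean(Sa), mean_s_b = mean(Sb),
                         t = 0, df = length(y) - 1, p_value = 1)
  } else {
    tt <- stats::t.test(Sa, Sb, paired = TRUE)
    st <- tibble::tibble(mean_s_a = mean(Sa), mean_s_b = mean(Sb),
                         t = as.numeric(tt$statistic),
                         df = as.numeric(tt$parameter),
                         p_value = tt$p.value)
  }
  structure(list(delong = delong, score_test = st, n = length(y)),
            class = "aki_comparison")
}

#' @export
print.aki_comparison <- function(x, ...) {
  cat(sprintf(
    "<aki_comparison> n = %d\n  AUC %.3f vs %.3f (DeLong Z = %.2f, p = %.3g)\n  mean S %.3f vs %.3f (paired t = %.2f, df = %d, p = %.3g)\n",
    x$n, x$delong$auc_a, x$delong$auc_b, x$delong$z, x$delong$p_value,
    x$score_test$mean_s_a, x$score_test$mean_s_b, x$score_test$t,
    x$score_test$df, x$score_test$p_value))
  invisible(x)
}

#' Stratify single-point predictions by time to event
#'
#' Assigns each admission's sampled prediction point to a half-open
#' time-to-event bin (`[0,2), [2,6), [6,12), [12,24), [24,48), [48,168]`
#' hours before the end of the observation window -- AKI onset for cases,
#' discharge or the 7-day cap for controls) and computes the full metric
#' roster inside each bin. One point per patient means no clustering, so
#' `n_eff = n` within bins.
#'
#' @param data one row per admission with columns `admission_id`, `risk`,
#'   `label`, `point_h` (prediction time) and `window_end_h`; optionally
#'   `window_length_h` for the per-bin median observation length.
#' @param threshold decision threshold for the threshold-dependent metrics.
#' @param breaks_h bin edges in hours.
#' @return tibble, one row per bin x metric, with per-bin `n`, `n_aki` and
#'   `median_obs_h`.
#' @export
stratify_by_time_to_event <- function(data, threshold = 0.5,
                                      breaks_h = c(0, 2, 6, 12, 24, 48, 168)) {
  stopifnot(all(c("admission_id", "risk", "label", "point_h", "window_end_h")
                %in% names(data)))
  tte <- data$window_end_h - data$point_h
  if (any(tte < 0)) abort("negative time-to-event: point after window end")
  bin <- cut(tte, breaks = breaks_h, right = FALSE, include.lowest = TRUE,
             labels = sprintf("%g-%g h", utils::head(breaks_h, -1),
                              utils::tail(breaks_h, -1)))
  data$tte_bin <- bin
  data %>%
    dplyr::group_by(.data$tte_bin, .drop = FALSE) %>%
    dplyr::group_modify(function(d, key) {
      if (nrow(d) == 0) return(tibble::tibble())
      mets <- if (length(unique(d$label)) < 2) {
        suppressWarnings(compute_metrics(d, threshold = threshold))
      } else {
        compute_metrics(d, threshold = threshold)
      }
      mets$n <- nrow(d)
      mets$n_aki <- sum(d$label)
      mets$median_obs_h <- if ("window_length_h" %in% names(d)) {
        stats::median(d$window_length_h)
      } else NA_real_
      mets
    }) %>%
    dplyr::ungroup()
}
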