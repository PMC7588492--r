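test_that("score S rewards probability mass on the truth", {
  d <- score_predictions(data.frame(risk = c(0.8, 0.8), label = c(1, 0)))
  expect_equal(d$S, c(0.8, 0.2))
  # X transform: S = e^-1 maps to exactly 0
  d2 <- score_predictions(data.frame(risk = exp(-1), label = 1))
  expect_equal(d2$X_t, 0)
  # boundary handling: S = 1 is clipped, transform stays finite
  d3 <- score_predictions(data.frame(risk = 1, label = 1))
  expect_true(is.finite(d3$X_t))
  expect_error(score_predictions(data.frame(risk = 1.2, label = 1)),
               "probabilities")
})

test_that("S distribution is invariant under joint relabeling r -> 1 - r", {
  set.seed(4)
  d <- data.frame(risk = runif(500), label = rbinom(500, 1, 0.4))
  flipped <- data.frame(risk = 1 - d$risk, label = 1 - d$label)
  expect_equal(score_predictions(d)$S, score_predictions(flipped)$S)
})

test_that("per-patient Brier score weights patients, not time steps", {
  d <- tibble::tibble(
    admission_id = rep(c("a", "b"), c(2, 4)),
    risk = c(1, 0, rep(0.5, 4)),
    label = rep(c(1, 0), c(2, 4))
  )
  r <- mean_mse_pat(d)
  expect_equal(r$estimate, (0.5 + 0.25) / 2)  # ((0 + 1)/2, const-0.5) halves
  # perfect predictions score zero
  d2 <- dplyr::mutate(d, risk = label)
  expect_equal(mean_mse_pat(d2)$estimate, 0)
  # duplicating every step of one patient changes nothing
  dup <- dplyr::bind_rows(d, d[d$admission_id == "a", ])
  expect_equal(mean_mse_pat(dup)$estimate, r$estimate)
})

test_that("classification metrics match the brute-force confusion matrix", {
  d <- data.frame(risk = c(0.9, 0.6, 0.2, 0.8, 0.3, 0.1),
                  label = c(1, 1, 1, 0, 0, 0))
  m <- compute_metrics(d, threshold = 0.5)
  g <- function(x) m$estimate[m$metric == x]
  expect_equal(g("sensitivity"), 2 / 3)
  expect_equal(g("specificity"), 2 / 3)
  # pairs won: 0.9 beats all three; 0.6 beats 0.3, 0.1; 0.2 beats 0.1
  expect_equal(g("auc"), 6 / 9)
  expect_equal(g("fpr"), 1 / 3)
  # perfect separation
  mp <- compute_metrics(data.frame(risk = c(0.9, 0.8, 0.1, 0.2),
                                   label = c(1, 1, 0, 0)))
  expect_equal(mp$estimate[mp$metric %in% c("auc", "sensitivity",
                                            "specificity")], c(1, 1, 1))
})

test_that("rank AUC agrees with pROC and is ~0.5 under independence", {
  set.seed(11)
  r <- runif(400); y <- rbinom(400, 1, 0.5)
  mine <- akirisk:::auc_rank(r, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, r, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(mine, ref)
  se <- sqrt(1 / 12 * (1 / sum(y) + 1 / sum(1 - y)))
  expect_lt(abs(mine - 0.5), 3 * se)
})

test_that("single-class input signals undefined ranking metrics", {
  d <- data.frame(risk = c(0.2, 0.4), label = c(0, 0))
  expect_warning(m <- compute_metrics(d), "one outcome class")
  expect_true(is.na(m$estimate[m$metric == "auc"]))
})

test_that("one-way ANOVA ICC hits its closed-form anchors", {
  within_const <- tibble::tibble(admission_id = rep(1:4, each = 3),
                                 value = rep(c(1, 5, 9, 2), each = 3))
  expect_equal(estimate_icc(within_const), 1)
  expect_equal(estimate_icc(tibble::tibble(admission_id = rep(1:2, each = 2),
                                           value = c(1, 1, 3, 3))), 1)
  set.seed(2)
  iid <- tibble::tibble(admission_id = rep(1:200, each = 5),
                        value = rnorm(1000))
  expect_lt(estimate_icc(iid), 0.05)
  expect_error(estimate_icc(tibble::tibble(admission_id = 1, value = 1:3)),
               "two clusters")
})

test_that("design-effect CI machinery matches the defining equations", {
  # singleton clusters: no inflation whatever the ICC
  for (icc in c(0, 0.3, 1)) {
    r <- clustered_ci(0.8, m = rep(1, 350), icc = icc)
    expect_equal(r$de, 1)
    expect_equal(r$n_eff, 350)
  }
  expect_equal(clustered_ci(0.8, m = c(5, 9, 13), icc = 0)$de, 1)
  # full correlation collapses each cluster to one effective unit
  r <- clustered_ci(0.5, m = c(2, 4), icc = 1)
  expect_equal(r$de, 3)
  expect_equal(r$n_eff, 2)
  expect_error(clustered_ci(1.2, m = c(2, 2), icc = 0.5), "\\[0, 1\\]")
})

test_that("CI width is non-decreasing in the ICC", {
  m <- c(3, 7, 12, 1, 20)
  widths <- vapply(seq(0, 1, by = 0.05), function(icc) {
    r <- clustered_ci(0.7, m, icc)
    2 * 1.96 * r$se
  }, numeric(1))
  expect_true(all(diff(widths) >= -1e-12))
})

test_that("Hosmer-Lemeshow reports decile df and detects miscalibration", {
  set.seed(9)
  p <- runif(5000); y <- rbinom(5000, 1, p)
  hl <- hosmer_lemeshow(data.frame(risk = p, label = y))
  expect_equal(hl$df, 8)
  expect_equal(hl$g_used, 10)
  # validation reference for probabilities not fitted to these labels
  hlv <- hosmer_lemeshow(data.frame(risk = p, label = y),
                         reference = "validation")
  expect_equal(hlv$df, 10)
  # systematically shifted predictions are rejected decisively
  shifted <- pmin(pmax(p - 0.3, 0.01), 0.99)
  hs <- hosmer_lemeshow(data.frame(risk = shifted, label = y))
  expect_lt(hs$p_value, 0.001)
  # heavy ties collapse bins; degenerate input errors
  expect_error(hosmer_lemeshow(data.frame(risk = rep(0.4, 50),
                                          label = rbinom(50, 1, 0.4))),
               "bins")
})

test_that("identical predictors compare as exactly equal", {
  set.seed(3)
  d <- data.frame(risk_a = runif(60), label = rbinom(60, 1, 0.5))
  d$risk_b <- d$risk_a
  cmp <- compare_predictors(d, risk_a, risk_b)
  expect_equal(cmp$delong$z, 0)
  expect_equal(cmp$delong$p_value, 1)
  expect_equal(cmp$score_test$t, 0)
  expect_equal(cmp$delong$auc_a, cmp$delong$auc_b)
})

test_that("a signal predictor beats pure noise decisively at n = 350", {
  set.seed(21)
  y <- rbinom(350, 1, 0.5)
  a <- pmin(pmax(y * 0.7 + 0.15 + rnorm(350, 0, 0.12), 0), 1)
  b <- runif(350)
  cmp <- compare_predictors(data.frame(risk_a = a, risk_b = b, label = y),
                            risk_a, risk_b)
  expect_lt(cmp$delong$p_value, 0.001)
  expect_lt(cmp$score_test$p_value, 0.001)
  expect_error(
    compare_predictors(data.frame(risk_a = a[1:10], risk_b = b[1:20],
                                  label = y[1:20])[0, ], risk_a, risk_b))
})

test_that("time-to-event strata partition the sampled points", {
  d <- tibble::tibble(
    admission_id = sprintf("a%d", 1:6),
    risk = c(0.9, 0.8, 0.3, 0.7, 0.2, 0.6),
    label = c(1, 1, 0, 1, 0, 0),
    point_h = c(47, 44, 20, 10, 100, 5),
    window_end_h = c(50, 46, 40, 12, 160, 6)
  )
  s <- stratify_by_time_to_event(d)
  # 3 h and 2 h before the event both land in [2, 6)
  expect_true(all(c("2-6 h") %in% s$tte_bin[s$n > 0]))
  counts <- dplyr::distinct(s[!is.na(s$n), ], .data$tte_bin, .data$n)
  expect_equal(sum(counts$n), 6)
  # boundary: exactly 2 h -> [2, 6) bin
  d2 <- d[1:2, ]; d2$point_h <- c(48, 44); d2$window_end_h <- c(50, 46)
  s2 <- suppressWarnings(stratify_by_time_to_event(d2))
  expect_true(all(s2$tte_bin[s2$n > 0] == "2-6 h"))
  expect_error(stratify_by_time_to_event(dplyr::mutate(d, point_h = 200)),
               "negative time-to-event")
})
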