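test_that("baseline creatinine prefers the last pre-operative value", {
  # surgery on day 0 at hour 0 (absolute hours: negative = pre-op)
  creat <- tibble::tibble(time_h = c(-144, -48), value = c(1.4, 1.1))
  b <- select_baseline_creatinine(creat, surgery_start_h = 0,
                                  surgery_end_h = 4)
  expect_equal(b$baseline, 1.1)
  expect_equal(b$rule, "preoperative")
  # only a stale value (6 days old): fall back to first post-operative
  creat2 <- tibble::tibble(time_h = c(-144, 8), value = c(1.4, 1.3))
  b2 <- select_baseline_creatinine(creat2, 0, 4)
  expect_equal(b2$baseline, 1.3)
  expect_equal(b2$rule, "first_postoperative")
  # a single value one hour before surgery qualifies
  b3 <- select_baseline_creatinine(tibble::tibble(time_h = -1, value = 0.9),
                                   0, 4)
  expect_equal(b3$baseline, 0.9)
  expect_error(select_baseline_creatinine(tibble::tibble(time_h = numeric(0),
                                                         value = numeric(0)),
                                          0, 4), "excluded")
})

test_that("creatinine onset is the earliest doubling, at a measurement", {
  cr <- tibble::tibble(time_h = c(6, 18, 30), value = c(1.5, 2.0, 2.6))
  r <- detect_creatinine_onset(cr, baseline = 1.0, study_end_h = 168)
  expect_equal(r$onset_h, 18)
  expect_equal(r$stage_hint, 2L)
  # never doubles
  r2 <- detect_creatinine_onset(tibble::tibble(time_h = 10, value = 1.9),
                                1.0, 168)
  expect_true(is.na(r2$onset_h))
  # stage-3 hint: 3.7 >= 3 x 1.2
  r3 <- detect_creatinine_onset(tibble::tibble(time_h = 24, value = 3.7),
                                1.2, 168)
  expect_equal(r3$onset_h, 24)
  expect_equal(r3$stage_hint, 3L)
  # measurements past the study end never create an onset
  r4 <- detect_creatinine_onset(tibble::tibble(time_h = 180, value = 5),
                                1.0, 168)
  expect_true(is.na(r4$onset_h))
})

test_that("urine onset needs 12 sustained hours in reliable locations", {
  loc <- tibble::tibble(start_h = 0, end_h = 48, location = "icu")
  # constant oliguria from hour 0: definitional onset at 12 h
  u <- urine_series(rep(0.4, 30))
  r <- detect_urine_onset(u, 80, loc, study_end_h = 48)
  expect_equal(r$onset_h, 12)
  # 11 h below threshold, then recovery: never a criterion hit
  u2 <- urine_series(c(rep(0.4, 11), rep(1.0, 19)))
  expect_true(is.na(detect_urine_onset(u2, 80, loc, 48)$onset_h))
  # 14 h low, but hours 5-9 on the ward: no fully reliable 12-h window
  loc3 <- tibble::tibble(start_h = c(0, 5, 9), end_h = c(5, 9, 48),
                         location = c("icu", "ward", "icu"))
  u3 <- urine_series(c(rep(0.4, 14), rep(1.0, 16)))
  expect_true(is.na(detect_urine_onset(u3, 80, loc3, 48)$onset_h))
  # no reliable locations at all: criterion inapplicable
  ward <- tibble::tibble(start_h = 0, end_h = 48, location = "ward")
  expect_true(is.na(detect_urine_onset(u, 80, ward, 48)$onset_h))
})

test_that("urine threshold is monotone: raising it never removes an onset", {
  loc <- tibble::tibble(start_h = 0, end_h = 60, location = "icu")
  set.seed(13)
  n_hit <- 0
  for (rep in 1:30) {
    # block structure so sustained low runs actually occur
    u <- urine_series(rep(runif(6, 0.2, 1.2), each = 7))
    lo <- detect_urine_onset(u, 80, loc, 60, threshold = 0.5)$onset_h
    hi <- detect_urine_onset(u, 80, loc, 60, threshold = 0.7)$onset_h
    if (!is.na(lo)) {
      n_hit <- n_hit + 1
      expect_false(is.na(hi))
      expect_lte(hi, lo)
    }
  }
  expect_gte(n_hit, 3)
})

test_that("charting gaps make windows ineligible rather than evaluated", {
  loc <- tibble::tibble(start_h = 0, end_h = 60, location = "icu")
  # oliguric records with a 6-h documentation hole in the middle
  u <- dplyr::bind_rows(urine_series(rep(0.3, 6), t0 = 0),
                        urine_series(rep(0.3, 20), t0 = 12))
  r <- detect_urine_onset(u, 80, loc, 60)
  # only the post-gap run can qualify: onset 12 h after it starts
  expect_equal(r$onset_h, 24)
})

test_that("global label combines both criteria with provenance", {
  st <- toy_static(s_start = 10, s_end = 14, discharge = 200)
  loc <- toy_locations(s_start = 10, s_end = 14, discharge = 200)
  mk_events <- function(creat, urine_rates) {
    dplyr::bind_rows(
      dplyr::mutate(creat, channel = "creatinine"),
      dplyr::mutate(urine_series(urine_rates, t0 = 10), channel = "urine_flow")
    )
  }
  # creatinine-only: doubling 18 h after surgery end
  ev <- mk_events(tibble::tibble(time_h = c(8, 32), value = c(1.0, 2.1)),
                  rep(1.0, 100))
  l <- label_admission(st, ev, loc)
  expect_equal(l$label, 1L)
  expect_equal(l$criterion, "creatinine")
  expect_equal(l$onset_h, 32)
  expect_true(is.na(l$urine_onset_h))
  # both criteria: onset is the earlier (urine), delay is the gap
  ev2 <- mk_events(
    tibble::tibble(time_h = c(8, 44), value = c(1.0, 2.2)),
    c(rep(1.0, 8), rep(0.3, 14), rep(1.0, 80)))  # low hours 18..31
  l2 <- label_admission(st, ev2, loc)
  expect_equal(l2$criterion, "both")
  expect_equal(l2$urine_onset_h, 30)   # 12 h after the low run starts
  expect_equal(l2$creatinine_onset_h, 44)
  expect_equal(l2$onset_h, 30)
  expect_equal(l2$diagnosis_delay_h, 14)
  # dialysis before surgery end: excluded, not negative
  l3 <- label_admission(toy_static(dialysis = TRUE), ev, loc)
  expect_true(l3$excluded)
  expect_equal(l3$exclusion_reason, "pre-existing dialysis")
  expect_true(is.na(l3$label))
  # baseline >= 4 mg/dl: excluded
  ev4 <- mk_events(tibble::tibble(time_h = c(8, 32), value = c(4.2, 9.0)),
                   rep(1.0, 100))
  l4 <- label_admission(st, ev4, loc)
  expect_true(l4$excluded)
  expect_match(l4$exclusion_reason, "baseline")
})

test_that("observation windows end at discharge, onset, or the 7-day cap", {
  st <- toy_static(s_start = 10, s_end = 14, discharge = 50)
  loc <- toy_locations(s_start = 10, s_end = 14, discharge = 50)
  neg <- tibble::tibble(onset_h = NA_real_)
  w <- build_observation_window(st, loc, neg)
  expect_equal(w$start_h, 14)  # recovery starts at surgery end
  expect_equal(w$end_h, 50)
  # AKI truncates the window at onset
  w2 <- build_observation_window(st, loc, tibble::tibble(onset_h = 30))
  expect_equal(w2$end_h, 30)
  # 7-day cap
  st3 <- toy_static(discharge = 200); loc3 <- toy_locations(discharge = 200)
  w3 <- build_observation_window(st3, loc3, neg)
  expect_equal(w3$end_h, 14 + 168)
  # no postoperative ICU/recovery segment is an error
  loc_bad <- tibble::tibble(start_h = c(0, 10), end_h = c(10, 50),
                            location = c("ward", "theatre"))
  expect_error(build_observation_window(st, loc_bad, neg), "ICU/recovery")
})

test_that("greedy matching on observation length is sane and beats chance", {
  cases <- tibble::tibble(admission_id = c("c1", "c2"), length_h = c(10, 20))
  controls <- tibble::tibble(admission_id = c("k1", "k2", "k3"),
                             length_h = c(19, 11, 25))
  m <- match_cases_controls(cases, controls)
  expect_equal(m$control_id[m$case_id == "c2"], "k1")  # 20 <-> 19
  expect_equal(m$control_id[m$case_id == "c1"], "k2")  # 10 <-> 11
  expect_equal(sort(m$delta_h), c(1, 1))
  # single case, single control
  m1 <- match_cases_controls(cases[1, ], controls[1, ])
  expect_equal(nrow(m1), 1)
  expect_error(match_cases_controls(cases, controls[1, ]), "at least as many")
  # each control used at most once
  set.seed(31)
  ca <- tibble::tibble(admission_id = sprintf("c%03d", 1:200),
                       length_h = rlnorm(200, log(30), 0.7))
  co <- tibble::tibble(admission_id = sprintf("k%04d", 1:1000),
                       length_h = rlnorm(1000, log(30), 0.7))
  mm <- match_cases_controls(ca, co)
  expect_equal(anyDuplicated(mm$control_id), 0)
  random_delta <- mean(abs(ca$length_h - co$length_h[sample(1000, 200)]))
  expect_lt(mean(mm$delta_h), random_delta)
})

test_that("criterion summary counts fractions and the diagnosis delay", {
  lab <- tibble::tibble(
    admission_id = sprintf("a%02d", 1:12),
    excluded = FALSE, label = c(rep(1L, 10), 0L, 0L),
    criterion = c("urine", rep("creatinine", 6), rep("both", 3),
                  "none", "none"),
    diagnosis_delay_h = c(rep(NA, 7), 10, 14, 18, NA, NA)
  )
  s <- summarize_cohort_labels(lab)
  expect_equal(s$frac_urine_only, 0.1)
  expect_equal(s$frac_urine_involved, 0.4)
  expect_equal(s$delay_median_h, 14)
  # all creatinine-only
  lab2 <- dplyr::mutate(lab, criterion = ifelse(label == 1, "creatinine",
                                                "none"),
                        diagnosis_delay_h = NA_real_)
  expect_equal(summarize_cohort_labels(lab2)$frac_urine_only, 0)
  # zero AKI cases is signalled
  expect_warning(s0 <- summarize_cohort_labels(
    dplyr::mutate(lab, label = 0L, criterion = "none")), "undefined")
  expect_true(is.na(s0$frac_urine_only))
})

test_that("no data after the window end leaks into the feature grid", {
  co <- demo_cohort()
  id <- demo_windows()$admission_id[1]
  w <- demo_windows()[demo_windows()$admission_id == id, ]
  ev <- co$events[co$events$admission_id == id, ]
  g1 <- resample_to_grid(ev, w, c("creatinine", "map"))
  # deleting every event after the window end changes nothing
  ev2 <- ev[ev$time_h <= w$end_h, ]
  g2 <- resample_to_grid(ev2, w, c("creatinine", "map"))
  expect_identical(g1$values, g2$values)
})
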