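test_that("configuration invariants are enforced", {
  expect_error(cohort_config(criterion_mix = c(creatinine_only = 0.5,
                                               urine_only = 0.5,
                                               both = 0.5)), "sum to 1")
  expect_error(cohort_config(aki_fraction = 1.2), "aki_fraction")
  expect_error(cohort_config(observation_cap_h = 200), "observation_cap_h")
  expect_error(cohort_config(oliguria_rate_band = c(0.2, 0.6)), "interval")
  expect_error(cohort_config(peak_creatinine_multiplier = list(
    meanlog = 0, sdlog = 0.1, min = 1.5)), ">= 2")
})

test_that("the planted AKI split is exact and the seed determines the cohort", {
  co <- generate_cohort(cohort_config(n_admissions = 100, aki_fraction = 0.5,
                                      seed = 1))
  expect_equal(sum(co$truth$aki), 50)
  co2 <- generate_cohort(cohort_config(n_admissions = 100, aki_fraction = 0.5,
                                       seed = 1))
  expect_identical(co$events, co2$events)
  expect_identical(co$static, co2$static)
  expect_identical(co$truth, co2$truth)
  co3 <- generate_cohort(cohort_config(n_admissions = 100, aki_fraction = 0.5,
                                       seed = 2))
  expect_false(identical(co$events, co3$events))
})

test_that("generated admissions satisfy the structural invariants", {
  co <- demo_cohort()
  st <- co$static
  expect_true(all(st$weight_kg > 0))
  expect_true(all(st$age >= 18))
  for (id in st$admission_id[1:15]) {
    loc <- co$locations[co$locations$admission_id == id, ]
    s <- st[st$admission_id == id, ]
    # ordered, non-overlapping, covering admission -> discharge
    expect_true(all(diff(loc$start_h) > 0))
    expect_equal(loc$start_h[-1], loc$end_h[-nrow(loc)])
    expect_equal(loc$start_h[1], 0)
    expect_equal(loc$end_h[nrow(loc)], s$discharge_h)
    ev <- co$events[co$events$admission_id == id, ]
    expect_true(all(ev$time_h >= 0 & ev$time_h <= s$discharge_h))
    # strictly increasing timestamps within each channel, finite values
    for (ch in unique(ev$channel)) {
      tt <- ev$time_h[ev$channel == ch]
      expect_true(all(diff(tt) > 0))
    }
    expect_true(all(is.finite(ev$value)))
  }
})

test_that("planted scenarios are recovered by the labeler", {
  cfg <- cohort_config(n_admissions = 10, seed = 77)
  run_scenario <- function(scen) {
    set.seed(123)
    sim <- simulate_admission(scen, cfg)
    label_admission(sim$static, sim$events, sim$locations)
  }
  base <- list(admission_id = "t1", outcome = "non_aki", criterion = NA,
               onset_offset_h = NA_real_, lag_h = NA_real_,
               hard_negative = "none", disch_offset_h = 60)
  # hard negative: a deep 11-h oliguric dip stays negative by definition
  l_dip <- run_scenario(modifyList(base, list(hard_negative = "short_dip")))
  expect_equal(l_dip$label, 0L)
  # ward-only oliguria is masked by the reliable-location rule
  l_ward <- run_scenario(modifyList(base,
                                    list(hard_negative = "ward_oliguria")))
  expect_equal(l_ward$label, 0L)
  # urine-only case: onset recovered to within one grid step, no creatinine
  l_ur <- run_scenario(modifyList(base, list(
    outcome = "aki", criterion = "urine", onset_offset_h = 20,
    disch_offset_h = NA_real_)))
  expect_equal(l_ur$label, 1L)
  expect_equal(l_ur$criterion, "urine")
  expect_true(is.na(l_ur$creatinine_onset_h))
  # dual-criterion case: creatinine lags urine by the planted 14 h
  l_both <- run_scenario(modifyList(base, list(
    outcome = "aki", criterion = "both", onset_offset_h = 20, lag_h = 14,
    disch_offset_h = NA_real_)))
  expect_equal(l_both$criterion, "both")
  expect_lt(abs(l_both$diagnosis_delay_h - 14), 0.3)
  # onset beyond the cap is a configuration error
  expect_error(run_scenario(modifyList(base, list(
    outcome = "aki", criterion = "creatinine", onset_offset_h = 180))),
    "observation cap")
})

test_that("urine-only onsets land within one grid step of the plan", {
  cfg <- cohort_config(n_admissions = 10, seed = 78)
  set.seed(55)
  for (off in c(16, 30.3, 55.7)) {
    sim <- simulate_admission(list(
      admission_id = "u1", outcome = "aki", criterion = "urine",
      onset_offset_h = off, lag_h = NA_real_, hard_negative = "none",
      disch_offset_h = NA_real_), cfg)
    l <- label_admission(sim$static, sim$events, sim$locations)
    planted <- sim$static$surgery_end_h + off
    expect_lt(abs(l$urine_onset_h - planted), 0.26)
  }
})

test_that("surgery text is template-based and category-bearing", {
  set.seed(9)
  txt <- generate_surgery_text("cabg", n = 5)
  expect_true(all(grepl("cabg", txt)))
  expect_error(generate_surgery_text("appendectomy"), "unknown")
  set.seed(42); a <- generate_surgery_text("avr")
  set.seed(42); b <- generate_surgery_text("avr")
  expect_identical(a, b)
})

test_that("cohorts round-trip through the CSV/JSON exchange format", {
  co <- demo_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("events.csv", "static.csv", "drugs.csv", "surgery_text.csv",
           "truth.json", "config.yaml")))))
  back <- read_cohort(dir)
  expect_equal(back$events$value, co$events$value)
  expect_equal(back$events$time_h, co$events$time_h, tolerance = 1e-3)
  expect_equal(back$truth$aki, co$truth$aki)
  blinded <- read_cohort(dir, blinded = TRUE)
  expect_null(blinded$truth)
})
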