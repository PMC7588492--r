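# Shared fixtures, built once per test run and cached in-process.
.fixtures <- new.env(parent = emptyenv())

with_seed_local <- akirisk:::with_seed

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

demo_cohort <- function() {
  cached("cohort", generate_cohort(cohort_config(n_admissions = 60,
                                                 seed = 301)))
}

demo_labels <- function() cached("labels", label_cohort(demo_cohort()))

demo_windows <- function() {
  cached("windows", build_observation_windows(demo_cohort(), demo_labels()))
}

demo_text_model <- function() {
  cached("text_model", {
    # balanced template corpus: the tiny demo cohort alone cannot give
    # every one of the 17 types two texts
    cats <- rep(names(akirisk:::surgery_vocab()), each = 6)
    set.seed(404)
    texts <- vapply(cats, generate_surgery_text, character(1))
    fit_surgery_text_model(texts, cats)
  })
}

demo_grids <- function() {
  cached("grids", build_feature_grids(demo_cohort(), demo_windows(),
                                      demo_labels(), demo_text_model()))
}

# minimal hand-built admission pieces for labeling unit tests
toy_static <- function(admission_id = "a1", age = 60, weight = 80,
                       s_start = 10, s_end = 14, discharge = 120,
                       dialysis = FALSE) {
  tibble::tibble(admission_id = admission_id, age = age, weight_kg = weight,
                 surgery_start_h = s_start, surgery_end_h = s_end,
                 discharge_h = discharge,
                 dialysis_before_surgery_end = dialysis)
}

toy_locations <- function(admission_id = "a1", s_start = 10, s_end = 14,
                          discharge = 120) {
  tibble::tibble(
    admission_id = admission_id,
    start_h = c(0, s_start, s_end, s_end + 2),
    end_h = c(s_start, s_end, s_end + 2, discharge),
    location = c("ward", "theatre", "recovery", "icu")
  )
}

# hourly urine records at given ml/kg/h rates (converted to ml/h)
urine_series <- function(rates, weight = 80, t0 = 0) {
  tibble::tibble(time_h = t0 + seq_along(rates) - 1, value = rates * weight)
}
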