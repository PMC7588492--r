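#' Baseline serum creatinine for an admission
#'
#' The reference value against which the postoperative doubling criterion
#' is judged: the last creatinine measured within the five days before the
#' start of surgery. If no value exists in that lookback, the first value
#' after the end of surgery is used instead (and flagged).
#'
#' @param creatinine data frame with columns `time_h`, `value` (mg/dl),
#'   times in hours from admission.
#' @param surgery_start_h,surgery_end_h surgery episode bounds in hours.
#' @param lookback_h pre-operative lookback (default 120 h = 5 days).
#' @return one-row tibble: `baseline` (mg/dl), `rule`
#'   (`"preoperative"` or `"first_postoperative"`), `time_h` of the value.
#' @export
select_baseline_creatinine <- function(creatinine, surgery_start_h,
                                       surgery_end_h, lookback_h = 120) {
  if (is.null(creatinine) || nrow(creatinine) == 0) {
    abort("no creatinine values: admission must be excluded, not labeled")
  }
  pre <- creatinine %>%
    dplyr::filter(.data$time_h >= surgery_start_h - lookback_h,
                  .data$time_h < surgery_start_h) %>%
    dplyr::arrange(.data$time_h)
  if (nrow(pre) > 0) {
    last <- pre[nrow(pre), ]
    return(tibble::tibble(baseline = last$value, rule = "preoperative",
                          time_h = last$time_h))
  }
  post <- creatinine %>%
    dplyr::filter(.data$time_h >= surgery_end_h) %>%
    dplyr::arrange(.data$time_h)
  if (nrow(post) == 0) {
    abort("no creatinine value in the pre-operative lookback or after surgery")
  }
  tibble::tibble(baseline = post$value[1], rule = "first_postoperative",
                 time_h = post$time_h[1])
}

#' Creatinine criterion: earliest doubling over baseline
#'
#' Returns the earliest measurement timestamp at which serum creatinine
#' reaches at least twice the baseline, or `NA` if it never does within
#' the study period. Onset can only occur at measurement timestamps --
#' a diagnosis exists when a lab value exists; no interpolation. A stage-3
#' hint (creatinine >= 3x baseline or >= 4.0 mg/dl at onset) is recorded
#' for information only; the composite stage >= 2 label is what the
#' pipeline predicts.
#'
#' @param creatinine data frame `time_h`, `value`; pass the postoperative
#'   series (values before `study_start_h` are ignored).
#' @param baseline baseline creatinine, mg/dl (> 0).
#' @param study_end_h end of the study period in hours.
#' @param study_start_h start of eligibility (default `-Inf`).
#' @return one-row tibble `onset_h` (NA if none) and `stage_hint` (2, 3 or NA).
#' @export
detect_creatinine_onset <- function(creatinine, baseline, study_end_h,
                                    study_start_h = -Inf) {
  stopifnot(baseline > 0)
  if (is.null(creatinine) || nrow(creatinine) == 0) {
    return(tibble::tibble(onset_h = NA_real_, stage_hint = NA_integer_))
  }
  hits <- creatinine %>%
    dplyr::filter(.data$time_h >= study_start_h, .data$time_h <= study_end_h,
                  .data$value >= 2 * baseline) %>%
    dplyr::arrange(.data$time_h)
  if (nrow(hits) == 0) {
    return(tibble::tibble(onset_h = NA_real_, stage_hint = NA_integer_))
  }
  v <- hits$value[1]
  tibble::tibble(
    onset_h = hits$time_h[1],
    stage_hint = if (v >= 3 * baseline || v >= 4.0) 3L else 2L
  )
}

# Merge overlapping/touching [start, end) intervals into a disjoint union.
merge_intervals <- function(start, end, tol = 1e-9) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  out_s <- c(); out_e <- c()
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + tol) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# Piecewise-constant urine-rate coverage: record i holds from its
# timestamp until the next record, or for at most `max_carry_h` after the
# final record / across charting gaps. Returns step-function segments.
urine_segments <- function(urine, weight_kg, max_carry_h = 2) {
  u <- dplyr::arrange(urine, .data$time_h)
  t0 <- u$time_h
  t1 <- c(u$time_h[-1], u$time_h[nrow(u)] + max_carry_h)
  t1 <- pmin(t1, t0 + max_carry_h)
  tibble::tibble(start = t0, end = t1, rate = u$value / weight_kg)
}

#' Urine criterion: earliest sustained oliguria
#'
#' Implements the urine-output arm of the severe-AKI definition: a
#' decrease in urine flow below 0.5 ml/kg/h sustained for at least 12
#' hours. Flow records (ml/h as charted) are weight-normalised and held as
#' a step function between records; an onset at time t requires the step
#' rate to stay below the threshold throughout the trailing 12-h window
#' `[t - 12, t]`, AND the whole window to (a) have record coverage (no
#' charting gap longer than `max_carry_h`) and (b) lie inside locations
#' where urine charting is considered reliable (theatre, recovery room,
#' ICU -- not the normal ward, where incomplete documentation would
#' create false positives). The earliest such t, snapped up to the 15-min
#' evaluation grid anchored at `study_start_h`, is the onset; `NA` if no
#' window qualifies. A dip of any depth shorter than 12 h never fires.
#'
#' @param urine data frame `time_h`, `value` (ml/h as recorded).
#' @param weight_kg admission body weight.
#' @param locations data frame `start_h`, `end_h`, `location` with
#'   locations in `c("theatre", "recovery", "icu", "ward")`.
#' @param study_end_h latest admissible onset.
#' @param study_start_h earliest admissible onset (the trailing window may
#'   extend before it, e.g. into theatre time).
#' @param threshold oliguria threshold, ml/kg/h (default 0.5).
#' @param window_h sustained-episode length (default 12 h).
#' @param step_h evaluation grid (default 0.25 h).
#' @param max_carry_h maximum carry-forward of one record (default 2 h).
#' @return one-row tibble `onset_h` (NA if none).
#' @export
detect_urine_onset <- function(urine, weight_kg, locations, study_end_h,
                               study_start_h = 0, threshold = 0.5,
                               window_h = 12, step_h = 0.25,
                               max_carry_h = 2) {
  stopifnot(weight_kg > 0)
  reliable <- locations %>%
    dplyr::filter(.data$location %in% c("theatre", "recovery", "icu")) %>%
    dplyr::arrange(.data$start_h)
  if (is.null(urine) || nrow(urine) == 0 || nrow(reliable) == 0) {
    return(tibble::tibble(onset_h = NA_real_))
  }
  seg <- urine_segments(urine, weight_kg, max_carry_h)
  # maximal runs where the step rate stays below threshold without a
  # coverage break (consecutive segments are contiguous iff end == next
  # start; urine_segments already caps carry at max_carry_h)
  low <- seg$rate < threshold
  if (!any(low)) return(tibble::tibble(onset_h = NA_real_))
  contiguous <- c(FALSE, abs(seg$start[-1] - seg$end[-nrow(seg)]) < 1e-9)
  run_id <- cumsum(!(low & contiguous & c(FALSE, low[-length(low)])))
  runs <- tibble::tibble(start = seg$start, end = seg$end,
                         low = low, run = run_id) %>%
    dplyr::filter(.data$low) %>%
    dplyr::group_by(.data$run) %>%
    dplyr::summarise(a = min(.data$start), b = max(.data$end),
                     .groups = "drop")
  if (nrow(runs) == 0) return(tibble::tibble(onset_h = NA_real_))
  # merge touching reliable segments (theatre -> recovery -> icu are
  # typically contiguous) so windows may span their boundaries
  reliable <- merge_intervals(reliable$start_h, reliable$end_h)
  onset <- Inf
  for (i in seq_len(nrow(runs))) {
    lo <- pmax(runs$a[i], reliable$start)
    hi <- pmin(runs$b[i], reliable$end)
    keep <- hi - lo >= window_h
    for (j in which(keep)) {
      # earliest admissible window end inside [lo + 12, hi]
      t_min <- max(lo[j] + window_h, study_start_h)
      t <- study_start_h +
        ceiling((t_min - study_start_h) / step_h - 1e-9) * step_h
      if (t <= min(hi[j], study_end_h)) onset <- min(onset, t)
    }
  }
  tibble::tibble(onset_h = if (is.finite(onset)) onset else NA_real_)
}

#' Label one admission against the severe-AKI (stage 2/3) definition
#'
#' Applies both criteria over the 7-day study period after the end of the
#' first surgery: creatinine doubling over baseline, and sustained
#' oliguria (< 0.5 ml/kg/h for >= 12 h in reliable locations). The global
#' label is positive if either criterion fires at any point within the
#' study period; the onset is the earlier of the two criterion onsets.
#' Admissions hitting an exclusion rule (age < 18, dialysis before the end
#' of surgery, baseline creatinine >= 4.0 mg/dl, no creatinine and no
#' urine values) are signalled as excluded -- distinct from a negative
#' label -- with a reason code, and must never reach training.
#'
#' @param static one-row data frame of admission statics (`admission_id`,
#'   `age`, `weight_kg`, `surgery_start_h`, `surgery_end_h`,
#'   `discharge_h`, `dialysis_before_surgery_end`).
#' @param events long data frame (`channel`, `time_h`, `value`) for this
#'   admission; channels `creatinine` and `urine_flow` are used.
#' @param locations care-location segments for this admission.
#' @param study_period_h study-period length (default 168 h = 7 days).
#' @return one-row tibble: `admission_id`, `excluded`, `exclusion_reason`,
#'   `label`, `criterion` (`"creatinine"`, `"urine"`, `"both"`, `"none"`),
#'   `creatinine_onset_h`, `urine_onset_h`, `onset_h`, `baseline`,
#'   `baseline_rule`, `diagnosis_delay_h`, `stage_hint`.
#' @export
label_admission <- function(static, events, locations, study_period_h = 168) {
  id <- static$admission_id[1]
  excluded <- function(reason) tibble::tibble(
    admission_id = id, excluded = TRUE, exclusion_reason = reason,
    label = NA_integer_, criterion = NA_character_,
    creatinine_onset_h = NA_real_, urine_onset_h = NA_real_,
    onset_h = NA_real_, baseline = NA_real_, baseline_rule = NA_character_,
    diagnosis_delay_h = NA_real_, stage_hint = NA_integer_
  )
  if (!is.na(static$age[1]) && static$age[1] < 18) return(excluded("minor"))
  if (isTRUE(static$dialysis_before_surgery_end[1])) {
    return(excluded("pre-existing dialysis"))
  }
  creat <- dplyr::filter(events, .data$channel == "creatinine")
  urine <- dplyr::filter(events, .data$channel == "urine_flow")
  if (nrow(creat) == 0 && nrow(urine) == 0) {
    return(excluded("no creatinine or urine flow values"))
  }
  s_start <- static$surgery_start_h[1]
  s_end <- static$surgery_end_h[1]
  study_end <- s_end + study_period_h
  bl <- if (nrow(creat) > 0) {
    select_baseline_creatinine(creat, s_start, s_end)
  } else {
    tibble::tibble(baseline = NA_real_, rule = NA_character_, time_h = NA_real_)
  }
  if (!is.na(bl$baseline) && bl$baseline >= 4.0) {
    return(excluded("baseline creatinine >= 4.0 mg/dl"))
  }
  cr <- if (nrow(creat) > 0 && !is.na(bl$baseline)) {
    detect_creatinine_onset(creat, bl$baseline, study_end, study_start_h = s_end)
  } else {
    tibble::tibble(onset_h = NA_real_, stage_hint = NA_integer_)
  }
  ur <- detect_urine_onset(urine, static$weight_kg[1], locations, study_end,
                           study_start_h = s_end)
  onsets <- c(creatinine = cr$onset_h, urine = ur$onset_h)
  have <- !is.na(onsets)
  criterion <- if (all(have)) "both" else if (have["creatinine"]) "creatinine"
  else if (have["urine"]) "urine" else "none"
  onset <- if (any(have)) min(onsets[have]) else NA_real_
  tibble::tibble(
    admission_id = id, excluded = FALSE, exclusion_reason = NA_character_,
    label = as.integer(!is.na(onset)), criterion = criterion,
    creatinine_onset_h = cr$onset_h, urine_onset_h = ur$onset_h,
    onset_h = onset, baseline = bl$baseline, baseline_rule = bl$rule,
    diagnosis_delay_h = if (criterion == "both") abs(cr$onset_h - ur$onset_h)
                        else NA_real_,
    stage_hint = cr$stage_hint
  )
}

#' Label every admission of a cohort
#'
#' Vectorised wrapper around [label_admission()] over a synthetic cohort
#' object (see [generate_cohort()]) or any list with `static`, `events`
#' and `locations` tibbles keyed by `admission_id`.
#'
#' @param cohort a cohort object.
#' @param study_period_h study period (default 168 h).
#' @return tibble of per-admission labels (one row each).
#' @export
label_cohort <- function(cohort, study_period_h = 168) {
  ids <- cohort$static$admission_id
  ev <- split(cohort$events, factor(cohort$events$admission_id, levels = ids))
  loc <- split(cohort$locations,
               factor(cohort$locations$admission_id, levels = ids))
  purrr::map_dfr(seq_along(ids), function(i) {
    label_admission(cohort$static[i, ],
                    ev[[i]] %||% cohort$events[0, ],
                    loc[[i]] %||% cohort$locations[0, ],
                    study_period_h = study_period_h)
  })
}

#' Observation window of an admission
#'
#' The span over which the model observes and predicts: from the first
#' transfer to ICU or recovery room after the end of the first surgery,
#' until discharge, AKI onset, or 7 days after surgery end -- whichever
#' comes first. AKI patients' windows therefore end exactly at onset: no
#' post-onset data are ever visible downstream.
#'
#' @param static one-row admission statics (needs `discharge_h`,
#'   `surgery_end_h`).
#' @param locations care-location segments.
#' @param label one-row label tibble from [label_admission()].
#' @param study_period_h cap after surgery end (default 168 h).
#' @return one-row tibble `admission_id`, `start_h`, `end_h`, `length_h`.
#' @export
build_observation_window <- function(static, locations, label,
                                     study_period_h = 168) {
  s_end <- static$surgery_end_h[1]
  post <- locations %>%
    dplyr::filter(.data$location %in% c("icu", "recovery"),
                  .data$end_h > s_end) %>%
    dplyr::arrange(.data$start_h)
  if (nrow(post) == 0) {
    abort(sprintf("admission %s: no ICU/recovery segment after surgery",
                  static$admission_id[1]))
  }
  start <- max(post$start_h[1], s_end)
  end <- min(static$discharge_h[1],
             if (!is.na(label$onset_h[1])) label$onset_h[1] else Inf,
             s_end + study_period_h)
  if (end <= start) {
    abort(sprintf("admission %s: empty observation window",
                  static$admission_id[1]))
  }
  tibble::tibble(admission_id = static$admission_id[1], start_h = start,
                 end_h = end, length_h = end - start)
}

#' Observation windows for a labeled cohort
#'
#' @param cohort cohort object.
#' @param labels label tibble from [label_cohort()]; excluded admissions
#'   are skipped.
#' @inheritParams build_observation_window
#' @return tibble of windows, one row per non-excluded admission.
#' @export
build_observation_windows <- function(cohort, labels, study_period_h = 168) {
  keep <- labels$admission_id[!labels$excluded]
  purrr::map_dfr(keep, function(id) {
    build_observation_window(
      dplyr::filter(cohort$static, .data$admission_id == id),
      dplyr::filter(cohort$locations, .data$admission_id == id),
      dplyr::filter(labels, .data$admission_id == id),
      study_period_h = study_period_h
    )
  })
}

#' Match controls to cases on observation length
#'
#' Builds a balanced case-control set by 1:1 greedy nearest-neighbour
#' matching on observation-window length, without replacement. Cases are
#' processed in descending length (longest first, since long controls are
#' scarce), ties broken by `admission_id`; each case takes the unused
#' control with the smallest absolute length difference (ties again by
#' `admission_id`).
#'
#' @param cases,controls data frames with `admission_id` and `length_h`.
#' @return object of class `aki_matched_cohort`: tibble with `pair_id`,
#'   `case_id`, `control_id`, `case_length_h`, `control_length_h`,
#'   `delta_h`.
#' @export
match_cases_controls <- function(cases, controls) {
  if (nrow(controls) < nrow(cases)) {
    abort("need at least as many controls as cases for 1:1 matching")
  }
  cases <- dplyr::arrange(cases, dplyr::desc(.data$length_h),
                          .data$admission_id)
  avail <- dplyr::arrange(controls, .data$admission_id)
  used <- rep(FALSE, nrow(avail))
  out <- purrr::map_dfr(seq_len(nrow(cases)), function(i) {
    d <- abs(avail$length_h - cases$length_h[i])
    d[used] <- Inf
    j <- which.min(d)  # first index on ties = smallest admission_id
    used[j] <<- TRUE
    tibble::tibble(
      pair_id = i,
      case_id = cases$admission_id[i], control_id = avail$admission_id[j],
      case_length_h = cases$length_h[i], control_length_h = avail$length_h[j],
      delta_h = d[j]
    )
  })
  class(out) <- c("aki_matched_cohort", class(out))
  out
}

#' Criterion-mix summary of a labeled cohort
#'
#' Among AKI cases: the fractions diagnosed by creatinine only, urine
#' only, or both, the urine-involved fraction (urine-only plus both), and
#' the median/IQR of the diagnosis delay (the absolute gap between the two
#' criterion onsets) among patients meeting both. The urine-only fraction
#' is the share of cases that would be missed entirely by a
#' creatinine-only definition; the delay quantifies how much later the
#' creatinine criterion fires when both eventually do.
#'
#' @param labels label tibble from [label_cohort()].
#' @return one-row tibble of counts, fractions and delay quantiles.
#' @export
summarize_cohort_labels <- function(labels) {
  if (nrow(labels) == 0) abort("no labels supplied")
  aki <- dplyr::filter(labels, !.data$excluded, .data$label == 1)
  n_aki <- nrow(aki)
  if (n_aki == 0) {
    warn("no AKI cases: criterion fractions are undefined")
    return(tibble::tibble(
      n = nrow(labels), n_aki = 0L, frac_creatinine_only = NA_real_,
      frac_urine_only = NA_real_, frac_both = NA_real_,
      frac_urine_involved = NA_real_, delay_median_h = NA_real_,
      delay_q25_h = NA_real_, delay_q75_h = NA_real_
    ))
  }
  delays <- aki$diagnosis_delay_h[aki$criterion == "both"]
  q <- if (length(delays)) stats::quantile(delays, c(0.25, 0.5, 0.75))
       else rep(NA_real_, 3)
  tibble::tibble(
    n = nrow(labels), n_aki = n_aki,
    frac_creatinine_only = mean(aki$criterion == "creatinine"),
    frac_urine_only = mean(aki$criterion == "urine"),
    frac_both = mean(aki$criterion == "both"),
    frac_urine_involved = mean(aki$criterion %in% c("urine", "both")),
    delay_median_h = q[[2]], delay_q25_h = q[[1]], delay_q75_h = q[[3]]
  )
}
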